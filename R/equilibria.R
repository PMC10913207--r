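# Closed-form equilibria, Jacobian, eigenvalues and stability
# classification for the adaptive PI feedback model under constant inputs
# r(t) = r, d(t) = d.
#
# E1 = (-d/b, 0)                      : feedback off, biologically infeasible
# E2 = (r, (d + b r) / (s r (1 - l))) : the tracking equilibrium (y = r)

#' Equilibrium object
#'
#' Bundles an equilibrium point of the adaptive PI model with the trace and
#' determinant of the Jacobian there, the eigenvalue pair, and a stability
#' class. Eigenvalues are ordered with the non-negative imaginary part
#' first, ties broken by decreasing real part.
#'
#' @param point Named numeric vector `(y, z)`.
#' @param tau Trace of the Jacobian at `point`.
#' @param delta Determinant of the Jacobian at `point`.
#' @param label Label, e.g. `"E1"`.
#' @return An object of class `pi_equilibrium` with fields `point`,
#'   `eigenvalues`, `tau`, `delta`, `stability_class`, `label`.
#' @export
equilibrium <- function(point, tau, delta, label = "") {
  lam <- quadratic_eigenvalues(tau, delta)
  eq <- structure(list(point = point, eigenvalues = lam, tau = tau,
                       delta = delta, stability_class = NA_character_,
                       label = label),
                  class = "pi_equilibrium")
  eq$stability_class <- classify_stability(eq)
  eq
}

# Roots of lambda^2 - tau*lambda + delta, ordered (+Im first, then
# decreasing Re). Returned as complex even when real.
quadratic_eigenvalues <- function(tau, delta) {
  disc <- as.complex(tau^2 - 4 * delta)
  lam <- c((tau + sqrt(disc)) / 2, (tau - sqrt(disc)) / 2)
  lam[order(-Im(lam), -Re(lam))]
}

#' Equilibria of the adaptive PI model under constant inputs
#'
#' @param params An [adaptive_pi_params()] object.
#' @param r Constant reference level (positive).
#' @param d Constant disturbance level (positive).
#' @return A list with elements `E1` and `E2`, both [equilibrium()] objects.
#' @export
equilibrium_points <- function(params, r, d) {
  stopifnot(inherits(params, "adaptive_pi_params"), r > 0, d > 0)
  if (params$l == 1) {
    stop("l = 1 makes the tracking equilibrium E2 degenerate ",
         "(z2 diverges); equilibria require l != 1")
  }
  b <- params$b; s <- params$s; l <- params$l; cc <- params$c
  p1 <- c(y = -d / b, z = 0)
  E1 <- equilibrium(p1, tau = b - cc * (r + d / b),
                    delta = b * (-cc * (r + d / b)), label = "E1")
  z2 <- (d + b * r) / (s * r * (1 - l))
  E2 <- equilibrium(c(y = r, z = z2),
                    tau = (d + b * l * r) / (r * (l - 1)),
                    delta = cc * (d + b * r), label = "E2")
  list(E1 = E1, E2 = E2)
}

#' Jacobian of the adaptive PI right-hand side
#'
#' Closed form of the matrix of partial derivatives at a state `(y, z)` with
#' constant reference `r`:
#' \deqn{J = \begin{pmatrix} b - s z & s (l r - y) \\ c z & -c (r - y)
#' \end{pmatrix}.}
#'
#' @param params An [adaptive_pi_params()] object.
#' @param state Numeric vector `(y, z)`.
#' @param r Constant reference level.
#' @return A 2x2 numeric matrix.
#' @export
adaptive_pi_jacobian <- function(params, state, r) {
  stopifnot(inherits(params, "adaptive_pi_params"), length(state) == 2)
  y <- state[[1]]; z <- state[[2]]
  b <- params$b; s <- params$s; l <- params$l; cc <- params$c
  matrix(c(b - s * z, s * (l * r - y),
           cc * z, -cc * (r - y)),
         nrow = 2, byrow = TRUE)
}

#' Closed-form eigenvalues at the infeasible equilibrium E1
#'
#' At `E1 = (-d/b, 0)` the Jacobian is upper triangular, so the eigenvalues
#' are the diagonal entries `b` and `-c (d + b r) / b`: one positive, one
#' negative for any valid positive parameters, hence E1 is always a saddle.
#'
#' @inheritParams equilibrium_points
#' @return Complex vector of length 2 (ordered as in [equilibrium()]).
#' @export
eigenvalues_E1 <- function(params, r, d) {
  stopifnot(inherits(params, "adaptive_pi_params"), r > 0, d > 0)
  if (params$b == 0) stop("b = 0: eigenvalues of E1 undefined")
  lam <- as.complex(c(params$b, -params$c * (d + params$b * r) / params$b))
  lam[order(-Im(lam), -Re(lam))]
}

#' Closed-form eigenvalues at the tracking equilibrium E2
#'
#' Roots of \eqn{\lambda^2 - \tau \lambda + \delta} with
#' \eqn{\tau = (d + b l r) / (r (l - 1))} and \eqn{\delta = c (d + b r)}.
#' Neither \eqn{\tau} nor \eqn{\delta} contains `s`, so the local dynamics
#' at E2 are exactly independent of the adaptive gain scale.
#'
#' @inheritParams equilibrium_points
#' @return Complex vector of length 2 (ordered as in [equilibrium()]).
#' @export
eigenvalues_E2 <- function(params, r, d) {
  stopifnot(inherits(params, "adaptive_pi_params"), r > 0, d > 0)
  if (params$l == 1) stop("l = 1: E2 degenerate, eigenvalues undefined")
  tau <- (d + params$b * params$l * r) / (r * (params$l - 1))
  delta <- params$c * (d + params$b * r)
  quadratic_eigenvalues(tau, delta)
}

#' Classify the local stability of an equilibrium
#'
#' Based on the eigenvalue pair (equivalently the trace/determinant of the
#' Jacobian): `saddle` for real eigenvalues of opposite sign, `stable_focus`
#' for a complex pair with negative real part, `stable_node` for distinct
#' negative real eigenvalues, `degenerate_node` for a repeated negative
#' eigenvalue (discriminant zero within `disc_tol`), `unstable` otherwise.
#'
#' @param eq A [equilibrium()] object (eigenvalues populated).
#' @param disc_tol Absolute tolerance for detecting a zero discriminant.
#' @return One of `"saddle"`, `"stable_focus"`, `"stable_node"`,
#'   `"degenerate_node"`, `"unstable"`.
#' @export
classify_stability <- function(eq, disc_tol = 1e-12) {
  stopifnot(inherits(eq, "pi_equilibrium"))
  lam <- eq$eigenvalues
  disc <- eq$tau^2 - 4 * eq$delta
  if (abs(disc) <= disc_tol) {
    return(if (eq$tau < 0) "degenerate_node" else "unstable")
  }
  if (all(abs(Im(lam)) < disc_tol)) {
    re <- Re(lam)
    if (prod(re) < 0) return("saddle")
    if (all(re < 0)) return("stable_node")
    return("unstable")
  }
  if (all(Re(lam) < 0)) "stable_focus" else "unstable"
}

#' @export
print.pi_equilibrium <- function(x, ...) {
  fmt_lam <- function(l) {
    if (abs(Im(l)) < 1e-12) sprintf("%.3f", Re(l))
    else sprintf("%.3f %+.3fi", Re(l), Im(l))
  }
  cat(sprintf("%s = (%.3f, %.3f)  [%s]\n", x$label,
              x$point[1], x$point[2], x$stability_class))
  cat(sprintf("  tau = %.4f, delta = %.4f, eigenvalues = {%s, %s}\n",
              x$tau, x$delta,
              fmt_lam(x$eigenvalues[1]), fmt_lam(x$eigenvalues[2])))
  invisible(x)
}

#' Table of equilibria and eigenvalues across parameter sets
#'
#' Convenience for the reproduction workflow: computes E1 and E2 with their
#' eigenvalues and stability classes for each parameter set.
#'
#' @param param_sets Named list of [adaptive_pi_params()] objects.
#' @param r,d Constant input levels shared by all sets.
#' @return A data frame with one row per (parameter set, equilibrium).
#' @export
equilibrium_table <- function(param_sets, r, d) {
  rows <- lapply(names(param_sets), function(nm) {
    eqs <- equilibrium_points(param_sets[[nm]], r, d)
    do.call(rbind, lapply(eqs, function(e) {
      data.frame(set = nm, equilibrium = e$label,
                 y = e$point[["y"]], z = e$point[["z"]],
                 tau = e$tau, delta = e$delta,
                 lambda1_re = Re(e$eigenvalues[1]),
                 lambda1_im = Im(e$eigenvalues[1]),
                 lambda2_re = Re(e$eigenvalues[2]),
                 lambda2_im = Im(e$eigenvalues[2]),
                 stability = e$stability_class)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
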