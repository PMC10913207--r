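# P-invariance and dynamical-compensation (DC) verification.
#
# A parameter p of dx/dt = f(x, u, p), y = g(x) is P-invariant when there
# is a state transformation eta_p fixing the output coordinate
# (eta_p(x1, x2) = (alpha_p(x1, x2), x2)) that intertwines the vector
# fields:
#     f(eta_p(x), u, p) = (eta_p)_* (x) f(x, u)          (vector-field)
# where the right-hand side uses the reference system (p = 1) and
# (eta_p)_* is the Jacobian of eta_p. With the output fixed, the
# candidate alpha_p is pinned down by the output-coordinate equation; the
# remaining equation becomes two coefficient conditions (a first-order PDE
# in alpha). The adaptive PI model satisfies them for p = s (alpha = x1/s)
# and provably fails them for p = b and p = c.
#
# Coordinate frames: for p in {s, b} the hidden coordinate is the adapting
# state (x1 = z, x2 = y, output y); for p = c the roles flip (x1 = y,
# x2 = z, output z) because c multiplies the z equation.

inv_frame <- function(parameter_name) {
  switch(parameter_name,
    s = ,
    b = list(
      coords = c(x1 = "z", x2 = "y"), output = "y",
      f = function(x1, x2, r, d, pr)
        c(-pr$c * x1 * (r - x2),
          pr$b * x2 + d + pr$s * x1 * (pr$l * r - x2))),
    c = list(
      coords = c(x1 = "y", x2 = "z"), output = "z",
      f = function(x1, x2, r, d, pr)
        c(pr$b * x1 + d + pr$s * x2 * (pr$l * r - x1),
          -pr$c * x2 * (r - x1))),
    stop("unknown parameter name: ", parameter_name,
         " (expected one of 's', 'b', 'c')"))
}

set_param <- function(params, name, value) {
  params[[name]] <- value
  params
}

# Candidate alpha_p solved from the output-coordinate equation of the
# vector-field condition, plus the two coefficient conditions it must
# satisfy. Expressions are in x1, x2 and the parameter symbols.
candidate_exprs <- function(parameter_name) {
  switch(parameter_name,
    s = list(
      alpha = quote(x1 / s),
      # first-component comparison: d(alpha)/dx1 = alpha/x1, d(alpha)/dx2 = 0
      required_dx1 = quote((x1 / s) / x1),
      exclusions = "l*r - x2 != 0"),
    b = list(
      alpha = quote((x2 + s * x1 * (l * r - x2) - b * x2) /
                      (s * (l * r - x2))),
      required_dx1 = quote(((x2 + s * x1 * (l * r - x2) - b * x2) /
                              (s * (l * r - x2))) / x1),
      exclusions = "l*r - x2 != 0"),
    c = list(
      alpha = quote(((c - 1) * r + x1) / c),
      # here the first component of f carries alpha, so the requirement is a
      # ratio of the transformed to the original first component
      required_dx1 = quote((b * (((c - 1) * r + x1) / c) + d +
                              s * x2 * (l * r - (((c - 1) * r + x1) / c))) /
                             (b * x1 + d + s * x2 * (l * r - x1))),
      exclusions = "c*x2 != 0"))
}

#' Equivariance candidate and consistency verdict for a parameter
#'
#' Implements the coefficient-comparison procedure: the output-coordinate
#' equation of the vector-field condition is solved for the candidate
#' transformation `alpha_p` (closed form, valid away from the recorded
#' exclusion set), its partial derivatives are obtained by symbolic
#' differentiation, and both coefficient conditions
#' (`d(alpha)/dx1` equal to the required ratio, `d(alpha)/dx2 = 0`) are
#' verified at randomly sampled states. For `s` the candidate
#' `alpha = x1/s` satisfies both conditions identically; for `b` and `c` no
#' candidate in this ansatz does, and the violated conditions are reported.
#'
#' @param parameter_name One of `"s"`, `"b"`, `"c"`.
#' @param params An [adaptive_pi_params()] object supplying the non-varied
#'   parameter values (default: baseline scenario).
#' @param p_values Values of the varied parameter at which consistency is
#'   probed.
#' @param n_states Number of random states per probe.
#' @param tol Absolute tolerance below which a condition residual counts as
#'   identically zero.
#' @param seed Seed for the random states.
#' @return An object of class `equivariance_candidate` with fields
#'   `parameter_name`, `coords`, `alpha`, `d_alpha_dx1`, `d_alpha_dx2`
#'   (expressions), `initial_condition_map`, `exclusions`, `consistent`,
#'   `violated_conditions`, and `condition_residuals` (max abs residual per
#'   condition).
#' @export
equivariance_consistency <- function(parameter_name,
                                     params = baseline_scenario()$params,
                                     p_values = c(0.25, 0.5, 1.5, 2, 4),
                                     n_states = 50, tol = 1e-9,
                                     seed = 42L) {
  frame <- inv_frame(parameter_name)
  ce <- candidate_exprs(parameter_name)
  d1 <- stats::D(ce$alpha, "x1")
  d2 <- stats::D(ce$alpha, "x2")

  # sampled states stay bounded away from the candidate's exclusion set
  # (l*r - x2 = 0 resp. the vanishing first component): with l near 0.7 and
  # r >= 10, x2 <= 4 keeps l*r - x2 >= 3, and x1 <= 5 keeps the c-frame
  # first component strictly positive
  samp <- with_seed(seed, {
    data.frame(x1 = stats::runif(n_states, 0.5, 5),
               x2 = stats::runif(n_states, 0.5, 4),
               r = stats::runif(n_states, 10, 14),
               d = stats::runif(n_states, 0.01, 2))
  })
  res1 <- res2 <- 0
  for (p in p_values) {
    pr <- set_param(unclass(params), parameter_name, p)
    env <- c(as.list(samp), pr)
    req1 <- eval(ce$required_dx1, env)
    res1 <- max(res1, max(abs(eval(d1, env) - req1)))
    res2 <- max(res2, max(abs(eval(d2, env) - 0)))
  }
  residuals <- c(dalpha_dx1_matches_ratio = res1, dalpha_dx2_zero = res2)
  violated <- names(residuals)[residuals > tol]
  structure(list(parameter_name = parameter_name,
                 coords = frame$coords, output = frame$output,
                 alpha = ce$alpha, d_alpha_dx1 = d1, d_alpha_dx2 = d2,
                 initial_condition_map = ce$alpha,
                 exclusions = ce$exclusions,
                 consistent = length(violated) == 0,
                 violated_conditions = violated,
                 condition_residuals = residuals),
            class = "equivariance_candidate")
}

#' @export
print.equivariance_candidate <- function(x, ...) {
  cat(sprintf("equivariance candidate for '%s' (coords x1 = %s, x2 = %s; output %s)\n",
              x$parameter_name, x$coords[["x1"]], x$coords[["x2"]],
              x$output))
  cat("  alpha =", deparse(x$alpha), "\n")
  cat("  consistent:", x$consistent, "\n")
  if (!x$consistent) {
    cat("  violated:", paste(x$violated_conditions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Numeric residual of the vector-field (equivariance) condition
#'
#' Evaluates both components of
#' `f(eta_p(x), u, p) - (eta_p)_*(x) f(x, u)` at a state, with the
#' reference system taken at parameter value 1. For the consistent
#' `s`-candidate the residual vanishes to machine precision; for the `b`
#' and `c` candidates it does not.
#'
#' @param candidate An [equivariance_consistency()] object.
#' @param state Numeric `(x1, x2)` in the candidate's coordinate frame.
#' @param r,d Input levels at which the condition is evaluated.
#' @param p_value Value of the varied parameter.
#' @param params Non-varied parameter values.
#' @return Numeric vector of length 2 (componentwise residual).
#' @export
equivariance_residual <- function(candidate, state, r, d, p_value,
                                  params = baseline_scenario()$params) {
  stopifnot(inherits(candidate, "equivariance_candidate"),
            length(state) == 2)
  pn <- candidate$parameter_name
  frame <- inv_frame(pn)
  pr_p <- set_param(unclass(params), pn, p_value)
  pr_ref <- set_param(unclass(params), pn, 1)
  env <- c(list(x1 = state[[1]], x2 = state[[2]], r = r, d = d), pr_p)
  a <- eval(candidate$alpha, env)
  if (!is.finite(a)) {
    stop("alpha undefined at this state/parameter (division by zero)")
  }
  j11 <- eval(candidate$d_alpha_dx1, env)
  j12 <- eval(candidate$d_alpha_dx2, env)
  f_ref <- frame$f(state[[1]], state[[2]], r, d, pr_ref)
  f_trans <- frame$f(a, state[[2]], r, d, pr_p)
  f_trans - c(j11 * f_ref[1] + j12 * f_ref[2], f_ref[2])
}

# ---- DC state rescalings -------------------------------------------------

# Scale factors (v1, v2) = (a1 * x1, a2 * x2) in the (x1 = z, x2 = y)
# frame, and the closed-form transformed right-hand sides.
rescaling_spec <- function(parameter_name) {
  switch(parameter_name,
    s = list(a1 = quote(s), a2 = quote(1),
             rhs = list(quote(-c * v1 * (r - v2)),
                        quote(b * v2 + d + v1 * (l * r - v2)))),
    b = list(a1 = quote(1), a2 = quote(b),
             rhs = list(quote(-c * v1 * (r - v2 / b)),
                        quote(b * v2 + b * d +
                                b * s * v1 * (l * r - v2 / b)))),
    c = list(a1 = quote(c), a2 = quote(1),
             rhs = list(quote(-c * v1 * (r - v2)),
                        quote(b * v2 + d + (s / c) * v1 * (l * r - v2)))),
    stop("unknown parameter name: ", parameter_name))
}

#' DC state rescaling for a parameter
#'
#' The DC route to compensation: rescale the hidden state,
#' `(v1, v2) = (a1 x1, a2 x2)` in the `(x1 = z, x2 = y)` frame with the
#' output `y = v2` unchanged, and ask whether the rescaled system no longer
#' contains the parameter (so it can be set to 1 without loss). The
#' transformed right-hand side is verified numerically against the original
#' right-hand side composed with the scaling, and parameter elimination is
#' decided by probing whether the transformed field depends on the
#' parameter value. For `s` (with `v1 = s x1`) the parameter is eliminated;
#' the analogous rescalings for `b` and `c` leave the parameter in the
#' field.
#'
#' @param parameter_name One of `"s"`, `"b"`, `"c"`.
#' @param params Non-varied parameter values.
#' @param p_values Two or more parameter values used for the dependence
#'   probe.
#' @param n_states Random states per check.
#' @param tol Tolerance for "identical" fields.
#' @param seed Seed for the random states.
#' @return An object of class `dc_rescaling`: `parameter_name`, `scaling`
#'   (expressions for the two scale factors), `transformed_rhs`
#'   (expressions in `v1, v2`), `composition_residual` (max abs mismatch
#'   between the stated transformed field and the composed original field),
#'   `parameter_eliminated` (logical).
#' @export
dc_rescaling <- function(parameter_name,
                         params = baseline_scenario()$params,
                         p_values = c(0.25, 0.5, 1.5, 2, 4),
                         n_states = 50, tol = 1e-9, seed = 42L) {
  spec <- rescaling_spec(parameter_name)
  frame <- inv_frame("s")  # (x1 = z, x2 = y) frame for all three scalings
  samp <- with_seed(seed, {
    data.frame(v1 = stats::runif(n_states, 0.5, 10),
               v2 = stats::runif(n_states, 0.5, 6),
               r = stats::runif(n_states, 8, 14),
               d = stats::runif(n_states, 0.01, 2))
  })
  eval_rhs <- function(p) {
    pr <- set_param(unclass(params), parameter_name, p)
    env <- c(as.list(samp), pr)
    a1 <- eval(spec$a1, pr); a2 <- eval(spec$a2, pr)
    stated <- cbind(eval(spec$rhs[[1]], env), eval(spec$rhs[[2]], env))
    # compose: vdot = (a1 f1(v1/a1, v2/a2), a2 f2(v1/a1, v2/a2))
    composed <- t(mapply(function(v1, v2, r, d) {
      f <- frame$f(v1 / a1, v2 / a2, r, d, pr)
      c(a1 * f[1], a2 * f[2])
    }, samp$v1, samp$v2, samp$r, samp$d))
    list(stated = stated, composed = composed)
  }
  fields <- lapply(p_values, eval_rhs)
  comp_res <- max(vapply(fields, function(fl)
    max(abs(fl$stated - fl$composed)), numeric(1)))
  spread <- 0
  for (i in seq_along(fields)[-1]) {
    spread <- max(spread,
                  max(abs(fields[[i]]$stated - fields[[1]]$stated)))
  }
  structure(list(parameter_name = parameter_name,
                 scaling = list(v1 = spec$a1, v2 = spec$a2),
                 transformed_rhs = spec$rhs,
                 composition_residual = comp_res,
                 parameter_dependence = spread,
                 parameter_eliminated = spread < tol),
            class = "dc_rescaling")
}

#' @export
print.dc_rescaling <- function(x, ...) {
  cat(sprintf("DC rescaling for '%s': v1 = %s * x1, v2 = %s * x2\n",
              x$parameter_name, deparse(x$scaling$v1),
              deparse(x$scaling$v2)))
  cat("  dv1/dt =", deparse(x$transformed_rhs[[1]]), "\n")
  cat("  dv2/dt =", deparse(x$transformed_rhs[[2]]), "\n")
  cat(sprintf("  parameter eliminated: %s (dependence %.2e)\n",
              x$parameter_eliminated, x$parameter_dependence))
  invisible(x)
}

# ---- paired-simulation output-invariance experiments ---------------------

#' Paired-simulation output-invariance test
#'
#' Runs the model twice with the parameter at `p1` and `p2`, identical
#' step-and-noise input schedules (shared seed, so both runs see bit-equal
#' noise), and compares the output `y(t)`. Two protocols:
#' \describe{
#'   \item{`strict`}{the second run starts from the equivariance image of
#'     the first run's initial state (for `s`: `z(0)` scaled by `p1/p2`);
#'     the difference is assessed over the full span. This is the
#'     P-invariance statement.}
#'   \item{`dc_after_adaptation`}{both runs start from the same state; the
#'     difference is assessed only after `adaptation_start`, once the
#'     adapting state has converged. This is the DC statement.}
#' }
#'
#' @param parameter_name One of `"s"`, `"b"`, `"c"`.
#' @param p1,p2 The two parameter values.
#' @param protocol `"strict"` or `"dc_after_adaptation"`.
#' @param shared_seed Seed of the shared input schedule.
#' @param threshold Invariance threshold on `max |dy|`; defaults to `1e-5`
#'   (strict) or `1e-3` (after adaptation).
#' @param x0 Initial state `(y, z)` of the first run.
#' @param t_span Integration span.
#' @param adaptation_start Start of the assessed window for
#'   `dc_after_adaptation`.
#' @param scenario Baseline scenario ([baseline_scenario()]) providing the
#'   non-varied parameters and starting input levels.
#' @param signals Optional pre-built schedule (list with `r`, `d`) for the
#'   first run; built with [make_step_schedule()] from `shared_seed` if
#'   omitted.
#' @param signals2 Optional schedule for the second run; must carry the
#'   same seeds as `signals` (paired runs must share the noise), otherwise
#'   an error is raised. Defaults to `signals`.
#' @param grid_step,rtol,atol Passed to [integrate_model()].
#' @return An object of class `invariance_report`: `parameter_name`,
#'   `value_pair`, `protocol`, `max_abs_output_diff`,
#'   `terminal_abs_output_diff`, `adaptation_window`, `threshold`,
#'   `verdict` (`"invariant"` or `"not_invariant"`), and the `times` / `dy`
#'   series.
#' @export
paired_output_test <- function(parameter_name, p1, p2,
                               protocol = c("strict",
                                            "dc_after_adaptation"),
                               shared_seed = 1L, threshold = NULL,
                               x0 = c(y = 8, z = 2), t_span = c(0, 400),
                               adaptation_start = 40,
                               scenario = baseline_scenario(),
                               signals = NULL, signals2 = NULL,
                               grid_step = 0.01, rtol = 1e-8,
                               atol = 1e-10) {
  protocol <- match.arg(protocol)
  if (!parameter_name %in% c("s", "b", "c")) {
    stop("unknown parameter name: ", parameter_name)
  }
  if (is.null(threshold)) {
    threshold <- if (protocol == "strict") 1e-5 else 1e-3
  }
  if (is.null(signals)) {
    signals <- make_step_schedule(r0 = scenario$r0, d0 = scenario$d0,
                                  seed = shared_seed)
  }
  if (is.null(signals2)) signals2 <- signals
  if (!identical(c(signals$r$seed, signals$d$seed),
                 c(signals2$r$seed, signals2$d$seed))) {
    stop("paired runs must share the noise realisation: ",
         "signal seeds differ between the two runs")
  }
  base <- unclass(scenario$params)
  params1 <- do.call(adaptive_pi_params, set_param(base, parameter_name, p1))
  params2 <- do.call(adaptive_pi_params, set_param(base, parameter_name, p2))

  x0_2 <- x0
  if (protocol == "strict" && parameter_name == "s") {
    # equivariance image: s z is the invariant gain, so z(0) scales by p1/p2
    x0_2[["z"]] <- x0[["z"]] * p1 / p2
  }
  tr1 <- integrate_model("adaptive_pi", params1, x0,
                         inputs = list(r = signals$r, d = signals$d),
                         t_span = t_span, grid_step = grid_step,
                         rtol = rtol, atol = atol)
  tr2 <- integrate_model("adaptive_pi", params2, x0_2,
                         inputs = list(r = signals2$r, d = signals2$d),
                         t_span = t_span, grid_step = grid_step,
                         rtol = rtol, atol = atol)
  stopifnot(identical(tr1$times, tr2$times))
  dy <- tr1$output - tr2$output
  window <- if (protocol == "strict") c(t_span[1], t_span[2])
            else c(adaptation_start, t_span[2])
  in_win <- tr1$times >= window[1] & tr1$times <= window[2]
  max_diff <- max(abs(dy[in_win]))
  structure(list(parameter_name = parameter_name,
                 value_pair = c(p1, p2), protocol = protocol,
                 max_abs_output_diff = max_diff,
                 terminal_abs_output_diff = abs(dy[length(dy)]),
                 adaptation_window = window, threshold = threshold,
                 verdict = if (max_diff < threshold) "invariant"
                           else "not_invariant",
                 shared_seed = as.integer(shared_seed),
                 times = tr1$times, dy = dy,
                 y1 = tr1$output, y2 = tr2$output,
                 z1 = tr1$states[, "z"], z2 = tr2$states[, "z"]),
            class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  cat(sprintf("paired output test: %s = %g vs %g, protocol %s\n",
              x$parameter_name, x$value_pair[1], x$value_pair[2],
              x$protocol))
  cat(sprintf("  max |dy| over [%g, %g] = %.3e (threshold %.0e)\n",
              x$adaptation_window[1], x$adaptation_window[2],
              x$max_abs_output_diff, x$threshold))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Write an invariance report as JSON plus a difference-series CSV
#'
#' @param report An [paired_output_test()] report.
#' @param json_path Path of the JSON summary.
#' @param csv_path Optional path of the `(t, dy)` CSV series; skipped if
#'   `NULL`.
#' @param thin Keep every `thin`-th sample in the CSV.
#' @return `json_path`, invisibly.
#' @export
invariance_report_to_files <- function(report, json_path, csv_path = NULL,
                                       thin = 10L) {
  stopifnot(inherits(report, "invariance_report"))
  summary <- report[c("parameter_name", "value_pair", "protocol",
                      "max_abs_output_diff", "terminal_abs_output_diff",
                      "adaptation_window", "threshold", "verdict",
                      "shared_seed")]
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    keep <- seq(1, length(report$times), by = thin)
    utils::write.csv(data.frame(t = report$times[keep],
                                dy = report$dy[keep]),
                     csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
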