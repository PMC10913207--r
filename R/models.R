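# Model definitions: parameter constructors and right-hand sides for the
# three ODE systems under study.
#
# State ordering convention (fixed across the whole package):
#   * adaptive PI model and simplified model: (y, z)
#   * three-state hormonal circuit:           (y, x, z)
# y is always the regulated output; z is the adapting (feedback) state.

#' Parameters of the three-state hormonal circuit model
#'
#' The circuit couples a regulated variable `y` to a hormone `x` secreted by
#' tissue of functional mass `z`:
#' \deqn{dy/dt = u_0 + u(t) - s x y, \quad dx/dt = p z y - x, \quad
#'       dz/dt = z (y - y_0).}
#'
#' @param s Feedback gain of `x` (positive).
#' @param p Feedback gain of `z` (positive).
#' @param u0 Basal input rate (non-negative).
#' @param y0 Output set-point (positive).
#' @return An object of class `karin_params`.
#' @export
karin_params <- function(s, p, u0 = 0, y0 = 1) {
  stopifnot(is.numeric(s), s > 0, is.numeric(p), p > 0,
            is.numeric(u0), u0 >= 0, is.numeric(y0), y0 > 0)
  structure(list(s = s, p = p, u0 = u0, y0 = y0), class = "karin_params")
}

#' Parameters of the simplified two-state model
#'
#' \deqn{dy/dt = u_0 + u(t) - s z y, \quad dz/dt = z (y - y_0).}
#' The product `s z` acts as a single effective gain, which is what makes the
#' output invariant to `s` after the rescaling `z -> s z`.
#'
#' @param s Feedback gain (positive).
#' @param u0 Basal input rate (non-negative).
#' @param y0 Output set-point (positive).
#' @return An object of class `simplified_params`.
#' @export
simplified_params <- function(s, u0 = 0, y0 = 1) {
  stopifnot(is.numeric(s), s > 0, is.numeric(u0), u0 >= 0,
            is.numeric(y0), y0 > 0)
  structure(list(s = s, u0 = u0, y0 = y0), class = "simplified_params")
}

#' Parameters of the adaptive proportional-integral feedback model
#'
#' The core system of the package: an open-loop exponential growth
#' `dy/dt = b y` closed by an adaptive PI feedback with time-varying gain
#' `s z(t)`:
#' \deqn{dy/dt = b y + d(t) + s z (l r(t) - y), \quad
#'       dz/dt = -c z (r(t) - y).}
#' `r(t)` is the reference the output tracks, `d(t)` an additive disturbance,
#' `l` scales the proportional error and `c` is the adaptation rate.
#' Local stability of the tracking equilibrium requires `0 < l < 1`;
#' values `l >= 1` are permitted for model evaluation but flagged with a
#' warning.
#'
#' @param b Open-loop growth rate (positive).
#' @param s Adaptive gain scale (positive).
#' @param l Reference scaling of the proportional error, in (0, 1) for the
#'   stable regime.
#' @param c Adaptation rate (positive).
#' @return An object of class `adaptive_pi_params`.
#' @export
adaptive_pi_params <- function(b, s, l, c) {
  stopifnot(is.numeric(b), b > 0, is.numeric(s), s > 0,
            is.numeric(l), l > 0, is.numeric(c), c > 0)
  if (l >= 1) {
    warning("l >= 1 lies outside the stable tracking regime (0 < l < 1); ",
            "model evaluation proceeds but equilibrium E2 may be ",
            "degenerate or unstable")
  }
  structure(list(b = b, s = s, l = l, c = c), class = "adaptive_pi_params")
}

#' Baseline parameter set of the numerical experiments
#'
#' The reference scenario used throughout: `b = 0.3`, `s = 0.25`, `l = 0.7`,
#' `c = 2`, with starting inputs `r = 11`, `d = 0.01`.
#'
#' @return A list with elements `params` (an [adaptive_pi_params()] object),
#'   `r0` and `d0` (the starting constant input levels).
#' @export
baseline_scenario <- function() {
  list(params = adaptive_pi_params(b = 0.3, s = 0.25, l = 0.7, c = 2),
       r0 = 11, d0 = 0.01)
}

# Coerce a constant or function to a callable signal f(t).
as_signal <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "piecewise_signal")) return(function(t) signal_value(x, t))
  if (is.numeric(x) && length(x) == 1L) return(function(t) rep(x, length(t)))
  stop("signal must be a single number, a function of time, ",
       "or a piecewise_signal")
}

check_state <- function(state, n, model) {
  if (length(state) != n) {
    stop(sprintf("%s expects a state of length %d, got %d",
                 model, n, length(state)))
  }
  invisible(state)
}

#' Right-hand side of the three-state hormonal circuit
#'
#' @param state Numeric vector `(y, x, z)`.
#' @param t Time at which input signals are evaluated.
#' @param params A [karin_params()] object.
#' @param u Input signal: a constant, a function of time, or a
#'   [piecewise_signal()].
#' @return Numeric vector `(dy/dt, dx/dt, dz/dt)`.
#' @export
karin_rhs <- function(state, t, params, u = 0) {
  stopifnot(inherits(params, "karin_params"))
  check_state(state, 3L, "karin_rhs")
  uf <- as_signal(u)
  y <- state[[1]]; x <- state[[2]]; z <- state[[3]]
  c(params$u0 + uf(t) - params$s * x * y,
    params$p * z * y - x,
    z * (y - params$y0))
}

#' Right-hand side of the simplified two-state model
#'
#' @param state Numeric vector `(y, z)`.
#' @param t Time at which the input signal is evaluated.
#' @param params A [simplified_params()] object.
#' @param u Input signal: a constant, a function of time, or a
#'   [piecewise_signal()].
#' @return Numeric vector `(dy/dt, dz/dt)`.
#' @export
simplified_rhs <- function(state, t, params, u = 0) {
  stopifnot(inherits(params, "simplified_params"))
  check_state(state, 2L, "simplified_rhs")
  uf <- as_signal(u)
  y <- state[[1]]; z <- state[[2]]
  c(params$u0 + uf(t) - params$s * z * y,
    z * (y - params$y0))
}

#' Right-hand side of the adaptive PI feedback model
#'
#' @param state Numeric vector `(y, z)`.
#' @param t Time at which the signals are evaluated.
#' @param params An [adaptive_pi_params()] object.
#' @param r Reference signal: a constant, a function of time, or a
#'   [piecewise_signal()].
#' @param d Disturbance signal, same forms as `r`.
#' @return Numeric vector `(dy/dt, dz/dt)`.
#' @export
adaptive_pi_rhs <- function(state, t, params, r, d) {
  stopifnot(inherits(params, "adaptive_pi_params"))
  check_state(state, 2L, "adaptive_pi_rhs")
  rf <- as_signal(r); df <- as_signal(d)
  y <- state[[1]]; z <- state[[2]]
  rt <- rf(t); dt_ <- df(t)
  c(params$b * y + dt_ + params$s * z * (params$l * rt - y),
    -params$c * z * (rt - y))
}

#' Check post-hoc positivity of a trajectory's states
#'
#' The model's biological interpretation assumes `y`, `z` and `r` stay
#' positive; integration does not clip negative excursions, so this helper
#' flags them after the fact.
#'
#' @param traj A trajectory as returned by [integrate_model()].
#' @return Logical: `TRUE` if all state components stayed non-negative.
#' @export
positivity_ok <- function(traj) {
  stopifnot(inherits(traj, "pi_trajectory"))
  all(traj$states >= 0)
}

#' Write model parameters to a YAML file
#'
#' Parameter names in the file are exactly `b, s, l, c, u0, y0, p` as
#' applicable to the parameter class.
#'
#' @param params A parameter object
#'   ([adaptive_pi_params()], [simplified_params()] or [karin_params()]).
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
params_to_yaml <- function(params, path) {
  cls <- class(params)[1]
  stopifnot(cls %in% c("adaptive_pi_params", "simplified_params",
                       "karin_params"))
  yaml::write_yaml(c(list(model = cls), unclass(params)), path)
  invisible(path)
}

#' Read model parameters from a YAML file
#'
#' @param path File written by [params_to_yaml()] (or hand-written with a
#'   `model:` key naming the parameter class).
#' @return The reconstructed parameter object.
#' @export
params_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$model
  x$model <- NULL
  ctor <- switch(cls,
                 adaptive_pi_params = adaptive_pi_params,
                 simplified_params = simplified_params,
                 karin_params = karin_params,
                 stop("unknown model class in YAML: ", cls))
  do.call(ctor, x)
}
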