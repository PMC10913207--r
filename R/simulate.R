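# Numerical integration with breakpoint-aware restarts, the equilibration
# ("settle") protocol, and phase-portrait trajectory bundles.
#
# All drive signals are piecewise constant (zero-order hold), so the solver
# is restarted at every signal breakpoint and noise refresh time; within a
# segment the right-hand side is smooth and the signals are evaluated once.

model_dim <- function(model) {
  switch(model, adaptive_pi = 2L, simplified = 2L, karin = 3L,
         stop("unknown model id: ", model))
}

model_state_names <- function(model) {
  switch(model, adaptive_pi = c("y", "z"), simplified = c("y", "z"),
         karin = c("y", "x", "z"))
}

# deSolve-style RHS factory with the signals frozen at constant values
# (valid inside one integration segment).
frozen_rhs <- function(model, params, sig_vals) {
  switch(model,
    adaptive_pi = function(t, state, parms) {
      list(adaptive_pi_rhs(state, t, params,
                           r = sig_vals[["r"]], d = sig_vals[["d"]]))
    },
    simplified = function(t, state, parms) {
      list(simplified_rhs(state, t, params, u = sig_vals[["u"]]))
    },
    karin = function(t, state, parms) {
      list(karin_rhs(state, t, params, u = sig_vals[["u"]]))
    })
}

rhs_at <- function(model, params, state, t, inputs) {
  switch(model,
    adaptive_pi = adaptive_pi_rhs(state, t, params,
                                  r = inputs$r, d = inputs$d),
    simplified = simplified_rhs(state, t, params, u = inputs$u),
    karin = karin_rhs(state, t, params, u = inputs$u))
}

input_names_for <- function(model) {
  if (model == "adaptive_pi") c("r", "d") else "u"
}

# Normalise inputs to piecewise_signal objects spanning t_span.
normalise_inputs <- function(model, inputs, t_span) {
  need <- input_names_for(model)
  if (!all(need %in% names(inputs))) {
    stop("model '", model, "' needs input signal(s): ",
         paste(need, collapse = ", "))
  }
  out <- lapply(inputs[need], function(s) {
    if (inherits(s, "piecewise_signal")) s
    else if (is.numeric(s) && length(s) == 1L) constant_signal(s, t_span)
    else stop("inputs must be constants or piecewise_signal objects")
  })
  names(out) <- need
  out
}

#' Integrate a model over a time span
#'
#' Adaptive explicit Runge-Kutta 5(4) integration (via \pkg{deSolve}'s
#' `ode45` method), restarted at every signal breakpoint and noise refresh
#' time so discontinuities in the drive signals are never smoothed over by
#' the step-size controller. The solution is reported on a fixed output
#' grid whose points include all restart times.
#'
#' @param model One of `"adaptive_pi"`, `"simplified"`, `"karin"`.
#' @param params Matching parameter object.
#' @param x0 Initial state (length 2, or 3 for the three-state circuit).
#' @param inputs Named list of drive signals: `r` and `d` for the adaptive
#'   PI model, `u` for the other two. Constants or [piecewise_signal()]s.
#' @param t_span Numeric `(t0, t1)`.
#' @param rtol,atol Solver tolerances.
#' @param grid_step Output grid spacing (time units).
#' @return An object of class `pi_trajectory`: list with `times`, `states`
#'   (matrix, one named column per state), `output` (the `y` column), and
#'   `meta` (params, tolerances, signal seeds).
#' @export
integrate_model <- function(model, params, x0, inputs,
                            t_span = c(0, 400), rtol = 1e-8, atol = 1e-10,
                            grid_step = 0.01) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1],
            rtol > 0, atol > 0, all(is.finite(x0)))
  nd <- model_dim(model)
  if (length(x0) != nd) {
    stop(sprintf("model '%s' has dimension %d; x0 has length %d",
                 model, nd, length(x0)))
  }
  sigs <- normalise_inputs(model, inputs, t_span)

  ev <- sort(unique(unlist(lapply(sigs, signal_event_times))))
  ev <- ev[ev > t_span[1] & ev < t_span[2]]
  seg_bounds <- c(t_span[1], ev, t_span[2])

  grid <- seq(t_span[1], t_span[2], by = grid_step)
  grid <- sort(unique(c(grid, seg_bounds)))

  state <- stats::setNames(as.numeric(x0), model_state_names(model))
  times_out <- grid[1]
  states_out <- matrix(state, nrow = 1,
                       dimnames = list(NULL, names(state)))
  for (k in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[k]; b <- seg_bounds[k + 1]
    tt <- grid[grid >= a & grid <= b]
    if (tt[1] > a) tt <- c(a, tt)
    if (tt[length(tt)] < b) tt <- c(tt, b)
    # signals are constant within (a, b); sample them just inside
    mid <- a + min((b - a) / 2, grid_step / 2)
    vals <- vapply(sigs, signal_value, numeric(1), t = mid)
    sol <- deSolve::ode(y = state, times = tt,
                        func = frozen_rhs(model, params, as.list(vals)),
                        parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, -1]))) {
      stop(sprintf("integration failed near t = %g", a))
    }
    state <- sol[nrow(sol), -1]
    keep <- sol[, 1] > a
    times_out <- c(times_out, sol[keep, 1])
    states_out <- rbind(states_out, sol[keep, -1, drop = FALSE])
  }
  structure(list(times = times_out,
                 states = states_out,
                 output = states_out[, "y"],
                 meta = list(model = model, params = params,
                             t_span = t_span, rtol = rtol, atol = atol,
                             grid_step = grid_step,
                             signal_seeds = vapply(sigs, function(s) s$seed,
                                                   integer(1)))),
            class = "pi_trajectory")
}

#' @export
print.pi_trajectory <- function(x, ...) {
  cat(sprintf("trajectory of '%s' on [%g, %g]: %d samples, %d states\n",
              x$meta$model, x$meta$t_span[1], x$meta$t_span[2],
              length(x$times), ncol(x$states)))
  cat("final state:", paste(sprintf("%s = %.4f", colnames(x$states),
                                    x$states[nrow(x$states), ]),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' @param traj A [integrate_model()] trajectory.
#' @param path Output CSV path (columns `t` then the state names).
#' @param thin Keep every `thin`-th sample (1 = all).
#' @return `path`, invisibly.
#' @export
trajectory_to_csv <- function(traj, path, thin = 1L) {
  keep <- seq(1, length(traj$times), by = thin)
  df <- data.frame(t = traj$times[keep], traj$states[keep, , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Settle a model to equilibrium under constant inputs
#'
#' Integrates with constant inputs in chunks until the right-hand side norm
#' falls below `tol` or `horizon` is reached. The experiments require the
#' system to sit at an equilibrium before it is perturbed; this implements
#' that equilibration step and flags non-convergence rather than failing
#' silently.
#'
#' @param model,params,x0 As in [integrate_model()].
#' @param inputs Named list of constant input levels (numbers).
#' @param horizon Maximum integration time.
#' @param tol Convergence tolerance on the RHS Euclidean norm.
#' @return The terminal state, with attributes `converged` (logical) and
#'   `t_settle` (time at which the tolerance was first met, or `horizon`).
#' @export
settle <- function(model, params, x0, inputs, horizon = 500, tol = 1e-9) {
  stopifnot(all(vapply(inputs, function(v)
    is.numeric(v) && length(v) == 1L, logical(1))))
  state <- as.numeric(x0)
  rhs0 <- rhs_at(model, params, state, 0, inputs)
  if (sqrt(sum(rhs0^2)) < tol) {
    return(structure(stats::setNames(state, model_state_names(model)),
                     converged = TRUE, t_settle = 0))
  }
  chunk <- 25
  t_now <- 0
  while (t_now < horizon) {
    t_end <- min(t_now + chunk, horizon)
    traj <- integrate_model(model, params, state, inputs,
                            t_span = c(t_now, t_end), grid_step = 0.1)
    state <- traj$states[nrow(traj$states), ]
    if (any(!is.finite(state)) || max(abs(state)) > 1e12) {
      return(structure(state, converged = FALSE, t_settle = NA_real_))
    }
    t_now <- t_end
    rhs_now <- rhs_at(model, params, state, t_now, inputs)
    if (sqrt(sum(rhs_now^2)) < tol) {
      return(structure(state, converged = TRUE, t_settle = t_now))
    }
  }
  structure(state, converged = FALSE, t_settle = horizon)
}

#' Phase portrait of the adaptive PI model
#'
#' Samples the vector field on a rectangular grid in the `(y, z)` plane and
#' integrates one trajectory from each grid node under constant inputs;
#' per-trajectory integration failures are recorded, not fatal. The two
#' equilibria are attached.
#'
#' @param params An [adaptive_pi_params()] object.
#' @param r,d Constant input levels.
#' @param y_range,z_range Numeric `(lo, hi)` ranges of the sampled box.
#' @param grid_n Nodes per axis (`grid_n^2` trajectories).
#' @param horizon Integration horizon for each trajectory.
#' @return An object of class `pi_phase_portrait`: `field` (data frame of
#'   grid states and derivatives), `trajectories` (list, one per node, with
#'   failures stored as `NULL` plus a message in `errors`), `equilibria`.
#' @export
phase_portrait <- function(params, r, d, y_range = c(0, 20),
                           z_range = c(0, 10), grid_n = 15, horizon = 60) {
  stopifnot(grid_n >= 2, diff(y_range) > 0, diff(z_range) > 0)
  ys <- seq(y_range[1], y_range[2], length.out = grid_n)
  zs <- seq(z_range[1], z_range[2], length.out = grid_n)
  nodes <- expand.grid(y = ys, z = zs)
  derivs <- t(apply(nodes, 1, function(p)
    adaptive_pi_rhs(c(p[["y"]], p[["z"]]), 0, params, r, d)))
  field <- data.frame(y = nodes$y, z = nodes$z,
                      dy = derivs[, 1], dz = derivs[, 2])
  trajectories <- vector("list", nrow(nodes))
  errors <- character(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    tr <- tryCatch(
      integrate_model("adaptive_pi", params,
                      c(nodes$y[i], nodes$z[i]),
                      inputs = list(r = r, d = d),
                      t_span = c(0, horizon), grid_step = 0.1),
      error = function(e) conditionMessage(e))
    if (is.character(tr)) errors[i] <- tr else trajectories[[i]] <- tr
  }
  structure(list(field = field, trajectories = trajectories,
                 errors = errors,
                 equilibria = equilibrium_points(params, r, d),
                 meta = list(params = params, r = r, d = d,
                             grid_n = grid_n, horizon = horizon)),
            class = "pi_phase_portrait")
}

#' @export
print.pi_phase_portrait <- function(x, ...) {
  ok <- sum(!vapply(x$trajectories, is.null, logical(1)))
  cat(sprintf("phase portrait: %d field samples, %d/%d trajectories ok\n",
              nrow(x$field), ok, length(x$trajectories)))
  print(x$equilibria$E1); print(x$equilibria$E2)
  invisible(x)
}
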