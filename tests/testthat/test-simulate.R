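sc <- baseline_scenario()

test_that("an equilibrium initial state stays put under constant inputs", {
  eqs <- equilibrium_points(sc$params, sc$r0, sc$d0)
  tr <- integrate_model("adaptive_pi", sc$params, eqs$E2$point,
                        inputs = list(r = sc$r0, d = sc$d0),
                        t_span = c(0, 100), grid_step = 0.1)
  dev <- sweep(tr$states, 2, eqs$E2$point)
  expect_lt(max(abs(dev)), 1e-6)
})

test_that("trajectories in the region of attraction reach the tracking equilibrium", {
  eqs <- equilibrium_points(sc$params, sc$r0, sc$d0)
  tr <- integrate_model("adaptive_pi", sc$params, c(y = 8, z = 2),
                        inputs = list(r = sc$r0, d = sc$d0),
                        t_span = c(0, 100), grid_step = 0.1)
  terminal <- tr$states[nrow(tr$states), ]
  expect_lt(max(abs(terminal - eqs$E2$point)), 1e-3)
  expect_equal(round(terminal[["y"]], 3), 11.000)
  expect_equal(round(terminal[["z"]], 3), 4.012)
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  rhs <- function(x, t) adaptive_pi_rhs(x, t, sc$params,
                                        r = sc$r0, d = sc$d0)
  x0 <- c(y = 8, z = 2)
  oracle <- rk4_integrate(rhs, x0, c(0, 10), h = 1e-4)
  tr <- integrate_model("adaptive_pi", sc$params, x0,
                        inputs = list(r = sc$r0, d = sc$d0),
                        t_span = c(0, 10), grid_step = 0.1)
  expect_lt(max(abs(tr$states[nrow(tr$states), ] - oracle)), 1e-5)
})

test_that("solver tolerances are converged on the step schedule", {
  sch <- make_step_schedule(seed = 4)
  run <- function(rtol, atol) {
    integrate_model("adaptive_pi", sc$params, c(y = 8, z = 2),
                    inputs = list(r = sch$r, d = sch$d),
                    t_span = c(0, 60), grid_step = 0.1,
                    rtol = rtol, atol = atol)$output
  }
  y1 <- run(1e-6, 1e-8)
  y2 <- run(5e-7, 5e-9)
  expect_lt(max(abs(y1 - y2)), 10 * 1e-6)
})

test_that("output grid contains every signal breakpoint and refresh time", {
  sch <- make_step_schedule(seed = 4)
  tr <- integrate_model("adaptive_pi", sc$params, c(y = 8, z = 2),
                        inputs = list(r = sch$r, d = sch$d),
                        t_span = c(0, 70), grid_step = 0.1)
  ev <- signal_event_times(sch$r)
  expect_true(all(ev[ev <= 70] %in% tr$times))
  expect_true(all(diff(tr$times) > 0))
})

test_that("the z = 0 axis is preserved exactly and flagged as runaway", {
  tr <- integrate_model("adaptive_pi", sc$params, c(y = 2, z = 0),
                        inputs = list(r = sc$r0, d = sc$d0),
                        t_span = c(0, 5), grid_step = 0.01)
  expect_true(all(abs(tr$states[, "z"]) <= 1e-12))
  # with no feedback the output grows exponentially; settle flags it
  out <- settle("adaptive_pi", sc$params, c(y = 2, z = 0),
                inputs = list(r = sc$r0, d = sc$d0), horizon = 150)
  expect_false(attr(out, "converged"))
})

test_that("settle returns equilibria immediately and converges otherwise", {
  eqs <- equilibrium_points(sc$params, sc$r0, sc$d0)
  out0 <- settle("adaptive_pi", sc$params, eqs$E2$point,
                 inputs = list(r = sc$r0, d = sc$d0))
  expect_true(attr(out0, "converged"))
  expect_equal(attr(out0, "t_settle"), 0)
  out <- settle("adaptive_pi", sc$params, c(y = 10, z = 4),
                inputs = list(r = sc$r0, d = sc$d0), horizon = 500,
                tol = 1e-9)
  expect_true(attr(out, "converged"))
  expect_equal(round(as.numeric(out), 3), c(11.000, 4.012),
               ignore_attr = TRUE)
})

test_that("positivity check flags negative excursions post hoc", {
  tr <- integrate_model("adaptive_pi", sc$params, c(y = 8, z = 2),
                        inputs = list(r = sc$r0, d = sc$d0),
                        t_span = c(0, 30), grid_step = 0.1)
  expect_true(positivity_ok(tr))
  tr_neg <- integrate_model("adaptive_pi", sc$params, c(y = -1, z = 0.5),
                            inputs = list(r = sc$r0, d = sc$d0),
                            t_span = c(0, 1), grid_step = 0.1)
  expect_false(positivity_ok(tr_neg))
})

test_that("phase portrait: grid field, convergence to E2, equilibrium node", {
  pp <- phase_portrait(sc$params, sc$r0, sc$d0,
                       y_range = c(2, 14), z_range = c(0.5, 6),
                       grid_n = 4, horizon = 80)
  eqs <- pp$equilibria
  expect_equal(nrow(pp$field), 16)
  # every trajectory started at z > 0 inside the box ends at E2
  for (i in seq_along(pp$trajectories)) {
    tr <- pp$trajectories[[i]]
    expect_false(is.null(tr))
    terminal <- tr$states[nrow(tr$states), ]
    expect_lt(max(abs(terminal - eqs$E2$point)), 1e-2)
  }
  # a grid node placed exactly at an equilibrium samples a zero field
  pp1 <- phase_portrait(sc$params, sc$r0, sc$d0,
                        y_range = c(eqs$E1$point[["y"]], 10),
                        z_range = c(0, 4), grid_n = 2, horizon = 1)
  at_e1 <- pp1$field[1, ]
  expect_equal(c(at_e1$dy, at_e1$dz), c(0, 0), tolerance = 1e-14)
})

test_that("terminal output level is gain-independent but the adapting state is not", {
  sets <- study_param_sets()
  term <- lapply(sets[c("baseline", "s_1.5")], function(p) {
    tr <- integrate_model("adaptive_pi", p, c(y = 8, z = 2),
                          inputs = list(r = sc$r0, d = sc$d0),
                          t_span = c(0, 80), grid_step = 0.1)
    tr$states[nrow(tr$states), ]
  })
  expect_equal(term$baseline[["y"]], term$s_1.5[["y"]], tolerance = 1e-6)
  expect_equal(term$baseline[["z"]] / term$s_1.5[["z"]], 6,
               tolerance = 1e-4)
})

test_that("integration validates inputs and dimensions", {
  expect_error(integrate_model("adaptive_pi", sc$params, c(1, 2, 3),
                               inputs = list(r = 11, d = 0.01)),
               "dimension")
  expect_error(integrate_model("adaptive_pi", sc$params, c(1, 2),
                               inputs = list(r = 11)), "needs input")
  expect_error(integrate_model("nope", sc$params, c(1, 2),
                               inputs = list(u = 1)), "unknown model")
})
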