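sc <- baseline_scenario()

test_that("equivariance consistency: s admits alpha = x1/s, b and c do not", {
  cs <- equivariance_consistency("s")
  expect_true(cs$consistent)
  expect_length(cs$violated_conditions, 0)
  # the candidate is literally x1/s
  expect_equal(eval(cs$alpha, list(x1 = 2, s = 0.25)), 8)
  expect_lt(max(cs$condition_residuals), 1e-9)

  cb <- equivariance_consistency("b")
  expect_false(cb$consistent)
  expect_true("dalpha_dx2_zero" %in% cb$violated_conditions)
  expect_gt(max(cb$condition_residuals), 1e-3)

  cc <- equivariance_consistency("c")
  expect_false(cc$consistent)
  expect_true("dalpha_dx1_matches_ratio" %in% cc$violated_conditions)
  # the c-candidate does satisfy the second condition
  expect_lt(cc$condition_residuals[["dalpha_dx2_zero"]], 1e-12)
  expect_error(equivariance_consistency("l"), "unknown parameter")
})

test_that("vector-field residual vanishes for the s-equivariance", {
  cand <- equivariance_consistency("s")
  set.seed(61)
  for (i in 1:100) {
    st <- c(runif(1, 0.2, 8), runif(1, 0.2, 6))
    r <- runif(1, 8, 14); d <- runif(1, 0.01, 2)
    for (s in c(0.25, 1.5)) {
      res <- equivariance_residual(cand, st, r, d, p_value = s)
      expect_lt(sqrt(sum(res^2)), 1e-12)
    }
  }
})

test_that("identity transformation at the reference parameter has zero residual", {
  cand <- equivariance_consistency("s")
  res <- equivariance_residual(cand, c(3, 2), r = 11, d = 0.01,
                               p_value = 1)
  expect_identical(res, c(0, 0))
})

test_that("b and c candidates leave a macroscopic residual", {
  cb <- equivariance_consistency("b")
  cc <- equivariance_consistency("c")
  set.seed(62)
  worst_b <- worst_c <- 0
  for (i in 1:20) {
    st <- c(runif(1, 0.5, 5), runif(1, 0.5, 4))
    r <- runif(1, 10, 14); d <- runif(1, 0.01, 2)
    worst_b <- max(worst_b, sqrt(sum(
      equivariance_residual(cb, st, r, d, p_value = 0.6)^2)))
    worst_c <- max(worst_c, sqrt(sum(
      equivariance_residual(cc, st, r, d, p_value = 4)^2)))
  }
  expect_gt(worst_b, 1e-3)
  expect_gt(worst_c, 1e-3)
})

test_that("alpha division by zero is an error", {
  cand <- equivariance_consistency("s")
  expect_error(equivariance_residual(cand, c(3, 2), 11, 0.01, p_value = 0),
               "division by zero")
})

test_that("DC rescaling eliminates s but not b or c", {
  ds <- dc_rescaling("s")
  expect_true(ds$parameter_eliminated)
  expect_lt(ds$composition_residual, 1e-12)
  db <- dc_rescaling("b")
  expect_false(db$parameter_eliminated)
  expect_lt(db$composition_residual, 1e-12)
  dcc <- dc_rescaling("c")
  expect_false(dcc$parameter_eliminated)
  expect_lt(dcc$composition_residual, 1e-12)
})

test_that("s-rescaling round-trips: scaling then unscaling recovers the field", {
  # v = (s x1, x2); evaluating the transformed field at v and mapping back
  # must equal the original field at x
  set.seed(63)
  pr <- unclass(sc$params)
  frame_f <- function(x1, x2, r, d, pr) {
    c(-pr$c * x1 * (r - x2),
      pr$b * x2 + d + pr$s * x1 * (pr$l * r - x2))
  }
  ds <- dc_rescaling("s")
  for (i in 1:25) {
    x <- c(runif(1, 0.2, 8), runif(1, 0.2, 6))
    r <- runif(1, 8, 14); d <- runif(1, 0.01, 2)
    env <- c(list(v1 = pr$s * x[1], v2 = x[2], r = r, d = d), pr)
    vdot <- c(eval(ds$transformed_rhs[[1]], env),
              eval(ds$transformed_rhs[[2]], env))
    xdot_back <- c(vdot[1] / pr$s, vdot[2])
    expect_equal(xdot_back, frame_f(x[1], x[2], r, d, pr),
                 tolerance = 1e-12)
  }
})

test_that("identical parameter values give an exactly zero output difference", {
  rep0 <- paired_output_test("s", 0.25, 0.25, protocol = "strict",
                             shared_seed = 8, grid_step = 0.1)
  expect_identical(max(abs(rep0$dy)), 0)
  expect_equal(rep0$verdict, "invariant")
})

test_that("strict s-invariance holds across random gain pairs", {
  set.seed(64)
  for (i in 1:5) {
    pp <- sort(runif(2, 0.1, 10))
    # solver error must sit well below the invariance threshold even for
    # extreme gain ratios, where the adapting states differ by 100x
    rep <- paired_output_test("s", pp[1], pp[2], protocol = "strict",
                              shared_seed = 100 + i, grid_step = 0.1,
                              rtol = 1e-10, atol = 1e-12)
    expect_equal(rep$verdict, "invariant")
    expect_lt(rep$max_abs_output_diff, 1e-5)
  }
})

test_that("c-variation breaks the transient but not the equilibrium output", {
  rep <- paired_output_test("c", 2, 4, protocol = "strict",
                            shared_seed = 7, grid_step = 0.05)
  expect_equal(rep$verdict, "not_invariant")
  expect_gt(rep$max_abs_output_diff, 0.1)
  # both runs settle to y = r, so the terminal difference is tiny
  expect_lt(rep$terminal_abs_output_diff, 1e-3)
})

test_that("paired runs must share the noise realisation", {
  sch1 <- make_step_schedule(seed = 1)
  sch2 <- make_step_schedule(seed = 2)
  expect_error(paired_output_test("s", 0.25, 1.5, shared_seed = 1,
                                  signals = sch1, signals2 = sch2),
               "share the noise")
})

test_that("invariance reports serialise to JSON and CSV", {
  rep <- paired_output_test("s", 0.25, 1.5, protocol = "strict",
                            shared_seed = 3, grid_step = 0.25)
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  invariance_report_to_files(rep, fj, fc)
  js <- jsonlite::read_json(fj)
  expect_equal(js$verdict, "invariant")
  expect_equal(js$parameter_name, "s")
  expect_equal(unlist(js$value_pair), c(0.25, 1.5))
  df <- read.csv(fc)
  expect_named(df, c("t", "dy"))
})
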