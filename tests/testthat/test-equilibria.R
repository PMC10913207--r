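sc <- baseline_scenario()

test_that("closed-form equilibria reproduce the studied coordinates to 3 decimals", {
  sets <- study_param_sets()
  eqs <- equilibrium_points(sets$baseline, sc$r0, sc$d0)
  expect_equal(round(eqs$E1$point[["y"]], 3), -0.033)
  expect_equal(round(eqs$E2$point[["z"]], 3), 4.012)
  expect_equal(eqs$E2$point[["y"]], 11)
  eqs_s <- equilibrium_points(sets$s_1.5, sc$r0, sc$d0)
  expect_equal(round(eqs_s$E2$point[["z"]], 3), 0.669)
  eqs_b <- equilibrium_points(sets$b_0.6, sc$r0, sc$d0)
  expect_equal(round(eqs_b$E1$point[["y"]], 3), -0.017)
  expect_equal(round(eqs_b$E2$point[["z"]], 3), 8.012)
  # d -> 0 drives E1 to the origin
  eqs0 <- equilibrium_points(sets$baseline, sc$r0, 1e-12)
  expect_equal(eqs0$E1$point[["y"]], 0, tolerance = 1e-10)
})

test_that("Jacobian closed form matches central finite differences", {
  set.seed(31)
  for (i in 1:50) {
    p <- random_valid_params()
    r <- runif(1, 1, 15); d <- runif(1, 0.01, 3)
    st <- c(runif(1, -2, 15), runif(1, 0, 8))
    J <- adaptive_pi_jacobian(p, st, r)
    Jfd <- fd_jacobian(function(x) adaptive_pi_rhs(x, 0, p, r, d), st)
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("Jacobian structure at the equilibria", {
  p <- sc$params
  eqs <- equilibrium_points(p, sc$r0, sc$d0)
  J1 <- adaptive_pi_jacobian(p, eqs$E1$point, sc$r0)
  expect_equal(J1[2, 1], 0)  # triangular: eigenvalues on the diagonal
  expect_equal(diag(J1), c(p$b, -p$c * (sc$r0 + sc$d0 / p$b)))
  J2 <- adaptive_pi_jacobian(p, eqs$E2$point, sc$r0)
  expect_equal(J2[2, 2], 0)  # y = r kills the lower-right entry
})

test_that("closed-form eigenvalues reproduce the studied values", {
  sets <- study_param_sets()
  lam1 <- eigenvalues_E1(sets$baseline, sc$r0, sc$d0)
  expect_equal(round(Re(lam1), 3), c(0.300, -22.067))
  lam1c <- eigenvalues_E1(sets$c_4, sc$r0, sc$d0)
  expect_equal(round(Re(lam1c), 3), c(0.300, -44.133))
  lam1b <- eigenvalues_E1(sets$b_0.6, sc$r0, sc$d0)
  expect_equal(round(Re(lam1b), 3), c(0.600, -22.033))

  lam2 <- eigenvalues_E2(sets$baseline, sc$r0, sc$d0)
  expect_lt(max(abs(Re(lam2) - (-0.351))), 1e-3)  # printed precision
  expect_equal(round(Im(lam2), 3), c(2.549, -2.549))
  lam2b <- eigenvalues_E2(sets$b_0.6, sc$r0, sc$d0)
  expect_lt(max(abs(Re(lam2b) - (-0.701))), 1e-3)
  expect_equal(round(Im(lam2b), 3), c(3.568, -3.568))
  lam2c <- eigenvalues_E2(sets$c_4, sc$r0, sc$d0)
  expect_equal(round(Im(lam2c), 3), c(3.622, -3.622))
})

test_that("E2 eigenvalues are exactly independent of the gain scale s", {
  base <- unclass(sc$params)
  ref <- eigenvalues_E2(sc$params, sc$r0, sc$d0)
  for (s in c(0.01, 0.1, 0.25, 1, 1.5, 10, 100)) {
    p <- adaptive_pi_params(b = base$b, s = s, l = base$l, c = base$c)
    expect_identical(eigenvalues_E2(p, sc$r0, sc$d0), ref)
  }
})

test_that("closed-form eigenvalues agree with a dense eigensolver", {
  set.seed(41)
  for (i in 1:50) {
    p <- random_valid_params()
    r <- runif(1, 1, 15); d <- runif(1, 0.01, 3)
    eqs <- equilibrium_points(p, r, d)
    for (eq in eqs) {
      J <- adaptive_pi_jacobian(p, eq$point, r)
      lam_num <- sort_eig(as.complex(eigen(J, only.values = TRUE)$values))
      expect_lt(max(Mod(eq$eigenvalues - lam_num)), 1e-9)
    }
  }
})

test_that("stability classification covers each class", {
  # saddle and stable focus from the studied scenario
  eqs <- equilibrium_points(sc$params, sc$r0, sc$d0)
  expect_equal(eqs$E1$stability_class, "saddle")
  expect_equal(eqs$E2$stability_class, "stable_focus")
  # stable node: strong damping, weak rotation
  p_node <- adaptive_pi_params(b = 0.5, s = 1, l = 0.5, c = 0.01)
  eq_node <- equilibrium_points(p_node, r = 1, d = 1)$E2
  expect_equal(eq_node$stability_class, "stable_node")
  # degenerate node at a vanishing discriminant, unstable for tau > 0
  expect_equal(equilibrium(c(y = 0, z = 0), tau = -2, delta = 1)$stability_class,
               "degenerate_node")
  expect_equal(equilibrium(c(y = 0, z = 0), tau = 2, delta = 1)$stability_class,
               "unstable")
  expect_equal(equilibrium(c(y = 0, z = 0), tau = 1, delta = 0.2)$stability_class,
               "unstable")
})

test_that("stable tracking regime: E1 saddle, E2 stable, over random draws", {
  set.seed(51)
  for (i in 1:200) {
    p <- random_valid_params()
    r <- runif(1, 0.5, 20); d <- runif(1, 0.001, 5)
    eqs <- equilibrium_points(p, r, d)
    expect_equal(eqs$E1$stability_class, "saddle")
    expect_lt(eqs$E2$tau, 0)
    expect_gt(eqs$E2$delta, 0)
    expect_true(eqs$E2$stability_class %in%
                  c("stable_focus", "stable_node", "degenerate_node"))
  }
})

test_that("degenerate reference scaling l = 1 is rejected", {
  p <- suppressWarnings(adaptive_pi_params(b = 0.3, s = 0.25, l = 1, c = 2))
  expect_error(equilibrium_points(p, 11, 0.01), "degenerate")
  expect_error(eigenvalues_E2(p, 11, 0.01), "degenerate")
})

test_that("equilibrium table gathers coordinates and classes per set", {
  tab <- equilibrium_table(study_param_sets(), sc$r0, sc$d0)
  expect_equal(nrow(tab), 8)
  row <- tab[tab$set == "baseline" & tab$equilibrium == "E2", ]
  expect_equal(round(row$z, 3), 4.012)
  expect_equal(row$stability, "stable_focus")
})
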