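# Independent oracles used by the tests: a fixed-step classical RK4
# integrator and a central-difference Jacobian. Both are deliberately
# separate from the package's adaptive integration and closed forms.

rk4_integrate <- function(rhs, x0, t_span, h) {
  n <- ceiling(diff(t_span) / h)
  state <- x0
  t <- t_span[1]
  for (i in seq_len(n)) {
    hh <- min(h, t_span[2] - t)
    k1 <- rhs(state, t)
    k2 <- rhs(state + hh / 2 * k1, t + hh / 2)
    k3 <- rhs(state + hh / 2 * k2, t + hh / 2)
    k4 <- rhs(state + hh * k3, t + hh)
    state <- state + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + hh
  }
  state
}

fd_jacobian <- function(rhs, state, h = 1e-6) {
  n <- length(state)
  J <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- h
    J[, j] <- (rhs(state + e) - rhs(state - e)) / (2 * h)
  }
  J
}

# random valid parameter draw in the stable tracking regime 0 < l < 1
random_valid_params <- function() {
  adaptive_pi_params(b = runif(1, 0.05, 2), s = runif(1, 0.05, 3),
                     l = runif(1, 0.05, 0.95), c = runif(1, 0.1, 5))
}

sort_eig <- function(lam) lam[order(-Im(lam), -Re(lam))]
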