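# Independent oracles, deliberately written without reusing package code paths.

# Hand-rolled binomial IRLS (logit link) on an explicit design matrix.
irls_binomial <- function(X, succ, size, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- size * mu * (1 - mu)
    z <- eta + (succ - size * mu) / pmax(w, 1e-12)
    fit <- lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta
}

# Weighted least-squares projection of a true logit curve onto an
# orthogonal basis: the population value of the per-degree trends.
wls_trend_oracle <- function(eta_fun, basis) {
  temps <- basis$temps
  M <- cbind(1, predict(basis, temps))
  drop(solve(crossprod(M), crossprod(M, eta_fun(temps))))
}

# Random logit-scale cubic curves for descriptor property tests: a mix of
# peaked curves (interior optimum) and unconstrained small cubics.
random_cubics <- function(n, peaked_frac = 0.75) {
  lapply(seq_len(n), function(i) {
    if (runif(1) < peaked_frac) {
      t0 <- runif(1, 12, 26)
      pk <- runif(1, 0.5, 3)
      w <- runif(1, 0.01, 0.12)
      s <- runif(1, -0.003, 0.003)
      c(pk - w * t0^2 - s * t0^3,
        2 * w * t0 + 3 * s * t0^2,
        -w - 3 * s * t0,
        s)
    } else {
      c(runif(1, -3, 3), runif(1, -0.5, 0.5),
        runif(1, -0.03, 0.03), runif(1, -0.002, 0.002))
    }
  })
}
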