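test_that("grouped Wald table has the full factorial structure and df", {
  w <- wald_tests(tiny_fit())
  expect_equal(w$term, c("fert", "embryo", "fert:embryo", "trend",
                         "fert:trend", "embryo:trend", "fert:embryo:trend"))
  expect_equal(w$df, c(1L, 2L, 2L, 3L, 3L, 6L, 6L))
  expect_true(all(w$chi2 >= 0))
  expect_true(all(w$p >= 0 & w$p <= 1))
  # p is the upper-tail chi-square probability of the statistic
  expect_equal(w$p, pchisq(w$chi2, w$df, lower.tail = FALSE))
})

test_that("a null coefficient combination gives chi2 = 0, p = 1", {
  res <- tpcglmm:::wald_stat(rep(0, 3), diag(3))
  expect_equal(res$chi2, 0)
  expect_equal(res$df, 3L)
  expect_equal(res$p, 1)
  # singular covariance: rank-adjusted df
  V <- matrix(1, 2, 2)
  res2 <- tpcglmm:::wald_stat(c(1, 1), V)
  expect_equal(res2$df, 1L)
})

test_that("Wald statistics and curves are invariant to factor coding", {
  tab <- tiny_tab()
  f_trt <- fit_tpc_glmm(tab, tpc_model_spec(contrasts = "treatment"))
  f_sum <- fit_tpc_glmm(tab, tpc_model_spec(contrasts = "sum"))
  w1 <- wald_tests(f_trt); w2 <- wald_tests(f_sum)
  expect_equal(w1$chi2, w2$chi2, tolerance = 1e-6)
  expect_equal(w1$df, w2$df)
  grid <- seq(10, 28, by = 0.5)
  for (e in c(18, 20, 22))
    expect_equal(predict_curve(f_trt, e, grid), predict_curve(f_sum, e, grid),
                 tolerance = 1e-6)
  t1 <- trend_contrasts(f_trt); t2 <- trend_contrasts(f_sum)
  expect_equal(t1$trends$estimate, t2$trends$estimate, tolerance = 1e-6)
})

test_that("trend estimates match a weighted-least-squares projection oracle", {
  fit <- full_fit()
  cfg_topts <- c("18" = 19, "20" = 20, "22" = 21.2)   # truth behind full_tab()
  tr <- trend_contrasts(fit)
  for (e in names(cfg_topts)) {
    eta_true <- function(t) 2 - 0.05 * (t - cfg_topts[[e]])^2
    oracle <- wls_trend_oracle(eta_true, fit$basis)[-1]
    est <- tr$trends$estimate[tr$trends$embryo_temp == as.numeric(e)]
    se <- tr$trends$se[tr$trends$embryo_temp == as.numeric(e)]
    expect_true(all(abs(est - oracle) <= 4 * se), info = paste("embryo", e))
  }
  # sign pattern: optima increasing across embryo temps straddling the
  # assay midpoint => linear trend increases from negative to positive
  lin <- tr$trends$estimate[tr$trends$degree == "linear"]
  expect_true(all(diff(lin) > 0))
  expect_lt(lin[1], 0)
  expect_gt(lin[3], 0)
})

test_that("contrasts are antisymmetric differences with Tukey p >= unadjusted p", {
  tr <- trend_contrasts(tiny_fit())
  # each contrast equals the difference of the two trend estimates (exact)
  for (i in seq_len(nrow(tr$contrasts))) {
    row <- tr$contrasts[i, ]
    gs <- as.numeric(strsplit(row$pair, " - ")[[1]])
    ta <- tr$trends$estimate[tr$trends$embryo_temp == gs[1] &
                             tr$trends$degree == row$degree]
    tb <- tr$trends$estimate[tr$trends$embryo_temp == gs[2] &
                             tr$trends$degree == row$degree]
    expect_equal(row$estimate, ta - tb, tolerance = 1e-12)
  }
  expect_true(all(tr$contrasts$p_tukey >= tr$contrasts$p_value - 1e-12))
})

test_that("null generator yields near-zero contrasts", {
  cfg <- shifted_topt_config(c("18" = 19.5, "20" = 19.5, "22" = 19.5),
                             design = tiny_design(25), seed = 81)
  tr <- trend_contrasts(fit_tpc_glmm(simulate_survival_table(cfg)))
  expect_true(all(abs(tr$contrasts$z) < 3.5))
})

test_that("under a true null the embryo:trend Wald p-values are uniform (GLM route)", {
  # The Type-II construction itself, isolated from mixed-model small-sample
  # effects: no random effects, balanced allocation, large vials. The GLMM
  # small-design behaviour is characterized in the acceptance suite.
  d <- experiment_design(n_per_vial = 40, replicates = 2, n_blocks = 4,
                         temps_per_block = c(2, 5))
  ps <- vapply(1:150, function(i) {
    tab <- simulate_survival_table(shifted_topt_config(
      c("18" = 20, "20" = 20, "22" = 20), design = d, sigma_block = 0,
      sigma_vial = 0, allocation = "balanced", seed = 60000 + i))
    w <- wald_tests(fit_tpc_glm(tab))
    w$p[w$term == "embryo:trend"]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("inference requires a converged fit", {
  d <- tiny_design()
  params <- lapply(tpcglmm:::group_keys(d), function(k) c(50, 0, 0, 0))
  names(params) <- tpcglmm:::group_keys(d)
  cfg <- tpc_gen_config(d, params, sigma_block = 0, sigma_vial = 0,
                        allocation = "balanced")
  tab <- suppressWarnings(simulate_survival_table(cfg, seed = 61))
  bad <- fit_tpc_glm(tab)
  expect_error(wald_tests(bad), "converged")
  expect_error(trend_contrasts(bad), "converged")
})
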