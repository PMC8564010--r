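test_that("bootstrap draws are reproducible and shaped correctly", {
  fit <- tiny_fit()
  b1 <- parametric_bootstrap(fit, tiny_tab(), B = 2, seed = 9)
  expect_equal(dim(b1$draws), c(2L, 3L, 7L))
  b2 <- parametric_bootstrap(fit, tiny_tab(), B = 2, seed = 9)
  expect_identical(b1$draws, b2$draws)
  b3 <- parametric_bootstrap(fit, tiny_tab(), B = 2, seed = 10)
  expect_false(identical(b1$draws, b3$draws))
})

test_that("summaries satisfy the percentile-CI and mean identities", {
  fit <- tiny_fit()
  boot <- parametric_bootstrap(fit, tiny_tab(), B = 40, seed = 17)
  s <- boot$summary
  ok <- s$n_eff > 0
  expect_true(all(s$ci_lo[ok] <= s$boot_mean[ok] + 1e-12))
  expect_true(all(s$boot_mean[ok] <= s$ci_hi[ok] + 1e-12))
  expect_true(all(s$n_eff <= boot$B))

  # replicate-wise differencing: mean of difference draws equals the
  # difference of group means when no draws are censored
  d <- boot$draws
  for (k in dimnames(d)[[3]]) {
    if (!anyNA(d[, , k])) {
      expect_equal(mean(d[, 1, k] - d[, 2, k]),
                   mean(d[, 1, k]) - mean(d[, 2, k]), tolerance = 1e-12)
    }
  }
  dd <- boot$differences
  expect_true(all(dd$n_eff <= boot$B))
})

test_that("comparison rules behave on handcrafted draws", {
  groups <- c(18, 20)
  mk_boot <- function(draws) {
    plug <- data.frame(embryo_temp = groups)
    for (nm in tpcglmm:::descriptor_names) plug[[nm]] <- colMeans(draws[, , nm])
    structure(list(draws = draws,
                   summary = tpcglmm:::summarize_draws(draws, groups, plug),
                   differences = tpcglmm:::summarize_differences(draws, groups),
                   groups = groups, B = dim(draws)[1], n_failed = 0L, seed = 1),
              class = "tpc_bootstrap")
  }
  B <- 50
  draws <- array(NA_real_, c(B, 2, 7),
                 dimnames = list(NULL, groups, tpcglmm:::descriptor_names))
  # disjoint supports: both rules fire
  draws[, 1, ] <- matrix(runif(B * 7, 0, 1), B)
  draws[, 2, ] <- matrix(runif(B * 7, 2, 3), B)
  cmp <- compare_descriptors(mk_boot(draws))
  expect_true(all(cmp$sig_nonoverlap))
  expect_true(all(cmp$sig_difference))

  # identical draws: degenerate difference CI [0,0] is not significant
  draws[, 2, ] <- draws[, 1, ]
  cmp2 <- compare_descriptors(mk_boot(draws))
  expect_true(all(!cmp2$sig_nonoverlap))
  expect_true(all(!cmp2$sig_difference))
  expect_true(all(cmp2$diff_ci_lo == 0 & cmp2$diff_ci_hi == 0))

  # the overlap rule is conservative: nonoverlap implies difference-CI
  # significance on any draws
  set.seed(5)
  draws[, 1, ] <- matrix(rnorm(B * 7, 0, 1), B)
  draws[, 2, ] <- matrix(rnorm(B * 7, 1.5, 1), B)
  cmp3 <- compare_descriptors(mk_boot(draws))
  expect_true(all(!cmp3$sig_nonoverlap | cmp3$sig_difference))
})

test_that("censored draws are excluded and counted in n_eff", {
  groups <- c(18, 20)
  B <- 10
  draws <- array(runif(B * 2 * 7), c(B, 2, 7),
                 dimnames = list(NULL, groups, tpcglmm:::descriptor_names))
  draws[1:3, 1, "CTmax"] <- NA_real_
  plug <- data.frame(embryo_temp = groups)
  for (nm in tpcglmm:::descriptor_names) plug[[nm]] <- 0.5
  s <- tpcglmm:::summarize_draws(draws, groups, plug)
  expect_equal(s$n_eff[s$embryo_temp == 18 & s$descriptor == "CTmax"], 7L)
  d <- tpcglmm:::summarize_differences(draws, groups)
  expect_equal(d$n_eff[d$descriptor == "CTmax"], 7L)   # pairwise-complete
})

test_that("percentile CIs widen as the per-vial sample size shrinks", {
  widths <- sapply(c(30, 10, 4), function(n) {
    cfg <- shifted_topt_config(c("18" = 18, "20" = 19.5, "22" = 21),
                               design = tiny_design(n), seed = 300 + n)
    tab <- simulate_survival_table(cfg)
    fit <- fit_tpc_glmm(tab)
    boot <- parametric_bootstrap(fit, tab, B = 30, seed = 400 + n)
    s <- boot$summary
    mean((s$ci_hi - s$ci_lo)[s$descriptor == "Topt"])
  })
  expect_true(all(diff(widths) > 0))   # 30 < 10 < 4 per vial
})

test_that("profiled replicate refits track the joint Laplace refits in distribution", {
  cfg <- shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21.2),
                             design = reduced_design(), seed = 77)
  tab <- simulate_survival_table(cfg)
  fit <- fit_tpc_glmm(tab)
  bp <- parametric_bootstrap(fit, tab, B = 24, seed = 23, refits = "profiled")
  bj <- parametric_bootstrap(fit, tab, B = 24, seed = 23, refits = "joint")
  # same seed ladder => identical simulated responses. Individual replicates
  # may differ by a fraction of the replicate spread (the two schemes are
  # different estimators), but the draw distributions must agree: centers
  # within half a spread, spreads within a factor ~2.
  for (g in 1:3) {
    tp <- bp$draws[, g, "Topt"]; tj <- bj$draws[, g, "Topt"]
    expect_lt(abs(mean(tp) - mean(tj)), 0.5 * sd(tj))
    expect_gt(sd(tp) / sd(tj), 0.5)
    expect_lt(sd(tp) / sd(tj), 2)
  }
})

test_that("the base fit must have converged and a seed is mandatory", {
  fit <- tiny_fit()
  expect_error(parametric_bootstrap(fit, tiny_tab(), B = 2), "seed")
  bad <- fit; bad$converged <- FALSE
  expect_error(parametric_bootstrap(bad, tiny_tab(), B = 2, seed = 1),
               "converged")
})
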