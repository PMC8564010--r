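flat_config <- function(eta0, design, sigma_block = 0, sigma_vial = 0,
                        allocation = "balanced") {
  params <- lapply(tpcglmm:::group_keys(design), function(k) c(eta0, 0, 0, 0))
  names(params) <- tpcglmm:::group_keys(design)
  tpc_gen_config(design, params, sigma_block = sigma_block,
                 sigma_vial = sigma_vial, allocation = allocation)
}

test_that("row counts match the design combinatorics exactly", {
  # default design: 2 x 3 treatments x (9 temps x 4 + 1 temp x 2) vials x 30
  for (alloc in c("balanced", "incomplete")) {
    cfg <- shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21),
                               allocation = alloc, seed = 5)
    tab <- simulate_survival_table(cfg)
    expect_equal(nrow(tab), 2 * 3 * (9 * 4 + 1 * 2) * 30)
    agg <- tpcglmm:::aggregate_vials(tab)
    # every combination hits its replicate quota
    reps <- table(agg$fert_temp, agg$embryo_temp, agg$assay_temp)
    expect_true(all(reps[, , "27"] == 2), info = alloc)
    expect_true(all(reps[, , dimnames(reps)[[3]] != "27"] == 4), info = alloc)
  }
  # incomplete allocation respects the block-size range
  cfg <- shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21), seed = 5)
  tab <- simulate_survival_table(cfg)
  per_block <- tapply(tab$assay_temp, tab$block, function(x) length(unique(x)))
  expect_true(all(per_block >= 2 & per_block <= 5))
  expect_equal(length(per_block), 10L)
})

test_that("generation is deterministic given the seed", {
  cfg <- shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21),
                             design = tiny_design(), seed = 11)
  t1 <- simulate_survival_table(cfg)
  t2 <- simulate_survival_table(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_survival_table(cfg, seed = 12)
  expect_false(identical(t1$outcome, t3$outcome))
})

test_that("flat curves reproduce their inverse-logit survival fraction", {
  # ~10,000 individuals: tiny design at 139/vial = 72 vials x 139 = 10,008
  d <- tiny_design(n_per_vial = 139)
  tab0 <- simulate_survival_table(flat_config(0, d), seed = 21)
  expect_equal(mean(tab0$outcome), 0.5, tolerance = 0.02)  # +- 0.01 absolute
  expect_lt(abs(mean(tab0$outcome) - 0.5), 0.01)

  tab2 <- simulate_survival_table(flat_config(2, d), seed = 22)
  expect_lt(abs(mean(tab2$outcome) - plogis(2)), 0.01)
})

test_that("with zero SDs the per-temperature proportions converge to the curve", {
  # law of large numbers at ~1e5 individuals: 6 temps x 12 vials x 1400
  d <- tiny_design(n_per_vial = 1400)
  cfg <- shifted_topt_config(c("18" = 17, "20" = 19, "22" = 21), design = d,
                             sigma_block = 0, sigma_vial = 0,
                             allocation = "balanced")
  tab <- simulate_survival_table(cfg, seed = 31)
  df <- as.data.frame(tab)
  for (e in d$embryo_temps) {
    sub <- df[df$embryo_temp == e, ]
    prop <- tapply(sub$outcome, sub$assay_temp, mean)
    n_t <- tapply(sub$outcome, sub$assay_temp, length)
    key <- paste(d$fert_temps[1], e, sep = ":")
    truth <- plogis(tpcglmm:::cubic_eta(cfg$curve_params[[key]],
                                        as.numeric(names(prop))))
    se <- sqrt(truth * (1 - truth) / n_t)
    expect_true(all(abs(prop - truth) <= 3 * se),
                info = paste("embryo", e))
  }
})

test_that("block-level variance increases with sigma_block", {
  d <- tiny_design(n_per_vial = 60)
  between_block_var <- function(sigma, seed) {
    cfg <- shifted_topt_config(c("18" = 18, "20" = 19, "22" = 20), design = d,
                               sigma_block = sigma, sigma_vial = 0)
    v <- numeric(6)
    for (i in seq_along(v)) {
      tab <- simulate_survival_table(cfg, seed = seed + i)
      block_means <- tapply(tab$outcome, tab$block, mean)
      v[i] <- var(qlogis(pmin(pmax(block_means, 0.01), 0.99)))
    }
    mean(v)
  }
  expect_lt(between_block_var(0, 400), between_block_var(1.2, 500))
})

test_that("shifted_topt_config places the analytic optimum exactly", {
  topts <- c("18" = 19, "20" = 20, "22" = 21)
  cfg <- shifted_topt_config(topts, skew = 0)
  for (e in names(topts)) {
    b <- cfg$curve_params[[paste("18", e, sep = ":")]]
    expect_equal(-b[2] / (2 * b[3]), unname(topts[e]), tolerance = 1e-9)
    # shared height at the optimum
    expect_equal(tpcglmm:::cubic_eta(b, topts[[e]]), 2, tolerance = 1e-9)
  }
  expect_error(shifted_topt_config(c("18" = 19)), "every embryogenesis")
})

test_that("extreme linear predictors are clamped with a warning", {
  d <- tiny_design()
  params <- lapply(tpcglmm:::group_keys(d), function(k) c(50, 0, 0, 0))
  names(params) <- tpcglmm:::group_keys(d)
  cfg <- tpc_gen_config(d, params, sigma_block = 0, sigma_vial = 0,
                        allocation = "balanced")
  expect_warning(tab <- simulate_survival_table(cfg, seed = 41), "clamped")
  expect_true(all(tab$outcome == 1L))
})

test_that("generator configs round-trip through JSON", {
  cfg <- shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21.2),
                             design = tiny_design(), sigma_block = 0.25,
                             sigma_vial = 0.4, seed = 13)
  p <- withr::local_tempfile(fileext = ".json")
  write_gen_config(cfg, p)
  back <- read_gen_config(p)
  expect_equal(back$curve_params, cfg$curve_params, tolerance = 1e-12)
  expect_equal(back$sigma_block, cfg$sigma_block)
  expect_equal(unclass(back$design), unclass(cfg$design), tolerance = 1e-12)
  expect_identical(simulate_survival_table(back)$outcome,
                   simulate_survival_table(cfg)$outcome)
})

test_that("generator config validates its inputs", {
  d <- tiny_design()
  expect_error(tpc_gen_config(d, list()), "missing group")
  params <- lapply(tpcglmm:::group_keys(d), function(k) c(0, 0, 0))
  names(params) <- tpcglmm:::group_keys(d)
  expect_error(tpc_gen_config(d, params), "4 finite cubic")
  expect_error(simulate_survival_table(
    shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21), design = d)),
    "seed")
})
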