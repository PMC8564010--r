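#' Parametric bootstrap of curve descriptors
#'
#' Unconditional parametric bootstrap of the fitted model: each replicate
#' redraws block and vial intercepts from the fitted Normal variances,
#' computes per-vial survival probabilities over the original design rows,
#' draws fresh binomial outcomes, refits the full mixed model, and
#' re-extracts every embryogenesis group's descriptors. Replicate `r` uses
#' a child seed derived from `(seed, r)`, so the draws matrix is invariant
#' to execution order. Replicates whose refit fails are dropped and
#' counted; more than `0.1 * B` failures is an error.
#'
#' @param fit A converged [fit_tpc_glmm()] (or [fit_tpc_glm()], in which
#'   case no random effects are simulated) on the data in `table`.
#' @param table The [survival_table()] the model was fitted to (used only
#'   for its design rows; the original outcomes are not reused).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (required).
#' @param refits How each replicate is refitted: `"profiled"` (default)
#'   re-estimates the variance parameters by Laplace maximum likelihood
#'   with the fixed effects profiled out inside the penalized IRLS loop
#'   (lme4's `nAGQ = 0` scheme; an order of magnitude faster, and for
#'   binomial responses with non-trivial vial sizes its fixed effects agree
#'   closely with the joint fit), or `"joint"` for the full joint
#'   optimization used by the base fit.
#' @param search_range,breadth_fraction,limit_fraction,extrapolation_margin
#'   Passed to [extract_descriptors()].
#' @return Object of class `tpc_bootstrap`: list with `draws` (B x group x
#'   descriptor array, censored values `NA`), `summary` (per group x
#'   descriptor: plug-in estimate, bootstrap mean, percentile 95% CI,
#'   effective replicate count), `differences` (pairwise group differences,
#'   replicate-wise, with means and 95% CIs), `n_failed`, `B`, `seed`.
#' @export
parametric_bootstrap <- function(fit, table, B = 1000, seed,
                                 refits = c("profiled", "joint"),
                                 search_range = NULL,
                                 breadth_fraction = 0.5,
                                 limit_fraction = 0.05,
                                 extrapolation_margin = 10) {
  stopifnot(inherits(fit, "tpc_fit"), inherits(table, "survival_table"))
  refits <- match.arg(refits)
  if (!fit$converged) stop_validation("base fit has not converged")
  if (missing(seed)) stop_validation("a seed is required")
  B <- as.integer(B)
  search_range <- search_range %||% range(fit$basis$temps)

  fr <- fit$frame
  X <- stats::model.matrix(
    stats::delete.response(stats::terms(fixed_formula(fit$spec$degree, fit$factors))),
    fr, contrasts.arg = contrast_list(fit$spec, fit$factors))
  eta_fixed <- drop(X %*% fit$beta)
  groups <- embryo_levels(fit)
  seeds <- child_seeds(seed, B)

  is_glmm <- inherits(fit$model, "glmerMod")
  nb <- nlevels(fr$block); nv <- nlevels(fr$vial_uid)

  draws <- array(NA_real_, dim = c(B, length(groups), length(descriptor_names)),
                 dimnames = list(NULL, as.character(groups), descriptor_names))
  flags_censored <- array(FALSE, dim = dim(draws), dimnames = dimnames(draws))
  n_failed <- 0L
  ctrl <- glmer_fast_control()
  template <- if (!is_glmm) NULL
              else if (refits == "joint") fit$model
              else nagq0_template(fit, ctrl)
  ## coefficient maps depend on the design only, not on beta: build once
  emaps <- lapply(groups, function(e) embryo_coef_map(fit, e))

  for (r in seq_len(B)) {
    res <- with_seed(seeds[r], {
      u <- stats::rnorm(nb, 0, fit$sigma_block)[as.integer(fr$block)]
      v <- stats::rnorm(nv, 0, fit$sigma_vial)[as.integer(fr$vial_uid)]
      p <- stats::plogis(clamp_eta(eta_fixed + u + v, warn = FALSE))
      s_new <- stats::rbinom(nrow(fr), fr$size, p)
      refit_and_extract(fit, template, s_new, ctrl, groups, emaps,
                        search_range, breadth_fraction, limit_fraction,
                        extrapolation_margin)
    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      draws[r, , ] <- res$values
      flags_censored[r, , ] <- res$censored
    }
  }
  if (n_failed > 0.1 * B)
    stop_validation("%d of %d bootstrap replicates failed to converge", n_failed, B)

  draws[flags_censored] <- NA_real_
  plug_in <- extract_descriptors(fit, search_range = search_range,
                                 breadth_fraction = breadth_fraction,
                                 limit_fraction = limit_fraction,
                                 extrapolation_margin = extrapolation_margin)

  summary <- summarize_draws(draws, groups, plug_in)
  differences <- summarize_differences(draws, groups)
  structure(list(draws = draws, summary = summary, differences = differences,
                 n_failed = n_failed, B = B, seed = seed,
                 groups = groups, refits = refits,
                 settings = list(search_range = search_range,
                                 breadth_fraction = breadth_fraction,
                                 limit_fraction = limit_fraction,
                                 extrapolation_margin = extrapolation_margin)),
            class = "tpc_bootstrap")
}

## Template mixed model estimated with lme4's nAGQ = 0 scheme; replicate
## responses are swapped into it with lme4::refit.
nagq0_template <- function(fit, ctrl) {
  fo <- stats::update(fixed_formula(fit$spec$degree, fit$factors),
                      . ~ . + (1 | block) + (1 | vial_uid))
  withCallingHandlers(
    lme4::glmer(fo, data = fit$frame, family = stats::binomial(),
                contrasts = contrast_list(fit$spec, fit$factors),
                control = ctrl, nAGQ = 0),
    warning = function(w) invokeRestart("muffleWarning"))
}

## Refit the model with a new success vector and extract descriptors for
## every group; NULL on failure. Mixed fits go through lme4::refit (reuses
## the factorization structure), GLM fits through stats::glm.
refit_and_extract <- function(fit, template, s_new, ctrl, groups, emaps,
                              search_range, breadth_fraction, limit_fraction,
                              margin) {
  fr <- fit$frame
  newresp <- cbind(s_new, fr$size - s_new)
  refitted <- tryCatch(
    withCallingHandlers({
      if (inherits(template, "glmerMod")) {
        m <- lme4::refit(template, newresp = newresp, control = ctrl)
        list(beta = lme4::fixef(m))
      } else {
        fr2 <- fr; fr2$succ <- s_new; fr2$fail <- fr2$size - s_new
        m <- stats::glm(fixed_formula(fit$spec$degree, fit$factors),
                        data = fr2, family = stats::binomial(),
                        contrasts = contrast_list(fit$spec, fit$factors))
        list(beta = stats::coef(m))
      }
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(refitted) || anyNA(refitted$beta)) return(NULL)

  values <- matrix(NA_real_, length(groups), length(descriptor_names),
                   dimnames = list(as.character(groups), descriptor_names))
  censored <- matrix(FALSE, length(groups), length(descriptor_names),
                     dimnames = dimnames(values))
  for (i in seq_along(groups)) {
    a <- pad4(basis_to_monomial(fit$basis,
                                drop(emaps[[i]] %*% refitted$beta)))
    d <- cubic_descriptors(a, search_range, breadth_fraction,
                           limit_fraction, margin)
    values[i, ] <- d$values[descriptor_names]
    censored[i, ] <- vapply(d$flags[descriptor_names],
                            function(f) identical(f, "censored"), logical(1))
  }
  list(values = values, censored = censored)
}

summarize_draws <- function(draws, groups, plug_in) {
  out <- list()
  for (g in seq_along(groups)) {
    for (k in seq_along(descriptor_names)) {
      x <- draws[, g, k]
      ok <- !is.na(x)
      nm <- descriptor_names[k]
      out[[length(out) + 1L]] <- data.frame(
        embryo_temp = groups[g], descriptor = nm,
        estimate = plug_in[plug_in$embryo_temp == groups[g], nm],
        boot_mean = if (any(ok)) mean(x[ok]) else NA_real_,
        ci_lo = if (any(ok)) stats::quantile(x[ok], 0.025, names = FALSE) else NA_real_,
        ci_hi = if (any(ok)) stats::quantile(x[ok], 0.975, names = FALSE) else NA_real_,
        n_eff = sum(ok))
    }
  }
  do.call(rbind, out)
}

summarize_differences <- function(draws, groups) {
  pairs <- utils::combn(seq_along(groups), 2)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    for (k in seq_along(descriptor_names)) {
      dx <- draws[, a, k] - draws[, b, k]   # pairwise-complete by NA arithmetic
      ok <- !is.na(dx)
      out[[length(out) + 1L]] <- data.frame(
        pair = paste(groups[a], "-", groups[b]),
        descriptor = descriptor_names[k],
        mean = if (any(ok)) mean(dx[ok]) else NA_real_,
        ci_lo = if (any(ok)) stats::quantile(dx[ok], 0.025, names = FALSE) else NA_real_,
        ci_hi = if (any(ok)) stats::quantile(dx[ok], 0.975, names = FALSE) else NA_real_,
        n_eff = sum(ok))
    }
  }
  do.call(rbind, out)
}

#' Compare descriptors among groups with both significance rules
#'
#' Applies the two decision rules to a bootstrap result: (a) two groups
#' differ if their individual 95% CIs do not overlap (conservative), and
#' (b) they differ if the 95% percentile CI of their replicate-wise
#' difference excludes 0 (closed interval: a degenerate CI at exactly 0 is
#' not significant). Rule (a) significant implies rule (b) significant on
#' the same draws.
#'
#' @param result A [parametric_bootstrap()] result.
#' @return Data frame of class `tpc_comparison` with one row per
#'   descriptor x group pair: both groups' CIs, the difference CI, and
#'   logical columns `sig_nonoverlap` and `sig_difference`.
#' @export
compare_descriptors <- function(result) {
  stopifnot(inherits(result, "tpc_bootstrap"))
  s <- result$summary
  d <- result$differences
  rows <- list()
  for (i in seq_len(nrow(d))) {
    gs <- strsplit(d$pair[i], " - ", fixed = TRUE)[[1]]
    sa <- s[s$embryo_temp == as.numeric(gs[1]) & s$descriptor == d$descriptor[i], ]
    sb <- s[s$embryo_temp == as.numeric(gs[2]) & s$descriptor == d$descriptor[i], ]
    nonoverlap <- isTRUE(sa$ci_lo > sb$ci_hi || sb$ci_lo > sa$ci_hi)
    excl0 <- isTRUE(d$ci_lo[i] > 0 || d$ci_hi[i] < 0)
    rows[[i]] <- data.frame(
      descriptor = d$descriptor[i], pair = d$pair[i],
      ci_lo_1 = sa$ci_lo, ci_hi_1 = sa$ci_hi,
      ci_lo_2 = sb$ci_lo, ci_hi_2 = sb$ci_hi,
      diff_mean = d$mean[i], diff_ci_lo = d$ci_lo[i], diff_ci_hi = d$ci_hi[i],
      sig_nonoverlap = nonoverlap, sig_difference = excl0)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tpc_comparison", "data.frame")
  out
}

#' @export
print.tpc_bootstrap <- function(x, ...) {
  cat(sprintf("Parametric bootstrap: B = %d (%d failed), seed = %s\n",
              x$B, x$n_failed, format(x$seed)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
print.tpc_comparison <- function(x, ...) {
  cat("Descriptor comparisons (CI-overlap and difference-CI rules):\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
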