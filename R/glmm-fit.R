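#' Specify the thermal-performance model
#'
#' Fixed effects: the full factorial of the degree-`degree` orthogonal
#' polynomial trend in assay temperature with the fertilization and
#' embryogenesis factors (all lower-order terms included), giving
#' `(degree + 1) * n_fert * n_embryo` fixed parameters (24 for the default
#' design). Random effects: intercepts for block and for vial nested in
#' block. Link: logit.
#'
#' @param degree Polynomial degree of the thermal trend (default 3).
#' @param contrasts Factor coding for the two treatment factors:
#'   `"treatment"` (reference = lowest temperature) or `"sum"`. All
#'   reported quantities are coding-invariant.
#' @return Object of class `tpc_model_spec`.
#' @export
tpc_model_spec <- function(degree = 3L, contrasts = c("treatment", "sum")) {
  contrasts <- match.arg(contrasts)
  structure(list(degree = as.integer(degree), contrasts = contrasts),
            class = "tpc_model_spec")
}

## Collapse individual rows to one binomial row per vial. The binomial
## likelihood factorizes over individuals sharing covariates and random
## effects, so this is exact and much faster than Bernoulli rows.
aggregate_vials <- function(table) {
  df <- as.data.frame(table)
  key <- interaction(df$block, df$vial, df$fert_temp, df$embryo_temp,
                     df$assay_temp, drop = TRUE, sep = "\r")
  idx <- !duplicated(key)
  agg <- df[idx, c("block", "vial", "fert_temp", "embryo_temp", "assay_temp")]
  succ <- tapply(df$outcome, key, sum)
  size <- tapply(df$outcome, key, length)
  ord <- match(as.character(key[idx]), names(succ))
  agg$succ <- as.integer(succ[ord])
  agg$size <- as.integer(size[ord])
  agg$fail <- agg$size - agg$succ
  agg$block <- factor(agg$block)
  agg$vial_uid <- factor(paste(agg$block, agg$vial, sep = ":"))
  rownames(agg) <- NULL
  agg[order(agg$block, agg$fert_temp, agg$embryo_temp, agg$assay_temp), ]
}

## Model frame for the fixed-effect structure: basis columns P1..Pd plus
## ordered treatment factors with the requested coding.
build_model_frame <- function(agg, basis, spec) {
  d <- basis$degree
  P <- predict(basis, agg$assay_temp)
  fr <- agg
  for (j in seq_len(d)) fr[[paste0("P", j)]] <- P[, j]
  fr$fert <- factor(agg$fert_temp)
  fr$embryo <- factor(agg$embryo_temp)
  fr
}

## Fixed-effect formula; factors with a single level in the data are
## dropped (no contrast is estimable for them).
fixed_formula <- function(degree, factors = c("fert", "embryo"),
                          response = TRUE) {
  poly_part <- paste0("(", paste0("P", seq_len(degree), collapse = " + "), ")")
  rhs <- paste(c(poly_part, factors), collapse = " * ")
  lhs <- if (response) "cbind(succ, fail) ~ " else "~ "
  stats::as.formula(paste0(lhs, rhs))
}

contrast_list <- function(spec, factors = c("fert", "embryo")) {
  if (length(factors) == 0) return(NULL)
  fun <- if (spec$contrasts == "sum") "contr.sum" else "contr.treatment"
  stats::setNames(as.list(rep(fun, length(factors))), factors)
}

## Fast optimizer settings: nloptwrap bobyqa with explicit stopping rules.
## The absolute tolerances matter: with flat likelihood directions (small
## vials, boundary variance estimates) the default rules can leave bobyqa
## polishing noise for thousands of evaluations.
glmer_fast_control <- function() {
  lme4::glmerControl(optimizer = "nloptwrap", calc.derivs = FALSE,
                     check.conv.grad = "ignore",
                     check.conv.singular = "ignore",
                     check.conv.hess = "ignore",
                     optCtrl = list(maxeval = 800, xtol_abs = 1e-6,
                                    ftol_abs = 1e-6))
}

## Separation screen: a treatment cell whose outcomes are constant across
## the whole temperature axis cannot identify its curve.
detect_separation <- function(agg) {
  cells <- split(agg, interaction(agg$fert_temp, agg$embryo_temp, drop = TRUE))
  any(vapply(cells, function(cl) {
    tot <- sum(cl$succ); n <- sum(cl$size)
    tot == 0L || tot == n
  }, logical(1)))
}

#' Fit the binomial mixed-effects thermal performance model
#'
#' Maximizes the Laplace-approximated marginal likelihood of the model in
#' [tpc_model_spec()] (backed by `lme4::glmer`; penalized IRLS for the
#' conditional modes inside a derivative-free optimization of the variance
#' parameters). Boundary fits (an SD estimated at 0) are reported, not
#' treated as failures. Individual rows are aggregated to vial-level
#' binomial counts before fitting, which leaves the likelihood unchanged.
#'
#' @param table A [survival_table()].
#' @param spec A [tpc_model_spec()].
#' @param fast If `TRUE` (default) use the fast optimizer settings
#'   (nloptwrap bobyqa, no finite-difference derivative check); if `FALSE`
#'   use the lme4 defaults.
#' @return Object of class `tpc_fit` with elements `beta` (fixed-effect
#'   coefficients), `vcov_beta`, `sigma_block`, `sigma_vial`, `loglik`,
#'   `converged`, `boundary` (named logical: which SDs collapsed to ~0),
#'   `separation`, `basis` (the [poly_basis()]), `spec`, `frame` (the
#'   vial-level model frame), `model` (the underlying fit), `re_modes`.
#' @export
fit_tpc_glmm <- function(table, spec = tpc_model_spec(), fast = TRUE) {
  pre <- prepare_fit(table, spec)
  ctrl <- if (fast) glmer_fast_control() else lme4::glmerControl()
  fo <- stats::update(fixed_formula(spec$degree, pre$factors),
                      . ~ . + (1 | block) + (1 | vial_uid))
  fit <- withCallingHandlers(
    tryCatch(lme4::glmer(fo, data = pre$frame, family = stats::binomial(),
                         contrasts = contrast_list(spec, pre$factors),
                         control = ctrl),
             error = function(e) e),
    warning = function(w) invokeRestart("muffleWarning"))
  if (inherits(fit, "error")) {
    if (grepl("rank", conditionMessage(fit), ignore.case = TRUE)) stop(fit)
    return(make_failed_fit(pre, spec, conditionMessage(fit)))
  }

  vc <- lme4::VarCorr(fit)
  sigma_block <- attr(vc$block, "stddev")[[1]]
  sigma_vial <- attr(vc$vial_uid, "stddev")[[1]]
  conv_ok <- is.null(fit@optinfo$conv$lme4$code) &&
    (fit@optinfo$conv$opt %in% c(0, 1, 2, 3, 4))
  out <- new_tpc_fit(
    beta = lme4::fixef(fit),
    vcov_beta = as.matrix(stats::vcov(fit)),
    sigma_block = sigma_block,
    sigma_vial = sigma_vial,
    loglik = as.numeric(stats::logLik(fit)),
    converged = conv_ok && !pre$separation,
    separation = pre$separation,
    boundary = c(block = sigma_block < 1e-4, vial = sigma_vial < 1e-4),
    basis = pre$basis, spec = spec, factors = pre$factors,
    frame = pre$frame, model = fit,
    re_modes = lme4::ranef(fit),
    message = if (pre$separation) "complete separation in a treatment cell" else NULL)
  out
}

#' Fit the fixed-effects-only binomial GLM
#'
#' Same fixed-effect structure as [fit_tpc_glmm()] with both random-effect
#' SDs fixed at zero; standard binomial IRLS. Serves as the degenerate-case
#' reference and as a fallback when the mixed model is not identifiable.
#'
#' @inheritParams fit_tpc_glmm
#' @return A `tpc_fit` with `sigma_block = sigma_vial = 0`.
#' @export
fit_tpc_glm <- function(table, spec = tpc_model_spec()) {
  pre <- prepare_fit(table, spec)
  fit <- withCallingHandlers(
    stats::glm(fixed_formula(spec$degree, pre$factors), data = pre$frame,
               family = stats::binomial(),
               contrasts = contrast_list(spec, pre$factors)),
    warning = function(w) invokeRestart("muffleWarning"))
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_validation("rank-deficient fixed-effect design; aliased: %s",
                    paste(aliased, collapse = ", "))
  }
  new_tpc_fit(
    beta = stats::coef(fit),
    vcov_beta = as.matrix(stats::vcov(fit)),
    sigma_block = 0, sigma_vial = 0,
    loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged && !pre$separation,
    separation = pre$separation,
    boundary = c(block = NA, vial = NA),
    basis = pre$basis, spec = spec, factors = pre$factors,
    frame = pre$frame, model = fit,
    re_modes = NULL,
    message = if (pre$separation) "complete separation in a treatment cell" else NULL)
}

prepare_fit <- function(table, spec) {
  stopifnot(inherits(table, "survival_table"), inherits(spec, "tpc_model_spec"))
  df <- as.data.frame(table)
  if (length(unique(df$assay_temp)) < spec$degree + 1L)
    stop_validation("need >= %d distinct assay temperatures for degree %d",
                    spec$degree + 1L, spec$degree)
  ## basis built on the observation-level (per-individual) temperature
  ## vector so replicate weighting matches standard software
  basis <- poly_basis(df$assay_temp, spec$degree)
  agg <- aggregate_vials(table)
  frame <- build_model_frame(agg, basis, spec)
  factors <- c(if (nlevels(frame$fert) > 1) "fert",
               if (nlevels(frame$embryo) > 1) "embryo")
  list(basis = basis, frame = frame, factors = factors,
       separation = detect_separation(agg))
}

new_tpc_fit <- function(...) {
  structure(list(...), class = "tpc_fit")
}

make_failed_fit <- function(pre, spec, msg) {
  p <- (spec$degree + 1L) * nlevels(pre$frame$fert) * nlevels(pre$frame$embryo)
  new_tpc_fit(beta = rep(NA_real_, p), vcov_beta = matrix(NA_real_, p, p),
              sigma_block = NA_real_, sigma_vial = NA_real_,
              loglik = NA_real_, converged = FALSE,
              separation = pre$separation,
              boundary = c(block = NA, vial = NA),
              basis = pre$basis, spec = spec, factors = pre$factors,
              frame = pre$frame,
              model = NULL, re_modes = NULL, message = msg)
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("Binomial thermal-performance model",
      if (x$sigma_block == 0 && x$sigma_vial == 0 && !anyNA(x$boundary)) "(GLM)"
      else "(GLMM, Laplace)", "\n")
  cat(sprintf("  %d fixed effects; sigma_block = %.4f, sigma_vial = %.4f\n",
              length(x$beta), x$sigma_block, x$sigma_vial))
  cat(sprintf("  logLik = %.2f; converged: %s\n", x$loglik, x$converged))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' @export
coef.tpc_fit <- function(object, ...) object$beta

#' @export
vcov.tpc_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.tpc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) +
              2 * !(anyNA(object$boundary)), class = "logLik")
}

## Linear maps from beta to the (intercept, P1..Pd) coefficients of each
## treatment cell's logit curve. Returns a list keyed "<fert>:<embryo>" of
## (d+1) x p matrices A with curve coefficients = A %*% beta.
cell_coef_maps <- function(fit) {
  d <- fit$spec$degree
  tt <- stats::delete.response(stats::terms(fixed_formula(d, fit$factors)))
  fr <- fit$frame
  xlev <- list(fert = levels(fr$fert), embryo = levels(fr$embryo))
  ctr <- contrast_list(fit$spec, fit$factors)
  maps <- list()
  for (f in xlev$fert) {
    for (e in xlev$embryo) {
      nd <- as.data.frame(c(
        stats::setNames(as.list(rep(0, d)), paste0("P", seq_len(d))),
        list(fert = factor(f, levels = xlev$fert),
             embryo = factor(e, levels = xlev$embryo))))
      nd <- nd[rep(1, d + 1L), , drop = FALSE]
      for (j in seq_len(d)) nd[[paste0("P", j)]][j + 1L] <- 1
      X <- stats::model.matrix(tt, nd, contrasts.arg = ctr)
      A <- X
      A[-1, ] <- sweep(X[-1, , drop = FALSE], 2, X[1, ], "-")
      maps[[paste(f, e, sep = ":")]] <- A
    }
  }
  maps
}

## Linear map from beta to the (intercept, P1..Pd) coefficients of the
## embryogenesis-level curve: fertilization levels averaged with equal
## weights on the logit scale.
embryo_coef_map <- function(fit, embryo_temp) {
  maps <- cell_coef_maps(fit)
  ferts <- levels(fit$frame$fert)
  keys <- paste(ferts, embryo_temp, sep = ":")
  if (!all(keys %in% names(maps)))
    stop_validation("unknown embryogenesis level: %s", embryo_temp)
  Reduce(`+`, maps[keys]) / length(keys)
}

embryo_levels <- function(fit) as.numeric(levels(fit$frame$embryo))

## Synthetic stand-in fit for testing: constructs a tpc_fit object whose
## population-level logit curve for each treatment cell equals a given raw
## cubic exactly (beta is solved from the stacked cell coefficient maps).
## `cubics` is a named list keyed by embryo level (curve shared across
## fertilization levels) or by "<fert>:<embryo>". Not a real model fit:
## vcov is a small identity, loglik NA.
synthetic_fit_from_cubics <- function(cubics, temps,
                                      fert_levels = c(18, 22),
                                      degree = 3L,
                                      contrasts = "treatment") {
  spec <- tpc_model_spec(degree = degree, contrasts = contrasts)
  basis <- poly_basis(temps, degree)
  embryo_keys <- if (all(grepl(":", names(cubics)))) {
    unique(vapply(strsplit(names(cubics), ":"), `[`, "", 2))
  } else names(cubics)
  frame <- expand.grid(fert = factor(fert_levels),
                       embryo = factor(as.numeric(embryo_keys)),
                       KEEP.OUT.ATTRS = FALSE)
  frame$size <- 1L
  factors <- c(if (nlevels(frame$fert) > 1) "fert",
               if (nlevels(frame$embryo) > 1) "embryo")
  fit <- new_tpc_fit(beta = NULL, vcov_beta = NULL,
                     sigma_block = 0, sigma_vial = 0,
                     loglik = NA_real_, converged = TRUE, separation = FALSE,
                     boundary = c(block = NA, vial = NA),
                     basis = basis, spec = spec, factors = factors,
                     frame = frame, model = NULL, re_modes = NULL,
                     message = "synthetic fit (not estimated from data)")
  maps <- cell_coef_maps(fit)

  ## basis-scale representation of a raw cubic: match eta at degree+1 nodes
  nodes <- seq(min(temps), max(temps), length.out = degree + 1L)
  M <- cbind(1, predict(basis, nodes))
  target <- function(key, e) {
    a <- cubics[[key]] %||% cubics[[e]]
    if (is.null(a)) stop_validation("no cubic supplied for cell %s", key)
    solve(M, cubic_eta(pad4(a), nodes))
  }
  A_all <- do.call(rbind, maps)
  c_all <- unlist(lapply(names(maps), function(k)
    target(k, strsplit(k, ":")[[1]][2])))
  beta <- qr.solve(A_all, c_all)
  fit$beta <- stats::setNames(drop(beta), colnames(A_all))
  fit$vcov_beta <- diag(1e-6, length(beta))
  fit
}
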