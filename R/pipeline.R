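#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the simulate - fit - test - descriptors -
#' bootstrap - report chain. All randomness flows from two named seeds:
#' `data_seed` (synthetic data) and `boot_seed` (bootstrap replicates).
#'
#' @param topts Named vector of true thermal optima per embryogenesis
#'   temperature for the generator (see [shifted_topt_config()]).
#' @param data_seed,boot_seed Integer seeds.
#' @param B Bootstrap replicate count.
#' @param design An [experiment_design()].
#' @param peak_logit,width,skew,sigma_block,sigma_vial,allocation Generator
#'   settings, see [shifted_topt_config()].
#' @param degree,contrasts Model settings, see [tpc_model_spec()].
#' @param breadth_fraction,limit_fraction,extrapolation_margin Descriptor
#'   settings, see [extract_descriptors()].
#' @return Object of class `tpc_run_config`.
#' @export
pipeline_config <- function(topts = c("18" = 19, "20" = 20.4, "22" = 21.2),
                            data_seed = 1, boot_seed = 2, B = 1000,
                            design = experiment_design(),
                            peak_logit = 2, width = 0.05, skew = 0,
                            sigma_block = 0.3, sigma_vial = 0.3,
                            allocation = "incomplete",
                            degree = 3, contrasts = "treatment",
                            breadth_fraction = 0.5, limit_fraction = 0.05,
                            extrapolation_margin = 10) {
  structure(list(topts = topts, data_seed = data_seed, boot_seed = boot_seed,
                 B = B, design = design, peak_logit = peak_logit,
                 width = width, skew = skew, sigma_block = sigma_block,
                 sigma_vial = sigma_vial, allocation = allocation,
                 degree = degree, contrasts = contrasts,
                 breadth_fraction = breadth_fraction,
                 limit_fraction = limit_fraction,
                 extrapolation_margin = extrapolation_margin),
            class = "tpc_run_config")
}

config_hash <- function(config) {
  flat <- unlist(config[setdiff(names(config), "design")])
  fnv1a32(paste(c(names(flat), format(flat, digits = 15),
                  format(unlist(config$design), digits = 15)), collapse = "|"))
}

provenance <- function(config) {
  list(package = "tpcglmm",
       version = as.character(utils::packageVersion("tpcglmm")),
       config_hash = config_hash(config),
       data_seed = config$data_seed,
       boot_seed = config$boot_seed)
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

## Serializable representation of a fit (coefficients, covariance, SDs,
## basis constants with run-length-encoded construction temps, spec).
fit_to_list <- function(fit) {
  tt <- table(fit$basis$temps)
  list(beta = as.list(fit$beta),
       vcov_beta = unname(apply(fit$vcov_beta, 1, as.list)),
       sigma_block = fit$sigma_block,
       sigma_vial = fit$sigma_vial,
       loglik = fit$loglik,
       converged = fit$converged,
       separation = fit$separation,
       boundary = as.list(fit$boundary),
       basis = list(degree = fit$basis$degree,
                    alpha = fit$basis$alpha,
                    norm2 = fit$basis$norm2,
                    temp_values = as.numeric(names(tt)),
                    temp_counts = as.integer(tt)),
       spec = unclass(fit$spec))
}

#' Run the full analysis pipeline
#'
#' Chains the whole method end to end on synthetic data: simulate a
#' survival table, fit the mixed model, run the grouped Wald tests and
#' trend contrasts, extract descriptors, bootstrap them, and apply both
#' significance rules. Writes `data.csv`, `fit.json`, `tests.csv`,
#' `trends.csv`, `descriptors.csv`, `boot.json`, `compare.csv`, and
#' `summary.txt` into `out_dir`; every JSON artifact embeds the package
#' version, a config hash, and the seeds. Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts (`table`, `fit`,
#'   `wald`, `trends`, `descriptors`, `bootstrap`, `comparison`, `paths`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "tpc_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  prov <- provenance(config)
  paths <- file.path(out_dir, c(data = "data.csv", fit = "fit.json",
                                tests = "tests.csv", trends = "trends.csv",
                                descriptors = "descriptors.csv",
                                boot = "boot.json", compare = "compare.csv",
                                summary = "summary.txt"))
  names(paths) <- c("data", "fit", "tests", "trends", "descriptors",
                    "boot", "compare", "summary")

  gen <- stage("simulate", shifted_topt_config(
    config$topts, design = config$design, peak_logit = config$peak_logit,
    width = config$width, skew = config$skew,
    sigma_block = config$sigma_block, sigma_vial = config$sigma_vial,
    allocation = config$allocation, seed = config$data_seed))
  tab <- stage("simulate", simulate_survival_table(gen))
  write_survival_csv(tab, paths["data"])
  say("simulate", "%d individuals -> %s", nrow(tab), paths["data"])

  spec <- tpc_model_spec(degree = config$degree, contrasts = config$contrasts)
  fit <- stage("fit", fit_tpc_glmm(tab, spec))
  write_json_artifact(c(prov, fit_to_list(fit)), paths["fit"])
  say("fit", "logLik %.2f, sigma_block %.3f, sigma_vial %.3f",
      fit$loglik, fit$sigma_block, fit$sigma_vial)

  wald <- stage("tests", wald_tests(fit))
  utils::write.csv(as.data.frame(wald), paths["tests"], row.names = FALSE)
  trends <- stage("tests", trend_contrasts(fit))
  utils::write.csv(trends$contrasts, paths["trends"], row.names = FALSE)
  say("tests", "embryo x trend: chi2 = %.2f on %d df",
      wald$chi2[wald$term == "embryo:trend"], wald$df[wald$term == "embryo:trend"])

  des <- stage("descriptors", extract_descriptors(
    fit, breadth_fraction = config$breadth_fraction,
    limit_fraction = config$limit_fraction,
    extrapolation_margin = config$extrapolation_margin))
  utils::write.csv(as.data.frame(des), paths["descriptors"], row.names = FALSE)
  say("descriptors", "Topt: %s",
      paste(sprintf("%.2f", des$Topt), collapse = ", "))

  boot <- stage("bootstrap", parametric_bootstrap(
    fit, tab, B = config$B, seed = config$boot_seed,
    breadth_fraction = config$breadth_fraction,
    limit_fraction = config$limit_fraction,
    extrapolation_margin = config$extrapolation_margin))
  write_json_artifact(
    c(prov, list(B = boot$B, n_failed = boot$n_failed,
                 groups = boot$groups,
                 descriptors = descriptor_names,
                 draws = unname(lapply(seq_along(boot$groups), function(g)
                   unname(apply(boot$draws[, g, , drop = FALSE], 3, as.list)))),
                 summary = boot$summary, differences = boot$differences)),
    paths["boot"])
  cmp <- stage("report", compare_descriptors(boot))
  utils::write.csv(as.data.frame(cmp), paths["compare"], row.names = FALSE)
  say("bootstrap", "B = %d, %d failed", boot$B, boot$n_failed)

  writeLines(c(
    sprintf("tpcglmm %s  (config %s; data_seed %s, boot_seed %s)",
            prov$version, prov$config_hash, prov$data_seed, prov$boot_seed),
    sprintf("individuals: %d, vials: %d", nrow(tab), nrow(fit$frame)),
    sprintf("sigma_block %.4f, sigma_vial %.4f, logLik %.2f",
            fit$sigma_block, fit$sigma_vial, fit$loglik),
    "",
    "Wald tests:",
    utils::capture.output(print(as.data.frame(wald), digits = 4)),
    "",
    "Descriptors:",
    utils::capture.output(print(as.data.frame(des), digits = 5)),
    "",
    "Comparisons:",
    utils::capture.output(print(as.data.frame(cmp), digits = 4))),
    paths["summary"])
  invisible(list(table = tab, fit = fit, wald = wald, trends = trends,
                 descriptors = des, bootstrap = boot, comparison = cmp,
                 paths = paths))
}
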