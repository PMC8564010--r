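#' Configure the synthetic survival-data generator
#'
#' The generator draws individual binary outcomes from the same model the
#' analysis assumes: a logit-scale cubic thermal performance curve per
#' treatment group, plus Normal block and vial-in-block random intercepts.
#'
#' @param design An [experiment_design()].
#' @param curve_params Named list of logit-scale cubic coefficient vectors
#'   `c(b0, b1, b2, b3)` (eta(T) = b0 + b1 T + b2 T^2 + b3 T^3), one per
#'   treatment group, named `"<fert>:<embryo>"` (e.g. `"18:20"`). Every
#'   group in the design must be covered.
#' @param sigma_block SD of the block random intercept (logit units, >= 0).
#' @param sigma_vial SD of the vial random intercept (logit units, >= 0).
#' @param allocation `"incomplete"` (blocks receive random subsets of assay
#'   temperatures under replicate quotas) or `"balanced"` (deterministic:
#'   block r receives every temperature with replicate quota >= r).
#' @param seed Default seed used by [simulate_survival_table()].
#' @return Object of class `tpc_gen_config`.
#' @seealso [shifted_topt_config()] for a descriptor-based parameterization.
#' @export
tpc_gen_config <- function(design = experiment_design(),
                           curve_params,
                           sigma_block = 0.3,
                           sigma_vial = 0.3,
                           allocation = c("incomplete", "balanced"),
                           seed = NULL) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(design, "experiment_design"),
            sigma_block >= 0, sigma_vial >= 0)
  need <- group_keys(design)
  missing_groups <- setdiff(need, names(curve_params))
  if (length(missing_groups))
    stop_validation("curve_params missing group(s): %s",
                    paste(missing_groups, collapse = ", "))
  for (k in need) {
    b <- curve_params[[k]]
    if (!is.numeric(b) || length(b) != 4 || any(!is.finite(b)))
      stop_validation("curve_params[['%s']] must be 4 finite cubic coefficients", k)
  }
  structure(list(design = design,
                 curve_params = curve_params[need],
                 sigma_block = sigma_block,
                 sigma_vial = sigma_vial,
                 allocation = allocation,
                 seed = seed),
            class = "tpc_gen_config")
}

group_keys <- function(design) {
  g <- expand.grid(fert = design$fert_temps, embryo = design$embryo_temps,
                   KEEP.OUT.ATTRS = FALSE)
  paste(g$fert, g$embryo, sep = ":")
}

## eta(T) for a raw cubic coefficient vector
cubic_eta <- function(b, temps) b[1] + b[2] * temps + b[3] * temps^2 + b[4] * temps^3

#' Generator config with group-specific thermal optima
#'
#' Convenience parameterization: all groups share peak height and
#' curvature on the logit scale, but each embryogenesis temperature's curve
#' is centred at its own thermal optimum,
#' `eta(T) = peak_logit - width (T - Topt)^2 + skew (T - Topt)^3`.
#' There is no fertilization effect. With `skew = 0` the true descriptors
#' have closed forms, which the test-suite oracles exploit.
#'
#' @param topts Named numeric vector mapping each embryogenesis temperature
#'   (as character) to its true thermal optimum (degC), e.g.
#'   `c("18" = 19, "20" = 20, "22" = 21.2)`.
#' @param design An [experiment_design()].
#' @param peak_logit Logit-scale curve height at the optimum (default 2,
#'   i.e. peak survival 0.88).
#' @param width Quadratic curvature per degC^2 (default 0.05).
#' @param skew Cubic coefficient probing asymmetry (default 0).
#' @inheritParams tpc_gen_config
#' @return A [tpc_gen_config()].
#' @export
shifted_topt_config <- function(topts,
                                design = experiment_design(),
                                peak_logit = 2,
                                width = 0.05,
                                skew = 0,
                                sigma_block = 0.3,
                                sigma_vial = 0.3,
                                allocation = "incomplete",
                                seed = NULL) {
  keys <- as.character(design$embryo_temps)
  if (!all(keys %in% names(topts)))
    stop_validation("topts must name every embryogenesis temperature: %s",
                    paste(keys, collapse = ", "))
  params <- list()
  for (f in design$fert_temps) {
    for (e in design$embryo_temps) {
      t0 <- topts[[as.character(e)]]
      ## expand peak - w (T-t0)^2 + s (T-t0)^3 into raw monomials
      b <- c(peak_logit - width * t0^2 - skew * t0^3,
             2 * width * t0 + 3 * skew * t0^2,
             -width - 3 * skew * t0,
             skew)
      params[[paste(f, e, sep = ":")]] <- b
    }
  }
  tpc_gen_config(design, params, sigma_block = sigma_block,
                 sigma_vial = sigma_vial, allocation = allocation, seed = seed)
}

## Allocate assay temperatures to blocks.
## incomplete: every temperature t must land in exactly replicates[t]
## distinct blocks; block sizes are drawn within temps_per_block so sizes
## sum to the total quota, then temperatures are placed largest remaining
## quota first into blocks with most remaining capacity (random tie-break),
## which is feasibility-preserving (Gale-Ryser style greedy).
## balanced: block r deterministically receives all temps with quota >= r.
allocate_blocks <- function(design, allocation) {
  temps <- design$assay_temps
  reps <- design$replicates
  if (allocation == "balanced") {
    nb <- max(reps)
    return(lapply(seq_len(nb), function(r) temps[reps >= r]))
  }
  nb <- design$n_blocks
  lo <- design$temps_per_block[1]; hi <- design$temps_per_block[2]
  Q <- sum(reps)
  if (Q < nb * lo || Q > nb * hi)
    stop_validation("replicate quota %d infeasible for %d blocks of %d-%d temps",
                    Q, nb, lo, hi)
  if (max(reps) > nb)
    stop_validation("a replicate quota exceeds the number of blocks")

  ## block sizes: base + randomly placed remainder, kept within [lo, hi]
  sizes <- rep(Q %/% nb, nb)
  extra <- Q - sum(sizes)
  if (extra > 0) {
    bump <- sample.int(nb, extra)
    sizes[bump] <- sizes[bump] + 1L
  }
  sizes <- pmin(pmax(sizes, lo), hi)
  while (sum(sizes) != Q) {     # repair any clamping drift
    d <- Q - sum(sizes)
    i <- if (d > 0) which(sizes < hi)[1] else which(sizes > lo)[1]
    sizes[i] <- sizes[i] + sign(d)
  }

  capacity <- sizes
  assign <- lapply(seq_len(nb), function(i) numeric(0))
  remaining <- reps
  while (any(remaining > 0)) {
    t_ord <- order(-remaining, stats::runif(length(remaining)))
    t <- t_ord[1]
    open <- which(capacity > 0 &
                  !vapply(assign, function(a) temps[t] %in% a, logical(1)))
    if (length(open) < remaining[t])
      stop_validation("block allocation infeasible; adjust temps_per_block")
    pick <- open[order(-capacity[open], stats::runif(length(open)))][seq_len(remaining[t])]
    for (b in pick) assign[[b]] <- c(assign[[b]], temps[t])
    capacity[pick] <- capacity[pick] - 1L
    remaining[t] <- 0
  }
  lapply(assign, sort)
}

#' Simulate an individual-level survival table
#'
#' For each block a Normal(0, sigma_block^2) intercept is drawn; the block
#' receives a set of assay temperatures according to the configured
#' allocation; each block x treatment x assay-temperature cell holds one
#' vial with its own Normal(0, sigma_vial^2) intercept; each of the
#' `n_per_vial` individuals survives with probability
#' `plogis(eta_group(T) + u_block + v_vial)`. Deterministic given the seed:
#' each block consumes its own child RNG stream, so earlier blocks are
#' unaffected by adding later ones.
#'
#' @param config A [tpc_gen_config()].
#' @param seed Integer seed (falls back to `config$seed`).
#' @return A [survival_table()].
#' @examples
#' cfg <- shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21), seed = 1)
#' tab <- simulate_survival_table(cfg)
#' nrow(tab)  # 6840 for the default design
#' @export
simulate_survival_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "tpc_gen_config"))
  if (is.null(seed)) stop_validation("a seed is required (config$seed or argument)")
  design <- config$design

  with_seed(seed, {
    blocks <- allocate_blocks(design, config$allocation)
    seeds <- child_seeds(seed + 1L, length(blocks))
    groups <- expand.grid(fert = design$fert_temps, embryo = design$embryo_temps,
                          KEEP.OUT.ATTRS = FALSE)
    n <- design$n_per_vial
    n_clamped <- 0L

    parts <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      parts[[b]] <- with_seed(seeds[b], {
        u_b <- stats::rnorm(1, 0, config$sigma_block)
        btab <- vector("list", length(blocks[[b]]) * nrow(groups))
        k <- 0
        for (tmp in blocks[[b]]) {
          for (g in seq_len(nrow(groups))) {
            k <- k + 1
            f <- groups$fert[g]; e <- groups$embryo[g]
            v <- stats::rnorm(1, 0, config$sigma_vial)
            eta <- cubic_eta(config$curve_params[[paste(f, e, sep = ":")]], tmp) +
              u_b + v
            n_clamped <- n_clamped + sum(abs(eta) > 36)
            p <- stats::plogis(clamp_eta(eta, warn = FALSE))
            btab[[k]] <- data.frame(
              block = sprintf("B%02d", b),
              vial = sprintf("B%02d_F%g_E%g_T%g", b, f, e, tmp),
              fert_temp = f, embryo_temp = e, assay_temp = tmp,
              outcome = stats::rbinom(n, 1L, p),
              stringsAsFactors = FALSE)
          }
        }
        do.call(rbind, btab)
      })
    }
    if (n_clamped > 0)
      warning(sprintf(
        "%d vial linear predictor(s) exceeded |eta| = 36 and were clamped",
        n_clamped), call. = FALSE)
    survival_table(do.call(rbind, parts), design)
  })
}

#' Write / read a generator configuration as JSON
#'
#' Round-trips a [tpc_gen_config()] (design, per-group cubic coefficients,
#' random-effect SDs, allocation rule, seed) through a JSON file, so
#' simulations can be configured outside R and replayed exactly.
#'
#' @param config A [tpc_gen_config()].
#' @param path JSON file path.
#' @return `write_gen_config`: `path`, invisibly. `read_gen_config`: a
#'   [tpc_gen_config()].
#' @export
write_gen_config <- function(config, path) {
  stopifnot(inherits(config, "tpc_gen_config"))
  design <- unclass(config$design)
  design$replicates <- as.list(design$replicates)  # keep temperature names
  x <- list(design = design,
            curve_params = config$curve_params,
            sigma_block = config$sigma_block,
            sigma_vial = config$sigma_vial,
            allocation = config$allocation,
            seed = config$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_gen_config
#' @export
read_gen_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- x$design
  reps <- unlist(d$replicates)
  if (is.null(names(reps)))   # stored in assay-temperature order
    names(reps) <- as.character(d$assay_temps)
  design <- experiment_design(fert_temps = d$fert_temps,
                              embryo_temps = d$embryo_temps,
                              assay_temps = d$assay_temps,
                              n_per_vial = d$n_per_vial,
                              replicates = reps,
                              n_blocks = d$n_blocks,
                              temps_per_block = d$temps_per_block)
  tpc_gen_config(design,
                 curve_params = lapply(x$curve_params, as.numeric),
                 sigma_block = x$sigma_block,
                 sigma_vial = x$sigma_vial,
                 allocation = x$allocation,
                 seed = x$seed)
}
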