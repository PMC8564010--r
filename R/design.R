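#' Declare a factorial split-cohort experimental design
#'
#' Describes the layout of a thermal-performance assay: two prior-temperature
#' factors (fertilization and embryogenesis), a set of assay temperatures
#' along which the performance curve is measured, per-vial sample size,
#' replicate vials per treatment combination, and an incomplete block
#' structure in which each block receives only a subset of assay
#' temperatures.
#'
#' The default instance is a 2 (fertilization: 18, 22 degC) x 3
#' (embryogenesis: 18, 20, 22 degC) factorial with 10 assay temperatures
#' spanning 10-28 degC, 30 individuals per vial, 4 replicate vials per
#' combination (2 at 27 degC), and 10 blocks each assaying 2-5 temperatures.
#'
#' @param fert_temps Numeric vector of fertilization temperatures (degC).
#' @param embryo_temps Numeric vector of embryogenesis temperatures (degC).
#' @param assay_temps Numeric vector of assay temperatures (degC).
#' @param n_per_vial Individuals per vial (count, >= 1).
#' @param replicates Named numeric vector or single number: replicate vials
#'   per assay temperature. A single number is recycled; names (temperature
#'   as character) override per temperature.
#' @param n_blocks Number of blocks (>= 1).
#' @param temps_per_block Integer range (length-2) of assay temperatures a
#'   single block may receive under incomplete-block allocation.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design()
#' d$replicates[["27"]]  # 2, all other temperatures 4
#' @export
experiment_design <- function(fert_temps = c(18, 22),
                              embryo_temps = c(18, 20, 22),
                              assay_temps = c(10, 13, 16, 18, 20, 22, 24, 26, 27, 28),
                              n_per_vial = 30,
                              replicates = c("27" = 2),
                              n_blocks = 10,
                              temps_per_block = c(2L, 5L)) {
  stopifnot(is.numeric(fert_temps), length(fert_temps) >= 1,
            is.numeric(embryo_temps), length(embryo_temps) >= 1,
            is.numeric(assay_temps), length(assay_temps) >= 2,
            all(is.finite(c(fert_temps, embryo_temps, assay_temps))))
  if (anyDuplicated(assay_temps))
    stop_validation("assay temperatures must be distinct")
  if (n_per_vial < 1) stop_validation("n_per_vial must be >= 1")
  if (n_blocks < 1) stop_validation("n_blocks must be >= 1")

  ## replicate quota per assay temperature: default 4, overridable by name
  reps <- rep(4, length(assay_temps))
  names(reps) <- as.character(assay_temps)
  if (!is.null(replicates)) {
    if (is.null(names(replicates)) || any(!nzchar(names(replicates)))) {
      stopifnot(length(replicates) == 1L)
      reps[] <- replicates
    } else {
      bad <- setdiff(names(replicates), names(reps))
      if (length(bad))
        stop_validation("replicates named for unknown assay temperature: %s",
                        paste(bad, collapse = ", "))
      reps[names(replicates)] <- replicates
    }
  }
  if (any(reps < 1)) stop_validation("every assay temperature needs >= 1 replicate")
  temps_per_block <- as.integer(round(range(temps_per_block)))

  structure(
    list(fert_temps = sort(fert_temps),
         embryo_temps = sort(embryo_temps),
         assay_temps = sort(assay_temps),
         n_per_vial = as.integer(n_per_vial),
         replicates = reps[as.character(sort(assay_temps))],
         n_blocks = as.integer(n_blocks),
         temps_per_block = temps_per_block),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experimental design:\n")
  cat("  fertilization temps :", paste(x$fert_temps, collapse = ", "), "degC\n")
  cat("  embryogenesis temps :", paste(x$embryo_temps, collapse = ", "), "degC\n")
  cat("  assay temps         :", paste(x$assay_temps, collapse = ", "), "degC\n")
  cat("  individuals/vial    :", x$n_per_vial, "\n")
  cat("  replicate vials     :", paste(x$replicates, collapse = ", "), "\n")
  cat("  blocks              :", x$n_blocks,
      sprintf("(%d-%d assay temps each)\n", x$temps_per_block[1], x$temps_per_block[2]))
  cat("  expected individuals:", design_n_individuals(x), "\n")
  invisible(x)
}

## Total individuals implied by the replicate quotas.
design_n_individuals <- function(design) {
  length(design$fert_temps) * length(design$embryo_temps) *
    sum(design$replicates) * design$n_per_vial
}
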