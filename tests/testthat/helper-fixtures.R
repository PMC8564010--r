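# Shared designs and lazily computed fitted objects (built once per run).

tiny_design <- function(n_per_vial = 10) {
  experiment_design(assay_temps = c(10, 14, 18, 21, 24, 28),
                    n_per_vial = n_per_vial,
                    replicates = 2,
                    n_blocks = 4,
                    temps_per_block = c(2, 4))
}

# Down-scaled version of the full layout: same 10 assay temperatures,
# 5 blocks, 15 per vial, 2 replicates per combination (1 at 27 degC).
reduced_design <- function(n_per_vial = 15) {
  experiment_design(n_per_vial = n_per_vial,
                    replicates = c("10" = 2, "13" = 2, "16" = 2, "18" = 2,
                                   "20" = 2, "22" = 2, "24" = 2, "26" = 2,
                                   "27" = 1, "28" = 2),
                    n_blocks = 5,
                    temps_per_block = c(2, 5))
}

.fixtures <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Default-design dataset with distinct optima, and its mixed-model fit.
full_tab <- function() fixture("full_tab", function() {
  simulate_survival_table(
    shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21.2), seed = 101))
})
full_fit <- function() fixture("full_fit", function() fit_tpc_glmm(full_tab()))

tiny_tab <- function() fixture("tiny_tab", function() {
  simulate_survival_table(
    shifted_topt_config(c("18" = 18, "20" = 19.5, "22" = 21),
                        design = tiny_design(), seed = 7))
})
tiny_fit <- function() fixture("tiny_fit", function() fit_tpc_glmm(tiny_tab()))
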