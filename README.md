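# tpcglmm

Thermal performance curves (TPCs) for **binary survival** under factorial
prior-temperature treatments: binomial mixed-model estimation, grouped Wald
tests, analytic curve-descriptor extraction, and parametric-bootstrap
comparison of descriptors among treatment groups — plus a synthetic-data
generator that reproduces the split-cohort incomplete block design, so the
whole chain is testable against known truth without any external data.

## Who this is for

Ecophysiologists and biostatisticians estimating how survival-based TPCs
respond to earlier-life thermal environments (carryover / developmental
plasticity designs): individuals are reared through two prior-temperature
stages (fertilization at 18/22 °C, embryogenesis at 18/20/22 °C by
default), then assayed for survival of development at 10 temperatures
spanning 10–28 °C, 30 individuals per vial, replicate vials nested in
incomplete blocks.

## The model

Survival is Bernoulli on the logit scale,

    logit p = η_fe(T) + u_block + w_vial,   u ~ N(0, σ²_block), w ~ N(0, σ²_vial),

with η_fe(T) a cubic in assay temperature (orthogonal polynomial basis,
Forsythe recurrence) crossed with both prior-temperature factors (24 fixed
effects), fitted by Laplace-approximated maximum likelihood (`lme4`).
From the fitted population-level curve of each embryogenesis group the
package extracts

* **Pmax** — peak survival probability, at the thermal optimum **Topt**;
* **Tbr** — thermal breadth: width of the region with survival ≥ 50% of peak;
* **CTmin / CTmax** — temperatures where survival falls to 5% of peak;

analytically (cubic stationary points + closed-form threshold roots), with
boundary / extrapolation / censoring flags, and compares them among groups
with percentile CIs from an unconditional parametric bootstrap (fresh
random effects + binomial outcomes per replicate, full model refit).
Fixed effects are tested with Type-II grouped Wald χ² tests and
Tukey-adjusted pairwise trend contrasts.

## Worked example

```r
library(tpcglmm)

# simulate the default design with true optima 19 / 20 / 21.2 degC
cfg <- shifted_topt_config(c("18" = 19, "20" = 20, "22" = 21.2), seed = 11)
tab <- simulate_survival_table(cfg)   # 6,840 individuals, 10 blocks
fit <- fit_tpc_glmm(tab)
wald_tests(fit)
```

    Type-II Wald chi-square tests:
                   term      chi2 df          p
    1              fert    0.1094  1  7.408e-01
    2            embryo    1.5256  2  4.664e-01
    3       fert:embryo    3.1299  2  2.091e-01
    4             trend 1038.7259  3 7.147e-225
    5        fert:trend    5.0214  3  1.702e-01
    6      embryo:trend  184.0590  6  4.660e-37
    7 fert:embryo:trend    9.8912  6  1.293e-01

The survival curve itself is overwhelmingly significant, and only its
interaction with embryogenesis temperature matters — the curve shifts with
the embryonic environment while fertilization temperature does nothing,
which is exactly the structure the generator encodes.

```r
extract_descriptors(fit)
```

      embryo_temp   Pmax  Topt   Tbr Tbr_lo Tbr_hi  CTmin CTmax
    1          18 0.8866 19.24 13.24  12.40  25.64  8.774 28.69
    2          20 0.8904 20.24 12.94  13.67  26.61 10.354 29.68
    3          22 0.8560 21.42 13.10  14.67  27.76 10.828 31.02

Estimated optima 19.24 / 20.24 / 21.42 °C against truth 19 / 20 / 21.2 °C;
peak height and breadth are shared across groups, as generated. (CTmin for
the coldest group falls below the assay range and is flagged
`extrapolated`.)

```r
boot <- parametric_bootstrap(fit, tab, B = 200, seed = 12)
subset(boot$summary, descriptor == "Topt")
```

       embryo_temp descriptor estimate boot_mean ci_lo ci_hi n_eff
    2           18       Topt    19.24     19.22 18.63 19.74   200
    9           20       Topt    20.24     20.22 19.71 20.76   200
    16          22       Topt    21.42     21.37 20.90 21.87   200

```r
subset(compare_descriptors(boot), descriptor == "Topt")
```

          pair diff_mean diff_ci_lo diff_ci_hi sig_nonoverlap sig_difference
    2  18 - 20    -1.005     -1.751    -0.2259          FALSE           TRUE
    9  18 - 22    -2.155     -2.829    -1.3984           TRUE           TRUE
    16 20 - 22    -1.150     -1.951    -0.3366           TRUE           TRUE

Every 95% CI covers its true optimum; the conservative CI-overlap rule
fires for the extreme pair while the difference-CI rule detects all three
shifts — the characteristic pattern for a ~1 °C per 2 °C carryover shift
at this sample size.

## Command line

```sh
Rscript -e 'tpcglmm::tpc_cli()' simulate --seed 42 --out data.csv
Rscript -e 'tpcglmm::tpc_cli()' fit --data data.csv --out fit.json
Rscript -e 'tpcglmm::tpc_cli()' run-all --out-dir run1 --data-seed 1 --boot-seed 2 --B 1000
```

`run-all` writes `data.csv`, `fit.json`, `tests.csv`, `trends.csv`,
`descriptors.csv`, `boot.json`, `compare.csv`, and `summary.txt`, each
stamped with the package version, config hash, and seeds; identical
configs give byte-identical artifacts.

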