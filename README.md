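# dsrtools

Analytics for **drug sensitivity and resistance testing (DSRT)** — the
functional precision oncology workflow in which patient-derived cancer
cells (PDCs) are screened ex vivo against a large oncology drug library
and the resulting dose–response profiles guide therapy hypotheses. The
package covers the full analysis path for a multi-subtype cohort (e.g.
high-grade serous, low-grade serous and mucinous ovarian cancer PDCs):

* **Plate normalization** — raw 384-well luminescence viability signals to
  %inhibition via in-plate DMSO / benzethonium chloride controls, with
  Z′-factor QC.
* **Dose–response fitting** — constrained four-parameter logistic model
  `y(x) = b + (a − b)/(1 + 10^{s(m − x)})`, `x = log10(conc nM)`, bottom
  fixed at 0, multistart box-constrained least squares.
* **DSS scoring** — the drug sensitivity score, a normalized partial AUC
  over the activity window (10–100% inhibition) and tested dose window:
  `DSS1 = 100·I/((100−t)(x_max−x_min))`, and the default `DSS3 =
  DSS1·((x2−x1)/(x_max−x_min))/log10(a)`, which penalizes weak maximal
  responses. Effectiveness calls at the DSS ≥ 10 convention, and
  selective DSS (`sDSS = DSS − mean(healthy-control DSS)`).
* **Target addiction scores (TAS)** — `TAS_t = Σ DSS_i / n_t` over the
  `n_t` potency-filtered inhibitors of target `t`, with one-sided
  permutation p-values (add-one corrected).
* **HSA synergy** — per-cell excess over the highest single agent in 7×7
  combination matrices, mean-interior summary plus best 3×3 window.
* **Cohort statistics** — effective-drug fractions per subtype
  (mean ± SEM, Welch t, one-way ANOVA), Spearman subtype correlations,
  Ward/Euclidean clustering, PCA, and moderated-t differential drug
  sensitivity with Benjamini–Hochberg adjustment.
* **Synthetic screens** — a ground-truthed generator (16 samples /
  13 patients, 526 drugs, 5 doses over a 10,000-fold range, planted
  subtype effects and planted synergy) so every stage is testable without
  patient data. All generated data are synthetic and labelled as such.

See `vignettes/dsrt-methods.Rmd` for the full model description, the
stated synthetic world, and design rationale.

## Worked example

```r
library(dsrtools)

cfg <- sim_config(n_samples_per_subtype = c(HGSOC = 3L, LGSOC = 3L, MUCOC = 2L),
                  serial_counts = list(LGSOC = c(2L, 1L, 1L)),
                  n_drugs = 160L, seed = 7L)
sim    <- simulate_screen(cfg)                 # raw wells + ground truth
norm   <- normalize_plates(sim$wells)          # %inhibition + plate QC
series <- assemble_series(norm$wells)
fits   <- fit_screen(series)                   # 4PL per (sample, drug)
dss    <- dss_screen(fits)                     # DSS3 by default
mat    <- screen_matrix(dss, sim$samples, sim$library)

head(norm$qc[, c("plate_id", "mu_neg", "mu_pos", "z_prime")], 3)
#>   plate_id    mu_neg  mu_pos z_prime
#> 1 P01_PL01  99630.28 2021.50    0.73
#> 2 P01_PL02 102284.09 2003.84    0.71
#> 3 P01_PL03 103022.12 2016.76    0.75
```

Plates pass QC (Z′ ≈ 0.7: well-separated controls). Subtype-level
effectiveness (fraction of targeted drugs with DSS ≥ 10, averaged over
samples) recovers the planted LGSOC hypersensitivity:

```r
eff <- effectiveness_calls(mat)
eff$pooled_q85
#> [1] 15.21
fr <- eff$fractions[eff$fractions$class == "targeted", ]
round(tapply(fr$fraction, fr$subtype, mean), 3)
#> HGSOC LGSOC MUCOC
#> 0.154 0.237 0.181
```

TAS on one LGSOC sample ranks the planted dependencies first, with
significant permutation p-values:

```r
v <- setNames(dss$dss[dss$sample_id == "P04_1"],
              dss$drug_id[dss$sample_id == "P04_1"])
tas1 <- tas_permutation(v, build_membership(sim$targets),
                        n_perm = 1000, seed = 1)
head(tas1[order(-tas1$tas), ], 5)
#>    target_id   tas n_t      p_perm
#> 12      MDM2 23.96  11 0.000999001
#> 7       ERBB 15.64   9 0.025974026
#> 13       MEK 15.50  11 0.012987013
#> 8        ERK 13.22  18 0.017982018
#> 15      PARP  9.83  10 0.202797203
```

A planted MEK+SHP2-style combination is recovered by the HSA model
(12 points of excess planted, noise CV 0.1):

```r
cm <- simulate_combination_matrix(list(a = 60, m = 2,   s = 1, drug_id = "MEKi"),
                                  list(a = 30, m = 2.5, s = 1, drug_id = "SHP2i"),
                                  synergy_excess = 12, config = cfg)
hsa_excess(cm)
#> HSA synergy MEKi + SHP2i: mean interior excess 11.95, max 3x3 window 18.83
```

The end-to-end pipeline (normalize → fit → DSS → sDSS/TAS/cohort/synergy)
runs from CSV inputs and writes stage CSVs plus a digest manifest:

```r
write_screen(sim, "screen_dir",
             controls = simulate_healthy_controls(sim$library, cfg))
run_pipeline(pipeline_config("screen_dir", "out_dir", seed = 1L))
```

or from the shell: `Rscript inst/cli/dsrt.R run-all --in screen_dir
--out out_dir --seed 1`.

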