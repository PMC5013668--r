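# cfTP53

Liquid-biopsy monitoring of **emergent TP53 resistance mutations in
circulating cell-free DNA (cfDNA)** for patients treated with HDM2
antagonists. Tumours that keep wild-type p53 but amplify MDM2/HDM2 can be
treated by blocking the HDM2–p53 interaction; a predicted escape route is the
selection of TP53-mutant subclones, which become visible in plasma cfDNA
before they can be biopsied. `cfTP53` implements the analysis such a
monitoring study needs, end to end, for anyone working with targeted deep
sequencing of plasma:

- **Variant I/O** — per-strand variant tables (TSV or VCF 4.2 with `ADF`/`ADR`
  allelic depths), sample sheets, BED capture panels.
- **Strand-bias QC** — `ALT_RATIO = min(f, r) / (f + r)`, the fraction of
  alt-supporting reads on the minority strand: 0.5 means balanced (real
  variants), near 0 means artefact-like.
- **Threshold calibration** — the empirical noise ceiling from a healthy-donor
  panel and the tumour/plasma concordance table that justify calling variants
  only above a 1% VAF cutoff (strict `>`).
- **Mutation filtering and burden** — silent/non-coding calls and the germline
  TP53 P72R polymorphism are excluded; per patient and week, the allele burden
  is the sum of passing-variant VAFs (in %).
- **Statistics** — with detection probability *P* ~ Beta prior, the conjugate
  posterior after a donor panel with *k* detections in *n* samples is
  Beta(α+k, β+n−k); detection counts in baseline and on-treatment samples are
  scored with the beta-binomial posterior predictive
  `P(K = k) = C(n,k) B(α+k, β+n−k) / B(α, β)`.
  The transversion spectrum is tested with an exact binomial tail at p = ½;
  tumour-size change (CT) is regressed on log10 burden; Pearson tests carry
  Fisher-Z confidence intervals; ΔΔCt converts qPCR triplicates into MDM2
  copy-number calls (amplified when > 5 copies).
- **Synthetic cohorts** — a seeded generator producing donor panels, matched
  tumour/plasma pairs and longitudinal treated cohorts with logistic
  resistant-clone outgrowth, so the whole pipeline runs and is tested without
  any patient data.

Everything is tidyverse-shaped: variant calls and samples travel as two
tibbles joined on `sample_id`, every user-facing function takes a data frame
first and returns a tibble, fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(cfTP53)

cfg   <- sim_config(seed = 20)                       # 20 patients, weeks 0..24
coh   <- simulate_cohort(cfg)                        # variants + samples + truth
panel <- simulate_normal_panel(sim_config(seed = 9), 9)

report <- run_pipeline(coh$variants, coh$samples, run_config(), panel)
report
```

```
cfDNA TP53 emergence report
===========================
samples: 100 (20 baseline, 80 on-treatment)

filter boundary counts:
  input calls                      824
  coding non-silent                469
  non-germline                     404
  above VAF threshold              50
  strand-bias flagged (advisory)   626

detections: baseline 0/20, treatment 18/80
posterior for detection probability: Beta(1, 10)
posterior predictive: baseline 0.3333, treatment pmf 0.01302 / sf 0.09373
fold change (baseline / treatment): pmf 25.6, sf 3.556

spectrum: 12 transitions, 5 transversions (29.4% transversion)
binomial tail P(X <= k | p = 0.5): 0.071731567
burden vs time: r = 0.576 (t = 2.82, p = 0.0123, 95% CI 0.149..0.822)
CT change ~ log10(burden): slope 34.3 (t = 7.38, p = 1.57e-06), F = 54.4 (p = 1.57e-06), R^2 = 0.773
```

Reading the output: none of the 20 baseline samples carries a passing TP53
call while 18 of 80 on-treatment samples do; with the donor-panel posterior
Beta(1, 10) on the per-sample detection probability, 0 baseline detections
are unremarkable (predictive probability 0.33) whereas the on-treatment count
is improbable under the no-effect model (exact-count probability 0.013). The
generator planted a CT-change-on-log-burden slope of 30; the regression on
the detected samples recovers 34.3 ± 4.6.

The statistical primitives are also usable standalone on published counts:

```r
detection_predictive_test(panel_detections = 0, panel_n = 9,
                          baseline_detections = 0, baseline_n = 14,
                          treatment_detections = 12, treatment_n = 25)
#> posterior Beta(1, 10); baseline predictive 10/24 = 0.4167;
#> treatment pmf 0.00271 (fold change 153.8), sf 0.00623 (fold change 66.9)

binomial_tail_lower(3, 15, 0.5)   # 0.017578125, exact
mdm2_copy_number(c(24, 24, 24), c(28, 28, 28), calibrator_delta_ct = -2)
#> copy_number 8, amplified TRUE
```

A thin command-line wrapper over `run_pipeline()` ships at
`inst/scripts/run_pipeline.R` for shell use.

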