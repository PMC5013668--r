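---
title: "Monitoring emergent TP53 mutations in cfDNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring emergent TP53 mutations in cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfTP53)
```

## The problem

Tumours that retain wild-type p53 frequently silence it through MDM2 (HDM2)
amplification — de-differentiated liposarcoma is the extreme case, with
near-universal MDM2 amplification and wild-type TP53 at diagnosis. Small
molecules that block the HDM2–p53 interaction reactivate p53, and the
expected escape route is the outgrowth of TP53-mutant subclones under that
selective pressure. Serial tumour biopsies are impractical, so the natural
readout is circulating cell-free DNA (cfDNA): targeted deep sequencing of
TP53 in plasma, sampled every few weeks.

Working at sub-percent variant allele frequencies (VAF) puts the analysis in
a regime where sequencing artefacts outnumber real mutations. The package
therefore separates three concerns: (i) deciding what a credible call is
(strand-bias QC and a calibrated VAF threshold), (ii) summarising credible
calls per patient over time (detection flags and allele burden), and
(iii) asking whether the pattern of detections and its clinical correlates
could be chance (posterior predictive, spectrum and regression tests).

## Calling threshold and strand bias

Artefact calls have two signatures: they sit at very low VAF, and their
supporting reads pile up on one sequencing strand. The package scores the
second with

$$\mathrm{ALT\_RATIO} = \frac{\min(f, r)}{f + r},$$

where $f$ and $r$ are the alt-supporting read counts by read orientation
(orientation is a sequencing property, independent of the fact that TP53 is
a minus-strand gene). The score lives in $[0, 0.5]$: 0.5 means perfectly
balanced strands, values near 0 mean essentially single-stranded support.
`flag_strand_bias()` marks calls with ALT_RATIO strictly below a cutoff
(default 0.25). The flag is deliberately advisory: the hard filter is the
VAF threshold, so a genuinely balanced mutation can never be silently
discarded by a QC heuristic. The 0.25 default is a design choice — the score
is a continuum and no single published cutoff exists — and it is exposed as a
parameter.

The VAF threshold itself is calibrated empirically, not assumed:

- `noise_profile()` aggregates all calls across a healthy-donor panel and
  reports the maximum observed VAF — the noise ceiling. Donor plasma
  contains no tumour DNA, so everything it shows is artefact.
- `concordance_table()` takes matched tumour/plasma pairs and, at a candidate
  threshold, counts how many plasma calls above and below it are also present
  in the matched tumour (identical contig, position, ref **and** alt —
  position alone would wrongly merge independent variants hitting the same
  residue).

Under the defaults, donor noise concentrates far below 0.5% VAF and
concordance collapses from near-complete above 1% to a few percent below it,
which is the rationale for the package-wide default `vaf_threshold = 0.01`.
"Above threshold" is strict (`vaf > t`) everywhere — detection, filtering,
concordance — so a call exactly at the threshold is below it.

## Filtering, detection and burden

`filter_variants()` keeps calls that are coding and non-silent, are not the
germline TP53 P72R polymorphism (present in roughly half of all people and
appearing near 50% VAF in every sample of a carrier), and exceed the VAF
threshold. Indels pass when coding and non-silent; they are excluded only
from the substitution spectrum, which is defined for SNVs.

A plasma sample is *detected* when at least one call survives the filter.
Per patient and week, the *allele burden* is $100 \sum_i \mathrm{VAF}_i$ over
passing variants — a percentage that adds up subclones, so it can exceed the
VAF of any single clone. `burden_series()` returns the full trajectory, with
burden 0 at undetected timepoints.

The transition/transversion spectrum deduplicates repeated observations of
one mutation across timepoints. Two scopes exist because the mapping from
call lists to "mutation events" is genuinely ambiguous when two patients
acquire the same hotspot: the default counts unique
(patient, contig, pos, ref, alt) tuples; `scope = "cohort"` counts unique
alleles across the cohort. Both are exposed; analyses should state which
they use.

## The statistical machinery

**Posterior predictive for detection counts.** Let $P$ be the probability
that a TP53 mutation is detected in a single normal cfDNA sample. With a
uniform Beta(1, 1) prior and a donor panel showing $k$ detections in $n$
samples, the posterior is Beta$(1+k, 1+n-k)$ — Beta(1, 10) for the canonical
zero-in-nine panel. Future detection counts then follow the beta-binomial
posterior predictive

$$P(K = k \mid n) = \binom{n}{k}
  \frac{B(\alpha + k, \beta + n - k)}{B(\alpha, \beta)},$$

computed in log space (`lchoose` + `lbeta`) so large $n$ and extreme shapes
do not underflow. Both the exact-count probability (pmf) and the at-least-$k$
tail (sf) are reported for the treatment arm, because a published "probability
of detecting $k$ of $n$" is ambiguous between the two; the package never
guesses which was meant, it prints both, with fold changes relative to the
baseline-arm probability. For the zero-detection case the closed form
$P(0) = \beta / (\beta + n)$ holds when $\alpha = 1$; with Beta(1, 10) and
$n = 14$ this is $10/24 \approx 41.7\%$ — the exact counterpart of a commonly
rounded 40%.

**Spectrum test.** Chemotherapy-exposed haematopoietic clones show
transversion fractions near 50%; tumour-derived TP53 mutations under p53
reactivation are transition-dominated. The test is the exact lower binomial
tail $P(X \le k)$ at $p = \tfrac12$. For $p = \tfrac12$ the tail is the
rational $\sum_{i \le k} \binom{n}{i} / 2^n$ and is evaluated as such: for
the $n$ in scope the binomial coefficients, their partial sums and the
power-of-two denominator are all exactly representable in double precision,
so the printed value is exact to the last bit (3 of 15 gives
$576/32768 = 0.017578125$). Other $p$ delegate to `pbinom`.

**Clinical correlates.** Tumour-size change by CT is regressed on
$\log_{10}$ burden via ordinary least squares (`lm`); significance requires
*both* the overall F test and the slope t test to reject, and a Pearson test
on the same pairs lands at the same p value (the F statistic equals the
squared slope t in simple regression — both identities are unit-tested).
Only samples with positive burden enter: the log of zero burden is
undefined, and the package refuses to impute rather than invent a
pseudo-count (an error instructs the caller to restrict to detected
samples). Pearson tests report the t statistic on $n-2$ degrees of freedom
and the asymptotic Fisher-Z confidence interval, via `cor.test`. Group
comparisons (pharmacokinetics, tumour volume) use Welch's unequal-variance t
test by default — the variant is not always stated in publications, and
Welch is the safer default; `equal_var = TRUE` restores the pooled test.

**Copy number.** qPCR triplicates for target and reference genes give
$\Delta Ct$; subtracting the calibrator's $\Delta Ct$ (a normal diploid
donor) gives $\Delta\Delta Ct$, and the copy number is
$2 \cdot 2^{-\Delta\Delta Ct}$ — the leading 2 is the diploid calibrator.
Amplification is a strict `> 5` copies on the mean of triplicates.

## The synthetic cohort generator

`simulate_normal_panel()`, `simulate_matched_pairs()` and
`simulate_cohort()` generate data with the statistical structure the
analysis assumes, plus truth tables for scoring. What they emulate, and the
defaults (all in `sim_config()`, chosen once as a realistic monitoring
study):

- **Artefact noise**: Poisson(8) calls per sample; VAFs exponential with
  scale 0.1%, truncated at 1%; supporting reads split
  Binomial(skew = 0.9) onto a random dominant strand, so typical ALT_RATIO
  is ~0.1. Under these settings a 10-donor panel stays below 1% max VAF in
  well over 99% of seeds, and exceeds 0.5% only occasionally — a
  high-probability, not certain, event, matching how an empirical noise
  ceiling behaves.
- **Study design**: 20 patients, plasma at weeks 0/6/12/18/24 (the ~6-week
  imaging cadence), mean depth 8,000× (plasma) and 19,000× (tumour).
- **Resistant clones**: each patient develops ≥1 clone with probability
  0.25 (≈ the observed 5-of-~20 clustering); affected patients carry
  1 + Poisson(2.5) clones; mutation identities come from a packaged table of
  21 DNA-binding-domain missense hotspots (codon-consistent alleles, toy
  coordinates, Y220 variants included) sampled so the transversion fraction
  is 0.2. Clones emerge at a positive sampling week (never baseline, so
  baseline samples are always truly wild type) and grow logistically from a
  VAF of 1.1–5% at emergence toward a carrying VAF ≤ 0.5 (the heterozygous
  ceiling); an optional `decay_after_peak` switch produces the occasional
  non-monotone trajectory seen in practice.
- **Reads**: alt counts are Binomial(depth, true VAF) with balanced strands
  for true variants; a call that draws zero alt reads is simply not called.
- **Germline**: with probability 0.5 a patient carries P72R heterozygously;
  it appears near 50% VAF in every one of their samples and must be removed
  by the filter, exercising that rule end to end.
- **Clinical link**: for samples with positive true burden,
  `ct_change = 10 + 30 · log10(burden%) + N(0, 10)`; zero-burden samples get
  N(0, 10) baseline scatter and are excluded from the regression (no
  imputation rule is published, so none is invented).

What the generator does **not** model: read-level data (FASTQ/BAM), FFPE
deamination damage, PCR duplicates, CHIP-derived TP53 clones in patient
plasma, or inter-site depth variation beyond Poisson. Passing tests
therefore demonstrate the correctness and calibration of the *analysis*
under its stated assumptions, not the wet-lab performance of any assay.

Determinism: each generator seeds one RNG stream from `config$seed` (via
`withr::with_seed`, so the caller's RNG state is untouched) and draws in a
fixed documented order; identical config and seed give byte-identical
output.

## Numerical and design choices

- VAF uses total depth as denominator (the standard "fraction of all reads"
  reading); a reader flag recomputes from counts when a stored VAF disagrees
  beyond 1e-6.
- Variant positions are 1-based (VCF convention); panel intervals are
  0-based half-open (BED convention); `restrict_to_panel()` converts
  explicitly and is idempotent.
- Multi-allelic VCF records are split into one call per alt allele;
  per-strand alt counts come from the reserved `ADF`/`ADR` FORMAT keys
  (configurable).
- Ties: "above threshold" is strict everywhere; the strand-bias flag is
  strict less-than at its cutoff.
- Degenerate fits: a constant response gives slope 0 and $R^2 = 0$ (not
  NaN); $|r| = 1$ collapses the Fisher-Z interval to a point; constant
  input to a correlation is an error, not an NA.
- Problem sizes in the test suite: statistical calibration uses 5,000 null
  simulations (type-I error within ±0.01 of 0.05 and a KS uniformity check);
  parameter recovery uses 100 cohorts of 200 patients (slope recovered
  within 3 standard errors in ≥99% of seeds, pooled >2%-VAF detection
  sensitivity above 0.9); the noise-ceiling property uses 1,000 simulated
  panels. These sizes make the Monte-Carlo error small relative to every
  tolerance tested.

## Limitations

The analysis consumes annotations (`effect`, `protein_change`); it does not
align reads, call variants from pileups, or annotate. The concordance
calibration assumes one plasma and one tumour sample per patient. The
posterior predictive treats samples as exchangeable, ignoring that several
come from the same patient; with a handful of patients driving most
detections this overstates the effective sample size, which is one reason
the package reports probabilities rather than declaring significance. The
spectrum test conditions on the observed number of unique mutations and
ignores hotspot-specific mutability.
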