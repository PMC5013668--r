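test_that("mutation filter drops silent/non-coding calls, P72R, and sub-threshold VAFs", {
  v <- dplyr::bind_rows(
    make_variants("S1", pos = 524L, alt_fwd = 60, alt_rev = 60, depth = 10000,
                  protein_change = "R175H"),                   # VAF 0.012
    make_variants("S1", pos = 215L, ref = "C", alt = "G", alt_fwd = 2500,
                  alt_rev = 2500, depth = 10000,
                  protein_change = "P72R"),                    # germline, VAF 0.5
    make_variants("S1", pos = 300L, alt_fwd = 250, alt_rev = 250,
                  depth = 10000, effect = "silent",
                  protein_change = ""),                        # silent, VAF 0.05
    make_variants("S1", pos = 400L, alt_fwd = 50, alt_rev = 50,
                  depth = 10000, protein_change = "G245S")     # exactly 0.01
  )
  kept <- filter_variants(v, 0.01)
  expect_equal(kept$protein_change, "R175H")
  # idempotent
  expect_identical(filter_variants(kept, 0.01), kept)
  # coding, non-silent indels are retained
  indel <- make_variants("S1", pos = 700L, ref = "AT", alt = "A",
                         alt_fwd = 100, alt_rev = 100, depth = 10000,
                         effect = "indel_frameshift", protein_change = "")
  expect_equal(nrow(filter_variants(indel, 0.01)), 1L)
})

test_that("per-sample detection uses the strict VAF threshold and excludes germline", {
  samples <- make_samples("S1")
  below <- make_variants("S1", alt_fwd = 45, alt_rev = 45, depth = 10000)  # 0.009
  above <- make_variants("S1", alt_fwd = 55, alt_rev = 55, depth = 10000)  # 0.011
  germ <- make_variants("S1", pos = 215L, ref = "C", alt = "G",
                        alt_fwd = 1500, alt_rev = 1500, depth = 10000,
                        protein_change = "P72R")               # 0.30
  expect_false(detect_samples(below, samples)$detected)
  expect_true(detect_samples(above, samples)$detected)
  expect_false(detect_samples(germ, samples)$detected)
  tum <- make_samples("S1", material = "tumour_ffpe", timepoint_weeks = NA_real_)
  expect_error(detect_samples(above, tum), "plasma_cfdna")
})

test_that("burden trajectories sum passing VAFs x 100 and sort by week", {
  samples <- make_samples(
    sample_id = c("W12", "W0"), patient_id = "P1",
    timepoint_weeks = c(12, 0)
  )
  v <- dplyr::bind_rows(
    make_variants("W12", pos = 524L, alt_fwd = 75, alt_rev = 75,
                  depth = 10000, protein_change = "R175H"),    # 0.015
    make_variants("W12", pos = 733L, alt_fwd = 100, alt_rev = 100,
                  depth = 10000, protein_change = "G245S")     # 0.020
  )
  b <- burden_series(v, samples)
  expect_equal(b$timepoint_weeks, c(0, 12)) # sorted despite input order
  expect_equal(b$burden_pct, c(0, 3.5))
  expect_equal(b$detected, c(FALSE, TRUE))
  expect_equal(b$n_passing, c(0L, 2L))
  expect_error(
    burden_series(v, dplyr::mutate(samples, patient_id = c("P1", "P2"),
                                   material = c("plasma_cfdna", "tumour_ffpe"))),
    "plasma_cfdna"
  )
})

test_that("burden is monotone in VAFs and variant count", {
  set.seed(21)
  samples <- make_samples("S1", timepoint_weeks = 12)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    alt <- rbinom(n, 10000, runif(n, 0.005, 0.1))
    v <- make_variants(
      "S1", pos = sample.int(2000, n), depth = 10000,
      alt_fwd = floor(alt / 2), alt_rev = ceiling(alt / 2),
      protein_change = ""
    )
    base <- burden_series(v, samples)$burden_pct
    # raising one variant's VAF never decreases burden
    j <- sample.int(n, 1)
    v_up <- v
    extra <- 100
    v_up$alt_fwd[j] <- v_up$alt_fwd[j] + extra
    v_up$vaf[j] <- (v_up$alt_fwd[j] + v_up$alt_rev[j]) / v_up$depth[j]
    expect_gte(burden_series(v_up, samples)$burden_pct, base)
    # removing a variant never increases burden
    expect_lte(burden_series(v[-j, ], samples)$burden_pct, base)
  }
})

test_that("substitutions classify by purine/pyrimidine class", {
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("G", "T"), "transversion")
  expect_equal(classify_substitution("A", "G"), "transition")
  # full enumeration against an independent base-class oracle
  bases <- c("A", "C", "G", "T")
  purine <- function(b) b %in% c("A", "G")
  for (r in bases) {
    for (a in setdiff(bases, r)) {
      expected <- if (purine(r) == purine(a)) "transition" else "transversion"
      expect_equal(classify_substitution(r, a), expected)
    }
  }
  expect_error(classify_substitution("AT", "A"), "single-nucleotide")
})

test_that("spectrum counts deduplicate repeated observations of one mutation", {
  samples <- make_samples(
    sample_id = c("S1", "S2", "S3"), patient_id = "P1",
    timepoint_weeks = c(6, 12, 18)
  )
  # same Y220C call at three timepoints plus two distinct events
  v <- dplyr::bind_rows(
    make_variants(c("S1", "S2", "S3"), pos = 659L, ref = "A", alt = "G",
                  alt_fwd = 100, alt_rev = 100, depth = 10000,
                  protein_change = "Y220C"),
    make_variants("S2", pos = 743L, ref = "G", alt = "A",
                  alt_fwd = 100, alt_rev = 100, depth = 10000,
                  protein_change = "R248Q"),
    make_variants("S3", pos = 747L, ref = "G", alt = "T",
                  alt_fwd = 100, alt_rev = 100, depth = 10000,
                  protein_change = "R249S")
  )
  sp <- mutation_spectrum(v, samples)
  # brute-force oracle: unique (patient, contig, pos, ref, alt) tuples
  uniq <- unique(paste("P1", v$contig, v$pos, v$ref, v$alt))
  expect_equal(sp$n_total, length(uniq))
  expect_equal(sp$n_transitions, 2L) # A>G, G>A
  expect_equal(sp$n_transversions, 1L) # G>T
  expect_equal(sp$transversion_fraction, 1 / 3)

  empty <- mutation_spectrum(v[0, ], samples)
  expect_equal(empty$n_total, 0L)
})

test_that("patient vs cohort spectrum scope differ when patients share a mutation", {
  samples <- make_samples(
    sample_id = c("S1", "S2"), patient_id = c("P1", "P2"),
    timepoint_weeks = 6
  )
  v <- make_variants(c("S1", "S2"), pos = 659L, ref = "A", alt = "G",
                     alt_fwd = 100, alt_rev = 100, depth = 10000,
                     protein_change = "Y220C")
  expect_equal(mutation_spectrum(v, samples, scope = "patient")$n_total, 2L)
  expect_equal(mutation_spectrum(v, samples, scope = "cohort")$n_total, 1L)
})
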