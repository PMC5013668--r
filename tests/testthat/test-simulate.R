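test_that("generators are deterministic functions of (config, seed)", {
  cfg <- sim_config(seed = 99, n_patients = 10)
  expect_identical(
    serialize(simulate_normal_panel(cfg, 10), NULL),
    serialize(simulate_normal_panel(cfg, 10), NULL)
  )
  expect_identical(
    serialize(simulate_matched_pairs(cfg, 15), NULL),
    serialize(simulate_matched_pairs(cfg, 15), NULL)
  )
  expect_identical(
    serialize(simulate_cohort(cfg), NULL),
    serialize(simulate_cohort(cfg), NULL)
  )
  # a different seed changes the draw
  cfg2 <- sim_config(seed = 100, n_patients = 10)
  expect_false(identical(
    simulate_cohort(cfg)$variants, simulate_cohort(cfg2)$variants
  ))
})

test_that("generated variant tables satisfy the variant-call invariants", {
  for (seed in 1:3) {
    coh <- simulate_cohort(sim_config(seed = seed, n_patients = 15))
    expect_silent(validate_variants(coh$variants))
    expect_true(all(coh$variants$alt_fwd + coh$variants$alt_rev <=
                      coh$variants$depth))
    expect_true(all(coh$variants$pos >= 1))
    expect_silent(validate_samples(coh$samples))
  }
})

test_that("zero artefact rate yields empty donor panels", {
  cfg <- sim_config(seed = 5, artefact_rate = 0)
  panel <- simulate_normal_panel(cfg, 10)
  expect_equal(nrow(panel$variants), 0L)
  expect_equal(nrow(panel$samples), 10L)
  expect_equal(noise_profile(panel$variants, panel$samples)$max_vaf, 0)
})

test_that("artefacts are strand-biased: mean ALT_RATIO below 0.25 at skew 0.9", {
  # expectation oracle: with alt reads split Binomial(m, 0.9) onto the
  # dominant strand, E[min(S, m - S) / m] is ~0.1 for the m seen at these
  # depths and VAFs, far below 0.25
  panel <- simulate_normal_panel(sim_config(seed = 17, artefact_rate = 20), 10)
  flagged <- flag_strand_bias(panel$variants)
  expect_lt(mean(flagged$alt_ratio), 0.25)
})

test_that("clone-free cohorts contain no true mutations and no detections", {
  cfg <- sim_config(seed = 8, clone_prob = 0, n_patients = 10)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$clones), 0L)
  expect_true(all(coh$truth$true_burden_pct == 0))
  det <- detect_samples(coh$variants, coh$samples)
  expect_equal(sum(det$detected), 0L)
})

test_that("baseline samples never carry true clones and burdens grow logistically", {
  coh <- simulate_cohort(sim_config(seed = 12, n_patients = 30,
                                    clone_prob = 0.6))
  base_truth <- dplyr::filter(coh$truth, timepoint_weeks == 0)
  expect_true(all(base_truth$true_burden_pct == 0))
  expect_true(all(coh$clones$emergence_week >= 6))
  # without decay the true burden is non-decreasing in time per patient
  non_decreasing <- coh$truth |>
    dplyr::arrange(patient_id, timepoint_weeks) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(ok = all(diff(true_burden_pct) >= -1e-12))
  expect_true(all(non_decreasing$ok))
  expect_true(all(coh$clones$carrying_vaf <= 0.5))
})

test_that("planted-truth matched pairs are fully concordant above 1%", {
  pairs <- simulate_matched_pairs(sim_config(seed = 23, shared_per_pair = 2),
                                  n_pairs = 30, artefacts = FALSE)
  tab <- concordance_table(pairs$variants, pairs$samples, 0.01)
  expect_equal(tab$pct_above, 100)
  expect_gt(tab$n_above, 0)
  expect_error(simulate_matched_pairs(sim_config(seed = 1), n_pairs = 0),
               "n_pairs")
})

test_that("planted transversion fraction matches the configured probability", {
  # pool clones across many seeds (law of large numbers at ~1,000 clones)
  tv <- unlist(lapply(1:10, function(s) {
    simulate_cohort(sim_config(
      seed = s, n_patients = 60, clone_prob = 1,
      clones_per_patient_lambda = 1
    ))$clones$transversion
  }))
  expect_gt(length(tv), 900)
  expect_lt(abs(mean(tv) - 0.2), 0.03)
})

test_that("truth_report scores detection calls against the planted truth", {
  cfg <- sim_config(seed = 33, n_patients = 20, clone_prob = 0.5,
                    artefact_rate = 0, germline_p72r_prob = 0)
  coh <- simulate_cohort(cfg)
  b <- burden_series(coh$variants, coh$samples)
  rep_ok <- truth_report(coh$truth, b)
  # noise-free cohort: every true clone above threshold is found, nothing else
  expect_equal(rep_ok$fp, 0L)
  expect_equal(rep_ok$fn, 0L)
  expect_equal(rep_ok$sensitivity, 1)

  # an absurdly high threshold turns every positive into a miss
  b_hi <- burden_series(coh$variants, coh$samples, vaf_threshold = 0.999)
  rep_hi <- truth_report(coh$truth, b_hi, vaf_threshold = 0.01)
  expect_equal(rep_hi$tp, 0L)
  expect_equal(rep_hi$fn, rep_ok$tp)

  expect_error(
    truth_report(coh$truth, dplyr::mutate(b, sample_id = paste0(sample_id, "x"))),
    "do not match"
  )
})

test_that("decay-after-peak switch allows non-monotone trajectories", {
  cfg <- sim_config(seed = 44, n_patients = 40, clone_prob = 1,
                    decay_after_peak = TRUE, artefact_rate = 0,
                    germline_p72r_prob = 0)
  coh <- simulate_cohort(cfg)
  drops <- coh$truth |>
    dplyr::arrange(patient_id, timepoint_weeks) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(dropped = any(diff(true_burden_pct) < -1e-9))
  expect_true(any(drops$dropped))
})
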