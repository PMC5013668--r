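#' Simulation configuration for synthetic cfDNA cohorts
#'
#' Bundles every knob of the synthetic-data generators. Defaults describe a
#' cfDNA monitoring study of an HDM2-inhibitor expansion cohort: ~20 patients
#' sampled at a 6-week imaging cadence, targeted sequencing at 8,000x mean
#' depth, strand-biased artefact noise confined below 1% VAF, a minority of
#' patients developing resistant TP53 subclones with logistic VAF outgrowth,
#' a 20% transversion fraction among resistance mutations, and a linear-log
#' link between tumour-size change and allele burden.
#'
#' @param seed Integer seed; every generator is a deterministic function of
#'   (config, seed).
#' @param n_patients Number of treated patients in the cohort.
#' @param sampling_weeks Plasma collection weeks (0 = baseline).
#' @param mean_depth Mean sequencing depth of plasma cfDNA (reads).
#' @param tumour_mean_depth Mean depth for tumour samples in matched pairs.
#' @param artefact_rate Expected artefact variant calls per sample (Poisson).
#' @param artefact_vaf_scale Scale (mean) of the exponential artefact-VAF
#'   distribution, as a fraction (default 0.001 = 0.1%).
#' @param artefact_vaf_max Truncation point of the artefact VAF distribution
#'   (default 0.01 = 1%).
#' @param artefact_strand_skew Probability an artefact-supporting read falls
#'   on the artefact's dominant strand (default 0.9, i.e. strong strand bias).
#' @param clone_prob Probability a patient develops at least one resistant
#'   clone.
#' @param clones_per_patient_lambda Clone count per affected patient is
#'   `1 + Poisson(lambda)`.
#' @param transversion_prob Probability a resistant clone's mutation is a
#'   transversion (default 0.2).
#' @param clone_v0_range Range of a clone's true VAF at emergence.
#' @param clone_rate_range Range of logistic growth rates (per week).
#' @param clone_carrying_range Range of carrying VAFs (capped at 0.5, the
#'   heterozygous ceiling).
#' @param decay_after_peak If `TRUE`, clone VAFs decay after a drawn peak
#'   week, allowing non-monotone burden trajectories.
#' @param germline_p72r_prob Probability a patient carries the germline TP53
#'   P72R polymorphism (heterozygous), which then appears in every plasma
#'   sample near 50% VAF and must be removed by the mutation filter.
#' @param ct_link List `(intercept, slope, noise_sd)` of the linear-log link
#'   `ct_change_percent = intercept + slope * log10(burden_pct) + noise`,
#'   applied to samples with positive true burden.
#' @param baseline_ct_noise SD of the CT change (around 0) for samples with
#'   zero true burden.
#' @param shared_per_pair Expected number of true tumour-derived variants
#'   shared by a matched tumour/plasma pair (Poisson).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 20L,
                       sampling_weeks = c(0, 6, 12, 18, 24),
                       mean_depth = 8000,
                       tumour_mean_depth = 19000,
                       artefact_rate = 8,
                       artefact_vaf_scale = 0.001,
                       artefact_vaf_max = 0.01,
                       artefact_strand_skew = 0.9,
                       clone_prob = 0.25,
                       clones_per_patient_lambda = 2.5,
                       transversion_prob = 0.2,
                       clone_v0_range = c(0.011, 0.05),
                       clone_rate_range = c(0.3, 0.8),
                       clone_carrying_range = c(0.05, 0.4),
                       decay_after_peak = FALSE,
                       germline_p72r_prob = 0.5,
                       ct_link = list(intercept = 10, slope = 30, noise_sd = 10),
                       baseline_ct_noise = 10,
                       shared_per_pair = 0.3) {
  probs <- c(
    artefact_strand_skew, clone_prob, transversion_prob, germline_p72r_prob
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (is.unsorted(sampling_weeks, strictly = TRUE)) {
    abort("sampling_weeks must be strictly increasing")
  }
  if (any(sampling_weeks < 0)) abort("sampling_weeks must be non-negative")
  if (max(clone_carrying_range) > 0.5) {
    abort("carrying VAF cannot exceed 0.5 (heterozygous ceiling)")
  }
  if (artefact_vaf_scale <= 0 || artefact_vaf_max <= 0 || mean_depth <= 0) {
    abort("scales, truncation point and depth must be positive")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_patients = as.integer(n_patients),
      sampling_weeks = sampling_weeks,
      mean_depth = mean_depth,
      tumour_mean_depth = tumour_mean_depth,
      artefact_rate = artefact_rate,
      artefact_vaf_scale = artefact_vaf_scale,
      artefact_vaf_max = artefact_vaf_max,
      artefact_strand_skew = artefact_strand_skew,
      clone_prob = clone_prob,
      clones_per_patient_lambda = clones_per_patient_lambda,
      transversion_prob = transversion_prob,
      clone_v0_range = clone_v0_range,
      clone_rate_range = clone_rate_range,
      clone_carrying_range = clone_carrying_range,
      decay_after_peak = decay_after_peak,
      germline_p72r_prob = germline_p72r_prob,
      ct_link = ct_link,
      baseline_ct_noise = baseline_ct_noise,
      shared_per_pair = shared_per_pair
    ),
    class = "sim_config"
  )
}

# exponential VAF distribution truncated at `max` (inverse-CDF sampling)
rexp_truncated <- function(n, scale, max) {
  u <- runif(n)
  -scale * log(1 - u * (1 - exp(-max / scale)))
}

# logistic clone trajectory: 0 before emergence, v0 at emergence, saturating
# at the carrying VAF k
logistic_vaf <- function(t, emergence_week, v0, rate, k) {
  dt <- t - emergence_week
  grow <- exp(rate * pmax(dt, 0))
  ifelse(dt < 0, 0, k * v0 * grow / (k + v0 * (grow - 1)))
}

# one batch of artefact calls for the given sample ids (vectorised)
sim_artefact_calls <- function(sample_ids, config, mean_depth = NULL) {
  mean_depth <- mean_depth %||% config$mean_depth
  n_per_sample <- rpois(length(sample_ids), config$artefact_rate)
  total <- sum(n_per_sample)
  if (total == 0) {
    return(empty_variant_table())
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt_shift <- sample(1:3, total, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + alt_shift) %% 4L + 1L]
  true_vaf <- rexp_truncated(total, config$artefact_vaf_scale, config$artefact_vaf_max)
  depth <- rpois(total, mean_depth)
  alt_total <- rbinom(total, depth, true_vaf)
  dominant_fwd <- runif(total) < 0.5
  n_dom <- rbinom(total, alt_total, config$artefact_strand_skew)
  effect <- sample(
    c("missense", "silent", "noncoding", "nonsense", "splice"),
    total, replace = TRUE, prob = c(0.35, 0.25, 0.25, 0.1, 0.05)
  )
  out <- tibble(
    sample_id = rep(sample_ids, n_per_sample),
    contig = "TP53",
    pos = sample(1:2100, total, replace = TRUE),
    ref = ref,
    alt = alt,
    depth = as.numeric(depth),
    alt_fwd = ifelse(dominant_fwd, n_dom, alt_total - n_dom),
    alt_rev = ifelse(dominant_fwd, alt_total - n_dom, n_dom),
    vaf = ifelse(depth > 0, alt_total / depth, 0),
    effect = effect,
    protein_change = ""
  )
  filter(out, .data$alt_fwd + .data$alt_rev > 0)
}

# observed per-strand read counts for true (strand-balanced) variants
observe_true_reads <- function(df, mean_depth) {
  n <- nrow(df)
  depth <- rpois(n, mean_depth)
  alt_total <- rbinom(n, depth, df$true_vaf)
  alt_fwd <- rbinom(n, alt_total, 0.5)
  df$depth <- as.numeric(depth)
  df$alt_fwd <- alt_fwd
  df$alt_rev <- alt_total - alt_fwd
  df$vaf <- ifelse(depth > 0, alt_total / depth, 0)
  filter(df, .data$alt_fwd + .data$alt_rev > 0)
}

#' Simulate a healthy-donor cfDNA panel
#'
#' Generates artefact-only variant calls for `n_samples` healthy donors:
#' Poisson numbers of artefacts per sample, VAFs from an exponential
#' distribution truncated at 1% (concentrated well below 0.5%), and
#' strand-skewed supporting reads so artefacts carry low ALT_RATIO.
#'
#' @param config A [sim_config()]; `config$seed` makes the panel
#'   deterministic.
#' @param n_samples Number of donors (default 10).
#' @return A list with `variants` and `samples` tibbles.
#' @export
simulate_normal_panel <- function(config = sim_config(), n_samples = 10) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    samples <- tibble(
      sample_id = sprintf("HD%02d", seq_len(n_samples)),
      patient_id = sprintf("HD%02d", seq_len(n_samples)),
      material = "normal_plasma",
      timepoint_weeks = NA_real_,
      ct_change_percent = NA_real_
    )
    variants <- sim_artefact_calls(samples$sample_id, config)
    validate_variants(variants)
    list(variants = variants, samples = samples)
  })
}

#' Simulate matched tumour/plasma pairs
#'
#' Each pair shares a Poisson number of planted tumour-derived variants
#' (hotspot identities; plasma VAF above 1%, tumour VAF well above the plasma
#' VAF) and, optionally, carries independent sub-1% artefacts in both
#' materials. Truth labels for the planted variants are returned so
#' calibration can be scored against a known answer.
#'
#' @param config A [sim_config()].
#' @param n_pairs Number of matched pairs (>= 1).
#' @param artefacts Include artefact noise (default `TRUE`); with `FALSE` the
#'   pairs contain planted truths only.
#' @return A list with `variants`, `samples` and `truth` (the planted shared
#'   variants: `patient_id`, `contig`, `pos`, `ref`, `alt`, `plasma_vaf`,
#'   `tumour_vaf`).
#' @export
simulate_matched_pairs <- function(config = sim_config(), n_pairs = 60,
                                   artefacts = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  withr::with_seed(config$seed, {
    patient_id <- sprintf("PAIR%03d", seq_len(n_pairs))
    samples <- bind_rows(
      tibble(
        sample_id = paste0(patient_id, "_P"), patient_id = patient_id,
        material = "plasma_cfdna", timepoint_weeks = NA_real_,
        ct_change_percent = NA_real_
      ),
      tibble(
        sample_id = paste0(patient_id, "_T"), patient_id = patient_id,
        material = "tumour_ffpe", timepoint_weeks = NA_real_,
        ct_change_percent = NA_real_
      )
    )
    hot <- tp53_hotspots()
    n_shared <- pmin(rpois(n_pairs, config$shared_per_pair), nrow(hot))
    truth <- purrr::map_dfr(seq_len(n_pairs), function(i) {
      if (n_shared[i] == 0) {
        return(NULL)
      }
      picks <- hot[sample.int(nrow(hot), n_shared[i]), ]
      tibble(
        patient_id = patient_id[i],
        contig = picks$contig, pos = picks$pos,
        ref = picks$ref, alt = picks$alt,
        protein_change = picks$protein_change,
        plasma_vaf = runif(n_shared[i], 0.011, 0.2),
        tumour_vaf = runif(n_shared[i], 0.25, 0.5)
      )
    })
    plasma_true <- tumour_true <- empty_variant_table()
    if (nrow(truth) > 0) {
      base <- truth |>
        mutate(effect = "missense") |>
        select(all_of(c(
          "patient_id", "contig", "pos", "ref", "alt", "effect",
          "protein_change", "plasma_vaf", "tumour_vaf"
        )))
      plasma_true <- base |>
        mutate(sample_id = paste0(.data$patient_id, "_P"),
               true_vaf = .data$plasma_vaf) |>
        observe_true_reads(config$mean_depth)
      tumour_true <- base |>
        mutate(sample_id = paste0(.data$patient_id, "_T"),
               true_vaf = .data$tumour_vaf) |>
        observe_true_reads(config$tumour_mean_depth)
    }
    keep <- names(empty_variant_table())
    variants <- bind_rows(
      if (nrow(plasma_true) > 0) select(plasma_true, all_of(keep)),
      if (nrow(tumour_true) > 0) select(tumour_true, all_of(keep)),
      if (artefacts) sim_artefact_calls(paste0(patient_id, "_P"), config),
      if (artefacts) {
        sim_artefact_calls(paste0(patient_id, "_T"), config,
                           mean_depth = config$tumour_mean_depth)
      }
    )
    validate_variants(variants)
    list(variants = variants, samples = samples, truth = truth)
  })
}

#' Simulate a treated cohort with resistant-clone outgrowth
#'
#' Generates the full longitudinal study: per patient, plasma cfDNA samples
#' at the configured weeks; a fraction of patients develop one or more
#' resistant subclones whose true VAFs follow logistic growth curves starting
#' at an emergence week (>= week 6, never at baseline, so baseline samples
#' carry no true mutations); read counts are drawn binomially at the sample
#' depth with strand-balanced true variants; artefact noise and an optional
#' germline P72R call are layered on top; and the percent change in tumour
#' size by CT is generated from the true burden through the configured
#' linear-log link (samples with zero true burden get baseline CT noise).
#'
#' @param config A [sim_config()].
#' @return A list with `variants`, `samples`, `clones` (one row per planted
#'   clone with its logistic parameters) and `truth` (one row per sample:
#'   `true_burden_pct`, `max_true_vaf`, `n_true_clones`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  weeks <- config$sampling_weeks
  pos_weeks <- weeks[weeks > 0]
  if (length(pos_weeks) == 0) abort("sampling_weeks needs at least one week > 0")
  emergence_pool <- if (length(pos_weeks) > 1) {
    pos_weeks[-length(pos_weeks)]
  } else {
    pos_weeks
  }
  withr::with_seed(config$seed, {
    patient_id <- sprintf("P%03d", seq_len(config$n_patients))
    has_clone <- runif(config$n_patients) < config$clone_prob
    carrier <- runif(config$n_patients) < config$germline_p72r_prob
    hot <- tp53_hotspots()

    clones <- purrr::map_dfr(which(has_clone), function(i) {
      n_clones <- 1L + rpois(1, config$clones_per_patient_lambda)
      is_tv <- runif(n_clones) < config$transversion_prob
      picks <- sample_hotspots(hot, is_tv)
      n_clones <- nrow(picks)
      tibble(
        patient_id = patient_id[i],
        contig = picks$contig, pos = picks$pos,
        ref = picks$ref, alt = picks$alt,
        protein_change = picks$protein_change,
        transversion = picks$transversion,
        emergence_week = sample(emergence_pool, n_clones, replace = TRUE),
        v0 = runif(n_clones, config$clone_v0_range[1], config$clone_v0_range[2]),
        growth_rate = runif(n_clones, config$clone_rate_range[1],
                            config$clone_rate_range[2]),
        carrying_vaf = runif(n_clones, config$clone_carrying_range[1],
                             config$clone_carrying_range[2]),
        peak_week = if (config$decay_after_peak) {
          sample(pos_weeks, n_clones, replace = TRUE)
        } else {
          rep(Inf, n_clones)
        }
      )
    })

    samples <- tidyr::expand_grid(
      patient_id = patient_id,
      timepoint_weeks = weeks
    ) |>
      mutate(
        sample_id = sprintf("%s_W%02d", .data$patient_id, as.integer(round(.data$timepoint_weeks))),
        material = "plasma_cfdna"
      )

    clone_obs <- empty_variant_table()
    clone_truth <- tibble(
      sample_id = character(), true_vaf = numeric()
    )
    if (nrow(clones) > 0) {
      clone_weeks <- tidyr::expand_grid(
        clones, timepoint_weeks = weeks
      ) |>
        mutate(
          true_vaf = decayed_logistic_vaf(
            .data$timepoint_weeks, .data$emergence_week, .data$v0,
            .data$growth_rate, .data$carrying_vaf, .data$peak_week
          ),
          sample_id = sprintf("%s_W%02d", .data$patient_id, as.integer(round(.data$timepoint_weeks))),
          effect = "missense"
        ) |>
        filter(.data$true_vaf > 0)
      clone_truth <- select(clone_weeks, all_of(c("sample_id", "true_vaf")))
      if (nrow(clone_weeks) > 0) {
        clone_obs <- observe_true_reads(clone_weeks, config$mean_depth) |>
          select(all_of(names(empty_variant_table())))
      }
    }

    germ_obs <- empty_variant_table()
    carrier_ids <- patient_id[carrier]
    if (length(carrier_ids) > 0) {
      germ <- samples |>
        filter(.data$patient_id %in% carrier_ids) |>
        select("sample_id") |>
        dplyr::cross_join(p72r_variant()) |>
        mutate(true_vaf = 0.5)
      germ_obs <- observe_true_reads(germ, config$mean_depth) |>
        select(all_of(names(empty_variant_table())))
    }

    artefacts <- sim_artefact_calls(samples$sample_id, config)
    variants <- bind_rows(clone_obs, germ_obs, artefacts)
    validate_variants(variants)

    truth_summary <- if (nrow(clone_truth) > 0) {
      clone_truth |>
        group_by(.data$sample_id) |>
        summarise(
          true_burden_pct = 100 * sum(.data$true_vaf),
          max_true_vaf = max(.data$true_vaf),
          n_true_clones = n(),
          .groups = "drop"
        )
    } else {
      tibble(
        sample_id = character(), true_burden_pct = numeric(),
        max_true_vaf = numeric(), n_true_clones = integer()
      )
    }
    truth <- samples |>
      left_join(truth_summary, by = "sample_id") |>
      mutate(
        true_burden_pct = tidyr::replace_na(.data$true_burden_pct, 0),
        max_true_vaf = tidyr::replace_na(.data$max_true_vaf, 0),
        n_true_clones = tidyr::replace_na(.data$n_true_clones, 0L)
      )

    link <- config$ct_link
    ct_noise <- stats::rnorm(nrow(truth), 0, link$noise_sd)
    baseline_noise <- stats::rnorm(nrow(truth), 0, config$baseline_ct_noise)
    truth$ct_change_percent <- ifelse(
      truth$true_burden_pct > 0,
      link$intercept + link$slope * log10(truth$true_burden_pct) + ct_noise,
      baseline_noise
    )

    samples <- truth |>
      select(all_of(c(
        "sample_id", "patient_id", "material", "timepoint_weeks",
        "ct_change_percent"
      )))
    truth <- truth |>
      select(all_of(c(
        "sample_id", "patient_id", "timepoint_weeks", "true_burden_pct",
        "max_true_vaf", "n_true_clones", "ct_change_percent"
      )))
    validate_samples(samples)
    list(variants = variants, samples = samples, clones = clones, truth = truth)
  })
}

# sample hotspot mutations matching the requested transversion flags,
# without replacement within a patient; falls back to the other class when
# one class is exhausted
sample_hotspots <- function(hot, is_tv) {
  n <- length(is_tv)
  tv_pool <- which(hot$transversion)
  ti_pool <- which(!hot$transversion)
  n_tv <- min(sum(is_tv), length(tv_pool))
  n_ti <- min(n - n_tv, length(ti_pool))
  idx <- c(
    if (n_tv > 0) sample(tv_pool, n_tv),
    if (n_ti > 0) sample(ti_pool, n_ti)
  )
  hot[idx, ]
}

decayed_logistic_vaf <- function(t, emergence_week, v0, rate, k, peak_week) {
  base <- logistic_vaf(pmin(t, peak_week), emergence_week, v0, rate, k)
  ifelse(t > peak_week, base * exp(-0.15 * (t - peak_week)), base)
}

#' Score pipeline output against simulation truth
#'
#' Confusion summary of per-sample detection calls against the generator's
#' truth table: a sample is truth-positive when its largest true clone VAF
#' strictly exceeds the calling threshold. Also reports the mean absolute
#' burden error over true-positive samples and the detection sensitivity
#' restricted to samples harbouring a clone with true VAF > 2% (essentially
#' always observable at 8,000x depth).
#'
#' @param truth The `truth` tibble from [simulate_cohort()].
#' @param result A [burden_series()] (or [detect_samples()]) tibble with
#'   `sample_id`, `detected` and, if available, `burden_pct`.
#' @param vaf_threshold The calling threshold used to produce `result`.
#' @param high_vaf True-VAF level defining the high-confidence sensitivity
#'   stratum (default 0.02).
#' @return A one-row tibble: `n_samples`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `sensitivity_high_vaf`, `mean_abs_burden_error`.
#' @export
truth_report <- function(truth, result, vaf_threshold = 0.01, high_vaf = 0.02) {
  if (!setequal(truth$sample_id, result$sample_id)) {
    abort("truth and result sample ids do not match")
  }
  joined <- inner_join(
    truth,
    select(result, any_of(c("sample_id", "detected", "burden_pct"))),
    by = "sample_id"
  )
  positive <- joined$max_true_vaf > vaf_threshold
  det <- joined$detected
  tp <- sum(positive & det)
  high <- joined$max_true_vaf > high_vaf
  burden_err <- if ("burden_pct" %in% names(joined) && tp > 0) {
    mean(abs(joined$burden_pct[positive & det] -
               joined$true_burden_pct[positive & det]))
  } else {
    NA_real_
  }
  tibble(
    n_samples = nrow(joined),
    tp = tp,
    fp = sum(!positive & det),
    fn = sum(positive & !det),
    tn = sum(!positive & !det),
    sensitivity = if (any(positive)) tp / sum(positive) else NA_real_,
    sensitivity_high_vaf = if (any(high)) {
      sum(high & det) / sum(high)
    } else {
      NA_real_
    },
    mean_abs_burden_error = burden_err
  )
}
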