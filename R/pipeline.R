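#' Pipeline run configuration
#'
#' @param vaf_threshold VAF calling threshold in (0, 1); default 0.01 (1%),
#'   the conservative threshold calibrated from healthy donors and matched
#'   tumour/plasma pairs.
#' @param alt_ratio_cutoff Advisory strand-bias flag cutoff (default 0.25).
#' @param alpha Significance level (default 0.05).
#' @param prior_alpha,prior_beta Beta prior for the detection probability
#'   (default uniform).
#' @param germline_changes Protein changes excluded as germline (default
#'   `"P72R"`).
#' @param spectrum_scope Deduplication scope for the mutation spectrum
#'   (`"patient"` or `"cohort"`).
#' @param seed Seed recorded in the report provenance (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(vaf_threshold = 0.01, alt_ratio_cutoff = 0.25,
                       alpha = 0.05, prior_alpha = 1, prior_beta = 1,
                       germline_changes = "P72R",
                       spectrum_scope = c("patient", "cohort"),
                       seed = NA_integer_) {
  if (vaf_threshold <= 0 || vaf_threshold >= 1) {
    abort("vaf_threshold must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  structure(
    list(
      vaf_threshold = vaf_threshold,
      alt_ratio_cutoff = alt_ratio_cutoff,
      alpha = alpha,
      prior_alpha = prior_alpha,
      prior_beta = prior_beta,
      germline_changes = germline_changes,
      spectrum_scope = match.arg(spectrum_scope),
      seed = seed
    ),
    class = "run_config"
  )
}

#' Run the full cfDNA emergence analysis
#'
#' Orchestrates the stages on a treated cohort: strand-bias QC annotation,
#' mutation filtering at the VAF threshold, the per-sample detection matrix,
#' per-patient allele-burden trajectories, the transition/transversion
#' spectrum with its exact binomial test against a 50% transversion
#' frequency, the beta-binomial posterior predictive comparison of baseline
#' vs on-treatment detection counts (the healthy-donor panel fixes the
#' posterior; when no panel is supplied the prior alone is used), the Pearson
#' correlation of burden with time, and the linear-log regression of CT
#' change on burden (restricted to detected samples; skipped with an explicit
#' status when fewer than three are available).
#'
#' @param variants Variant tibble for the cohort's plasma samples.
#' @param samples Sample sheet (`plasma_cfdna` rows; `timepoint_weeks`
#'   required, 0 = baseline).
#' @param config A [run_config()].
#' @param normal_panel Optional list with `variants` and `samples` of a
#'   healthy-donor panel used for the conjugate update of the detection
#'   probability.
#' @return An object of class `cfdna_report`: a list with `detection`,
#'   `burden`, `spectrum`, `spectrum_test`, `predictive`, `time_correlation`,
#'   `regression` (a `burden_lm` or `NULL`), `regression_status`, `filter_log`
#'   and `provenance`.
#' @export
run_pipeline <- function(variants, samples, config = run_config(),
                         normal_panel = NULL) {
  stopifnot(inherits(config, "run_config"))
  validate_variants(variants)
  validate_samples(samples)

  qc <- flag_strand_bias(variants, config$alt_ratio_cutoff)
  passing <- filter_variants(variants, config$vaf_threshold,
                             config$germline_changes)
  filter_log <- tibble(
    stage = c(
      "input calls", "coding non-silent", "non-germline",
      "above VAF threshold", "strand-bias flagged (advisory)"
    ),
    n = c(
      nrow(variants),
      sum(!variants$effect %in% c("silent", "noncoding")),
      sum(!variants$effect %in% c("silent", "noncoding") &
            !variants$protein_change %in% config$germline_changes),
      nrow(passing),
      sum(qc$strand_biased)
    )
  )

  detection <- detect_samples(variants, samples, config$vaf_threshold,
                              config$germline_changes)
  burden <- burden_series(variants, samples, config$vaf_threshold,
                          config$germline_changes)
  spectrum <- mutation_spectrum(passing, samples, config$spectrum_scope)
  spectrum_test <- if (spectrum$n_total > 0) {
    binomial_tail_lower(spectrum$n_transversions, spectrum$n_total, 0.5)
  } else {
    NA_real_
  }

  panel_detections <- 0L
  panel_n <- 0L
  if (!is.null(normal_panel)) {
    # detection is defined on plasma material; donor plasma qualifies
    panel_det <- detect_samples(
      normal_panel$variants,
      mutate(normal_panel$samples, material = "plasma_cfdna"),
      vaf_threshold = config$vaf_threshold,
      germline_changes = config$germline_changes
    )
    panel_detections <- sum(panel_det$detected)
    panel_n <- nrow(panel_det)
  }
  baseline <- filter(detection, .data$timepoint_weeks == 0)
  treatment <- filter(detection, .data$timepoint_weeks > 0)
  predictive <- detection_predictive_test(
    panel_detections, panel_n,
    sum(baseline$detected), nrow(baseline),
    sum(treatment$detected), nrow(treatment),
    config$prior_alpha, config$prior_beta
  )

  detected_burden <- filter(burden, .data$detected)
  time_correlation <- if (nrow(detected_burden) >= 3 &&
                            stats::sd(detected_burden$timepoint_weeks) > 0 &&
                            stats::sd(detected_burden$burden_pct) > 0) {
    pearson_test(detected_burden$timepoint_weeks, detected_burden$burden_pct)
  } else {
    NULL
  }

  regression <- NULL
  regression_status <- "ok"
  usable <- filter(detected_burden, !is.na(.data$ct_change_percent))
  if (nrow(usable) < 3) {
    regression_status <- "insufficient detected samples"
  } else {
    regression <- burden_regression(usable, alpha = config$alpha)
  }

  structure(
    list(
      version = 1L,
      detection = detection,
      burden = burden,
      spectrum = spectrum,
      spectrum_test = spectrum_test,
      predictive = predictive,
      time_correlation = time_correlation,
      regression = regression,
      regression_status = regression_status,
      filter_log = filter_log,
      qc = qc,
      provenance = list(
        package_version = as.character(utils::packageVersion("cfTP53")),
        config = unclass(config),
        n_variants = nrow(variants),
        n_samples = nrow(samples),
        panel_n = panel_n,
        panel_detections = panel_detections
      )
    ),
    class = "cfdna_report"
  )
}

#' @export
print.cfdna_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a pipeline report as human-readable text
#'
#' Every number in the text exists in the report object; nothing is
#' recomputed here.
#'
#' @param report A `cfdna_report` from [run_pipeline()].
#' @return A character vector of lines.
#' @export
render_report <- function(report) {
  if (!inherits(report, "cfdna_report") || !identical(report$version, 1L)) {
    abort("unknown report version")
  }
  det <- report$detection
  baseline <- filter(det, .data$timepoint_weeks == 0)
  treatment <- filter(det, .data$timepoint_weeks > 0)
  p <- report$predictive
  lines <- c(
    "cfDNA TP53 emergence report",
    "===========================",
    sprintf("samples: %d (%d baseline, %d on-treatment)",
            nrow(det), nrow(baseline), nrow(treatment)),
    "",
    "filter boundary counts:",
    sprintf("  %-32s %d", report$filter_log$stage, report$filter_log$n),
    "",
    sprintf("detections: baseline %d/%d, treatment %d/%d",
            sum(baseline$detected), nrow(baseline),
            sum(treatment$detected), nrow(treatment)),
    sprintf("posterior for detection probability: Beta(%g, %g)",
            p$posterior_alpha, p$posterior_beta),
    sprintf("posterior predictive: baseline %.4g, treatment pmf %.4g / sf %.4g",
            p$p_baseline, p$p_treatment_pmf, p$p_treatment_sf),
    sprintf("fold change (baseline / treatment): pmf %.4g, sf %.4g",
            p$fold_change_pmf, p$fold_change_sf),
    "",
    sprintf("spectrum: %d transitions, %d transversions (%.3g%% transversion)",
            report$spectrum$n_transitions, report$spectrum$n_transversions,
            100 * report$spectrum$transversion_fraction),
    sprintf("binomial tail P(X <= k | p = 0.5): %.8g", report$spectrum_test)
  )
  if (!is.null(report$time_correlation)) {
    tc <- report$time_correlation
    lines <- c(lines, sprintf(
      "burden vs time: r = %.3f (t = %.3g, p = %.3g, 95%% CI %.3f..%.3f)",
      tc$estimate, tc$statistic, tc$p.value, tc$conf.low, tc$conf.high
    ))
  }
  if (!is.null(report$regression)) {
    r <- report$regression
    lines <- c(lines, sprintf(
      "CT change ~ log10(burden): slope %.3g (t = %.3g, p = %.3g), F = %.3g (p = %.3g), R^2 = %.3f",
      r$slope, r$slope_t, r$slope_p, r$f_stat, r$f_p, r$r_squared
    ))
  } else {
    lines <- c(lines, paste0("burden regression: ", report$regression_status))
  }
  lines
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `cfdna_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "cfdna_report")) abort("not a cfdna_report")
  out <- list(
    version = report$version,
    detection = report$detection,
    burden = report$burden,
    spectrum = report$spectrum,
    spectrum_test = report$spectrum_test,
    predictive = report$predictive,
    time_correlation = report$time_correlation,
    regression = if (!is.null(report$regression)) glance(report$regression),
    regression_status = report$regression_status,
    filter_log = report$filter_log,
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @method glance cfdna_report
#' @export
glance.cfdna_report <- function(x, ...) {
  det <- x$detection
  baseline <- filter(det, .data$timepoint_weeks == 0)
  treatment <- filter(det, .data$timepoint_weeks > 0)
  tibble(
    n_samples = nrow(det),
    baseline_detected = sum(baseline$detected),
    baseline_n = nrow(baseline),
    treatment_detected = sum(treatment$detected),
    treatment_n = nrow(treatment),
    p_baseline = x$predictive$p_baseline,
    p_treatment_sf = x$predictive$p_treatment_sf,
    n_transversions = x$spectrum$n_transversions,
    n_spectrum = x$spectrum$n_total,
    spectrum_test = x$spectrum_test,
    regression_slope = if (!is.null(x$regression)) x$regression$slope else NA_real_,
    regression_p = if (!is.null(x$regression)) x$regression$slope_p else NA_real_
  )
}
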