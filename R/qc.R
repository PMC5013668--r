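#' Strand-bias score (ALT_RATIO)
#'
#' ALT_RATIO is the proportion of variant-supporting reads in the
#' less-abundant read direction: `min(alt_fwd, alt_rev) / (alt_fwd +
#' alt_rev)`. It ranges over \[0, 0.5\]; 0.5 means perfectly balanced strands
#' (no bias) and values near 0 mean nearly all supporting reads came from one
#' strand, the signature of a sequencing artefact. The score is symmetric in
#' its arguments, so it does not depend on which strand is labelled forward.
#'
#' @param alt_fwd,alt_rev Alt-supporting read counts on the forward and
#'   reverse strand. Vectorised; each pair must have at least one alt read.
#' @return A numeric vector of ratios in \[0, 0.5\].
#' @examples
#' alt_ratio(30, 30) # 0.5, no strand bias
#' alt_ratio(40, 0)  # 0, maximal bias
#' @export
alt_ratio <- function(alt_fwd, alt_rev) {
  if (any(alt_fwd < 0 | alt_rev < 0)) abort("strand counts must be non-negative")
  total <- alt_fwd + alt_rev
  if (any(total == 0)) {
    abort("no variant evidence: alt_fwd + alt_rev must be positive")
  }
  pmin(alt_fwd, alt_rev) / total
}

#' Flag strand-biased variant calls
#'
#' Adds `alt_ratio` and a logical `strand_biased` column to a variant table.
#' A call is flagged when its ALT_RATIO is strictly below `min_alt_ratio`.
#' The flag is advisory QC only — downstream filtering uses the VAF threshold,
#' never this flag, so a balanced real mutation is never silently dropped.
#'
#' @param variants A variant tibble.
#' @param min_alt_ratio Cutoff below which a call is flagged (default 0.25).
#' @return The variant tibble with `alt_ratio` and `strand_biased` columns.
#' @export
flag_strand_bias <- function(variants, min_alt_ratio = 0.25) {
  validate_variants(variants)
  if (nrow(variants) == 0) {
    return(mutate(variants, alt_ratio = numeric(0), strand_biased = logical(0)))
  }
  variants |>
    mutate(
      alt_ratio = alt_ratio(.data$alt_fwd, .data$alt_rev),
      strand_biased = .data$alt_ratio < min_alt_ratio
    )
}

#' Noise profile of a healthy-donor cfDNA panel
#'
#' Aggregates all variant calls across a panel of healthy-donor
#' (`normal_plasma`) samples, attaches ALT_RATIO to each, and reports the
#' maximum observed VAF. The maximum VAF over such a panel is the empirical
#' noise ceiling used to motivate the VAF calling threshold: artefact calls
#' in donor plasma are strand-biased and concentrate well below 1% VAF.
#'
#' @param variants Variant tibble for the panel samples.
#' @param samples Sample sheet; every row must have `material ==
#'   "normal_plasma"`.
#' @return An object of class `noise_profile`: a list with `n_samples`,
#'   `max_vaf` (0 when the panel called no variants) and `variants`, the
#'   per-variant tibble with `alt_ratio` attached.
#' @export
noise_profile <- function(variants, samples) {
  validate_samples(samples)
  if (any(samples$material != "normal_plasma")) {
    abort("noise_profile expects only normal_plasma samples")
  }
  variants <- semi_join(variants, samples, by = "sample_id")
  per_variant <- flag_strand_bias(variants)
  structure(
    list(
      n_samples = nrow(samples),
      max_vaf = if (nrow(per_variant) > 0) max(per_variant$vaf) else 0,
      variants = per_variant
    ),
    class = "noise_profile"
  )
}

#' @export
print.noise_profile <- function(x, ...) {
  cat("Healthy-donor cfDNA noise profile\n")
  cat("  samples:        ", x$n_samples, "\n", sep = "")
  cat("  variant calls:  ", nrow(x$variants), "\n", sep = "")
  cat(sprintf("  max VAF:        %.4g%%\n", 100 * x$max_vaf))
  invisible(x)
}

#' @method glance noise_profile
#' @export
glance.noise_profile <- function(x, ...) {
  tibble(
    n_samples = x$n_samples,
    n_variants = nrow(x$variants),
    max_vaf = x$max_vaf,
    median_alt_ratio = if (nrow(x$variants) > 0) {
      stats::median(x$variants$alt_ratio)
    } else {
      NA_real_
    }
  )
}

#' Tumour/plasma concordance at a VAF threshold
#'
#' For matched tumour/plasma pairs (one plasma_cfdna and one tumour_ffpe
#' sample per patient), classifies each plasma variant as above
#' (strictly `vaf > threshold`) or below the threshold, and as concordant when
#' a variant with identical `(contig, pos, ref, alt)` — exact allele identity,
#' not just position — exists in the same patient's tumour sample. The
#' resulting two-by-two table is the evidence behind choosing a VAF calling
#' threshold: true tumour-derived variants dominate above it, artefacts below.
#'
#' @param variants Variant tibble covering both plasma and tumour samples.
#' @param samples Sample sheet; each patient must contribute exactly one
#'   `plasma_cfdna` and one `tumour_ffpe` sample.
#' @param threshold_vaf VAF threshold(s) in (0, 1); may be a vector.
#' @return A tibble with one row per threshold: `threshold_vaf`, `n_above`,
#'   `n_above_concordant`, `pct_above`, `n_below`, `n_below_concordant`,
#'   `pct_below`.
#' @export
concordance_table <- function(variants, samples, threshold_vaf = 0.01) {
  validate_variants(variants)
  validate_samples(samples)
  if (any(threshold_vaf <= 0 | threshold_vaf >= 1)) {
    abort("threshold_vaf must lie in (0, 1)")
  }
  plasma <- filter(samples, .data$material == "plasma_cfdna")
  tumour <- filter(samples, .data$material == "tumour_ffpe")
  unmatched <- c(
    setdiff(plasma$patient_id, tumour$patient_id),
    setdiff(tumour$patient_id, plasma$patient_id)
  )
  if (length(unmatched) > 0) {
    abort(paste0(
      "unmatched tumour/plasma pair for patient(s): ",
      paste(unique(unmatched), collapse = ", ")
    ))
  }
  if (anyDuplicated(plasma$patient_id) || anyDuplicated(tumour$patient_id)) {
    abort("each patient must contribute exactly one plasma and one tumour sample")
  }
  key <- c("patient_id", "contig", "pos", "ref", "alt")
  plasma_vars <- variants |>
    inner_join(select(plasma, "sample_id", "patient_id"), by = "sample_id")
  tumour_vars <- variants |>
    inner_join(select(tumour, "sample_id", "patient_id"), by = "sample_id") |>
    distinct(across(all_of(key)))
  plasma_vars$concordant <- vctrs_in(plasma_vars[key], tumour_vars[key])
  purrr::map_dfr(threshold_vaf, function(t) {
    above <- plasma_vars$vaf > t
    summarise_concordance(t, above, plasma_vars$concordant)
  })
}

# membership of rows of x in rows of table (both data frames, same columns)
vctrs_in <- function(x, table) {
  paste_key <- function(df) {
    do.call(paste, c(as.list(df), sep = "\r"))
  }
  paste_key(x) %in% paste_key(table)
}

summarise_concordance <- function(threshold, above, concordant) {
  n_above <- sum(above)
  n_below <- sum(!above)
  n_above_conc <- sum(above & concordant)
  n_below_conc <- sum(!above & concordant)
  tibble(
    threshold_vaf = threshold,
    n_above = n_above,
    n_above_concordant = n_above_conc,
    pct_above = if (n_above > 0) 100 * n_above_conc / n_above else NA_real_,
    n_below = n_below,
    n_below_concordant = n_below_conc,
    pct_below = if (n_below > 0) 100 * n_below_conc / n_below else NA_real_
  )
}

#' Concordance percentages from pre-tabulated counts
#'
#' Arithmetic helper for reporting a concordance table that was counted
#' elsewhere (e.g. from a published figure): percent concordant above and
#' below the threshold.
#'
#' @param n_above,n_above_concordant,n_below,n_below_concordant Counts of
#'   plasma variants above/below the VAF threshold and the subsets also found
#'   in the matched tumour.
#' @param threshold_vaf The threshold the counts refer to.
#' @return A one-row concordance tibble (see [concordance_table()]).
#' @examples
#' concordance_from_counts(18, 13, 208, 8) # 72.2% above, 3.8% below
#' @export
concordance_from_counts <- function(n_above, n_above_concordant,
                                    n_below, n_below_concordant,
                                    threshold_vaf = 0.01) {
  if (n_above_concordant > n_above || n_below_concordant > n_below) {
    abort("concordant counts cannot exceed totals")
  }
  tibble(
    threshold_vaf = threshold_vaf,
    n_above = n_above,
    n_above_concordant = n_above_concordant,
    pct_above = if (n_above > 0) 100 * n_above_concordant / n_above else NA_real_,
    n_below = n_below,
    n_below_concordant = n_below_concordant,
    pct_below = if (n_below > 0) 100 * n_below_concordant / n_below else NA_real_
  )
}
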