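#' Validate a variant table
#'
#' Checks the structural invariants of a variant table: required columns,
#' strand counts not exceeding depth, VAF consistent with counts, `ref != alt`
#' and positive 1-based positions.
#'
#' @param variants A tibble with one row per variant call. Required columns:
#'   `sample_id`, `contig`, `pos`, `ref`, `alt`, `depth`, `alt_fwd`,
#'   `alt_rev`, `vaf`, `effect`, `protein_change`.
#' @param vaf_tol Maximum tolerated absolute difference between the stored
#'   `vaf` and `(alt_fwd + alt_rev) / depth` at sites with positive depth.
#'
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_variants <- function(variants, vaf_tol = 1e-9) {
  required <- c(
    "sample_id", "contig", "pos", "ref", "alt", "depth",
    "alt_fwd", "alt_rev", "vaf", "effect", "protein_change"
  )
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "variant table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(variants) == 0) {
    return(invisible(variants))
  }
  if (any(variants$pos < 1)) abort("variant positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
  if (any(variants$depth < 0)) abort("depth must be non-negative")
  if (any(variants$alt_fwd < 0 | variants$alt_rev < 0)) {
    abort("per-strand alt counts must be non-negative")
  }
  if (any(variants$alt_fwd + variants$alt_rev > variants$depth)) {
    abort("alt_fwd + alt_rev exceeds depth for at least one variant")
  }
  has_depth <- variants$depth > 0
  expected <- (variants$alt_fwd + variants$alt_rev)[has_depth] /
    variants$depth[has_depth]
  if (any(abs(variants$vaf[has_depth] - expected) > vaf_tol)) {
    abort("vaf is inconsistent with (alt_fwd + alt_rev) / depth")
  }
  bad_effect <- setdiff(unique(variants$effect), variant_effects)
  if (length(bad_effect) > 0) {
    abort(paste0("unknown effect value(s): ", paste(bad_effect, collapse = ", ")))
  }
  invisible(variants)
}

#' Validate a sample sheet
#'
#' @param samples A tibble with one row per sample. Required columns:
#'   `sample_id`, `patient_id`, `material`, `timepoint_weeks`,
#'   `ct_change_percent`. `timepoint_weeks` is `NA` for tumour and
#'   healthy-donor samples; 0 denotes the pre-treatment baseline.
#'
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_samples <- function(samples) {
  required <- c(
    "sample_id", "patient_id", "material", "timepoint_weeks",
    "ct_change_percent"
  )
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "sample sheet is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- samples$sample_id[duplicated(samples$sample_id)][1]
    abort(paste0("duplicate sample_id in sample sheet: ", dup))
  }
  bad <- setdiff(unique(samples$material), sample_materials)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown material value(s): ", paste(bad, collapse = ", "),
      " (expected one of ", paste(sample_materials, collapse = ", "), ")"
    ))
  }
  tp <- samples$timepoint_weeks
  if (any(!is.na(tp) & tp < 0)) abort("timepoint_weeks must be non-negative")
  invisible(samples)
}
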