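#' Filter variant calls to reportable mutations
#'
#' Applies the mutation-calling filter: keep variants that are (a) coding and
#' non-silent (silent and non-coding calls are excluded), (b) not the known
#' germline TP53 P72R polymorphism, and (c) strictly above the VAF threshold.
#' Indels are retained when coding and non-silent. Input order is preserved
#' and the filter is idempotent.
#'
#' @param variants A variant tibble.
#' @param vaf_threshold VAF threshold in (0, 1); variants exactly at the
#'   threshold are removed (strict `>`). Default 0.01 (1%), the conservative
#'   cfDNA calling threshold calibrated from healthy donors and matched pairs.
#' @param germline_changes Protein changes treated as germline polymorphisms
#'   and always excluded (default `"P72R"`).
#' @return The filtered variant tibble.
#' @export
filter_variants <- function(variants, vaf_threshold = 0.01,
                            germline_changes = "P72R") {
  validate_variants(variants)
  if (vaf_threshold <= 0 || vaf_threshold >= 1) {
    abort("vaf_threshold must lie in (0, 1)")
  }
  variants |>
    filter(
      !.data$effect %in% c("silent", "noncoding"),
      !.data$protein_change %in% germline_changes,
      .data$vaf > vaf_threshold
    )
}

#' Per-sample mutation detection calls
#'
#' A plasma cfDNA sample is "detected" when at least one variant survives
#' [filter_variants()] at the given threshold — the per-timepoint detection
#' flag of a patient mutation-status matrix.
#'
#' @param variants Variant tibble.
#' @param samples Sample sheet; all rows must be `plasma_cfdna`.
#' @param vaf_threshold VAF threshold in (0, 1).
#' @inheritParams filter_variants
#' @return The sample sheet with `n_passing` and logical `detected` columns.
#' @export
detect_samples <- function(variants, samples, vaf_threshold = 0.01,
                           germline_changes = "P72R") {
  validate_samples(samples)
  if (any(samples$material != "plasma_cfdna")) {
    abort("detection calls are defined for plasma_cfdna samples only")
  }
  passing <- filter_variants(variants, vaf_threshold, germline_changes) |>
    count(.data$sample_id, name = "n_passing")
  samples |>
    left_join(passing, by = "sample_id") |>
    mutate(
      n_passing = tidyr::replace_na(.data$n_passing, 0L),
      detected = .data$n_passing >= 1L
    )
}

#' Mutation allele-burden trajectories
#'
#' Per patient and timepoint, the allele burden is the sum over passing
#' variants of VAF x 100 (a percentage). Burden is 0 with `detected = FALSE`
#' at timepoints where no variant passes the filter; output is sorted by
#' patient then week.
#'
#' @param variants Variant tibble.
#' @param samples Sample sheet of `plasma_cfdna` samples with
#'   `timepoint_weeks` present.
#' @param vaf_threshold VAF threshold in (0, 1).
#' @inheritParams filter_variants
#' @return A tibble with one row per (patient, timepoint): `patient_id`,
#'   `sample_id`, `timepoint_weeks`, `burden_pct`, `n_passing`, `detected`,
#'   `ct_change_percent`.
#' @export
burden_series <- function(variants, samples, vaf_threshold = 0.01,
                          germline_changes = "P72R") {
  validate_samples(samples)
  if (any(samples$material != "plasma_cfdna")) {
    abort("burden trajectories are defined for plasma_cfdna samples only")
  }
  if (anyNA(samples$timepoint_weeks)) {
    abort("all plasma samples need a timepoint_weeks for a burden trajectory")
  }
  per_sample <- filter_variants(variants, vaf_threshold, germline_changes) |>
    group_by(.data$sample_id) |>
    summarise(
      burden_pct = 100 * sum(.data$vaf),
      n_passing = n(),
      .groups = "drop"
    )
  samples |>
    left_join(per_sample, by = "sample_id") |>
    mutate(
      burden_pct = tidyr::replace_na(.data$burden_pct, 0),
      n_passing = tidyr::replace_na(.data$n_passing, 0L),
      detected = .data$n_passing >= 1L
    ) |>
    select(all_of(c(
      "patient_id", "sample_id", "timepoint_weeks", "burden_pct",
      "n_passing", "detected", "ct_change_percent"
    ))) |>
    arrange(.data$patient_id, .data$timepoint_weeks)
}

#' Classify a single-nucleotide substitution
#'
#' Purine-to-purine (A<->G) or pyrimidine-to-pyrimidine (C<->T) changes are
#' transitions; purine<->pyrimidine changes are transversions. Defined for
#' single-nucleotide substitutions only; indel alleles are an error.
#'
#' @param ref,alt Single-base reference and alternate alleles (vectorised),
#'   with `ref != alt`.
#' @return A character vector of `"transition"` / `"transversion"`.
#' @examples
#' classify_substitution("C", "T") # transition
#' classify_substitution("G", "T") # transversion
#' @export
classify_substitution <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    abort("substitution spectrum is defined for single-nucleotide variants only")
  }
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases | !alt %in% bases)) {
    abort("ref and alt must be single DNA bases (A, C, G, T)")
  }
  if (any(ref == alt)) abort("ref and alt must differ")
  purine <- c("A", "G")
  if_else(
    (ref %in% purine) == (alt %in% purine),
    "transition", "transversion"
  )
}

#' Transition/transversion spectrum of a mutation set
#'
#' Counts transitions and transversions over unique single-nucleotide
#' variants. The same mutation observed at several timepoints of one patient
#' is one event: deduplication is by `(patient_id, contig, pos, ref, alt)`
#' with `scope = "patient"` (the default), or by `(contig, pos, ref, alt)`
#' across the whole cohort with `scope = "cohort"`. Indel alleles are ignored
#' (the spectrum is defined for SNVs).
#'
#' @param variants Variant tibble.
#' @param samples Sample sheet mapping `sample_id` to `patient_id` (required
#'   for `scope = "patient"`).
#' @param scope `"patient"` or `"cohort"` deduplication.
#' @return A one-row tibble: `n_transitions`, `n_transversions`, `n_total`,
#'   `transversion_fraction`.
#' @export
mutation_spectrum <- function(variants, samples = NULL,
                              scope = c("patient", "cohort")) {
  scope <- match.arg(scope)
  validate_variants(variants)
  snv <- filter(variants, nchar(.data$ref) == 1L, nchar(.data$alt) == 1L)
  if (scope == "patient") {
    if (is.null(samples)) {
      abort("scope = 'patient' needs a sample sheet to map samples to patients")
    }
    validate_samples(samples)
    snv <- snv |>
      inner_join(select(samples, "sample_id", "patient_id"), by = "sample_id") |>
      distinct(across(all_of(c("patient_id", "contig", "pos", "ref", "alt"))))
  } else {
    snv <- distinct(snv, across(all_of(c("contig", "pos", "ref", "alt"))))
  }
  if (nrow(snv) == 0) {
    return(tibble(
      n_transitions = 0L, n_transversions = 0L, n_total = 0L,
      transversion_fraction = NA_real_
    ))
  }
  cls <- classify_substitution(snv$ref, snv$alt)
  tibble(
    n_transitions = sum(cls == "transition"),
    n_transversions = sum(cls == "transversion"),
    n_total = length(cls),
    transversion_fraction = sum(cls == "transversion") / length(cls)
  )
}
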