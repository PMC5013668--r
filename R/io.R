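#' Read a variant table
#'
#' Reads per-sample variant calls, with per-strand alternate-allele read
#' counts, from either a tab-separated table or a VCF 4.2 file. Per-strand
#' counts are mandatory: strand-bias QC is impossible without them.
#'
#' For the TSV dialect the columns are those of [validate_variants()]. When a
#' `vaf` column is present but disagrees with `(alt_fwd + alt_rev) / depth` by
#' more than `1e-6`, the VAF is recomputed from the counts and a warning is
#' raised.
#'
#' For the VCF dialect per-strand alternate counts are taken from a pair of
#' per-allele FORMAT fields, by default the reserved VCF 4.2 keys `ADF` and
#' `ADR` (allelic depths on the forward/reverse strand, reference allele
#' first); depth comes from `DP`. Multi-allelic records are split into one row
#' per alternate allele. Effect annotations are consumed, never computed: they
#' are read from INFO keys (`effect_key`, `pchange_key`) and default to
#' `"noncoding"` / `""` with a warning when absent.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param fwd_key,rev_key FORMAT keys holding per-allele forward/reverse
#'   allelic depths (VCF dialect only).
#' @param effect_key,pchange_key INFO keys holding the annotated effect and
#'   protein change (VCF dialect only).
#'
#' @return A tibble of variant calls (see [validate_variants()]).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "sample_id\tcontig\tpos\tref\talt\tdepth\talt_fwd\talt_rev\tvaf\teffect\tprotein_change",
#'   "S1\tTP53\t100\tG\tA\t10000\t50\t50\t0.01\tmissense\tR175H"
#' ), tsv)
#' read_variant_table(tsv)
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               fwd_key = "ADF", rev_key = "ADR",
                               effect_key = "EFFECT", pchange_key = "PCHANGE") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "tsv") {
    read_variant_tsv(path)
  } else {
    read_variant_vcf(path, fwd_key, rev_key, effect_key, pchange_key)
  }
}

read_variant_tsv <- function(path) {
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    contig = readr::col_character(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    effect = readr::col_character(),
    protein_change = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  for (col in c("alt_fwd", "alt_rev")) {
    if (!col %in% names(raw)) {
      abort(paste0(
        "per-strand alt read counts are mandatory; missing column: ", col
      ))
    }
  }
  missing_cols <- setdiff(
    c("sample_id", "contig", "pos", "ref", "alt", "depth"), names(raw)
  )
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed value at line ", probs$row[1],
      " (", probs$expected[1], " expected, got '", probs$actual[1], "')"
    ))
  }
  if (nrow(raw) > 0 && anyNA(raw$pos)) {
    abort(paste0(
      "malformed coordinate at line ", which(is.na(raw$pos))[1] + 1L
    ))
  }
  out <- raw |>
    mutate(
      pos = as.integer(.data$pos),
      protein_change = if ("protein_change" %in% names(raw)) {
        tidyr::replace_na(.data$protein_change, "")
      } else {
        ""
      }
    )
  if (nrow(out) > 0) {
    counts_vaf <- ifelse(out$depth > 0, (out$alt_fwd + out$alt_rev) / out$depth, 0)
    if (!"vaf" %in% names(out)) {
      out$vaf <- counts_vaf
    } else if (any(abs(out$vaf - counts_vaf) > 1e-6, na.rm = TRUE)) {
      warn("stored VAF disagrees with strand counts beyond 1e-6; recomputed from counts")
      out$vaf <- counts_vaf
    }
  } else if (!"vaf" %in% names(out)) {
    out$vaf <- numeric(0)
  }
  out <- select(out, all_of(c(
    "sample_id", "contig", "pos", "ref", "alt", "depth",
    "alt_fwd", "alt_rev", "vaf", "effect", "protein_change"
  )))
  validate_variants(out)
  out
}

read_variant_vcf <- function(path, fwd_key, rev_key, effect_key, pchange_key) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_raw <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_raw))) fix_raw <- t(fix_raw)
  fix <- as.data.frame(fix_raw, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_variant_table())
  }
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  for (key in c(fwd_key, rev_key)) {
    if (!key %in% fmt_keys) {
      abort(paste0(
        "per-strand alt read counts are mandatory; FORMAT field '", key,
        "' not found in VCF"
      ))
    }
  }
  as_gt_matrix <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = nrow(fix)) else x
  }
  adf <- as_gt_matrix(vcfR::extract.gt(vcf, element = fwd_key))
  adr <- as_gt_matrix(vcfR::extract.gt(vcf, element = rev_key))
  dp <- as_gt_matrix(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  eff <- unname(vcfR::extract.info(vcf, element = effect_key))
  pch <- unname(vcfR::extract.info(vcf, element = pchange_key))
  if (all(is.na(eff))) {
    warn(paste0(
      "INFO key '", effect_key, "' absent; effect set to 'noncoding'"
    ))
  }
  sample_ids <- colnames(vcf@gt)[-1]
  rows <- list()
  for (s in seq_along(sample_ids)) {
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      fwd_all <- parse_allelic_depths(adf[i, s], length(alts) + 1L, fwd_key, i)
      rev_all <- parse_allelic_depths(adr[i, s], length(alts) + 1L, rev_key, i)
      pos <- suppressWarnings(as.integer(fix$POS[i]))
      if (is.na(pos)) abort(paste0("malformed coordinate in VCF record ", i))
      for (a in seq_along(alts)) {
        depth <- dp[i, s]
        alt_fwd <- fwd_all[a + 1L]
        alt_rev <- rev_all[a + 1L]
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = sample_ids[s],
          contig = fix$CHROM[i],
          pos = pos,
          ref = fix$REF[i],
          alt = alts[a],
          depth = as.numeric(depth),
          alt_fwd = alt_fwd,
          alt_rev = alt_rev,
          vaf = if (!is.na(depth) && depth > 0) (alt_fwd + alt_rev) / depth else 0,
          effect = if (is.na(eff[i])) "noncoding" else eff[i],
          protein_change = if (is.na(pch[i])) "" else pch[i]
        )
      }
    }
  }
  out <- bind_rows(rows)
  validate_variants(out)
  out
}

parse_allelic_depths <- function(x, n_alleles, key, record) {
  if (is.na(x)) {
    abort(paste0("FORMAT field '", key, "' missing for VCF record ", record))
  }
  vals <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
  if (length(vals) != n_alleles || anyNA(vals)) {
    abort(paste0(
      "FORMAT field '", key, "' at record ", record,
      " must hold one value per allele (ref first)"
    ))
  }
  vals
}

empty_variant_table <- function() {
  tibble(
    sample_id = character(), contig = character(), pos = integer(),
    ref = character(), alt = character(), depth = numeric(),
    alt_fwd = numeric(), alt_rev = numeric(), vaf = numeric(),
    effect = character(), protein_change = character()
  )
}

#' Write a variant table to TSV
#'
#' Full-precision writer; [read_variant_table()] round-trips all fields.
#'
#' @param variants A validated variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  out <- mutate(variants, vaf = sprintf("%.15g", .data$vaf))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A CSV with one row per sequenced sample: `sample_id`, `patient_id`,
#' `material` (one of `plasma_cfdna`, `tumour_ffpe`, `normal_plasma`),
#' `timepoint_weeks` (0 = baseline; empty for tumour/donor samples) and
#' `ct_change_percent` (signed percent change in tumour size by CT; may be
#' empty). Duplicate sample ids and unknown materials are rejected.
#'
#' @param path Path to the CSV.
#' @return A validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    patient_id = readr::col_character(),
    material = readr::col_character(),
    timepoint_weeks = readr::col_double(),
    ct_change_percent = readr::col_double()
  ), progress = FALSE)
  validate_samples(out)
  out
}

#' Write a sample sheet to CSV
#'
#' @param samples A validated sample-sheet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_samples(samples)
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read a targeted-panel interval file (BED)
#'
#' BED intervals are 0-based half-open; the returned tibble keeps that
#' convention (`start` 0-based inclusive, `end` exclusive).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `contig`, `start`, `end`, `label`.
#' @export
read_panel_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = if (!is.null(gr$name)) as.character(gr$name) else ""
  )
}

#' Restrict variants to a capture panel
#'
#' Keeps variants whose 1-based position falls inside one of the panel's
#' 0-based half-open intervals; input order is preserved and the operation is
#' idempotent.
#'
#' @param variants A variant tibble.
#' @param panel A panel tibble as returned by [read_panel_bed()].
#' @return The filtered variant tibble.
#' @export
restrict_to_panel <- function(variants, panel) {
  validate_variants(variants)
  if (nrow(variants) == 0 || nrow(panel) == 0) {
    return(variants[0, ])
  }
  if (any(panel$start >= panel$end)) abort("panel intervals require start < end")
  var_gr <- GenomicRanges::GRanges(
    seqnames = variants$contig,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  panel_gr <- GenomicRanges::GRanges(
    seqnames = panel$contig,
    ranges = IRanges::IRanges(start = panel$start + 1L, end = panel$end)
  )
  hits <- GenomicRanges::findOverlaps(var_gr, panel_gr)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  variants[keep, ]
}
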