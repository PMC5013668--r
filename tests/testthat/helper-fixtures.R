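# Builders for in-memory fixtures. All fixtures are constructed in code; no
# files ship with the tests beyond what these helpers write to tempdir().

make_variants <- function(sample_id = "S1", contig = "TP53", pos = 100L,
                          ref = "G", alt = "A", depth = 10000,
                          alt_fwd = 50, alt_rev = 50,
                          effect = "missense", protein_change = "R175H") {
  tibble::tibble(
    sample_id = sample_id, contig = contig, pos = as.integer(pos),
    ref = ref, alt = alt, depth = depth,
    alt_fwd = alt_fwd, alt_rev = alt_rev,
    vaf = ifelse(depth > 0, (alt_fwd + alt_rev) / depth, 0),
    effect = effect, protein_change = protein_change
  )
}

make_samples <- function(sample_id = "S1", patient_id = "P1",
                         material = "plasma_cfdna", timepoint_weeks = 0,
                         ct_change_percent = NA_real_) {
  tibble::tibble(
    sample_id = sample_id, patient_id = patient_id, material = material,
    timepoint_weeks = timepoint_weeks, ct_change_percent = ct_change_percent
  )
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

variant_tsv_header <- paste(
  c("sample_id", "contig", "pos", "ref", "alt", "depth", "alt_fwd",
    "alt_rev", "vaf", "effect", "protein_change"),
  collapse = "\t"
)

# minimal single-sample VCF 4.2 with per-strand allelic depths (ADF/ADR,
# reference allele first) and INFO annotations
write_vcf_fixture <- function(records,
                              sample = "S1",
                              extra_header = character()) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=TP53,length=2100>",
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Annotated effect">',
    '##INFO=<ID=PCHANGE,Number=1,Type=String,Description="Protein change">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Forward allelic depths">',
    '##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Reverse allelic depths">',
    extra_header,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    records
  ), path)
  path
}
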