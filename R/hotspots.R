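#' TP53 DNA-binding-domain missense hotspot table
#'
#' A small built-in table of recurrent TP53 DNA-binding-domain missense
#' substitutions used by the synthetic cohort generator as the identities of
#' resistant subclones. Alleles are codon-consistent for each protein change;
#' coordinates live in a self-consistent toy panel space (contig `"TP53"`,
#' positions within the simulated capture panel), not hg19.
#'
#' @return A tibble: `contig`, `pos`, `ref`, `alt`, `protein_change`,
#'   `transversion`.
#' @export
tp53_hotspots <- function() {
  tab <- tibble::tribble(
    ~pos, ~ref, ~alt, ~protein_change,
    469L, "G", "T", "V157F",
    473L, "G", "T", "R158L",
    488L, "A", "G", "Y163C",
    524L, "G", "A", "R175H",
    527L, "G", "T", "C176F",
    536L, "A", "G", "H179R",
    658L, "T", "C", "Y220H",
    659L, "A", "G", "Y220C",
    659L, "A", "C", "Y220S",
    658L, "T", "A", "Y220N",
    713L, "G", "A", "C238Y",
    722L, "C", "T", "S241F",
    733L, "G", "A", "G245S",
    743L, "G", "A", "R248Q",
    742L, "C", "T", "R248W",
    747L, "G", "T", "R249S",
    797L, "G", "A", "G266E",
    817L, "C", "T", "R273C",
    818L, "G", "A", "R273H",
    844L, "C", "T", "R282W",
    853L, "G", "A", "E285K"
  )
  tab |>
    mutate(
      contig = "TP53",
      transversion = classify_substitution(.data$ref, .data$alt) == "transversion"
    ) |>
    select(all_of(c("contig", "pos", "ref", "alt", "protein_change", "transversion")))
}

# The known germline TP53 P72R polymorphism (c.215C>G) in the toy space.
p72r_variant <- function() {
  tibble(
    contig = "TP53", pos = 215L, ref = "C", alt = "G",
    effect = "missense", protein_change = "P72R"
  )
}
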