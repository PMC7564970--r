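#' Reference phenotype-driven SNP sets
#'
#' Bundled sets of muscle-related variants, one per phenotype, matching the
#' data-driven GPS models reported for the older training-cessation cohort
#' that the synthetic generator emulates: 9 SNPs for \eqn{\Delta}SMM, 7 for
#' \eqn{\Delta}PT_IM60, 13 for \eqn{\Delta}PV_IT20, 9 for
#' \eqn{\Delta}PT_IK60 and 18 for \eqn{\Delta}PT_IK240. They serve as
#' default causal sets in simulations and recovery experiments.
#'
#' @param phenotype Optional phenotype name; when given, returns that set's
#'   tibble only.
#' @return A named list of tibbles (`snp_id`, `gene`), or a single tibble.
#' @export
gps_snp_sets <- function(phenotype = NULL) {
  sets <- list(
    SMM = tibble::tribble(
      ~snp_id, ~gene,
      "rs4870044", "ESR1",
      "rs11549465", "HIF1A",
      "rs3741211", "IGF2",
      "rs7924316", "IGF2AS",
      "rs2390760", "METTL21C",
      "rs3762546", "MSTN",
      "rs97713", "MTRR",
      "rs2229139", "RYR1",
      "rs4790881", "SMG6"
    ),
    PT_IM60 = tibble::tribble(
      ~snp_id, ~gene,
      "rs2296383", "CACNA1S",
      "rs8111989", "CKM",
      "rs689", "INS",
      "rs2390760", "METTL21C",
      "rs3762546", "MSTN",
      "rs327575", "MTRR",
      "rs28357094", "SPP1"
    ),
    PV_IT20 = tibble::tribble(
      ~snp_id, ~gene,
      "rs3733890", "BHMT",
      "rs6107853", "BMP2",
      "rs1800169", "CNTF",
      "rs4511463", "GSC",
      "rs2251375", "H19",
      "rs3741211", "IGF2",
      "rs11121828", "MTHFR",
      "rs1805087", "MTR",
      "rs97713", "MTRR",
      "rs1801394", "MTRR",
      "rs162031", "MTRR",
      "rs1800470", "TGFB1",
      "rs1483246", "ZNF804A"
    ),
    PT_IK60 = tibble::tribble(
      ~snp_id, ~gene,
      "rs2854248", "ATP1A2",
      "rs10883631", "FN1",
      "rs17727841", "IGF1",
      "rs2390760", "METTL21C",
      "rs1801133", "MTHFR",
      "rs327575", "MTRR",
      "rs7703033", "MTRR",
      "rs4790881", "SMG6",
      "rs10497520", "TTN"
    ),
    PT_IK240 = tibble::tribble(
      ~snp_id, ~gene,
      "rs746434", "ACVR1B",
      "rs10783485", "ACVR1B",
      "rs12721026", "APOA1",
      "rs1016732", "ATP1A2",
      "rs3797297", "FST",
      "rs2251375", "H19",
      "rs2919358", "KBTBD13",
      "rs1137101", "LEPR",
      "rs3762546", "MSTN",
      "rs1476413", "MTHFR",
      "rs1009592", "MTHFR",
      "rs1805087", "MTR",
      "rs10475399", "MTRR",
      "rs326123", "MTRR",
      "rs9313211", "MTRR",
      "rs4950877", "MYOG",
      "rs4253778", "PPARA",
      "rs142196418", "RIMS1"
    )
  )
  if (is.null(phenotype)) {
    return(sets)
  }
  sets[[match.arg(phenotype, phenotype_names())]]
}

#' Default SNP identifiers for a simulated candidate panel
#'
#' Returns `n` unique SNP ids: first the union of the bundled reference sets
#' (see [gps_snp_sets()]), padded with synthetic rs-style identifiers. This
#' guarantees the reference causal SNPs are present in default panels.
#'
#' @param n Panel size.
#' @return Character vector of length `n`.
#' @export
muscle_snp_panel <- function(n = 224) {
  known <- unique(purrr::list_rbind(gps_snp_sets())$snp_id)
  if (n <= length(known)) {
    return(known[seq_len(n)])
  }
  c(known, sprintf("rs90%04d", seq_len(n - length(known))))
}

# gene labels matching muscle_snp_panel() ids
panel_genes <- function(snp_ids) {
  known <- unique(purrr::list_rbind(gps_snp_sets()))
  known <- known[!duplicated(known$snp_id), ]
  gene <- known$gene[match(snp_ids, known$snp_id)]
  ifelse(is.na(gene), paste0("GENE", seq_along(snp_ids)), gene)
}
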