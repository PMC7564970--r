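# A genotype panel is a wide tibble: one row per SNP, metadata columns
# (snp_id, gene, n_refs, allele_a, allele_b) followed by one call column per
# participant. Calls are unordered two-letter strings ("AG"), NA = no call.

geno_meta_cols <- function() c("snp_id", "gene", "n_refs", "allele_a", "allele_b")

#' Participant identifiers of a genotype panel
#'
#' @param genotypes A genotype panel tibble (see [simulate_genotypes()]).
#' @return Character vector of participant ids (the non-metadata columns).
#' @export
geno_participants <- function(genotypes) {
  setdiff(names(genotypes), geno_meta_cols())
}

#' Extract the call matrix of a genotype panel
#'
#' @inheritParams geno_participants
#' @return Character matrix (SNP x participant) of genotype calls,
#'   rownames = SNP ids, NA for missing calls.
#' @export
geno_calls <- function(genotypes) {
  validate_genotypes(genotypes)
  ids <- geno_participants(genotypes)
  m <- as.matrix(genotypes[, ids, drop = FALSE])
  rownames(m) <- genotypes$snp_id
  m
}

validate_genotypes <- function(genotypes) {
  if (!is.data.frame(genotypes) || nrow(genotypes) == 0) {
    abort("`genotypes` must be a non-empty genotype panel tibble.")
  }
  missing_cols <- setdiff(geno_meta_cols(), names(genotypes))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`genotypes` lacks metadata column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(genotypes$snp_id)) {
    abort("SNP ids in `genotypes` must be unique.")
  }
  if (length(geno_participants(genotypes)) == 0) {
    abort("`genotypes` has no participant call columns.")
  }
  invisible(genotypes)
}

#' Empirical minor alleles and allele frequencies
#'
#' The minor allele of each SNP is determined from the non-missing calls;
#' when both alleles are equally frequent (or the SNP has no calls),
#' `allele_b` is taken as minor.
#'
#' @inheritParams geno_participants
#' @return Tibble with `snp_id`, `allele_major`, `allele_minor`, `maf`.
#' @export
minor_alleles <- function(genotypes) {
  calls <- geno_calls(genotypes)
  n_b <- count_allele(calls, genotypes$allele_b)
  n_obs <- rowSums(!is.na(calls))
  freq_b <- ifelse(n_obs > 0, rowSums(n_b, na.rm = TRUE) / (2 * n_obs), 0.5)
  b_minor <- unname(freq_b <= 0.5)
  tibble::tibble(
    snp_id = genotypes$snp_id,
    allele_major = ifelse(b_minor, genotypes$allele_a, genotypes$allele_b),
    allele_minor = ifelse(b_minor, genotypes$allele_b, genotypes$allele_a),
    maf = unname(pmin(freq_b, 1 - freq_b))
  )
}

# count occurrences of per-SNP allele letters in a call matrix
count_allele <- function(calls, alleles) {
  out <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  for (i in seq_len(nrow(calls))) {
    out[i, ] <- stringr::str_count(calls[i, ], stringr::fixed(alleles[i]))
  }
  out
}

#' Allele-dosage matrix of a genotype panel
#'
#' Counts copies of a chosen allele per SNP and participant.
#'
#' @inheritParams geno_participants
#' @param alleles Either `"minor"` (default; empirical minor allele per SNP),
#'   or a character vector of allele letters, one per SNP in panel order (or
#'   named by SNP id).
#' @return Numeric matrix (SNP x participant) with entries 0/1/2 and NA for
#'   missing calls.
#' @export
geno_dosage <- function(genotypes, alleles = "minor") {
  calls <- geno_calls(genotypes)
  if (identical(alleles, "minor")) {
    alleles <- minor_alleles(genotypes)$allele_minor
  } else if (!is.null(names(alleles))) {
    alleles <- unname(alleles[genotypes$snp_id])
  }
  if (length(alleles) != nrow(genotypes)) {
    abort("`alleles` must supply one allele per SNP.")
  }
  ok <- is.na(alleles) | alleles == genotypes$allele_a |
    alleles == genotypes$allele_b
  if (!all(ok)) {
    abort(paste0(
      "Allele letter not in the SNP's allele pair for: ",
      paste(genotypes$snp_id[!ok], collapse = ", ")
    ))
  }
  count_allele(calls, alleles)
}

#' Per-SNP call rates
#'
#' @inheritParams geno_participants
#' @return Tibble with `snp_id`, `n_called`, `call_rate`.
#' @export
call_rates <- function(genotypes) {
  calls <- geno_calls(genotypes)
  tibble::tibble(
    snp_id = genotypes$snp_id,
    n_called = rowSums(!is.na(calls)),
    call_rate = rowSums(!is.na(calls)) / ncol(calls)
  )
}
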