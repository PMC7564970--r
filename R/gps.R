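#' Orient selected SNPs to their favourable alleles
#'
#' The favourable (predisposing) allele of a selected SNP is the allele
#' whose count is associated with less decrease, i.e. an algebraically
#' larger change. Selection coefficients arrive on the minor-allele dosage
#' scale: a positive coefficient makes the minor allele favourable; a
#' negative one makes the major allele favourable and the stored
#' coefficient is sign-flipped (counting the other allele reverses the
#' dosage).
#'
#' @param selection Tibble from [stepwise_select()] (`snp_id`, `estimate`,
#'   `p_value`, ...).
#' @param genotypes Genotype panel containing the selected SNPs.
#' @return Tibble of GPS entries: `snp_id`, `favourable_allele`, `weight`
#'   (always 1), `coefficient` (positive, % change per favourable allele),
#'   `p_value`.
#' @export
orient_favourable <- function(selection, genotypes) {
  if (any(selection$estimate == 0)) {
    abort("Cannot orient a SNP with a zero selection coefficient.")
  }
  ma <- minor_alleles(genotypes)
  ma <- ma[match(selection$snp_id, ma$snp_id), ]
  if (anyNA(ma$snp_id)) {
    abort("Selected SNP(s) absent from the genotype panel.")
  }
  minor_fav <- selection$estimate > 0
  tibble::tibble(
    snp_id = selection$snp_id,
    favourable_allele = ifelse(minor_fav, ma$allele_minor, ma$allele_major),
    weight = 1,
    coefficient = abs(selection$estimate),
    p_value = selection$p_value
  )
}

#' Score a genotype call against a favourable allele
#'
#' Counts copies of the favourable allele in an unphased biallelic call:
#' homozygous favourable scores 2, heterozygous 1, homozygous unfavourable
#' 0 (for favourable allele G of a C/G SNP: GG = 2, CG = 1, CC = 0).
#'
#' @param call Character vector of two-letter genotype calls (NA = missing).
#' @param favourable Favourable allele letter(s), length 1 or matching
#'   `call`.
#' @return Integer vector of scores in 0..2 (NA for missing calls).
#' @examples
#' genotype_score(c("GG", "CG", "CC"), "G")
#' @export
genotype_score <- function(call, favourable) {
  if (any(!nchar(favourable) == 1, na.rm = TRUE)) {
    abort("`favourable` must be single allele letters.")
  }
  bad <- !is.na(call) & nchar(call) != 2
  if (any(bad)) abort("Calls must be two-letter genotype strings.")
  if (length(favourable) == 1) {
    return(as.integer(stringr::str_count(call, stringr::fixed(favourable))))
  }
  favourable <- rep_len(favourable, length(call))
  as.integer(purrr::map2_int(
    call, favourable,
    ~ if (is.na(.x)) NA_integer_ else
      as.integer(stringr::str_count(.x, stringr::fixed(.y)))
  ))
}

#' Compute per-participant genetic predisposition scores
#'
#' Sums the favourable-allele genotype scores of a GPS model's SNPs for
#' every participant in the panel. Missing calls are handled per
#' `missing_policy`: `"mean-impute"` (default) substitutes the mean score
#' of the non-missing participants for that SNP; `"complete-case"` yields
#' `NA` for participants missing any model SNP.
#'
#' @param genotypes Genotype panel containing all model SNPs.
#' @param model A `gps_model` from [build_gps()], or any tibble with
#'   `snp_id`, `favourable_allele` and `weight` columns.
#' @param missing_policy How to treat missing calls.
#' @return Tibble with `id`, `gps` and `n_imputed` (SNPs imputed per
#'   participant).
#' @export
compute_gps <- function(genotypes, model,
                        missing_policy = c("mean-impute", "complete-case")) {
  missing_policy <- match.arg(missing_policy)
  entries <- if (inherits(model, "gps_model")) model$entries else model
  if (nrow(entries) == 0) abort("The GPS model has no entries.")
  missing_snps <- setdiff(entries$snp_id, genotypes$snp_id)
  if (length(missing_snps) > 0) {
    abort(paste0(
      "Model SNP(s) absent from the panel: ",
      paste(missing_snps, collapse = ", ")
    ))
  }
  geno <- genotypes[match(entries$snp_id, genotypes$snp_id), ]
  scores <- geno_dosage(
    geno, setNames(entries$favourable_allele, entries$snp_id)
  )
  n_imputed <- colSums(is.na(scores))
  if (missing_policy == "mean-impute") {
    for (i in seq_len(nrow(scores))) {
      mi <- is.na(scores[i, ])
      if (any(mi)) scores[i, mi] <- mean(scores[i, !mi])
    }
  }
  tibble::tibble(
    id = colnames(scores),
    gps = as.numeric(crossprod(scores, entries$weight)),
    n_imputed = as.integer(n_imputed)
  )
}

#' Build a phenotype-driven GPS model
#'
#' Pools all participants (both training groups), regresses the phenotype's
#' relative change on the panel's minor-allele dosages by stepwise
#' selection ([stepwise_select()]), orients each selected SNP to its
#' favourable allele, and returns the resulting equal-weight GPS model.
#'
#' @param phenotypes Phenotype table (`id`, `phenotype`, `relative_change`).
#' @param genotypes QC-passed genotype panel.
#' @param phenotype Which phenotype's change drives the selection.
#' @param config A [stepwise_config()].
#' @return A `gps_model`: list with `phenotype`, `entries` (tibble
#'   `snp_id`, `favourable_allele`, `weight`, `coefficient`, `p_value`),
#'   `config`, `n_candidates`, `n_used` and the selection `log`.
#'   [tidy()] returns the entries.
#' @export
build_gps <- function(phenotypes, genotypes, phenotype,
                      config = stepwise_config()) {
  validate_genotypes(genotypes)
  phenotype <- match.arg(phenotype, phenotype_names())
  ph <- phenotypes[phenotypes$phenotype == phenotype, ]
  if (nrow(ph) == 0) abort(paste0("No rows for phenotype ", phenotype, "."))
  ids <- intersect(ph$id, geno_participants(genotypes))
  ph <- ph[match(ids, ph$id), ]
  if (sum(!is.na(ph$relative_change)) < 10) {
    abort("Need at least 10 participants with non-missing change.")
  }
  dos <- geno_dosage(genotypes)[, ids, drop = FALSE]
  selection <- stepwise_select(ph$relative_change, dos, config)
  entries <- if (nrow(selection) == 0) {
    tibble::tibble(
      snp_id = character(), favourable_allele = character(),
      weight = numeric(), coefficient = numeric(), p_value = numeric()
    )
  } else {
    orient_favourable(selection, genotypes)
  }
  structure(
    list(
      phenotype = phenotype,
      entries = entries,
      config = config,
      n_candidates = nrow(genotypes),
      n_used = attr(selection, "n_used"),
      log = attr(selection, "log")
    ),
    class = "gps_model"
  )
}

#' @export
print.gps_model <- function(x, ...) {
  cat("<gps_model>", x$phenotype, "\n")
  cat(sprintf(
    "  %d SNP(s) selected from %d candidates (entry %g / stay %g), n = %d\n",
    nrow(x$entries), x$n_candidates, x$config$entry, x$config$stay, x$n_used
  ))
  if (nrow(x$entries) > 0) print(x$entries)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gps_model <- function(x, ...) {
  x$entries
}

#' @exportS3Method generics::glance
glance.gps_model <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotype,
    n_snps = nrow(x$entries),
    n_candidates = x$n_candidates,
    n_used = x$n_used,
    entry = x$config$entry,
    stay = x$config$stay
  )
}
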