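#' Write a genotype panel as minimal VCF v4.2
#'
#' Emits one record per SNP on a synthetic chromosome (`CHROM = 1`,
#' `POS` = panel position) with `REF = allele_a`, `ALT = allele_b`, a `GT`
#' FORMAT field (`./.` for missing calls) and gene / reference-count
#' metadata in INFO (`GENE=`, `NREFS=`).
#'
#' @param genotypes Genotype panel tibble.
#' @param path Output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  validate_genotypes(genotypes)
  ids <- geno_participants(genotypes)
  dos <- geno_dosage(
    genotypes, setNames(genotypes$allele_b, genotypes$snp_id)
  )
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1], nrow(dos), ncol(dos))
  gt[is.na(dos)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste0("##INFO=<ID=NREFS,Number=1,Type=Integer,",
           "Description=\"Supporting publications\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(genotypes)), function(i) {
    paste(c(
      "1", i, genotypes$snp_id[i], genotypes$allele_a[i],
      genotypes$allele_b[i], ".", "PASS",
      sprintf("GENE=%s;NREFS=%d", genotypes$gene[i], genotypes$n_refs[i]),
      "GT", gt[i, ]
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Reads a VCF (via vcfR), converting GT fields back into two-letter calls
#' using each record's REF/ALT alleles. `GENE=` and `NREFS=` INFO keys are
#' recovered when present.
#'
#' @param path VCF file path.
#' @return A genotype panel tibble (see [geno_calls()]).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v, getINFO = TRUE)))
  gt <- vcfR::extract.gt(v, element = "GT")
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  gene <- stringr::str_match(info, "GENE=([^;]+)")[, 2]
  nrefs <- suppressWarnings(
    as.integer(stringr::str_match(info, "NREFS=([0-9]+)")[, 2])
  )
  calls <- matrix(NA_character_, nrow(fix), ncol(gt))
  for (i in seq_len(nrow(fix))) {
    a <- fix$REF[i]
    b <- fix$ALT[i]
    het <- paste(sort(c(a, b)), collapse = "")
    g <- gsub("\\|", "/", gt[i, ])
    n_alt <- dplyr::case_match(
      g, "0/0" ~ 0L, c("0/1", "1/0") ~ 1L, "1/1" ~ 2L, .default = NA_integer_
    )
    calls[i, ] <- c(paste0(a, a), het, paste0(b, b))[n_alt + 1L]
  }
  colnames(calls) <- colnames(gt)
  dplyr::bind_cols(
    tibble::tibble(
      snp_id = fix$ID,
      gene = gene,
      n_refs = dplyr::coalesce(nrefs, 0L),
      allele_a = fix$REF,
      allele_b = fix$ALT
    ),
    tibble::as_tibble(calls)
  )
}

#' Write / read a genotype panel as wide CSV
#'
#' The wide CSV mirrors the in-memory panel: one row per SNP, metadata
#' columns then one call column per participant (calls like `"AG"`, empty
#' for missing).
#'
#' @inheritParams write_genotypes_vcf
#' @return `path` (writer) or a genotype panel tibble (reader).
#' @export
write_genotypes_csv <- function(genotypes, path) {
  validate_genotypes(genotypes)
  readr::write_csv(genotypes, path, na = "")
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path) {
  out <- readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      n_refs = readr::col_integer(),
      .default = readr::col_character()
    )
  )
  validate_genotypes(out)
  out
}

#' Serialize / restore a GPS model as JSON
#'
#' @param model A `gps_model` from [build_gps()].
#' @param path JSON file path.
#' @return `path` (writer) or a `gps_model` (reader).
#' @export
write_gps_model <- function(model, path) {
  if (!inherits(model, "gps_model")) abort("`model` must be a gps_model.")
  jsonlite::write_json(
    list(
      phenotype = model$phenotype,
      entries = model$entries,
      entry = model$config$entry %||% NA,
      stay = model$config$stay %||% NA,
      n_candidates = model$n_candidates,
      n_used = model$n_used
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_gps_model
#' @export
read_gps_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- if (!is.null(x$entry) && !is.na(x$entry)) {
    stepwise_config(entry = x$entry, stay = x$stay)
  }
  structure(
    list(
      phenotype = x$phenotype,
      entries = tibble::as_tibble(x$entries),
      config = cfg,
      n_candidates = x$n_candidates,
      n_used = x$n_used,
      log = character()
    ),
    class = "gps_model"
  )
}
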