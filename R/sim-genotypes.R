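#' Simulate a candidate SNP genotype panel
#'
#' Generates unphased biallelic genotype calls under Hardy-Weinberg
#' equilibrium at per-SNP minor allele frequencies drawn uniformly from the
#' configured range. Linkage-disequilibrium blocks are produced by copying
#' the block seed SNP's haplotype allele indicators with retention
#' probability equal to the block's correlation target (a retained indicator
#' is copied, otherwise redrawn at the block allele frequency), which yields
#' pairwise dosage correlations close to the target while keeping marginal
#' frequencies and HWE intact. Designated low-call SNPs have their call rate
#' forced strictly below 0.80; designated monomorphic SNPs carry one
#' genotype in every participant. All other missingness is
#' missing-completely-at-random at `config$missing_rate`.
#'
#' Structural roles are assigned deterministically by panel position: LD
#' blocks occupy the final positions, preceded by the monomorphic and then
#' the low-call SNPs, so the leading SNPs (including the bundled reference
#' sets from [muscle_snp_panel()]) are clean independent markers.
#'
#' @param config A [sim_config()].
#' @param snp_ids Optional character vector of `config$n_snps` SNP ids;
#'   defaults to [muscle_snp_panel()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A genotype panel tibble (see [geno_calls()]) with a
#'   `"structure"` attribute tibble (`snp_id`, `role`, `block`, `true_maf`).
#' @export
simulate_genotypes <- function(config = sim_config(), snp_ids = NULL,
                               seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_participants
  m <- config$n_snps
  if (n == 0) abort("Cannot simulate genotypes for an empty cohort.")
  if (is.null(snp_ids)) snp_ids <- muscle_snp_panel(m)
  if (length(snp_ids) != m || anyDuplicated(snp_ids)) {
    abort("`snp_ids` must supply `n_snps` unique identifiers.")
  }

  block_sizes <- vapply(config$ld_blocks, function(b) b[1], numeric(1))
  block_r <- vapply(config$ld_blocks, function(b) b[2], numeric(1))
  n_block <- sum(block_sizes)
  role <- rep("clean", m)
  block_id <- rep(NA_integer_, m)
  if (n_block > 0) {
    idx <- (m - n_block + 1):m
    role[idx] <- "block"
    block_id[idx] <- rep(seq_along(block_sizes), block_sizes)
  }
  if (config$monomorphic_snps > 0) {
    idx <- (m - n_block - config$monomorphic_snps + 1):(m - n_block)
    role[idx] <- "monomorphic"
  }
  if (config$low_call_snps > 0) {
    idx <- (m - n_block - config$monomorphic_snps - config$low_call_snps + 1):
      (m - n_block - config$monomorphic_snps)
    role[idx] <- "low_call"
  }

  with_optional_seed(seed, function() {
    pairs <- t(vapply(
      seq_len(m),
      function(i) sample(c("A", "C", "G", "T"), 2),
      character(2)
    ))
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    # block members share the seed SNP's MAF so indicator copying preserves
    # the marginal frequency
    for (b in seq_along(block_sizes)) {
      members <- which(!is.na(block_id) & block_id == b)
      maf[members] <- maf[members[1]]
    }

    dosage <- matrix(NA_real_, m, n)
    seed_h <- vector("list", length(block_sizes))
    for (i in seq_len(m)) {
      if (role[i] == "monomorphic") {
        dosage[i, ] <- 0
        next
      }
      if (role[i] == "block") {
        b <- block_id[i]
        members <- which(!is.na(block_id) & block_id == b)
        if (i == members[1]) {
          seed_h[[b]] <- cbind(
            rbinom(n, 1, maf[i]),
            rbinom(n, 1, maf[i])
          )
          h <- seed_h[[b]]
        } else {
          keep1 <- rbinom(n, 1, block_r[b]) == 1
          keep2 <- rbinom(n, 1, block_r[b]) == 1
          h <- cbind(
            ifelse(keep1, seed_h[[b]][, 1], rbinom(n, 1, maf[i])),
            ifelse(keep2, seed_h[[b]][, 2], rbinom(n, 1, maf[i]))
          )
        }
        dosage[i, ] <- h[, 1] + h[, 2]
        next
      }
      dosage[i, ] <- rbinom(n, 2, maf[i])
    }

    calls <- matrix(NA_character_, m, n)
    for (i in seq_len(m)) {
      a <- pairs[i, 1]
      b <- pairs[i, 2]
      het <- paste(sort(c(a, b)), collapse = "")
      calls[i, ] <- c(paste0(a, a), het, paste0(b, b))[dosage[i, ] + 1]
    }

    if (config$missing_rate > 0) {
      calls[matrix(runif(m * n) < config$missing_rate, m, n)] <- NA
    }
    low <- which(role == "low_call")
    n_miss <- max(floor(0.25 * n), floor(0.2 * n) + 1)
    for (i in low) {
      calls[i, sample(n, min(n_miss, n))] <- NA
    }

    participant_ids <- sprintf("P%03d", seq_len(n))
    colnames(calls) <- participant_ids
    out <- dplyr::bind_cols(
      tibble::tibble(
        snp_id = snp_ids,
        gene = panel_genes(snp_ids),
        n_refs = rpois(m, 2),
        allele_a = pairs[, 1],
        allele_b = pairs[, 2]
      ),
      tibble::as_tibble(calls)
    )
    attr(out, "structure") <- tibble::tibble(
      snp_id = snp_ids, role = role, block = block_id, true_maf = maf
    )
    out
  })
}
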