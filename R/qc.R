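#' Call-rate (detection) filter
#'
#' Removes SNPs whose fraction of non-missing calls is strictly below the
#' detection threshold (a SNP called in exactly 80% of participants is kept
#' at the default threshold).
#'
#' @param genotypes Genotype panel tibble.
#' @param threshold Detection threshold in (0, 1], default 0.80.
#' @return List with `kept` (panel tibble, input order preserved) and
#'   `removed` (character vector of SNP ids).
#' @export
detection_filter <- function(genotypes, threshold = 0.80) {
  validate_genotypes(genotypes)
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  cr <- call_rates(genotypes)
  low <- cr$call_rate < threshold
  list(
    kept = genotypes[!low, , drop = FALSE],
    removed = genotypes$snp_id[low]
  )
}

#' Monomorphic filter
#'
#' Removes SNPs whose non-missing calls are all one genotype. SNPs with no
#' non-missing calls at all are also removed here (they cannot enter any
#' downstream stage) and listed in the `all_missing` attribute.
#'
#' @inheritParams detection_filter
#' @return List with `kept` and `removed` as in [detection_filter()].
#' @export
monomorphic_filter <- function(genotypes) {
  validate_genotypes(genotypes)
  calls <- geno_calls(genotypes)
  n_distinct <- apply(calls, 1, function(x) length(unique(x[!is.na(x)])))
  mono <- n_distinct <= 1
  out <- list(
    kept = genotypes[!mono, , drop = FALSE],
    removed = genotypes$snp_id[mono]
  )
  attr(out, "all_missing") <- genotypes$snp_id[n_distinct == 0]
  out
}

# pairwise |r| of minor-allele dosages with joint-observation counts
ld_edges <- function(genotypes, r_threshold) {
  d <- t(geno_dosage(genotypes)) # participant x SNP
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  n_joint <- crossprod(!is.na(d))
  ut <- upper.tri(r)
  idx <- which(ut & !is.na(r) & abs(r) > r_threshold, arr.ind = TRUE)
  sparse_pairs <- which(ut & n_joint < 3, arr.ind = TRUE)
  edges <- tibble::tibble(
    snp_a = genotypes$snp_id[idx[, 1]],
    snp_b = genotypes$snp_id[idx[, 2]],
    r = r[idx],
    n_joint = n_joint[idx]
  )
  # pairs with < 3 joint observations never form an edge
  edges <- edges[edges$n_joint >= 3, , drop = FALSE]
  attr(edges, "sparse_pairs") <- nrow(sparse_pairs)
  edges
}

#' Linkage-disequilibrium subgrouping
#'
#' Builds a graph with an edge between two SNPs whenever the absolute
#' Pearson correlation of their minor-allele dosages, over jointly
#' non-missing participants, exceeds `r_threshold` (pairs with fewer than 3
#' joint observations never form an edge). Subgroups are the connected
#' components of size at least 2; singleton SNPs are not subgroups.
#'
#' @inheritParams detection_filter
#' @param r_threshold Absolute correlation threshold, default 0.8.
#' @return List of character vectors of SNP ids (one per subgroup), ordered
#'   by first panel appearance, with the edge table in attribute `"edges"`.
#' @export
ld_group <- function(genotypes, r_threshold = 0.8) {
  validate_genotypes(genotypes)
  if (nrow(genotypes) < 2) abort("LD grouping needs at least 2 SNPs.")
  edges <- ld_edges(genotypes, r_threshold)
  if (nrow(edges) == 0) {
    out <- list()
    attr(out, "edges") <- edges
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("snp_a", "snp_b")],
    directed = FALSE,
    vertices = genotypes$snp_id
  )
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  member <- member[lengths(member) >= 2]
  # order subgroups, and SNPs within them, by panel position
  pos <- match(genotypes$snp_id, genotypes$snp_id)
  names(pos) <- genotypes$snp_id
  member <- lapply(member, function(s) s[order(pos[s])])
  member <- member[order(vapply(member, function(s) pos[s[1]], numeric(1)))]
  out <- unname(member)
  attr(out, "edges") <- edges
  out
}

#' Representative SNP of each LD subgroup
#'
#' Within each subgroup the SNP with the largest number of correlated
#' subgroup members (edge degree) is selected; ties are broken by the
#' larger number of supporting publications (`n_refs`), remaining ties by
#' lexicographically smaller rs identifier.
#'
#' @inheritParams ld_group
#' @param subgroups Subgroup list from [ld_group()].
#' @return Character vector with one representative SNP id per subgroup.
#' @export
select_representatives <- function(genotypes, subgroups, r_threshold = 0.8) {
  if (length(subgroups) == 0) {
    return(character())
  }
  edges <- attr(subgroups, "edges") %||% ld_edges(genotypes, r_threshold)
  vapply(subgroups, function(members) {
    in_group <- edges$snp_a %in% members & edges$snp_b %in% members
    deg <- table(factor(
      c(edges$snp_a[in_group], edges$snp_b[in_group]),
      levels = members
    ))
    refs <- genotypes$n_refs[match(members, genotypes$snp_id)]
    ord <- order(-as.numeric(deg), -refs, members)
    members[ord[1]]
  }, character(1))
}

#' Full genotype panel quality control
#'
#' Applies the three-stage panel reduction in fixed order: detection filter
#' (call rate below `detection_threshold`), monomorphic filter, then LD
#' subgrouping at `ld_r` with one representative kept per subgroup. The
#' stage order matters: monomorphic SNPs have undefined correlations and
#' must leave before LD analysis.
#'
#' @inheritParams detection_filter
#' @param detection_threshold Call-rate threshold, default 0.80.
#' @param ld_r Absolute dosage-correlation threshold, default 0.8.
#' @return A `qc_report`: list with `n_input`, `kept` (SNP ids),
#'   `removed_low_detection`, `removed_monomorphic`, `removed_ld`,
#'   `subgroups` (list of id vectors), `representatives`, and `params`.
#'   [tidy()] gives a per-SNP status table, [glance()] the stage counts.
#' @export
run_qc <- function(genotypes, detection_threshold = 0.80, ld_r = 0.8) {
  validate_genotypes(genotypes)
  det <- detection_filter(genotypes, detection_threshold)
  mono <- monomorphic_filter(det$kept)
  if (nrow(mono$kept) >= 2) {
    subgroups <- ld_group(mono$kept, ld_r)
    reps <- select_representatives(mono$kept, subgroups, ld_r)
  } else {
    subgroups <- list()
    reps <- character()
  }
  removed_ld <- setdiff(unlist(subgroups), reps)
  kept <- setdiff(mono$kept$snp_id, removed_ld)
  report <- structure(
    list(
      n_input = nrow(genotypes),
      kept = kept,
      removed_low_detection = det$removed,
      removed_monomorphic = mono$removed,
      removed_ld = removed_ld,
      subgroups = unname(lapply(subgroups, identity)),
      representatives = reps,
      params = c(detection_threshold = detection_threshold, ld_r = ld_r)
    ),
    class = "qc_report"
  )
  stopifnot(
    length(report$kept) + length(report$removed_low_detection) +
      length(report$removed_monomorphic) + length(report$removed_ld) ==
      report$n_input,
    all(report$representatives %in% report$kept)
  )
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  input SNPs:        %d\n", x$n_input))
  cat(sprintf("  low detection:     %d removed\n",
              length(x$removed_low_detection)))
  cat(sprintf("  monomorphic:       %d removed\n",
              length(x$removed_monomorphic)))
  cat(sprintf("  high-LD subgroups: %d (%d SNPs, %d removed)\n",
              length(x$subgroups), length(unlist(x$subgroups)),
              length(x$removed_ld)))
  cat(sprintf("  kept:              %d\n", length(x$kept)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) {
  status <- c(
    setNames(rep("kept", length(x$kept)), x$kept),
    setNames(
      rep("removed_low_detection", length(x$removed_low_detection)),
      x$removed_low_detection
    ),
    setNames(
      rep("removed_monomorphic", length(x$removed_monomorphic)),
      x$removed_monomorphic
    ),
    setNames(rep("removed_ld", length(x$removed_ld)), x$removed_ld)
  )
  sub_of <- rep(NA_integer_, length(status))
  names(sub_of) <- names(status)
  for (i in seq_along(x$subgroups)) {
    sub_of[x$subgroups[[i]]] <- i
  }
  ids <- names(status)
  tibble::tibble(
    snp_id = ids,
    status = unname(status),
    subgroup = unname(sub_of[ids]),
    representative = ids %in% x$representatives
  )
}

#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_low_detection = length(x$removed_low_detection),
    n_monomorphic = length(x$removed_monomorphic),
    n_subgroups = length(x$subgroups),
    n_in_ld = length(unlist(x$subgroups)),
    n_removed_ld = length(x$removed_ld),
    n_kept = length(x$kept)
  )
}
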