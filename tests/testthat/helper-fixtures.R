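# Hand-built genotype panels and independent oracles used across tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build a genotype panel from a dosage matrix (SNP x participant, entries
# 0/1/2/NA). Each SNP gets alleles (a = major-designated, b = minor) and
# calls are two-letter strings; dosage counts allele b.
panel_from_dosage <- function(dosage, allele_a = "A", allele_b = "G",
                              snp_ids = NULL, n_refs = NULL) {
  m <- nrow(dosage)
  n <- ncol(dosage)
  allele_a <- rep_len(allele_a, m)
  allele_b <- rep_len(allele_b, m)
  snp_ids <- snp_ids %||% sprintf("rs%04d", seq_len(m))
  n_refs <- n_refs %||% rep(1L, m)
  calls <- matrix(NA_character_, m, n)
  for (i in seq_len(m)) {
    het <- paste(sort(c(allele_a[i], allele_b[i])), collapse = "")
    lv <- c(paste0(allele_a[i], allele_a[i]), het,
            paste0(allele_b[i], allele_b[i]))
    calls[i, ] <- lv[dosage[i, ] + 1]
  }
  ids <- sprintf("P%03d", seq_len(n))
  colnames(calls) <- ids
  dplyr::bind_cols(
    tibble::tibble(
      snp_id = snp_ids, gene = paste0("G", seq_len(m)),
      n_refs = as.integer(n_refs),
      allele_a = allele_a, allele_b = allele_b
    ),
    tibble::as_tibble(calls)
  )
}

# Minimal participant table compatible with the association helpers.
fake_participants <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    group = rep(c("FIT", "WBV"), length.out = n, each = ceiling(n / 2)),
    sex = rep_len(c("F", "M"), n),
    sex_code = as.numeric(rep_len(c("F", "M"), n) == "M"),
    age = runif(n, 61, 81),
    height_cm = rnorm(n, 167, 8),
    body_mass_post = rnorm(n, 74, 10),
    body_mass_follow = rnorm(n, 74, 10),
    bmi_post = rnorm(n, 26.5, 3.5),
    bmi_follow = rnorm(n, 26.6, 3.5),
    resistance_post = rnorm(n, 520, 60),
    resistance_follow = rnorm(n, 520, 60)
  ))
}

# Independent stepwise oracle: explicit per-candidate partial-F tests with
# plain lm() fits, same entry/stay/oscillation contract, written without
# reference to the package internals.
oracle_stepwise <- function(change, dosages, entry = 0.1, stay = 0.05) {
  D <- as.data.frame(t(dosages))
  snps <- colnames(D)
  inc <- character()
  repeat {
    cand <- setdiff(snps, inc)
    if (length(cand) == 0) break
    pvals <- sapply(cand, function(s) {
      d <- cbind(y = change, D[, c(inc, s), drop = FALSE])
      d <- d[stats::complete.cases(d), ]
      full <- lm(y ~ ., data = d)
      if (anyNA(coef(full))) return(NA_real_)
      red <- lm(
        as.formula(paste("y ~", if (length(inc)) paste(inc, collapse = "+")
                         else "1")),
        data = d
      )
      anova(red, full)[2, "Pr(>F)"]
    })
    if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= entry) break
    best <- cand[which.min(pvals)]
    inc <- c(inc, best)
    osc <- FALSE
    repeat {
      d <- cbind(y = change, D[, inc, drop = FALSE])
      d <- d[stats::complete.cases(d), ]
      fit <- lm(y ~ ., data = d)
      p_in <- summary(fit)$coefficients[-1, 4]
      names(p_in) <- inc
      if (max(p_in) <= stay) break
      worst <- inc[which.max(p_in)]
      inc <- setdiff(inc, worst)
      if (identical(worst, best)) {
        osc <- TRUE
        break
      }
      if (length(inc) == 0) break
    }
    if (osc) break
  }
  inc
}

# Squared semi-partial correlation via residual-on-residual regression.
oracle_semipartial_r2 <- function(y, x, others) {
  u <- if (length(others) == 0) {
    x - mean(x)
  } else {
    resid(lm(x ~ ., data = as.data.frame(others)))
  }
  stats::cor(y, u)^2
}

# 1-df Hardy-Weinberg chi-square p-value on a dosage vector.
hwe_chisq_p <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  n <- length(dosage)
  p <- mean(dosage) / 2
  obs <- c(sum(dosage == 0), sum(dosage == 1), sum(dosage == 2))
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  keep <- exp > 0
  stat <- sum((obs[keep] - exp[keep])^2 / exp[keep])
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Connected components via union-find over all-pairs correlations.
oracle_ld_components <- function(dosages, r_threshold = 0.8) {
  m <- nrow(dosages)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ok <- !is.na(dosages[i, ]) & !is.na(dosages[j, ])
      if (sum(ok) < 3) next
      r <- suppressWarnings(stats::cor(dosages[i, ok], dosages[j, ok]))
      if (!is.na(r) && abs(r) > r_threshold) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(m), find, numeric(1))
  groups <- split(seq_len(m), comp)
  unname(groups[lengths(groups) >= 2])
}
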