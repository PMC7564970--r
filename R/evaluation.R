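# in-sample GPS partial r2 of the full pipeline (0 when selection is empty)
pipeline_partial_r2 <- function(phenotypes, genotypes, participants,
                                phenotype, config, include_post) {
  model <- build_gps(phenotypes, genotypes, phenotype, config)
  if (nrow(model$entries) == 0) {
    return(list(partial_r2 = 0, n_snps = 0L, model = model))
  }
  res <- run_association(model, genotypes, phenotypes, participants,
                         include_post = include_post)
  list(
    partial_r2 = res$glm$terms$partial_r2[res$glm$terms$term == "gps"],
    n_snps = nrow(model$entries),
    model = model
  )
}

#' Cross-validated out-of-fold variance explained
#'
#' Repeats the entire data-driven pipeline (stepwise SNP selection,
#' favourable-allele orientation, GPS construction, GLM fit) inside each
#' training fold only, then predicts the held-out participants' changes
#' from their GPS and covariates. Because selection is refit per fold, the
#' out-of-fold R-squared is an honest estimate of predictive value, free of
#' the in-sample selection optimism. Folds whose selection is empty predict
#' from covariates alone (logged).
#'
#' @param phenotypes Phenotype table.
#' @param genotypes QC-passed genotype panel.
#' @param participants Cohort tibble.
#' @param phenotype Phenotype driving the pipeline.
#' @param k_folds Number of folds (>= 2; `k_folds = n` gives leave-one-out).
#' @param config A [stepwise_config()].
#' @param include_post Post-training covariate flag (default: omitted for
#'   `"SMM"`).
#' @param seed Optional seed for the fold split.
#' @return List with `cv_r2` (pooled out-of-fold R-squared), `folds`
#'   (per-fold tibble: `fold`, `n_test`, `n_snps`), `predictions`
#'   (tibble `id`, `fold`, `observed`, `predicted`).
#' @export
cross_validate <- function(phenotypes, genotypes, participants, phenotype,
                           k_folds = 5, config = stepwise_config(),
                           include_post = NULL, seed = NULL) {
  phenotype <- match.arg(phenotype, phenotype_names())
  include_post <- include_post %||% (phenotype != "SMM")
  ph <- phenotypes[phenotypes$phenotype == phenotype, ]
  ids <- intersect(
    ph$id[!is.na(ph$relative_change)],
    intersect(participants$id, geno_participants(genotypes))
  )
  n <- length(ids)
  if (k_folds < 2) abort("`k_folds` must be at least 2.")
  if (k_folds < n && n < 2 * k_folds) {
    abort("Need at least 2 participants per fold.")
  }
  if (k_folds > n) abort("More folds than participants.")
  fold_of <- with_optional_seed(seed, function() {
    sample(rep_len(seq_len(k_folds), n))
  })
  meta_cols <- geno_meta_cols()
  preds <- vector("list", k_folds)
  fold_rows <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    train_ids <- ids[fold_of != f]
    test_ids <- ids[fold_of == f]
    g_train <- genotypes[, c(meta_cols, train_ids)]
    ph_train <- ph[ph$id %in% train_ids, ]
    model <- build_gps(ph_train, g_train, phenotype, config)
    part_train <- participants[participants$id %in% train_ids, ]
    part_test <- participants[participants$id %in% test_ids, ]
    ph_test <- ph[ph$id %in% test_ids, ]
    if (nrow(model$entries) > 0) {
      gps_train <- compute_gps(g_train, model)
      d_train <- assemble_association_data(phenotype, gps_train, ph_train,
                                           part_train)
      fit <- fit_gps_glm(d_train, include_post = include_post)$fit
      g_test <- genotypes[, c(meta_cols, test_ids)]
      gps_test <- compute_gps(g_test, model)
      d_test <- assemble_association_data(phenotype, gps_test, ph_test,
                                          part_test)
    } else {
      # empty selection: covariates-only fallback
      d_train <- assemble_association_data(
        phenotype, tibble::tibble(id = train_ids, gps = 0),
        ph_train, part_train
      )
      covars <- setdiff(glm_term_names(include_post), "gps")
      fit <- lm(
        as.formula(paste("change ~", paste(covars, collapse = " + "))),
        data = d_train
      )
      d_test <- assemble_association_data(
        phenotype, tibble::tibble(id = test_ids, gps = 0),
        ph_test, part_test
      )
    }
    pred <- predict(fit, newdata = d_test)
    preds[[f]] <- tibble::tibble(
      id = d_test$id, fold = f,
      observed = d_test$change, predicted = unname(pred)
    )
    fold_rows[[f]] <- tibble::tibble(
      fold = f, n_test = nrow(d_test), n_snps = nrow(model$entries)
    )
  }
  predictions <- purrr::list_rbind(preds)
  cv_r2 <- 1 -
    sum((predictions$observed - predictions$predicted)^2) /
      sum((predictions$observed - mean(predictions$observed))^2)
  list(
    cv_r2 = cv_r2,
    folds = purrr::list_rbind(fold_rows),
    predictions = predictions
  )
}

#' Permutation null distribution of in-sample GPS variance explained
#'
#' Permutes the change scores across participants, reruns the full
#' data-driven pipeline (selection included) per permutation, and returns
#' the null distribution of the in-sample GPS partial r-squared together
#' with the empirical p-value of the observed value. Because stepwise
#' selection over many candidates always captures some variance, this null
#' distribution sits well above zero — the in-sample optimism the
#' permutation quantifies.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of permutations (at least 100).
#' @return List with `observed` (in-sample GPS partial r2), `null`
#'   (numeric vector of length `n_perm`), `p_value` (empirical, with the
#'   +1 correction), `n_snps_observed`.
#' @export
permutation_null <- function(phenotypes, genotypes, participants, phenotype,
                             n_perm = 200, config = stepwise_config(),
                             include_post = NULL, seed = NULL) {
  phenotype <- match.arg(phenotype, phenotype_names())
  include_post <- include_post %||% (phenotype != "SMM")
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  obs <- pipeline_partial_r2(phenotypes, genotypes, participants,
                             phenotype, config, include_post)
  ph <- phenotypes[phenotypes$phenotype == phenotype, ]
  null <- with_optional_seed(seed, function() {
    vapply(seq_len(n_perm), function(i) {
      ph_perm <- ph
      perm <- sample(nrow(ph_perm))
      ph_perm$relative_change <- ph_perm$relative_change[perm]
      ph_perm$post_value <- ph_perm$post_value[perm]
      pipeline_partial_r2(ph_perm, genotypes, participants, phenotype,
                          config, include_post)$partial_r2
    }, numeric(1))
  })
  list(
    observed = obs$partial_r2,
    null = null,
    p_value = (1 + sum(null >= obs$partial_r2)) / (n_perm + 1),
    n_snps_observed = obs$n_snps
  )
}

#' Construct the oracle GPS model implied by an effect specification
#'
#' Builds the GPS model a perfectly informed analyst would use: the causal
#' SNPs of `spec` with favourable allele equal to the minor allele when the
#' per-allele effect is positive (the major allele otherwise), each with
#' weight 1. Used by recovery experiments to separate estimation error from
#' selection error.
#'
#' @param spec An [effect_spec()].
#' @param genotypes Genotype panel containing the causal SNPs.
#' @return A `gps_model`.
#' @export
oracle_gps_model <- function(spec, genotypes) {
  ma <- minor_alleles(genotypes)
  ma <- ma[match(spec$causal_snps, ma$snp_id), ]
  if (anyNA(ma$snp_id)) abort("Causal SNP(s) absent from the panel.")
  entries <- tibble::tibble(
    snp_id = spec$causal_snps,
    favourable_allele = ifelse(spec$beta >= 0, ma$allele_minor,
                               ma$allele_major),
    weight = 1,
    coefficient = abs(spec$beta),
    p_value = NA_real_
  )
  structure(
    list(
      phenotype = spec$phenotype, entries = entries,
      config = NULL, n_candidates = nrow(genotypes),
      n_used = NA_integer_, log = "oracle model from effect_spec"
    ),
    class = "gps_model"
  )
}

#' Parameter-recovery experiment over simulated cohorts
#'
#' For each scenario (an [effect_spec()], calibrated per cohort when its
#' target variance fraction is set), simulates `replicates` cohorts under
#' `config_sim`, runs the pipeline, and aggregates the recovered GPS
#' coefficient, GPS partial r-squared and selected-SNP count. With
#' `selection = "stepwise"` the data-driven pipeline is rerun per cohort
#' (so the aggregate includes selection bias); with `"oracle"` the true
#' causal set is scored directly, isolating pure estimation error.
#' Optionally adds, per scenario, a cross-validated R-squared and a
#' permutation-null summary computed on the first replicate cohort.
#'
#' @param specs A single [effect_spec()] or list of them.
#' @param config_sim A [sim_config()] describing the cohorts (defaults to a
#'   clean 170-SNP panel without QC defects).
#' @param replicates Cohorts per scenario.
#' @param selection `"stepwise"` or `"oracle"`.
#' @param stepwise A [stepwise_config()].
#' @param cv_folds Optional: fold count for a first-replicate
#'   cross-validation.
#' @param n_perm Optional: permutation count for a first-replicate
#'   permutation null.
#' @param seed Integer seed.
#' @return A `recovery_report`: list with `summary` (one row per scenario:
#'   means, SDs and quantiles of estimate, partial r2, selected count,
#'   plus `cv_r2` / null summaries when requested) and `details` (one row
#'   per replicate). [tidy()] returns the summary.
#' @export
recovery_experiment <- function(specs, config_sim = NULL, replicates = 100,
                                selection = c("stepwise", "oracle"),
                                stepwise = stepwise_config(),
                                cv_folds = NULL, n_perm = NULL,
                                seed = 1) {
  selection <- match.arg(selection)
  if (inherits(specs, "effect_spec")) specs <- list(specs)
  if (length(specs) == 0) abort("`specs` must hold at least one scenario.")
  config_sim <- config_sim %||% sim_config(
    n_snps = 170, ld_blocks = list(), low_call_snps = 0,
    monomorphic_snps = 0
  )
  details <- vector("list", length(specs))
  extras <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    rows <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      rep_seed <- (seed + 7919L * s + r) %% .Machine$integer.max
      parts <- simulate_participants(config_sim, seed = rep_seed)
      geno <- simulate_genotypes(config_sim, seed = rep_seed + 1L)
      ph <- simulate_phenotype_changes(parts, geno, spec,
                                       seed = rep_seed + 2L)
      include_post <- spec$phenotype != "SMM"
      model <- if (selection == "stepwise") {
        build_gps(ph, geno, spec$phenotype, stepwise)
      } else {
        oracle_gps_model(spec, geno)
      }
      if (nrow(model$entries) == 0) {
        rows[[r]] <- tibble::tibble(
          scenario = s, replicate = r, estimate = NA_real_,
          partial_r2 = 0, n_snps = 0L
        )
        next
      }
      res <- run_association(model, geno, ph, parts,
                             include_post = include_post)
      rows[[r]] <- tibble::tibble(
        scenario = s, replicate = r,
        estimate = res$glm$terms$estimate[res$glm$terms$term == "gps"],
        partial_r2 =
          res$glm$terms$partial_r2[res$glm$terms$term == "gps"],
        n_snps = nrow(model$entries)
      )
      if (r == 1 && (!is.null(cv_folds) || !is.null(n_perm))) {
        extra <- list(scenario = s)
        if (!is.null(cv_folds)) {
          extra$cv_r2 <- cross_validate(
            ph, geno, parts, spec$phenotype, k_folds = cv_folds,
            config = stepwise, seed = rep_seed + 3L
          )$cv_r2
        }
        if (!is.null(n_perm)) {
          pn <- permutation_null(
            ph, geno, parts, spec$phenotype, n_perm = n_perm,
            config = stepwise, seed = rep_seed + 4L
          )
          extra$null_partial_r2_mean <- mean(pn$null)
          extra$null_partial_r2_q95 <- quantile(pn$null, 0.95,
                                                names = FALSE)
          extra$perm_p <- pn$p_value
        }
        extras[[s]] <- tibble::as_tibble(extra)
      }
    }
    details[[s]] <- purrr::list_rbind(rows)
  }
  details <- purrr::list_rbind(details)
  summarise_one <- function(d) {
    tibble::tibble(
      replicates = nrow(d),
      estimate_mean = mean(d$estimate, na.rm = TRUE),
      estimate_sd = sd(d$estimate, na.rm = TRUE),
      estimate_q05 = quantile(d$estimate, 0.05, na.rm = TRUE,
                              names = FALSE),
      estimate_q95 = quantile(d$estimate, 0.95, na.rm = TRUE,
                              names = FALSE),
      partial_r2_mean = mean(d$partial_r2),
      partial_r2_sd = sd(d$partial_r2),
      n_snps_mean = mean(d$n_snps),
      n_snps_sd = sd(d$n_snps)
    )
  }
  summary <- details |>
    dplyr::group_by(.data$scenario) |>
    dplyr::group_modify(~ summarise_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      phenotype = vapply(specs[.data$scenario], function(x) x$phenotype,
                         character(1)),
      true_beta = vapply(specs[.data$scenario],
                         function(x) mean(x$beta), numeric(1)),
      n_causal = vapply(specs[.data$scenario],
                        function(x) length(x$causal_snps), integer(1)),
      selection = selection,
      .after = "scenario"
    )
  extras <- purrr::list_rbind(purrr::compact(extras))
  if (nrow(extras) > 0) {
    summary <- dplyr::left_join(summary, extras, by = "scenario")
  }
  structure(
    list(summary = summary, details = details),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.recovery_report <- function(x, ...) {
  x$summary
}
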