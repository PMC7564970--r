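# sex-specific post-training phenotype distributions (mean, sd) anchoring
# simulated strength values to magnitudes typical of older adults
pheno_post_params <- function(phenotype) {
  p <- list(
    PT_IM60 = list(F = c(125, 24), M = c(183, 33)),
    PV_IT20 = list(F = c(329, 34), M = c(370, 36)),
    PT_IK60 = list(F = c(108, 18), M = c(162, 29)),
    PT_IK240 = list(F = c(58.5, 10), M = c(89, 15))
  )
  p[[phenotype]]
}

causal_dosage <- function(genotypes, participants, spec) {
  missing_snps <- setdiff(spec$causal_snps, genotypes$snp_id)
  if (length(missing_snps) > 0) {
    abort(paste0(
      "Causal SNP(s) absent from the panel: ",
      paste(missing_snps, collapse = ", ")
    ))
  }
  geno <- genotypes[match(spec$causal_snps, genotypes$snp_id), ]
  absent <- setdiff(participants$id, geno_participants(geno))
  if (length(absent) > 0) {
    abort(paste0(
      "Participant(s) missing from genotype data: ",
      paste(head(absent, 5), collapse = ", ")
    ))
  }
  d <- geno_dosage(geno)[, participants$id, drop = FALSE]
  # mean-impute missing calls so every participant gets a genetic term
  for (i in seq_len(nrow(d))) {
    mi <- is.na(d[i, ])
    if (any(mi)) d[i, mi] <- mean(d[i, !mi])
  }
  d
}

participant_covariates <- function(participants) {
  needed <- c("id", "sex_code", "age", "bmi_post")
  missing_cols <- setdiff(needed, names(participants))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`participants` lacks covariate column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyNA(participants[needed])) {
    abort("Covariates (sex_code, age, bmi_post) contain missing values.")
  }
  participants
}

draw_post_values <- function(participants, phenotype) {
  if (phenotype == "SMM") {
    return(janssen_smm(
      participants$height_cm, participants$resistance_post,
      participants$sex_code, participants$age
    ))
  }
  par <- pheno_post_params(phenotype)
  male <- participants$sex_code == 1
  n <- nrow(participants)
  ifelse(
    male,
    rnorm(n, par$M[1], par$M[2]),
    rnorm(n, par$F[1], par$F[2])
  )
}

#' Simulate phenotype values and relative changes
#'
#' Draws post-training phenotype values (SMM from the Janssen bioimpedance
#' equation applied to the cohort's resistance measurements; strength
#' phenotypes from sex-specific normal distributions), then generates each
#' participant's relative change (%) as
#' `intercept + sum_j beta_j * dosage_j + covariate terms + N(0, noise_sd)`,
#' where `dosage_j` counts the minor allele of causal SNP j (missing calls
#' mean-imputed), and back-computes the follow-up value from the change.
#'
#' @param participants Cohort tibble from [simulate_participants()].
#' @param genotypes Genotype panel containing all causal SNPs and all
#'   participants.
#' @param spec An [effect_spec()]; if its `target_variance_fraction` is set
#'   and `calibrate = TRUE`, the noise is first calibrated with
#'   [calibrate_effects()].
#' @param calibrate Whether to auto-calibrate when a target fraction is set.
#' @param seed Optional integer seed.
#' @return Phenotype table: tibble with `id`, `phenotype`, `post_value`,
#'   `followup_value`, `relative_change`.
#' @export
simulate_phenotype_changes <- function(participants, genotypes, spec,
                                       calibrate = TRUE, seed = NULL) {
  participant_covariates(participants)
  if (!is.null(spec$target_variance_fraction) && calibrate) {
    spec <- calibrate_effects(spec, genotypes, participants)
  }
  d <- causal_dosage(genotypes, participants, spec)
  with_optional_seed(seed, function() {
    n <- nrow(participants)
    post <- draw_post_values(participants, spec$phenotype)
    genetic <- as.numeric(crossprod(d, spec$beta))
    ce <- spec$covariate_effects
    change <- spec$intercept + genetic +
      ce["sex"] * participants$sex_code +
      ce["age"] * participants$age +
      ce["bmi"] * participants$bmi_post +
      ce["post"] * post +
      rnorm(n, 0, spec$noise_sd)
    tibble::tibble(
      id = participants$id,
      phenotype = spec$phenotype,
      post_value = post,
      followup_value = post * (1 + change / 100),
      relative_change = unname(change)
    )
  })
}

#' Calibrate generator noise to a target genetic variance fraction
#'
#' Solves for the residual standard deviation that makes the genetic term
#' account for `target_variance_fraction` of the total change variance,
#' using the empirical dosage covariance of the causal SNPs:
#' `noise_var = var_genetic * (1 - f) / f - var_covariates`. The covariate
#' term's variance is computed from the cohort's sex/age/BMI values and the
#' post-training value distribution (exact Janssen values for SMM, the
#' sex-specific generating distribution otherwise); without a cohort it is
#' taken as zero.
#'
#' @inheritParams simulate_phenotype_changes
#' @param participants Optional cohort tibble used to evaluate the
#'   covariate-term variance.
#' @return The `effect_spec` with `noise_sd` replaced by the calibrated
#'   value (attribute `"calibration"` records the variance components).
#' @export
calibrate_effects <- function(spec, genotypes, participants = NULL) {
  f <- spec$target_variance_fraction
  if (is.null(f)) {
    abort("`spec$target_variance_fraction` must be set for calibration.")
  }
  pseudo <- participants %||% tibble::tibble(
    id = geno_participants(genotypes), sex_code = 0, age = 0, bmi_post = 0
  )
  d <- causal_dosage(genotypes, pseudo, spec)
  var_g <- var(as.numeric(crossprod(d, spec$beta)))
  if (var_g <= 0) {
    abort("Causal SNPs carry no dosage variance; cannot calibrate.")
  }
  var_cov <- 0
  if (!is.null(participants)) {
    participant_covariates(participants)
    ce <- spec$covariate_effects
    if (spec$phenotype == "SMM") {
      mu_post <- janssen_smm(
        participants$height_cm, participants$resistance_post,
        participants$sex_code, participants$age
      )
      var_post_noise <- 0
    } else {
      par <- pheno_post_params(spec$phenotype)
      male <- participants$sex_code == 1
      mu_post <- ifelse(male, par$M[1], par$F[1])
      var_post_noise <- mean(ifelse(male, par$M[2], par$F[2])^2)
    }
    fixed <- ce["sex"] * participants$sex_code +
      ce["age"] * participants$age +
      ce["bmi"] * participants$bmi_post +
      ce["post"] * mu_post
    var_cov <- var(fixed) + ce["post"]^2 * var_post_noise
  }
  noise_var <- var_g * (1 - f) / f - var_cov
  if (noise_var <= 0) {
    abort(paste(
      "`target_variance_fraction` is not achievable: covariate variance",
      "already exceeds the implied non-genetic budget. Lower the target or",
      "the covariate effects."
    ))
  }
  spec$noise_sd <- sqrt(unname(noise_var))
  attr(spec, "calibration") <- c(
    var_genetic = var_g, var_covariates = unname(var_cov),
    var_noise = unname(noise_var)
  )
  spec
}

#' Preset effect specifications for each phenotype
#'
#' Returns an [effect_spec()] whose per-allele effect, covariate
#' coefficients, intercept and target genetic variance fraction reproduce
#' the fitted GPS models of the emulated cohort (per-allele effects 2.09,
#' 4.53, 2.24, 2.74 and 2.56% with variance fractions 0.27, 0.27, 0.36,
#' 0.37 and 0.26 for SMM, PT_IM60, PV_IT20, PT_IK60 and PT_IK240), with the
#' matching bundled reference SNP set as the causal set.
#'
#' @inheritParams gps_snp_sets
#' @return An [effect_spec()].
#' @export
default_effect_spec <- function(phenotype) {
  phenotype <- match.arg(phenotype, phenotype_names())
  presets <- list(
    SMM = list(beta = 2.09, f = 0.27, int = -29.36,
               cov = c(sex = -0.91, age = 0.07, bmi = 0.18, post = 0)),
    PT_IM60 = list(beta = 4.53, f = 0.27, int = -38.69,
                   cov = c(sex = 3.02, age = -0.02, bmi = 0.50, post = -0.06)),
    PV_IT20 = list(beta = 2.24, f = 0.36, int = -3.40,
                   cov = c(sex = 1.90, age = -0.31, bmi = -0.09, post = -0.04)),
    PT_IK60 = list(beta = 2.74, f = 0.37, int = -19.44,
                   cov = c(sex = 2.39, age = -0.16, bmi = 0.23, post = -0.01)),
    PT_IK240 = list(beta = 2.56, f = 0.26, int = -68.75,
                    cov = c(sex = 0.84, age = -0.03, bmi = 0.34, post = 0.02))
  )
  p <- presets[[phenotype]]
  effect_spec(
    phenotype = phenotype,
    causal_snps = gps_snp_sets(phenotype)$snp_id,
    beta = p$beta,
    covariate_effects = p$cov,
    intercept = p$int,
    noise_sd = 1,
    target_variance_fraction = p$f
  )
}
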