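#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the knobs of the synthetic study: cohort size and
#' group split, genotype panel structure (number of SNPs, minor-allele
#' frequency range, linkage-disequilibrium blocks, deliberately low-call and
#' monomorphic SNPs, background missingness) and participant demographics.
#' Defaults emulate the study conditions the package targets: 113 older
#' adults (44 combined-fitness, 69 whole-body-vibration), ages 61-81, and a
#' 224-SNP candidate muscle panel in which 12 SNPs fall below the 80%
#' detection threshold, 3 are monomorphic, and 58 SNPs sit in 19 high-LD
#' subgroups (18 blocks of 3 plus one of 4).
#'
#' @param n_fit,n_wbv Participants in the FIT and WBV groups.
#' @param n_snps Panel size.
#' @param maf_range Length-2 range in (0, 1) from which each SNP's minor
#'   allele frequency is drawn uniformly.
#' @param ld_blocks List of `c(size, r)` pairs: a block of `size` SNPs whose
#'   pairwise dosage correlation targets `r` (0 < r < 1). Block sizes must
#'   sum to at most `n_snps`.
#' @param low_call_snps Number of SNPs whose call rate is forced strictly
#'   below 0.80.
#' @param monomorphic_snps Number of SNPs carrying a single genotype in all
#'   participants.
#' @param missing_rate Background missing-completely-at-random call rate,
#'   in \[0, 1).
#' @param age_range Length-2 age range (years); ages are uniform on it.
#' @param female_prop Proportion of women.
#' @param seed Optional integer seed making every draw reproducible.
#' @return A `sim_config` list.
#' @seealso [simulate_participants()], [simulate_genotypes()]
#' @export
sim_config <- function(n_fit = 44, n_wbv = 69, n_snps = 224,
                       maf_range = c(0.05, 0.5),
                       ld_blocks = c(rep(list(c(3, 0.95)), 18), list(c(4, 0.95))),
                       low_call_snps = 12, monomorphic_snps = 3,
                       missing_rate = 0.02, age_range = c(61, 81),
                       female_prop = 0.5, seed = NULL) {
  cfg <- list(
    n_fit = n_fit, n_wbv = n_wbv,
    n_participants = n_fit + n_wbv, n_snps = n_snps,
    maf_range = maf_range, ld_blocks = ld_blocks,
    low_call_snps = low_call_snps, monomorphic_snps = monomorphic_snps,
    missing_rate = missing_rate, age_range = age_range,
    female_prop = female_prop, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
      abort(paste0("`", nm, "` must be a single non-negative integer."))
    }
  }
  chk_count(cfg$n_fit, "n_fit")
  chk_count(cfg$n_wbv, "n_wbv")
  chk_count(cfg$n_snps, "n_snps")
  chk_count(cfg$low_call_snps, "low_call_snps")
  chk_count(cfg$monomorphic_snps, "monomorphic_snps")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range >= 1) || cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("`maf_range` must be an increasing pair inside (0, 1).")
  }
  if (length(cfg$missing_rate) != 1 || cfg$missing_rate < 0 ||
      cfg$missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2]) {
    abort("`age_range` must be an increasing pair of ages.")
  }
  if (cfg$female_prop < 0 || cfg$female_prop > 1) {
    abort("`female_prop` must lie in [0, 1].")
  }
  block_sizes <- vapply(cfg$ld_blocks, function(b) b[1], numeric(1))
  block_r <- vapply(cfg$ld_blocks, function(b) b[2], numeric(1))
  if (length(block_sizes) > 0) {
    if (any(block_sizes < 2)) abort("LD block sizes must be at least 2.")
    if (any(block_r <= 0 | block_r >= 1)) {
      abort("LD block correlation targets must lie in (0, 1).")
    }
  }
  if (sum(block_sizes) + cfg$low_call_snps + cfg$monomorphic_snps >
      cfg$n_snps) {
    abort(paste(
      "`n_snps` too small: LD blocks, low-call and monomorphic SNPs",
      "must fit in the panel."
    ))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  cohort: %d participants (FIT %d / WBV %d), ages %g-%g, %.0f%% women\n",
    x$n_participants, x$n_fit, x$n_wbv, x$age_range[1], x$age_range[2],
    100 * x$female_prop
  ))
  cat(sprintf(
    "  panel: %d SNPs, MAF %g-%g, %d LD block(s), %d low-call, %d monomorphic\n",
    x$n_snps, x$maf_range[1], x$maf_range[2], length(x$ld_blocks),
    x$low_call_snps, x$monomorphic_snps
  ))
  invisible(x)
}

#' Additive effect specification for simulated phenotype change
#'
#' Describes how a relative phenotype change (% between post-training and
#' follow-up) is generated: an intercept, additive per-allele effects of a
#' causal SNP set, linear covariate contributions (sex, age, BMI,
#' post-training value) and Gaussian noise. When `target_variance_fraction`
#' is set, [calibrate_effects()] solves for the noise standard deviation
#' that makes the genetic term account for that fraction of the total change
#' variance.
#'
#' @param phenotype One of `"SMM"`, `"PT_IM60"`, `"PV_IT20"`, `"PT_IK60"`,
#'   `"PT_IK240"`.
#' @param causal_snps Character vector of SNP ids carrying an effect.
#' @param beta Per-allele effect(s) in percent-change units, recycled along
#'   `causal_snps`. Effects apply to the count of each SNP's minor allele;
#'   a positive `beta` makes the minor allele the favourable one.
#' @param covariate_effects Named numeric vector with elements `sex`
#'   (per unit of the male indicator), `age` (per year), `bmi` (per kg/m2)
#'   and `post` (per unit of the post-training phenotype value).
#' @param intercept Baseline change (%).
#' @param noise_sd Standard deviation of the Gaussian residual (%); must be
#'   positive.
#' @param target_variance_fraction Optional fraction in (0, 1) for
#'   [calibrate_effects()].
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(phenotype, causal_snps, beta,
                        covariate_effects = c(sex = 0, age = 0, bmi = 0,
                                              post = 0),
                        intercept = 0, noise_sd = 1,
                        target_variance_fraction = NULL) {
  phenotype <- match.arg(phenotype, phenotype_names())
  beta <- rep_len(beta, length(causal_snps))
  full <- c(sex = 0, age = 0, bmi = 0, post = 0)
  full[names(covariate_effects)] <- covariate_effects
  if (!is.null(target_variance_fraction)) {
    if (target_variance_fraction <= 0 || target_variance_fraction >= 1) {
      abort("`target_variance_fraction` must lie strictly inside (0, 1).")
    }
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  structure(
    list(
      phenotype = phenotype,
      causal_snps = as.character(causal_snps),
      beta = beta,
      covariate_effects = full,
      intercept = intercept,
      noise_sd = noise_sd,
      target_variance_fraction = target_variance_fraction
    ),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>", x$phenotype, "\n")
  cat(sprintf(
    "  %d causal SNP(s), per-allele effects %s %%\n",
    length(x$causal_snps), paste(unique(round(x$beta, 3)), collapse = "/")
  ))
  cat(sprintf(
    "  covariates: sex %g, age %g, bmi %g, post %g; intercept %g; noise sd %g\n",
    x$covariate_effects["sex"], x$covariate_effects["age"],
    x$covariate_effects["bmi"], x$covariate_effects["post"],
    x$intercept, x$noise_sd
  ))
  if (!is.null(x$target_variance_fraction)) {
    cat(sprintf("  target genetic variance fraction: %g\n",
                x$target_variance_fraction))
  }
  invisible(x)
}

phenotype_names <- function() {
  c("SMM", "PT_IM60", "PV_IT20", "PT_IK60", "PT_IK240")
}
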