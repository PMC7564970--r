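# small clean panels keep these pipeline-level simulations quick
eval_cfg <- function(n_fit = 56, n_wbv = 57, n_snps = 60) {
  sim_config(
    n_fit = n_fit, n_wbv = n_wbv, n_snps = n_snps, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0.02
  )
}

null_cohort <- function(cfg, seed) {
  p <- simulate_participants(cfg, seed = seed)
  g <- simulate_genotypes(cfg, seed = seed + 1)
  spec <- effect_spec("SMM", g$snp_id[1], beta = 0, intercept = -2,
                      noise_sd = 8)
  ph <- simulate_phenotype_changes(p, g, spec, seed = seed + 2)
  list(p = p, g = g, ph = ph)
}

test_that("under a null generator cross-validation strips the optimism", {
  cfg <- eval_cfg()
  cv <- insample <- numeric(3)
  for (i in 1:3) {
    co <- null_cohort(cfg, seed = 500 + 10 * i)
    insample[i] <- detraingps:::pipeline_partial_r2(
      co$ph, co$g, co$p, "SMM", stepwise_config(), FALSE
    )$partial_r2
    cv[i] <- cross_validate(co$ph, co$g, co$p, "SMM", k_folds = 5,
                            seed = i)$cv_r2
  }
  # selection bias: in-sample variance explained is materially positive
  # (60 candidate SNPs; the gap widens with panel size)
  expect_gt(mean(insample), 0.04)
  # while honest out-of-fold R^2 sits at (or below) zero
  expect_lt(mean(cv), 0.05)
  expect_gt(mean(insample) - mean(cv), 0.05)
})

test_that("cross-validation approaches in-sample fit when signal dominates", {
  # common high MAFs keep the equal-weight GPS from being diluted by the
  # occasional false entry, so selection is stable across folds
  cfg <- sim_config(
    n_fit = 56, n_wbv = 57, n_snps = 30, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0.02,
    maf_range = c(0.35, 0.5)
  )
  p <- simulate_participants(cfg, seed = 601)
  g <- simulate_genotypes(cfg, seed = 602)
  spec <- effect_spec("SMM", g$snp_id[1], beta = 15, intercept = -2,
                      noise_sd = 2)
  ph <- simulate_phenotype_changes(p, g, spec, seed = 603)
  cv <- cross_validate(ph, g, p, "SMM", k_folds = 5, seed = 2)
  model <- build_gps(ph, g, "SMM")
  insample <- summary(
    run_association(model, g, ph, p)$glm$fit
  )$r.squared
  expect_gt(cv$cv_r2, 0.35)
  expect_gt(cv$cv_r2, insample - 0.2)

  # leave-one-out on a 12-participant cohort runs and returns finite output
  cfg12 <- sim_config(
    n_fit = 6, n_wbv = 6, n_snps = 4, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0
  )
  p12 <- simulate_participants(cfg12, seed = 604)
  g12 <- simulate_genotypes(cfg12, seed = 605)
  ph12 <- simulate_phenotype_changes(
    p12, g12,
    effect_spec("SMM", g12$snp_id[1], beta = 10, noise_sd = 2),
    seed = 606
  )
  loo <- cross_validate(ph12, g12, p12, "SMM", k_folds = 12, seed = 3)
  expect_true(is.finite(loo$cv_r2))
  expect_equal(nrow(loo$predictions), 12)

  expect_error(
    cross_validate(ph12, g12, p12, "SMM", k_folds = 1),
    "at least 2"
  )
  expect_error(
    cross_validate(ph12, g12, p12, "SMM", k_folds = 13),
    "More folds"
  )
})

test_that("the permutation null of selected-GPS partial r2 sits above zero", {
  cfg <- eval_cfg(n_snps = 40)
  co <- null_cohort(cfg, seed = 700)
  pn <- permutation_null(co$ph, co$g, co$p, "SMM", n_perm = 100, seed = 4)
  expect_length(pn$null, 100)
  expect_gt(mean(pn$null), 0.02)
  expect_true(pn$p_value > 0 && pn$p_value <= 1)
  # the observed value comes from the same null world here, so its
  # empirical p-value should not be extreme
  expect_gt(pn$p_value, 0.005)

  expect_error(
    permutation_null(co$ph, co$g, co$p, "SMM", n_perm = 0),
    "at least 100"
  )
})

test_that("recovery experiments are reproducible and quantify selection bias", {
  cfg <- eval_cfg(n_snps = 30)
  spec <- effect_spec(
    "SMM", muscle_snp_panel(30)[1:3], beta = 2,
    covariate_effects = c(sex = -0.9, age = 0.07, bmi = 0.18),
    intercept = -10, target_variance_fraction = 0.2
  )
  rep1 <- recovery_experiment(spec, cfg, replicates = 4, seed = 5)
  rep2 <- recovery_experiment(spec, cfg, replicates = 4, seed = 5)
  expect_equal(rep1$summary, rep2$summary)
  expect_equal(nrow(rep1$details), 4)
  expect_s3_class(tidy(rep1), "tbl_df")

  # oracle selection recovers the per-allele effect without bias
  oracle <- recovery_experiment(spec, cfg, replicates = 12,
                                selection = "oracle", seed = 6)
  expect_equal(oracle$summary$estimate_mean, 2, tolerance = 0.25)

  # data-driven selection shows its two characteristic distortions: at the
  # study's own size the in-sample variance explained is optimistic, and
  # at larger n false entries dilute the equal-weight slope below truth
  step_small <- recovery_experiment(spec, cfg, replicates = 12, seed = 7)
  cfg_big <- eval_cfg(n_fit = 300, n_wbv = 300, n_snps = 30)
  step_big <- recovery_experiment(spec, cfg_big, replicates = 8, seed = 8)
  expect_gt(step_small$summary$partial_r2_mean, 0.2)
  expect_lt(step_big$summary$estimate_mean,
            step_small$summary$estimate_mean)
  expect_gte(step_big$summary$n_snps_mean, 3)

  expect_error(recovery_experiment(list()), "at least one")
})
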