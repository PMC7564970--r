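test_that("cohort generation honours sizes, groups and determinism", {
  cfg <- sim_config(seed = 11)
  p <- simulate_participants(cfg)
  expect_equal(nrow(p), 113)
  expect_equal(sum(p$group == "FIT"), 44)
  expect_equal(sum(p$group == "WBV"), 69)
  expect_true(all(p$age >= 61 & p$age <= 81))
  expect_true(all(p$resistance_post > 0))
  expect_equal(p$bmi_post, p$body_mass_post / (p$height_cm / 100)^2)

  expect_identical(p, simulate_participants(cfg))

  empty <- simulate_participants(sim_config(n_fit = 0, n_wbv = 0, seed = 1))
  expect_equal(nrow(empty), 0)

  expect_error(sim_config(n_fit = -1), "n_fit")
  expect_error(sim_config(maf_range = c(0.5, 0.05)), "maf_range")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("genotype panels carry the configured structural defects", {
  cfg <- sim_config(seed = 7)
  g <- simulate_genotypes(cfg)
  expect_equal(nrow(g), 224)
  info <- attr(g, "structure")
  expect_identical(g, simulate_genotypes(cfg))

  cr <- call_rates(g)
  low <- info$snp_id[info$role == "low_call"]
  expect_length(low, 12)
  expect_true(all(cr$call_rate[cr$snp_id %in% low] < 0.80))

  mono <- info$snp_id[info$role == "monomorphic"]
  expect_length(mono, 3)
  calls <- geno_calls(g)
  for (s in mono) {
    non_missing <- calls[s, !is.na(calls[s, ])]
    expect_length(unique(non_missing), 1)
  }

  # calls only ever use the SNP's two alleles
  d <- geno_dosage(g, setNames(g$allele_b, g$snp_id))
  expect_true(all(d[!is.na(d)] %in% 0:2))
})

test_that("LD blocks reach their correlation target", {
  cfg <- sim_config(
    n_fit = 56, n_wbv = 57, n_snps = 12,
    ld_blocks = list(c(4, 0.95)), low_call_snps = 0,
    monomorphic_snps = 0, missing_rate = 0.02, seed = 3
  )
  g <- simulate_genotypes(cfg)
  info <- attr(g, "structure")
  members <- info$snp_id[info$role == "block"]
  expect_length(members, 4)
  d <- geno_dosage(g[g$snp_id %in% members, ])
  r <- stats::cor(t(d), use = "pairwise.complete.obs")
  expect_true(all(abs(r[upper.tri(r)]) > 0.8))
})

test_that("clean SNPs follow Hardy-Weinberg at their MAF", {
  cfg <- sim_config(
    n_fit = 5000, n_wbv = 5000, n_snps = 60, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0,
    maf_range = c(0.5, 0.5), seed = 5
  )
  g <- simulate_genotypes(cfg)
  d <- geno_dosage(g, setNames(g$allele_b, g$snp_id))
  # genotype frequencies at MAF 0.5: (0.25, 0.5, 0.25) within 3 SE
  freq <- c(mean(d[1, ] == 0), mean(d[1, ] == 1), mean(d[1, ] == 2))
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
  # HWE chi-square rejects at about the nominal rate over the panel
  pvals <- apply(d, 1, hwe_chisq_p)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("phenotype changes follow the additive generating model", {
  cfg <- sim_config(
    n_fit = 20, n_wbv = 20, n_snps = 5, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0, seed = 2
  )
  p <- simulate_participants(cfg)
  g <- simulate_genotypes(cfg)
  snp1 <- g$snp_id[1]

  # degenerate model: no effects, tiny noise -> change == intercept
  spec0 <- effect_spec("PT_IK60", snp1, beta = 0, intercept = -4,
                       noise_sd = 1e-9)
  ph0 <- simulate_phenotype_changes(p, g, spec0, seed = 1)
  expect_equal(ph0$relative_change, rep(-4, nrow(p)), tolerance = 1e-6)
  expect_equal(ph0$followup_value, ph0$post_value * (1 - 4 / 100))

  # determinism
  spec <- effect_spec("SMM", snp1, beta = 3, noise_sd = 5)
  expect_identical(
    simulate_phenotype_changes(p, g, spec, seed = 9),
    simulate_phenotype_changes(p, g, spec, seed = 9)
  )

  # dosage-2 vs dosage-0 carriers differ by 2 * beta at large n
  cfg_big <- sim_config(
    n_fit = 2500, n_wbv = 2500, n_snps = 5, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0,
    maf_range = c(0.3, 0.5), seed = 4
  )
  pb <- simulate_participants(cfg_big)
  gb <- simulate_genotypes(cfg_big)
  spec5 <- effect_spec("SMM", gb$snp_id[1], beta = 5, noise_sd = 3)
  phb <- simulate_phenotype_changes(pb, gb, spec5, seed = 8)
  dos <- geno_dosage(gb[1, ])[1, pb$id]
  diff <- mean(phb$relative_change[dos == 2]) -
    mean(phb$relative_change[dos == 0])
  expect_equal(diff, 10, tolerance = 0.5)

  # missing covariate is a data error
  p_bad <- dplyr::select(p, -"bmi_post")
  expect_error(simulate_phenotype_changes(p_bad, g, spec), "bmi_post")
})

test_that("noise calibration hits the target variance fraction", {
  cfg <- sim_config(
    n_fit = 5000, n_wbv = 5000, n_snps = 12, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0, seed = 6
  )
  p <- simulate_participants(cfg)
  g <- simulate_genotypes(cfg)

  # algebra: without covariates, target 0.5 means noise var == genetic var
  spec <- effect_spec("SMM", g$snp_id[1:3], beta = 2,
                      target_variance_fraction = 0.5)
  cal <- calibrate_effects(spec, g)
  comp <- attr(cal, "calibration")
  expect_equal(cal$noise_sd^2, unname(comp["var_genetic"]),
               tolerance = 1e-10)

  # Monte-Carlo: realised genetic variance fraction within 0.02 of target
  spec27 <- effect_spec(
    "SMM", g$snp_id[1:4], beta = 2.09,
    covariate_effects = c(sex = -0.91, age = 0.07, bmi = 0.18),
    target_variance_fraction = 0.27
  )
  cal27 <- calibrate_effects(spec27, g, p)
  ph <- simulate_phenotype_changes(p, g, cal27, calibrate = FALSE, seed = 3)
  dos <- geno_dosage(g[match(cal27$causal_snps, g$snp_id), ])[, p$id]
  genetic <- as.numeric(crossprod(dos, cal27$beta))
  frac <- var(genetic) / var(ph$relative_change)
  expect_equal(frac, 0.27, tolerance = 0.02)

  # degenerate targets rejected
  expect_error(
    effect_spec("SMM", g$snp_id[1], 1, target_variance_fraction = 0),
    "target_variance_fraction"
  )
  expect_error(
    effect_spec("SMM", g$snp_id[1], 1, target_variance_fraction = 1),
    "target_variance_fraction"
  )
  expect_error(
    calibrate_effects(effect_spec("SMM", g$snp_id[1], 1), g),
    "must be set"
  )
})
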