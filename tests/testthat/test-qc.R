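test_that("detection filter applies the strict 80% boundary", {
  withr::with_seed(1, {
    dos <- matrix(rbinom(300, 2, 0.4), nrow = 3)
    dos[1, 1:21] <- NA # 79/100 calls -> removed
    dos[2, 1:20] <- NA # 80/100 calls -> kept
    g <- panel_from_dosage(dos)
    out <- detection_filter(g, 0.80)
    expect_equal(out$removed, "rs0001")
    expect_equal(out$kept$snp_id, c("rs0002", "rs0003"))
  })
  expect_error(detection_filter(panel_from_dosage(matrix(0, 1, 5)), 0),
               "threshold")
})

test_that("monomorphic filter removes constant and all-missing SNPs", {
  dos <- rbind(
    rep(0, 10),            # all homozygous -> removed
    c(0, rep(0, 8), 1),    # one heterozygote -> kept
    rep(NA, 10),           # no calls -> removed, logged
    rep(1, 10)             # constant heterozygote -> removed
  )
  g <- panel_from_dosage(dos)
  out <- monomorphic_filter(g)
  expect_setequal(out$removed, c("rs0001", "rs0003", "rs0004"))
  expect_equal(out$kept$snp_id, "rs0002")
  expect_equal(attr(out, "all_missing"), "rs0003")
})

test_that("LD grouping matches a brute-force union-find oracle", {
  # three identical dosage SNPs form one subgroup of 3
  withr::with_seed(11, {
    base <- rbinom(40, 2, 0.5)
    g3 <- panel_from_dosage(rbind(base, base, base,
                                  rbinom(40, 2, 0.5)))
  })
  sub <- ld_group(g3)
  expect_length(sub, 1)
  expect_setequal(sub[[1]], c("rs0001", "rs0002", "rs0003"))

  # independent SNPs at large n: no subgroups
  withr::with_seed(2, {
    g_ind <- panel_from_dosage(
      matrix(rbinom(20 * 500, 2, 0.3), nrow = 20)
    )
    expect_length(ld_group(g_ind), 0)
  })

  # randomized panels vs oracle
  for (s in 1:4) {
    withr::with_seed(100 + s, {
      m <- 25
      n <- 60
      dos <- matrix(rbinom(m * n, 2, runif(m, 0.2, 0.5)), nrow = m)
      # plant two correlated clusters by copying rows with sign flips
      dos[2, ] <- dos[1, ]
      dos[3, ] <- 2 - dos[1, ]
      dos[10, ] <- dos[9, ]
      dos[sample(length(dos), 50)] <- NA
      g <- panel_from_dosage(dos)
      canon <- function(groups) {
        sort(vapply(groups, function(x) paste(sort(x), collapse = ","),
                    character(1)))
      }
      got <- canon(lapply(ld_group(g), function(ids) match(ids, g$snp_id)))
      want <- canon(oracle_ld_components(dos))
      expect_equal(got, want)
    })
  }

  expect_error(ld_group(panel_from_dosage(matrix(0:1, 1, 2))), "2 SNPs")
})

test_that("representatives maximise degree, then references, then id", {
  # star: hub rs0001 correlated with three leaves whose perturbations live
  # on disjoint participant sets, so leaf-leaf correlations drop below the
  # threshold while hub-leaf correlations stay above it
  withr::with_seed(5, {
    n <- 300
    hub <- rbinom(n, 2, 0.5)
    pos <- matrix(sample(n, 60), ncol = 3)
    flip_at <- function(x, i) {
      x[i] <- 2 - x[i]
      x
    }
    leaves <- rbind(
      flip_at(hub, pos[, 1]), flip_at(hub, pos[, 2]), flip_at(hub, pos[, 3])
    )
    g <- panel_from_dosage(rbind(hub, leaves))
  })
  d <- geno_dosage(g)
  r <- stats::cor(t(d))
  expect_true(all(abs(r[1, 2:4]) > 0.8)) # hub-leaf edges present
  expect_true(all(abs(r[2:4, 2:4][upper.tri(diag(3))]) < 0.8)) # no leaf-leaf
  sub <- ld_group(g, 0.8)
  expect_length(sub, 1)
  expect_length(sub[[1]], 4)
  expect_equal(select_representatives(g, sub, 0.8), "rs0001")

  # 2-SNP subgroup: degree ties, reference count decides
  withr::with_seed(6, base <- rbinom(50, 2, 0.4))
  g2 <- panel_from_dosage(rbind(base, base), n_refs = c(5L, 1L))
  expect_equal(select_representatives(g2, ld_group(g2)), "rs0001")
  g2b <- panel_from_dosage(rbind(base, base), n_refs = c(1L, 5L))
  expect_equal(select_representatives(g2b, ld_group(g2b)), "rs0002")

  # equal degree and references: lexicographically smaller id
  g2c <- panel_from_dosage(rbind(base, base), n_refs = c(2L, 2L),
                           snp_ids = c("rs200", "rs100"))
  expect_equal(select_representatives(g2c, ld_group(g2c)), "rs100")
})

test_that("full QC conserves the panel partition and handles clean panels", {
  cfg <- sim_config(seed = 31)
  g <- simulate_genotypes(cfg)
  qc <- run_qc(g)
  expect_equal(
    length(qc$kept) + length(qc$removed_low_detection) +
      length(qc$removed_monomorphic) + length(qc$removed_ld),
    qc$n_input
  )
  expect_setequal(
    c(qc$kept, qc$removed_low_detection, qc$removed_monomorphic,
      qc$removed_ld),
    g$snp_id
  )
  expect_true(all(qc$representatives %in% qc$kept))
  td <- tidy(qc)
  expect_equal(nrow(td), nrow(g))
  expect_equal(sum(td$status == "kept"), length(qc$kept))

  # clean panel: everything kept
  clean <- simulate_genotypes(sim_config(
    n_fit = 30, n_wbv = 30, n_snps = 20, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0, seed = 8
  ))
  qc_clean <- run_qc(clean)
  expect_equal(qc_clean$kept, clean$snp_id)
  expect_length(qc_clean$subgroups, 0)

  expect_error(run_qc(clean[0, ]), "non-empty")
})

test_that("permuting SNP rows leaves the kept set unchanged", {
  cfg <- sim_config(
    n_fit = 40, n_wbv = 40, n_snps = 30, ld_blocks = list(c(3, 0.95)),
    low_call_snps = 2, monomorphic_snps = 1, seed = 12
  )
  g <- simulate_genotypes(cfg)
  qc1 <- run_qc(g)
  withr::with_seed(99, {
    g_perm <- g[sample(nrow(g)), ]
  })
  qc2 <- run_qc(g_perm)
  expect_setequal(qc1$kept, qc2$kept)
  expect_setequal(qc1$removed_ld, qc2$removed_ld)
})
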