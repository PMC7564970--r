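make_assoc_data <- function(n = 80, beta = 2, seed = 61, noise = 4) {
  withr::with_seed(seed, {
    gps <- rbinom(n, 10, 0.4)
    sex <- rep_len(0:1, n)
    age <- runif(n, 61, 81)
    bmi <- rnorm(n, 26, 3)
    post <- rnorm(n, 25, 3)
    change <- -10 + beta * gps - 0.9 * sex + 0.05 * age + 0.2 * bmi +
      rnorm(n, 0, noise)
    tibble::tibble(
      id = sprintf("P%03d", 1:n), change = change, gps = gps,
      sex_code = sex, age = age, bmi = bmi, post_value = post
    )
  })
}

test_that("GLM terms report estimates, standardized betas and partial r2", {
  d <- make_assoc_data()
  fit <- fit_gps_glm(d, include_post = TRUE)
  td <- tidy(fit)
  expect_setequal(
    td$term, c("gps", "sex_code", "age", "bmi", "post_value", "intercept")
  )
  expect_equal(td$estimate[td$term == "gps"], 2, tolerance = 0.3)
  # standardized beta identity
  est <- td$estimate[td$term == "gps"]
  expect_equal(
    td$standardized_beta[td$term == "gps"],
    est * sd(d$gps) / sd(d$change)
  )
  expect_true(all(td$partial_r2[!is.na(td$partial_r2)] >= 0))
  expect_lte(glance(fit)$adjusted_r2, 1)

  # omitting the post covariate drops the term
  fit2 <- fit_gps_glm(d, include_post = FALSE)
  expect_false("post_value" %in% tidy(fit2)$term)

  # duplicated predictor: rank-deficiency is an error
  d_bad <- d
  d_bad$bmi <- d_bad$gps
  expect_error(fit_gps_glm(d_bad), "collinear")
  expect_error(fit_gps_glm(d[1:5, ]), "complete cases")
})

test_that("partial r2 equals the squared semi-partial correlation oracle", {
  # single-predictor model: partial r2 is the plain regression R^2
  withr::with_seed(62, {
    x <- rnorm(40)
    y <- 2 * x + rnorm(40)
  })
  f1 <- lm(y ~ x)
  expect_equal(partial_r2(f1, "x"), summary(f1)$r.squared,
               tolerance = 1e-12)

  # residual-on-residual oracle to 1e-10 on random fixtures
  for (s in 1:5) {
    withr::with_seed(70 + s, {
      n <- 30
      X <- data.frame(a = rnorm(n), b = rnorm(n), c = rbinom(n, 2, 0.4))
      y <- 1 + 0.5 * X$a - 2 * X$c + rnorm(n)
    })
    fit <- lm(y ~ a + b + c, data = X)
    for (tm in c("a", "b", "c")) {
      expect_equal(
        partial_r2(fit, tm),
        oracle_semipartial_r2(y, X[[tm]], X[setdiff(names(X), tm)]),
        tolerance = 1e-10
      )
    }
  }

  # hand-computed integer fixture (n = 6, 2 predictors)
  hx <- c(0, 1, 2, 0, 1, 2)
  hz <- c(1, 1, 0, 0, 1, 0)
  hy <- c(2, 4, 7, 1, 5, 6)
  hfit <- lm(hy ~ hx + hz)
  sse_full <- sum(resid(hfit)^2)
  sse_no_x <- sum(resid(lm(hy ~ hz))^2)
  expect_equal(partial_r2(hfit, "hx"),
               (sse_no_x - sse_full) / sum((hy - mean(hy))^2),
               tolerance = 1e-12)

  # orthogonal predictors: partial r2 values add up to the model R^2
  ox <- rep(c(-1, 1), 10)
  oz <- rep(c(-1, -1, 1, 1), 5)
  withr::with_seed(77, oy <- ox - 2 * oz + rnorm(20))
  ofit <- lm(oy ~ ox + oz)
  expect_equal(
    partial_r2(ofit, "ox") + partial_r2(ofit, "oz"),
    summary(ofit)$r.squared,
    tolerance = 1e-12
  )

  expect_error(partial_r2(f1, "nope"), "not in the model")
})

test_that("standardized beta is invariant to affine rescaling", {
  d <- make_assoc_data()
  f0 <- fit_gps_glm(d)
  d2 <- d
  d2$age <- d2$age * 10 + 3
  d2$change <- d2$change * 2.5 - 7
  f2 <- fit_gps_glm(d2)
  expect_equal(
    tidy(f0)$standardized_beta[tidy(f0)$term == "age"],
    tidy(f2)$standardized_beta[tidy(f2)$term == "age"],
    tolerance = 1e-10
  )
  expect_equal(
    tidy(f0)$partial_r2[tidy(f0)$term == "gps"],
    tidy(f2)$partial_r2[tidy(f2)$term == "gps"],
    tolerance = 1e-10
  )
})

test_that("a null response yields near-zero estimates and adjusted r2", {
  ests <- r2s <- numeric(100)
  for (s in 1:100) {
    d <- make_assoc_data(n = 50, beta = 0, seed = 200 + s, noise = 5)
    fit <- fit_gps_glm(d)
    ests[s] <- fit$terms$estimate[fit$terms$term == "gps"]
    r2s[s] <- fit$adjusted_r2
  }
  expect_lt(abs(mean(ests)), 0.15)
  expect_lt(abs(mean(r2s)), 0.05)
})

test_that("GPS bins merge tails inward and respect the minimum size", {
  # documented trace: counts {2, 5, 2} collapse to a single bin of 9
  d <- make_assoc_data(n = 9)
  d$gps <- c(1, 1, 2, 2, 2, 2, 2, 3, 3)
  b <- gps_bins(d, min_bin = 3)
  expect_equal(nrow(b$bins), 1)
  expect_equal(b$bins$n, 9)
  expect_equal(b$bins$gps_lo, 1)
  expect_equal(b$bins$gps_hi, 3)

  # an already-adequate distribution is left alone
  d2 <- make_assoc_data(n = 12)
  d2$gps <- rep(c(2, 3, 4), each = 4)
  b2 <- gps_bins(d2, min_bin = 3)
  expect_equal(b2$bins$n, c(4, 4, 4))
  expect_true(all(!is.na(b2$bins$lsmean)) && all(b2$bins$se > 0))

  # single shared value: one bin whose LS-mean is the adjusted overall mean
  d3 <- make_assoc_data(n = 20)
  d3$gps <- 4
  b3 <- gps_bins(d3, min_bin = 3)
  expect_equal(nrow(b3$bins), 1)
  expect_equal(b3$bins$lsmean, mean(d3$change), tolerance = 1e-8)

  expect_error(gps_bins(make_assoc_data(n = 2), min_bin = 3), "min_bin")

  # strong positive effect: adjusted bin means increase with GPS
  d4 <- make_assoc_data(n = 600, beta = 3, noise = 2, seed = 99)
  b4 <- gps_bins(d4, min_bin = 3)
  expect_true(all(diff(b4$bins$lsmean) > 0))
  expect_equal(b4$trend[["slope"]], 3, tolerance = 0.15)
})

test_that("run_association populates every field deterministically", {
  cfg <- sim_config(
    n_fit = 60, n_wbv = 60, n_snps = 20, ld_blocks = list(),
    low_call_snps = 0, monomorphic_snps = 0, missing_rate = 0.02, seed = 23
  )
  p <- simulate_participants(cfg)
  g <- simulate_genotypes(cfg)
  spec <- effect_spec("PT_IK60", g$snp_id[1:2], beta = 8, intercept = -3,
                      noise_sd = 6)
  ph <- simulate_phenotype_changes(p, g, spec, seed = 24)
  model <- build_gps(ph, g, "PT_IK60")
  res <- run_association(model, g, ph, p)
  expect_s3_class(res, "association_result")
  expect_equal(res$n_snps, nrow(model$entries))
  expect_equal(res$n_used, 120)
  expect_true(all(c("gps", "sex_code", "age", "bmi", "post_value",
                    "intercept") %in% tidy(res)$term))
  expect_gt(glance(res)$gps_partial_r2, 0)

  res2 <- run_association(model, g, ph, p)
  expect_equal(tidy(res), tidy(res2))
  expect_equal(res$bins$bins, res2$bins$bins)

  plt <- autoplot(res)
  expect_s3_class(plt, "ggplot")
})
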