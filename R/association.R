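glm_term_names <- function(include_post) {
  c("gps", "sex_code", "age", "bmi", if (include_post) "post_value")
}

#' Fit the GPS general linear model
#'
#' Ordinary-least-squares fit of relative change on GPS with sex, age and
#' BMI (and, unless `include_post = FALSE`, the post-training phenotype
#' value) as covariates. Reports per term: the raw estimate, the
#' standardized coefficient `estimate * sd(term) / sd(change)`, the
#' Type-III partial r-squared `(SSE(model without term) - SSE(full)) /
#' SS(total)`, and the two-sided p-value.
#'
#' @param data Tibble with columns `change`, `gps`, `sex_code`, `age`,
#'   `bmi` and (when used) `post_value`.
#' @param include_post Include the post-training value covariate? The
#'   muscle-mass change model conventionally omits it.
#' @return A `gps_glm`: list with `terms` (tibble `term`, `estimate`,
#'   `standardized_beta`, `partial_r2`, `p_value`), `adjusted_r2`,
#'   `n_used`, and the underlying `fit`. [tidy()]/[glance()] methods
#'   available.
#' @export
fit_gps_glm <- function(data, include_post = TRUE) {
  terms <- glm_term_names(include_post)
  missing_cols <- setdiff(c("change", terms), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[, c("change", terms)]), ]
  if (nrow(d) < 10) abort("Need at least 10 complete cases.")
  form <- as.formula(paste("change ~", paste(terms, collapse = " + ")))
  fit <- lm(form, data = d)
  if (anyNA(coef(fit))) {
    abort(paste0(
      "Rank-deficient design; collinear term(s): ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  ct <- summary(fit)$coefficients
  ss_total <- sum((d$change - mean(d$change))^2)
  sse_full <- sum(resid(fit)^2)
  pr2 <- vapply(terms, function(tm) {
    red <- lm(
      as.formula(paste("change ~", paste(setdiff(terms, tm),
                                         collapse = " + "))),
      data = d
    )
    (sum(resid(red)^2) - sse_full) / ss_total
  }, numeric(1))
  sds <- vapply(terms, function(tm) sd(d[[tm]]), numeric(1))
  term_tbl <- tibble::tibble(
    term = c(terms, "intercept"),
    estimate = c(unname(ct[terms, 1]), unname(ct["(Intercept)", 1])),
    standardized_beta = c(
      unname(ct[terms, 1]) * unname(sds) / sd(d$change), NA_real_
    ),
    partial_r2 = c(unname(pr2), NA_real_),
    p_value = c(unname(ct[terms, 4]), unname(ct["(Intercept)", 4]))
  )
  structure(
    list(
      terms = term_tbl,
      adjusted_r2 = summary(fit)$adj.r.squared,
      n_used = nrow(d),
      include_post = include_post,
      fit = fit
    ),
    class = "gps_glm"
  )
}

#' Type-III partial r-squared of a model term
#'
#' `(SSE(model without the term) - SSE(full model)) / SS(total)`: the
#' fraction of total response variance attributable to the term when it is
#' entered last.
#'
#' @param fit A `gps_glm` from [fit_gps_glm()] or a plain `lm`.
#' @param term Term name as it appears in the model.
#' @return A fraction in \[0, 1\].
#' @export
partial_r2 <- function(fit, term) {
  lmfit <- if (inherits(fit, "gps_glm")) fit$fit else fit
  tms <- attr(stats::terms(lmfit), "term.labels")
  if (!term %in% tms) {
    abort(paste0("Term `", term, "` is not in the model."))
  }
  y <- stats::model.response(stats::model.frame(lmfit))
  mm <- stats::model.matrix(lmfit)
  # refit from the stored model matrix (robust to the original data object
  # having gone out of scope)
  drop_cols <- attr(mm, "assign") == match(term, tms)
  red <- lm.fit(mm[, !drop_cols, drop = FALSE], y)
  (sum(red$residuals^2) - sum(resid(lmfit)^2)) / sum((y - mean(y))^2)
}

#' @export
print.gps_glm <- function(x, ...) {
  cat("<gps_glm>\n")
  cat(sprintf("  n = %d, adjusted r^2 = %.3f\n", x$n_used, x$adjusted_r2))
  print(x$terms)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gps_glm <- function(x, ...) {
  x$terms
}

#' @exportS3Method generics::glance
glance.gps_glm <- function(x, ...) {
  tibble::tibble(
    adjusted_r2 = x$adjusted_r2,
    r_squared = summary(x$fit)$r.squared,
    n_used = x$n_used
  )
}

# iterative tail merge: leftmost / rightmost bins below min_bin are merged
# inward until every bin holds at least min_bin participants
merge_bins <- function(values, min_bin) {
  lev <- sort(unique(values))
  groups <- as.list(lev)
  counts <- vapply(groups, function(g) sum(values %in% g), numeric(1))
  repeat {
    if (length(groups) <= 1) break
    if (counts[1] < min_bin) {
      groups[[2]] <- c(groups[[1]], groups[[2]])
      counts[2] <- counts[1] + counts[2]
      groups <- groups[-1]
      counts <- counts[-1]
      next
    }
    k <- length(groups)
    if (counts[k] < min_bin) {
      groups[[k - 1]] <- c(groups[[k - 1]], groups[[k]])
      counts[k - 1] <- counts[k - 1] + counts[k]
      groups <- groups[-k]
      counts <- counts[-k]
      next
    }
    break
  }
  groups
}

#' Covariate-adjusted GPS bin summary
#'
#' Rounds GPS to integers, merges integer values from the distribution
#' tails inward until every bin holds at least `min_bin` participants, and
#' reports the covariate-adjusted (least-squares) mean change and standard
#' error per bin, together with the covariate-adjusted linear trend of
#' change on GPS (slope, and intercept evaluated at the covariate means).
#'
#' @inheritParams fit_gps_glm
#' @param min_bin Minimum participants per bin (default 3).
#' @return A `gps_bins` list: `bins` (tibble `bin`, `gps_lo`, `gps_hi`,
#'   `gps_mid`, `n`, `lsmean`, `se`), `trend` (named vector `slope`,
#'   `intercept`), `data`.
#' @export
gps_bins <- function(data, min_bin = 3, include_post = TRUE) {
  covars <- setdiff(glm_term_names(include_post), "gps")
  d <- data[stats::complete.cases(data[, c("change", "gps", covars)]), ]
  if (nrow(d) < min_bin) {
    abort("Fewer participants than `min_bin`.")
  }
  d$gps_int <- round(d$gps)
  groups <- merge_bins(d$gps_int, min_bin)
  labels <- vapply(groups, function(g) {
    if (length(g) == 1) as.character(g) else
      paste0(min(g), "-", max(g))
  }, character(1))
  d$bin <- factor(
    labels[vapply(d$gps_int, function(v) {
      which(vapply(groups, function(g) v %in% g, logical(1)))
    }, numeric(1))],
    levels = labels
  )
  use_covars <- covars[vapply(d[covars], function(x) length(unique(x)) > 1,
                              logical(1))]
  if (length(labels) == 1) {
    # single bin: the adjusted mean is the overall mean (LS-mean at the
    # covariate centroid), with the covariate-model residual SE
    fit <- lm(
      as.formula(paste("change ~", paste(c("1", use_covars),
                                         collapse = " + "))),
      data = d
    )
    em <- tibble::tibble(
      bin = labels,
      emmean = mean(d$change),
      SE = summary(fit)$sigma / sqrt(nrow(d))
    )
  } else {
    rhs <- paste(c("bin", use_covars), collapse = " + ")
    fit <- lm(as.formula(paste("change ~", rhs)), data = d)
    em <- tibble::as_tibble(emmeans::emmeans(fit, "bin"))
  }
  bins <- tibble::tibble(
    bin = labels,
    gps_lo = vapply(groups, min, numeric(1)),
    gps_hi = vapply(groups, max, numeric(1)),
    gps_mid = vapply(groups, function(g) mean(range(g)), numeric(1)),
    n = vapply(groups, function(g) sum(d$gps_int %in% g), numeric(1))
  )
  bins <- dplyr::left_join(
    bins,
    dplyr::select(em, bin = "bin", lsmean = "emmean", se = "SE"),
    by = "bin"
  )
  tr_fit <- lm(
    as.formula(paste("change ~", paste(c("gps", use_covars),
                                       collapse = " + "))),
    data = d
  )
  slope <- unname(coef(tr_fit)["gps"])
  cov_means <- vapply(use_covars, function(v) mean(d[[v]]), numeric(1))
  intercept <- unname(coef(tr_fit)["(Intercept)"]) +
    sum(coef(tr_fit)[use_covars] * cov_means)
  structure(
    list(
      bins = bins,
      trend = c(slope = slope, intercept = intercept),
      data = d
    ),
    class = "gps_bins"
  )
}

#' Evaluate a GPS model against observed changes
#'
#' End-to-end association step: computes each participant's GPS under the
#' model, assembles the analysis table (change, GPS, sex, age, BMI,
#' post-training value), fits the GPS general linear model and the
#' covariate-adjusted GPS bin summary.
#'
#' @param model A `gps_model` from [build_gps()].
#' @param genotypes Genotype panel.
#' @param phenotypes Phenotype table.
#' @param participants Cohort tibble.
#' @param include_post Include the post-training covariate; defaults to
#'   `FALSE` for the muscle-mass model (`"SMM"`), `TRUE` otherwise.
#' @param min_bin Minimum participants per GPS bin.
#' @return An `association_result`: list with `phenotype`, `glm`
#'   (`gps_glm`), `bins` (`gps_bins`), `gps` (per-participant scores),
#'   `n_snps`, `n_used`. [tidy()] returns the GLM term table augmented
#'   with phenotype and SNP count; [glance()] the fit summary;
#'   [autoplot()] a GPS-vs-change figure.
#' @export
run_association <- function(model, genotypes, phenotypes, participants,
                            include_post = NULL, min_bin = 3) {
  if (!inherits(model, "gps_model")) abort("`model` must be a gps_model.")
  include_post <- include_post %||% (model$phenotype != "SMM")
  gps <- compute_gps(genotypes, model)
  data <- assemble_association_data(
    model$phenotype, gps, phenotypes, participants
  )
  glm_fit <- fit_gps_glm(data, include_post = include_post)
  bins <- gps_bins(data, min_bin = min_bin, include_post = include_post)
  structure(
    list(
      phenotype = model$phenotype,
      glm = glm_fit,
      bins = bins,
      gps = gps,
      n_snps = nrow(model$entries),
      n_used = glm_fit$n_used
    ),
    class = "association_result"
  )
}

assemble_association_data <- function(phenotype, gps, phenotypes,
                                      participants) {
  ph <- phenotypes[phenotypes$phenotype == phenotype, ]
  if (nrow(ph) == 0) abort(paste0("No rows for phenotype ", phenotype, "."))
  participants |>
    dplyr::select("id", "sex_code", "age", bmi = "bmi_post") |>
    dplyr::inner_join(
      dplyr::select(ph, "id", change = "relative_change",
                    "post_value"),
      by = "id"
    ) |>
    dplyr::inner_join(dplyr::select(gps, "id", "gps"), by = "id")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result>", x$phenotype, "\n")
  cat(sprintf("  %d SNPs, n = %d, adjusted r^2 = %.3f\n",
              x$n_snps, x$n_used, x$glm$adjusted_r2))
  print(x$glm$terms)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.association_result <- function(x, ...) {
  dplyr::mutate(
    x$glm$terms,
    phenotype = x$phenotype, n_snps = x$n_snps,
    .before = 1
  )
}

#' @exportS3Method generics::glance
glance.association_result <- function(x, ...) {
  tibble::tibble(
    phenotype = x$phenotype,
    adjusted_r2 = x$glm$adjusted_r2,
    gps_partial_r2 =
      x$glm$terms$partial_r2[x$glm$terms$term == "gps"],
    gps_p = x$glm$terms$p_value[x$glm$terms$term == "gps"],
    n_snps = x$n_snps,
    n_used = x$n_used
  )
}

#' @rdname run_association
#' @param object An `association_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.association_result <- function(object, ...) {
  b <- object$bins$bins
  d <- object$bins$data
  tr <- object$bins$trend
  rng <- range(d$change)
  hist_scale <- 0.25 * diff(rng) / max(b$n)
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = b,
      ggplot2::aes(x = .data$gps_mid, y = rng[1] + .data$n * hist_scale),
      fill = "grey85", colour = "grey60", width = 0.8
    ) +
    ggplot2::geom_jitter(
      data = d, ggplot2::aes(x = .data$gps_int, y = .data$change),
      width = 0.12, alpha = 0.35, size = 1
    ) +
    ggplot2::geom_abline(
      intercept = tr["intercept"], slope = tr["slope"],
      linetype = 2, colour = "steelblue"
    ) +
    ggplot2::geom_pointrange(
      data = b,
      ggplot2::aes(
        x = .data$gps_mid, y = .data$lsmean,
        ymin = .data$lsmean - .data$se, ymax = .data$lsmean + .data$se
      ),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(
      name = paste0("Δ", object$phenotype, " (%)"),
      sec.axis = ggplot2::sec_axis(
        ~ (. - rng[1]) / hist_scale, name = "participants"
      )
    ) +
    ggplot2::labs(
      x = "GPS (favourable alleles)",
      title = paste0("GPS vs Δ", object$phenotype),
      subtitle = sprintf(
        "%d SNPs; least-squares bin means ± SE; adjusted trend",
        object$n_snps
      )
    ) +
    ggplot2::theme_minimal()
}
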