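#' Janssen bioimpedance skeletal muscle mass equation
#'
#' Estimates whole-body skeletal muscle mass (kg) from height, whole-body
#' BIA resistance, sex and age:
#' `SMM = (Ht^2 / R) * 0.401 + sex * 3.825 + age * (-0.071) + 5.102`,
#' with height in cm, resistance in ohm, and sex coded men = 1, women = 0.
#'
#' @param height_cm Height in centimetres (> 0).
#' @param resistance_ohm Whole-body BIA resistance in ohms (> 0).
#' @param sex Sex code: 1 = male, 0 = female (or `"M"`/`"F"`).
#' @param age Age in years (> 0).
#' @return Estimated skeletal muscle mass in kg.
#' @examples
#' janssen_smm(170, 500, 1, 67)
#' @export
janssen_smm <- function(height_cm, resistance_ohm, sex, age) {
  if (is.character(sex)) sex <- as.numeric(sex == "M")
  if (any(resistance_ohm <= 0, na.rm = TRUE)) {
    abort("`resistance_ohm` must be positive.")
  }
  if (any(height_cm <= 0, na.rm = TRUE)) abort("`height_cm` must be positive.")
  if (any(age <= 0, na.rm = TRUE)) abort("`age` must be positive.")
  if (!all(sex %in% c(0, 1) | is.na(sex))) {
    abort("`sex` must be coded 0 (female) or 1 (male).")
  }
  (height_cm^2 / resistance_ohm) * 0.401 + sex * 3.825 +
    age * (-0.071) + 5.102
}

#' Relative change between two timepoints
#'
#' `100 * (followup - post) / post`, the per-participant percent change used
#' throughout the package.
#'
#' @param post Value at the earlier timepoint (non-zero).
#' @param followup Value at the later timepoint.
#' @return Percent change.
#' @examples
#' relative_change(100, 90) # -10
#' @export
relative_change <- function(post, followup) {
  if (any(post == 0, na.rm = TRUE)) {
    abort("Relative change is undefined when `post` is 0.")
  }
  100 * (followup - post) / post
}

#' Descriptive summary of phenotypes by group, sex and timepoint
#'
#' Mean and SD of post-training values, follow-up values and relative
#' changes within each group x sex stratum, in the layout of a descriptive
#' cohort table. Strata with a single participant get `NA` SD; empty strata
#' are kept as explicit rows with `n = 0` rather than silently dropped.
#'
#' @param phenotypes Phenotype table (`id`, `phenotype`, `post_value`,
#'   `followup_value`, `relative_change`).
#' @param participants Cohort tibble with `id`, `group`, `sex`.
#' @return Tibble with one row per phenotype x group x sex and columns
#'   `n`, `post_mean`, `post_sd`, `followup_mean`, `followup_sd`,
#'   `change_mean`, `change_sd`.
#' @export
summarize_phenotypes <- function(phenotypes, participants) {
  if (nrow(phenotypes) == 0) abort("`phenotypes` is empty.")
  joined <- dplyr::inner_join(
    phenotypes, dplyr::select(participants, "id", "group", "sex"),
    by = "id"
  )
  filled <- tidyr::expand_grid(
    phenotype = unique(phenotypes$phenotype),
    group = unique(participants$group),
    sex = unique(participants$sex)
  )
  out <- joined |>
    dplyr::group_by(.data$phenotype, .data$group, .data$sex) |>
    dplyr::summarise(
      n = dplyr::n(),
      post_mean = mean(.data$post_value),
      post_sd = sd(.data$post_value),
      followup_mean = mean(.data$followup_value),
      followup_sd = sd(.data$followup_value),
      change_mean = mean(.data$relative_change),
      change_sd = sd(.data$relative_change),
      .groups = "drop"
    )
  out <- dplyr::left_join(filled, out,
    by = c("phenotype", "group", "sex")
  )
  out$n[is.na(out$n)] <- 0L
  out
}

# two-way (sex x group) Type-III ANOVA p-values on a response vector;
# factors with < 2 levels are dropped from the model, and a zero-variance
# response yields NA p-values rather than an error
two_way_p <- function(value, sex, group) {
  df <- data.frame(value = value, sex = factor(sex), group = factor(group))
  terms <- c(
    if (nlevels(df$sex) > 1) "sex",
    if (nlevels(df$group) > 1) "group"
  )
  if (length(terms) == 0 || sd(value) < 1e-12) {
    return(c(group = NA_real_, sex = NA_real_, `sex:group` = NA_real_))
  }
  rhs <- paste(terms, collapse = " * ")
  fit <- lm(
    as.formula(paste("value ~", rhs)),
    data = df,
    contrasts = stats::setNames(
      rep(list("contr.sum"), length(terms)), terms
    )
  )
  a3 <- car::Anova(fit, type = 3)
  p <- a3[["Pr(>F)"]]
  names(p) <- rownames(a3)
  c(
    group = unname(p["group"]),
    sex = unname(p["sex"]),
    `sex:group` = unname(p["sex:group"])
  )
}

#' Group, sex and time comparisons of phenotypes
#'
#' Reproduces the comparison layout of a two-group training study: at each
#' timepoint a two-way ANOVA with sex and group as factors (Type-III tests,
#' sum-to-zero contrasts); the same ANOVA on relative changes; and a
#' two-timepoint repeated-measures decomposition computed on
#' within-participant difference scores, whose intercept tests the time
#' main effect and whose sex/group terms test the time x sex, time x group
#' and time x sex x group interactions (exact for two timepoints).
#' Bonferroni-adjusted pairwise group contrasts are returned per stratum.
#' Participants missing either timepoint are excluded (and listed in the
#' `excluded` attribute).
#'
#' @inheritParams summarize_phenotypes
#' @return Tibble with one row per phenotype: p-values `post_group`,
#'   `post_sex`, `post_sex_group`, `followup_*`, `change_*`, `time`,
#'   `time_sex`, `time_group`, `time_sex_group`. Attribute `"pairwise"`
#'   holds Bonferroni-adjusted group contrasts by sex.
#' @export
compare_groups <- function(phenotypes, participants) {
  joined <- dplyr::inner_join(
    phenotypes,
    dplyr::select(participants, "id", "group", "sex"),
    by = "id"
  )
  complete <- !is.na(joined$post_value) & !is.na(joined$followup_value)
  excluded <- joined$id[!complete]
  joined <- joined[complete, ]
  if (nrow(joined) == 0) abort("No participants with both timepoints.")

  res <- joined |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::group_modify(function(d, key) {
      post <- two_way_p(d$post_value, d$sex, d$group)
      fol <- two_way_p(d$followup_value, d$sex, d$group)
      chg <- two_way_p(d$relative_change, d$sex, d$group)
      # repeated-measures decomposition via difference scores
      diff <- d$followup_value - d$post_value
      fsex <- factor(d$sex)
      fgrp <- factor(d$group)
      terms <- c(
        if (nlevels(fsex) > 1) "sex",
        if (nlevels(fgrp) > 1) "group"
      )
      if (sd(diff) < 1e-12) {
        # constant within-participant difference: the time effect is exact
        p <- c(
          `(Intercept)` = if (isTRUE(all.equal(mean(diff), 0))) 1 else 0,
          sex = NA_real_, group = NA_real_, `sex:group` = NA_real_
        )
      } else {
        dd <- data.frame(diff = diff, sex = fsex, group = fgrp)
        rhs <- if (length(terms) == 0) "1" else
          paste(terms, collapse = " * ")
        fit <- lm(
          as.formula(paste("diff ~", rhs)),
          data = dd,
          contrasts = stats::setNames(
            rep(list("contr.sum"), length(terms)), terms
          )
        )
        a3 <- car::Anova(fit, type = 3)
        p <- a3[["Pr(>F)"]]
        names(p) <- rownames(a3)
      }
      tibble::tibble(
        post_group = unname(post["group"]), post_sex = unname(post["sex"]),
        post_sex_group = unname(post["sex:group"]),
        followup_group = unname(fol["group"]),
        followup_sex = unname(fol["sex"]),
        followup_sex_group = unname(fol["sex:group"]),
        change_group = unname(chg["group"]),
        change_sex = unname(chg["sex"]),
        change_sex_group = unname(chg["sex:group"]),
        time = unname(p["(Intercept)"]),
        time_sex = unname(p["sex"]),
        time_group = unname(p["group"]),
        time_sex_group = unname(p["sex:group"])
      )
    }) |>
    dplyr::ungroup()

  pairwise <- joined |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$group)) < 2) {
        return(tibble::tibble())
      }
      has_sex <- length(unique(d$sex)) > 1
      rhs <- if (has_sex) "group * sex" else "group"
      fit <- lm(as.formula(paste("relative_change ~", rhs)), data = d)
      em <- emmeans::emmeans(
        fit, if (has_sex) ~ group | sex else ~group
      )
      tibble::as_tibble(summary(
        emmeans::contrast(em, method = "pairwise"),
        adjust = "bonferroni"
      ))
    }) |>
    dplyr::ungroup()

  attr(res, "pairwise") <- pairwise
  attr(res, "excluded") <- unique(excluded)
  res
}
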