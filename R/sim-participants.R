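with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code() else withr::with_seed(as.integer(seed), code())
}

#' Simulate a cohort of older participants
#'
#' Draws participant demographics and bioimpedance measurements for a
#' two-group (FIT / WBV) detraining study. Ages are uniform on the
#' configured range; height, body mass and whole-body BIA resistance come
#' from sex-specific normal distributions whose locations match descriptive
#' statistics typical of community-dwelling adults in their sixties and
#' seventies (women: 161 cm, 68 kg, 575 ohm; men: 174 cm, 80 kg, 465 ohm).
#' Follow-up body mass and resistance are the post-training values perturbed
#' by small relative changes (about +0.2% and 0% on average).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Tibble with one row per participant: `id`, `group`, `sex`
#'   (`"F"`/`"M"`), `sex_code` (M = 1, F = 0), `age`, `height_cm`,
#'   `body_mass_post`, `body_mass_follow`, `bmi_post`, `bmi_follow`,
#'   `resistance_post`, `resistance_follow`.
#' @export
simulate_participants <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_participants
  if (n == 0) {
    return(tibble::tibble(
      id = character(), group = character(), sex = character(),
      sex_code = numeric(), age = numeric(), height_cm = numeric(),
      body_mass_post = numeric(), body_mass_follow = numeric(),
      bmi_post = numeric(), bmi_follow = numeric(),
      resistance_post = numeric(), resistance_follow = numeric()
    ))
  }
  with_optional_seed(seed, function() {
    n_f <- round(n * config$female_prop)
    sex <- sample(rep(c("F", "M"), c(n_f, n - n_f)))
    male <- sex == "M"
    height <- ifelse(male, rnorm(n, 173.7, 6.3), rnorm(n, 160.6, 6.8))
    mass <- ifelse(male, rnorm(n, 80.5, 10.9), rnorm(n, 67.9, 9.3))
    resistance <- ifelse(male, rnorm(n, 465, 45), rnorm(n, 575, 55))
    resistance <- pmax(resistance, 250)
    mass_follow <- mass * (1 + rnorm(n, 0.2, 3) / 100)
    res_follow <- pmax(resistance * (1 + rnorm(n, 0, 2) / 100), 250)
    tibble::tibble(
      id = sprintf("P%03d", seq_len(n)),
      group = rep(c("FIT", "WBV"), c(config$n_fit, config$n_wbv)),
      sex = sex,
      sex_code = as.numeric(male),
      age = runif(n, config$age_range[1], config$age_range[2]),
      height_cm = height,
      body_mass_post = mass,
      body_mass_follow = mass_follow,
      bmi_post = mass / (height / 100)^2,
      bmi_follow = mass_follow / (height / 100)^2,
      resistance_post = resistance,
      resistance_follow = res_follow
    )
  })
}
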