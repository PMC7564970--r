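#' Stepwise selection configuration
#'
#' @param entry Significance level a candidate's partial F-test must beat to
#'   enter the model (default 0.10).
#' @param stay Significance level an included variable must keep to stay
#'   (default 0.05). Must satisfy `0 < stay <= entry < 1`.
#' @param max_steps Cap on entry steps.
#' @param missing_policy `"complete-case"` (default): a participant is
#'   dropped from a given fit only when missing a dosage used by that fit;
#'   `"mean-impute"`: missing dosages are mean-imputed once up front.
#' @return A `stepwise_config` list.
#' @export
stepwise_config <- function(entry = 0.10, stay = 0.05, max_steps = 100,
                            missing_policy = c("complete-case",
                                               "mean-impute")) {
  missing_policy <- match.arg(missing_policy)
  if (!(stay > 0 && stay <= entry && entry < 1)) {
    abort("Need 0 < stay <= entry < 1.")
  }
  if (max_steps < 1) abort("`max_steps` must be at least 1.")
  structure(
    list(entry = entry, stay = stay, max_steps = max_steps,
         missing_policy = missing_policy),
    class = "stepwise_config"
  )
}

# SSE of least squares fit; NULL if rank-deficient in the last column
fit_sse <- function(X, y) {
  fit <- lm.fit(X, y)
  if (anyNA(fit$coefficients[ncol(X)])) {
    return(NULL)
  }
  sum(fit$residuals^2)
}

#' Forward stepwise regression with backward elimination
#'
#' Classical stepwise variable selection of SNP dosages against a change
#' score. At each step the candidate with the smallest partial-F p-value
#' enters if that p-value is below `entry` (ties broken by panel order);
#' after every entry, included variables whose p-value exceeds `stay` are
#' removed one at a time (largest first). The procedure stops when no entry
#' occurs, when the variable just entered is immediately removed again
#' (oscillation), or at `max_steps`. Candidates that are collinear with the
#' included set are skipped and logged.
#'
#' @param change Numeric vector of per-participant relative changes (%).
#' @param dosages Numeric SNP x participant matrix of minor-allele dosages
#'   with SNP ids as rownames (participants in the same order as `change`).
#' @param config A [stepwise_config()].
#' @return Tibble of selected SNPs (`snp_id`, `estimate`, `std_error`,
#'   `p_value`, `step`), with coefficients from the final multivariable
#'   refit on the minor-allele dosage scale. Attributes: `"log"` (step
#'   trace), `"skipped"` (collinear candidates), `"n_used"` (final fit
#'   size).
#' @export
stepwise_select <- function(change, dosages, config = stepwise_config()) {
  if (is.null(rownames(dosages))) {
    abort("`dosages` must carry SNP ids as rownames.")
  }
  if (ncol(dosages) != length(change)) {
    abort("`dosages` columns must match `change` participants.")
  }
  if (sum(!is.na(change)) < 10) {
    abort("Need at least 10 participants with non-missing change.")
  }
  D <- t(dosages) # participant x SNP
  if (config$missing_policy == "mean-impute") {
    for (j in seq_len(ncol(D))) {
      mi <- is.na(D[, j])
      if (any(mi)) D[mi, j] <- mean(D[!mi, j])
    }
  }
  snps <- colnames(D)
  included <- character()
  skipped <- character()
  log <- character()
  just_entered <- NA_character_

  for (step in seq_len(config$max_steps)) {
    candidates <- setdiff(snps, c(included, skipped))
    if (length(candidates) == 0) break
    X_inc <- cbind(`(Intercept)` = 1, D[, included, drop = FALSE])
    p_cand <- rep(NA_real_, length(candidates))
    for (k in seq_along(candidates)) {
      xj <- D[, candidates[k]]
      rows <- !is.na(change) & !is.na(xj) & complete.cases(X_inc)
      n_k <- sum(rows)
      p_full <- ncol(X_inc) + 1
      if (n_k <= p_full) next
      sse_full <- fit_sse(cbind(X_inc[rows, , drop = FALSE], xj[rows]),
                          change[rows])
      if (is.null(sse_full)) {
        skipped <- c(skipped, candidates[k])
        log <- c(log, paste0("skip collinear candidate ", candidates[k]))
        next
      }
      sse_red <- sum(lm.fit(X_inc[rows, , drop = FALSE],
                            change[rows])$residuals^2)
      f <- (sse_red - sse_full) / (sse_full / (n_k - p_full))
      p_cand[k] <- pf(f, 1, n_k - p_full, lower.tail = FALSE)
    }
    if (all(is.na(p_cand)) || min(p_cand, na.rm = TRUE) >= config$entry) {
      break
    }
    best <- candidates[which.min(p_cand)]
    included <- c(included, best)
    just_entered <- best
    log <- c(log, sprintf("step %d: enter %s (p = %.3g)", step, best,
                          min(p_cand, na.rm = TRUE)))

    # backward elimination at the stay level
    oscillated <- FALSE
    repeat {
      if (length(included) == 0) break
      Xi <- D[, included, drop = FALSE]
      rows <- !is.na(change) & complete.cases(Xi)
      fit <- lm(change[rows] ~ Xi[rows, , drop = FALSE])
      ct <- summary(fit)$coefficients
      # rows of ct after the intercept correspond to `included`, in order
      p_inc <- ct[-1, 4]
      if (length(p_inc) == 0 || max(p_inc) <= config$stay) break
      worst <- included[which.max(p_inc)]
      included <- setdiff(included, worst)
      log <- c(log, sprintf("step %d: remove %s (p = %.3g)", step, worst,
                            max(p_inc)))
      if (identical(worst, just_entered)) {
        oscillated <- TRUE
        break
      }
    }
    if (oscillated) {
      log <- c(log, "stop: entering variable was removed again")
      break
    }
  }

  if (length(included) == 0) {
    out <- tibble::tibble(
      snp_id = character(), estimate = numeric(), std_error = numeric(),
      p_value = numeric(), step = integer()
    )
    attr(out, "log") <- log
    attr(out, "skipped") <- skipped
    attr(out, "n_used") <- 0L
    return(out)
  }

  Xi <- D[, included, drop = FALSE]
  rows <- !is.na(change) & complete.cases(Xi)
  fit <- lm(change[rows] ~ Xi[rows, , drop = FALSE])
  ct <- summary(fit)$coefficients[-1, , drop = FALSE]
  out <- tibble::tibble(
    snp_id = included,
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    p_value = unname(ct[, 4]),
    step = match(included, included)
  )
  attr(out, "log") <- log
  attr(out, "skipped") <- skipped
  attr(out, "n_used") <- sum(rows)
  out
}
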