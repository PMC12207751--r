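## Abundance inference: whole-area prediction under standardized survey
## conditions, per-cell CV, winsorised percentile-bootstrap CI and the
## 80/20 cross-validation harness.

#' Build the whole-area prediction table
#'
#' Covariates for every sea cell of the world under the standardized
#' prediction conditions: dynamic fields averaged across survey years at
#' the chosen Julian-day window, Beaufort sea state 0, survey altitude
#' "low", and any Box-Cox transform re-applied with the lambda stored from
#' the training table (never re-estimated).
#'
#' @param world a `dsm_world`.
#' @param training_covariates the (possibly [auto_boxcox()]-transformed)
#'   covariate table used for fitting; its stored transforms are reused.
#' @param colonies optional colony table (needed when the model uses the
#'   proximity score).
#' @param julian_day prediction day; default 195, the median survey day of
#'   a May-September season.
#' @return data.frame over sea cells with all model covariates,
#'   `julian_day`, `mean_ss = 0`, `altitude = "low"`.
#' @export
build_prediction_grid <- function(world, training_covariates = NULL,
                                  colonies = NULL, julian_day = 195) {
  tab <- build_covariates(world, colonies = colonies, year = "mean")
  tab$julian_day <- julian_day
  tab$mean_ss <- 0
  tab$altitude <- "low"
  if (!is.null(training_covariates) &&
      !is.null(attr(training_covariates, "boxcox")))
    tab <- reapply_boxcox(training_covariates, tab)
  tab
}

#' Total abundance with per-cell coefficient of variation
#'
#' Predicts the expected number of individuals in every prediction cell
#' with the full cell area as effort offset (density times area), sums and
#' rounds to the nearest whole number, and attaches the per-cell CV from
#' the link-scale standard error (delta method: CV of the response equals
#' the SE of the linear predictor).
#'
#' @param fit a [dsm_gam()] fit.
#' @param prediction_table output of [build_prediction_grid()].
#' @param cell_area_km2 full-cell offset (default 16 km^2 for a 4 km grid).
#' @return a `dsm_abundance`: `total` (rounded), `total_unrounded`,
#'   `cell_pred`, `cell_cv`, `prediction_table` row order preserved.
#' @export
estimate_total <- function(fit, prediction_table, cell_area_km2 = 16) {
  pr <- predict(fit, prediction_table, offset_km2 = cell_area_km2,
                se = TRUE, extrapolate = TRUE)
  structure(list(total = round(sum(pr$fit)),
                 total_unrounded = sum(pr$fit),
                 cell_pred = pr$fit,
                 cell_cv = pr$se_link,
                 cell_area_km2 = cell_area_km2,
                 n_cells = nrow(prediction_table)),
            class = "dsm_abundance")
}

#' @export
print.dsm_abundance <- function(x, ...) {
  cat(sprintf("Predicted abundance: %d individuals over %d cells (median CV %.2f)\n",
              x$total, x$n_cells, stats::median(x$cell_cv)))
  if (!is.null(x$ci))
    cat(sprintf("95%% bootstrap CI: %.0f - %.0f (B = %d, %d failures)\n",
                x$ci[1], x$ci[2], x$B, x$n_failed))
  invisible(x)
}

#' Winsorise counts at an upper percentile
#'
#' Caps values above the interpolated (type-7) `upper_percentile` quantile
#' at that quantile, leaving all other values (and their ranks) unchanged.
#' Applied to the observed counts before bootstrapping so extreme flocks do
#' not destabilize the resampled abundance estimates.
#'
#' @param counts non-negative numeric vector.
#' @param upper_percentile cap percentile (default 97.5).
#' @return the capped vector.
#' @export
winsorise <- function(counts, upper_percentile = 97.5) {
  if (length(counts) == 0) stop_param("empty input")
  cap <- quantile7(counts, upper_percentile / 100)
  pmin(counts, cap)
}

#' Winsorised percentile bootstrap CI for total abundance
#'
#' Resamples the surveyed (cell x pass) rows with replacement, refits the
#' final model structure (fixed term set; smoothing parameters re-estimated
#' each time, dispersion held at the point fit's value), predicts the
#' whole-area total, and returns the percentile interval of the `B`
#' totals. Counts are winsorised once before resampling. Replicates that
#' fail to fit are dropped and counted; more than 20% failures is an
#' error. With `method = "parametric"` the refits are replaced by
#' multivariate-normal draws of the coefficients from the fitted
#' covariance (much cheaper, no resampling of rows).
#'
#' @param fit the final [dsm_gam()] fit.
#' @param records the model frame used to fit it.
#' @param prediction_table whole-area covariates from
#'   [build_prediction_grid()].
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param winsor_percentile cap for [winsorise()].
#' @param method `"refit"` (nonparametric, default) or `"parametric"`.
#' @param cell_area_km2 prediction offset per cell.
#' @return a `dsm_abundance` as from [estimate_total()] with `ci`, `B`,
#'   `n_failed` and the vector `boot_totals` attached.
#' @export
bootstrap_ci <- function(fit, records, prediction_table, B = 1000, seed = 1,
                         level = 0.95, winsor_percentile = 97.5,
                         method = c("refit", "parametric"),
                         cell_area_km2 = 16) {
  method <- match.arg(method)
  if (B < 100) stop_param("B must be >= 100")
  est <- estimate_total(fit, prediction_table, cell_area_km2)
  alpha <- (1 - level) / 2
  with_seed(seed, {
    if (method == "parametric") {
      Xp <- prediction_design(fit, prediction_table)
      L <- chol(fit$cov_beta + diag(1e-12, ncol(Xp)))
      Z <- matrix(stats::rnorm(B * ncol(Xp)), B)
      Bmat <- Z %*% L
      totals <- as.vector(exp(sweep(Bmat %*% t(Xp), 2,
                                    drop(Xp %*% fit$beta), "+") +
                                log(cell_area_km2)) %*% rep(1, nrow(Xp)))
      n_failed <- 0L
    } else {
      rec <- records
      rec[[fit$response]] <- as.integer(round(
        winsorise(rec[[fit$response]], winsor_percentile)))
      totals <- rep(NA_real_, B)
      for (b in seq_len(B)) {
        idx <- sample.int(nrow(rec), replace = TRUE)
        ft <- tryCatch(
          dsm_gam(rec[idx, , drop = FALSE], smooths = fit$smooth_specs,
                  para = fit$para, response = fit$response,
                  offset = fit$offset_name, family = fit$family,
                  theta = fit$theta, gamma = fit$gamma),
          error = function(e) NULL)
        if (is.null(ft)) next
        totals[b] <- tryCatch(
          sum(predict(ft, prediction_table, offset_km2 = cell_area_km2,
                      extrapolate = TRUE)),
          error = function(e) NA_real_)
      }
      n_failed <- sum(!is.finite(totals))
      if (n_failed > 0.2 * B)
        stop_param("more than 20% of bootstrap replicates failed (",
                   n_failed, "/", B, ")")
      totals <- totals[is.finite(totals)]
    }
    ci <- c(quantile7(totals, alpha), quantile7(totals, 1 - alpha))
    if (est$total_unrounded < ci[1] || est$total_unrounded > ci[2])
      message("point estimate falls outside the percentile interval ",
              "(a known property of skewed bootstrap distributions)")
    est$ci <- ci; est$B <- B; est$n_failed <- n_failed
    est$boot_totals <- totals
    est
  })
}

#' 80/20 cross-validation of the abundance model
#'
#' Randomly splits the surveyed rows into training (80%) and test (20%)
#' sets `n_iter` times; each iteration refits the model structure on the
#' training rows, predicts the expected counts of the test rows with their
#' own effort offsets, and compares total predicted with total observed
#' abundance.
#'
#' @param fit the final [dsm_gam()] fit (defines the model structure).
#' @param records the model frame.
#' @param n_iter iterations (default 100).
#' @param frac training fraction (default 0.8).
#' @param seed integer seed.
#' @return a `dsm_validation`: per-iteration `predicted`, `observed` and
#'   `rel_error`, the shares within 5% and 10%, `median_abs_rel_error`,
#'   mean signed relative error `bias`, and `n_failed`.
#' @export
validate_split <- function(fit, records, n_iter = 100, frac = 0.8, seed = 1) {
  n <- nrow(records)
  if (n < 50) stop_param("need at least 50 surveyed rows to validate")
  n_train <- round(frac * n)
  with_seed(seed, {
    pred <- obs <- rep(NA_real_, n_iter)
    for (it in seq_len(n_iter)) {
      tr <- sample.int(n, n_train)
      te <- setdiff(seq_len(n), tr)
      ft <- tryCatch(
        dsm_gam(records[tr, , drop = FALSE], smooths = fit$smooth_specs,
                para = fit$para, response = fit$response,
                offset = fit$offset_name, family = fit$family,
                theta = fit$theta, gamma = fit$gamma),
        error = function(e) NULL)
      if (is.null(ft)) next
      mu <- tryCatch(predict(ft, records[te, , drop = FALSE],
                             extrapolate = TRUE),
                     error = function(e) NULL)
      if (is.null(mu)) next
      pred[it] <- sum(mu)
      obs[it] <- sum(records[[fit$response]][te])
    }
    ok <- is.finite(pred) & obs > 0
    rel <- (pred[ok] - obs[ok]) / obs[ok]
    structure(list(predicted = pred, observed = obs, rel_error = rel,
                   share_within_5 = mean(abs(rel) <= 0.05),
                   share_within_10 = mean(abs(rel) <= 0.10),
                   median_abs_rel_error = stats::median(abs(rel)),
                   bias = mean(rel), n_iter = n_iter,
                   n_failed = sum(!is.finite(pred))),
              class = "dsm_validation")
  })
}

#' @export
print.dsm_validation <- function(x, ...) {
  cat(sprintf(paste0("Validation over %d iterations (%d failed):\n",
                     "  within 5%%: %.0f%%   within 10%%: %.0f%%\n",
                     "  median |relative error|: %.1f%%   mean bias: %+.1f%%\n"),
              x$n_iter, x$n_failed, 100 * x$share_within_5,
              100 * x$share_within_10, 100 * x$median_abs_rel_error,
              100 * x$bias))
  invisible(x)
}
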