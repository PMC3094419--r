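# Model validation: internal leave-one-out cross-validation, external
# cross-campaign validation of a frozen model, prediction-vs-prediction
# comparison, and residual diagnostics (overall, by site type, and in the top
# concentration quartile, where both LUR and dispersion models tend to
# underestimate hot-spot concentrations).

#' Build a validation report from observed/predicted pairs
#'
#' R^2 is the squared Pearson correlation between observed and predicted (the
#' scatter-plot definition); `r2_1to1` additionally reports variance explained
#' against the identity line (`1 - SSE/SST`).
#'
#' @param observed,predicted numeric vectors.
#' @param site_types optional factor/character of site types.
#' @return a `validation_report` list.
#' @export
validation_report <- function(observed, predicted, site_types = NULL) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  r2 <- if (stats::sd(predicted) == 0) 0 else stats::cor(observed, predicted)^2
  fit <- stats::lm(observed ~ predicted)
  resid_mean <- mean(observed - predicted)
  by_type <- NULL
  if (!is.null(site_types)) {
    by_type <- tapply(observed - predicted, site_types, mean)
    by_type <- by_type[!is.na(by_type)]
  }
  structure(list(r2 = unname(r2),
                 r2_1to1 = 1 - sum((observed - predicted)^2) /
                   sum((observed - mean(observed))^2),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 mean_residual = resid_mean,
                 mean_residual_by_type = by_type,
                 n = length(observed),
                 observed = observed, predicted = predicted),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (n = %d)\n", x$n))
  cat(sprintf("  R2 (Pearson^2) = %.3f   R2 (1:1 line) = %.3f\n", x$r2, x$r2_1to1))
  cat(sprintf("  observed ~ predicted: slope %.3f, intercept %.2f\n",
              x$slope, x$intercept))
  cat(sprintf("  mean residual = %.2f ug/m3\n", x$mean_residual))
  invisible(x)
}

#' Leave-one-out cross-validation of a fixed variable set
#'
#' For each site the coefficients are refit on the remaining n-1 sites and the
#' held-out site is predicted; the selection path is not re-run per fold (the
#' variable set is frozen).
#'
#' @param y response vector.
#' @param table predictor table.
#' @param variables selected model columns.
#' @param site_types optional site types for the residual breakdown.
#' @return a `validation_report` over the held-out pairs.
#' @export
loocv <- function(y, table, variables, site_types = NULL) {
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_ols(y[-i], table[-i, , drop = FALSE], variables)
    co <- stats::coef(fit)
    co[is.na(co)] <- 0  # aliased in this fold (e.g., a column constant on n-1 sites)
    p <- co[1]
    for (v in variables) {
      p <- p + co[match(make.names(v), make.names(names(co)))] * table[[v]][i]
    }
    pred[i] <- p
  }
  validation_report(y, pred, site_types)
}

#' External validation of a frozen model on another campaign
#'
#' Predictions from the fitted model (no refitting) are scored against the
#' other campaign's observed annual means.
#'
#' @param model a `lur_model`.
#' @param y_other observed annual means of the other campaign.
#' @param table_other the other campaign's predictor table.
#' @param site_types optional site types.
#' @return a `validation_report`.
#' @export
external_validate <- function(model, y_other, table_other, site_types = NULL) {
  validation_report(y_other, predict(model, table_other), site_types)
}

#' Compare two prediction vectors
#'
#' @param pred_a,pred_b numeric vectors of predictions at the same sites.
#' @return list with `r2` (squared Pearson, symmetric), `slope` (OLS of b on
#'   a) and `mean_difference` (`mean(b - a)`).
#' @export
compare_predictions <- function(pred_a, pred_b) {
  r2 <- if (stats::sd(pred_a) == 0 || stats::sd(pred_b) == 0) 0 else
    stats::cor(pred_a, pred_b)^2
  list(r2 = unname(r2),
       slope = unname(stats::coef(stats::lm(pred_b ~ pred_a))[2]),
       mean_difference = mean(pred_b - pred_a))
}

#' Residual summary with hot-spot diagnostics
#'
#' Mean residual (observed minus predicted) overall, per site type, and within
#' the top quartile of observed concentrations.
#'
#' @param observed,predicted numeric vectors.
#' @param site_types factor/character of site types.
#' @return list with `overall`, `by_type`, `top_quartile`.
#' @export
residual_summary <- function(observed, predicted, site_types) {
  res <- observed - predicted
  hi <- observed >= stats::quantile(observed, 0.75)
  list(overall = mean(res),
       by_type = tapply(res, site_types, mean),
       top_quartile = mean(res[hi]))
}
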