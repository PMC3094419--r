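# Multiple imputation of missing period concentrations by chained equations:
# each period column is imputed by Bayesian normal linear regression on the
# other period columns plus site-type indicators, swept a fixed number of
# times; m independent completed tables are drawn. Regression parameters
# fitted per completed table are pooled by Rubin's rules.

# One Bayesian linear-regression draw: posterior draw of (beta, sigma^2) under
# the standard noninformative prior, then predictive draws at Xmis.
bayes_lm_draw <- function(Xobs, yobs, Xmis) {
  qr_ <- qr(Xobs)
  keep <- qr_$pivot[seq_len(qr_$rank)]
  Xo <- Xobs[, keep, drop = FALSE]
  Xm <- Xmis[, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yobs)
  p <- ncol(Xo)
  df <- max(1L, length(yobs) - p)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / stats::rchisq(1, df)
  XtXi <- chol2inv(chol(crossprod(Xo) + diag(1e-10, p)))
  beta <- fit$coefficients + t(chol(sigma2 * XtXi + diag(1e-14, p))) %*%
    stats::rnorm(p)
  as.numeric(Xm %*% beta + stats::rnorm(nrow(Xm)) * sqrt(sigma2))
}

#' Multiply impute missing period concentrations
#'
#' Chained-equations scheme with a Bayesian normal linear model per period
#' column, conditioning on the other periods and site-type dummies. Observed
#' cells are never touched; missing cells are initialised at the column
#' observed mean and updated over `sweeps` passes; `m` independent completed
#' tables are produced.
#'
#' @param table campaign table with `period_*` columns and `site_type`.
#' @param m number of imputations (default 10).
#' @param sweeps chained-equation passes per imputation (default 10).
#' @param seed integer seed (optional).
#' @return an `imputed_campaign`: list with `m`, `tables` (completed tables),
#'   `missing` (logical matrix of originally missing cells).
#' @export
impute_missing <- function(table, m = 10, sweeps = 10, seed = NULL) {
  if (m < 2) stop_config("need at least m = 2 imputations")
  cols <- period_columns(table)
  Y0 <- as.matrix(table[, cols, drop = FALSE])
  miss <- is.na(Y0)
  if (any(colSums(!miss) == 0L))
    stop_config("a period column is fully missing; cannot impute")
  if (any(rowSums(!miss) == 0L))
    stop_config("a site has no observed period; cannot impute")
  st <- droplevels(factor(table$site_type))
  dummies <- if (nlevels(st) >= 2) {
    stats::model.matrix(~ st)[, -1, drop = FALSE]
  } else matrix(numeric(0), nrow(table), 0)
  with_seed(seed, {
    tables <- vector("list", m)
    for (imp in seq_len(m)) {
      Y <- Y0
      for (j in seq_len(ncol(Y))) {
        Y[miss[, j], j] <- mean(Y0[!miss[, j], j])
      }
      if (any(miss)) {
        for (s in seq_len(sweeps)) {
          for (j in which(colSums(miss) > 0L)) {
            X <- cbind(1, Y[, -j, drop = FALSE], dummies)
            Y[miss[, j], j] <- bayes_lm_draw(X[!miss[, j], , drop = FALSE],
                                             Y[!miss[, j], j],
                                             X[miss[, j], , drop = FALSE])
          }
        }
      }
      tab <- table
      tab[, cols] <- Y
      tables[[imp]] <- tab
    }
    structure(list(m = m, tables = tables, missing = miss,
                   period_cols = cols),
              class = "imputed_campaign")
  })
}

#' Per-imputation annual means
#'
#' Unweighted mean over periods, per site and per imputation, plus the
#' across-imputation mean used as the working annual estimate.
#'
#' @param campaign an `imputed_campaign`.
#' @return data frame `id, imp_1..imp_m, mean`.
#' @export
annual_means <- function(campaign) {
  cols <- campaign$period_cols
  mat <- vapply(campaign$tables, function(tab) {
    rowMeans(as.matrix(tab[, cols, drop = FALSE]))
  }, numeric(nrow(campaign$tables[[1]])))
  colnames(mat) <- sprintf("imp_%d", seq_len(campaign$m))
  data.frame(id = campaign$tables[[1]]$id, mat, mean = rowMeans(mat),
             stringsAsFactors = FALSE)
}

#' Pool regression fits across imputations by Rubin's rules
#'
#' For each parameter: pooled estimate is the mean of the per-imputation
#' estimates; within-imputation variance W is the mean squared SE; between
#' variance B is the sample variance of the estimates; total variance
#' T = W + (1 + 1/m) B. Degrees of freedom use the Barnard-Rubin small-sample
#' formula when the complete-data df is supplied.
#'
#' @param fits list of per-imputation fits, each a list with named numeric
#'   `estimate` and `se` (or `lm` objects, from which both are extracted).
#' @param dfcom complete-data residual degrees of freedom (optional).
#' @return a `pooled_fit` data frame: `term, estimate, W, B, T, se, df, p`.
#' @export
pool_estimates <- function(fits, dfcom = NULL) {
  fits <- lapply(fits, function(f) {
    if (inherits(f, "lm")) {
      s <- summary(f)$coefficients
      list(estimate = s[, 1], se = s[, 2])
    } else f
  })
  m <- length(fits)
  if (m < 2) stop_config("need fits from at least 2 imputations")
  est <- do.call(rbind, lapply(fits, function(f) f$estimate))
  ses <- do.call(rbind, lapply(fits, function(f) f$se))
  qbar <- colMeans(est)
  W <- colMeans(ses^2)
  B <- apply(est, 2, stats::var)
  Tv <- W + (1 + 1 / m) * B
  lambda <- (1 + 1 / m) * B / ifelse(Tv > 0, Tv, 1)
  df_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
  if (!is.null(dfcom)) {
    nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- ifelse(is.finite(df_old), 1 / (1 / df_old + 1 / nu_obs), nu_obs)
  } else df <- df_old
  se <- sqrt(Tv)
  tstat <- ifelse(se > 0, qbar / se, Inf)
  p <- ifelse(is.finite(df),
              2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
              2 * stats::pnorm(abs(tstat), lower.tail = FALSE))
  structure(data.frame(term = colnames(est) %||% sprintf("b%d", seq_along(qbar)),
                       estimate = qbar, W = W, B = B, T = Tv, se = se,
                       df = df, p = p, row.names = NULL),
            class = c("pooled_fit", "data.frame"))
}
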