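# Supervised forward-selection land-use regression. Candidate predictors are
# organised in four ordered groups (traffic; traffic-related land use;
# population-density-related land use; other land use), each variable belongs
# to a family (e.g., one land-use category across its buffer radii) with a
# declared coefficient sign. Selection proceeds group by group: within a
# group, the best variant per family (highest univariate R^2) is offered in
# univariate-R^2 order and kept only if the adjusted R^2 improves by at least
# `delta` percentage points and every coefficient in the augmented model keeps
# its declared sign. An a priori term (the regional background, for the
# large-area configuration) is entered first and never removed. The final
# model is backward-pruned: variables with the highest p-value are dropped one
# at a time while the adjusted R^2 changes by less than `delta` points.

#' Variable plan for supervised selection
#'
#' Normally derived from the predictor table's column dictionary; can be
#' built by hand for custom tables.
#'
#' @param table a predictor table with a `"dictionary"` attribute, or `NULL`.
#' @param columns,family,group,sign,scale vectors defining the plan directly
#'   when `table` is `NULL`.
#' @return a `variable_plan` data frame with columns
#'   `column, family, group, sign, scale`.
#' @export
variable_plan <- function(table = NULL, columns = NULL, family = NULL,
                          group = NULL, sign = NULL, scale = NULL) {
  if (!is.null(table)) {
    dict <- attr(table, "dictionary")
    if (is.null(dict)) stop_config("table has no column dictionary; supply a plan")
    plan <- dict
  } else {
    plan <- data.frame(column = columns, family = family, group = as.integer(group),
                       sign = sign,
                       scale = if (is.null(scale)) NA_real_ else scale,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(plan$sign %in% c(-1, 1)))
  structure(plan, class = c("variable_plan", "data.frame"))
}

#' Univariate R-squared
#'
#' Squared Pearson correlation between the response and a single predictor
#' (equal to the R^2 of the simple linear regression). Zero-variance
#' predictors score 0.
#'
#' @param y response vector.
#' @param x predictor vector.
#' @return proportion in `[0, 1]`.
#' @export
univariate_r2 <- function(y, x) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(y, x)^2
}

#' Best variant within a predictor family
#'
#' Among the family's buffer/cutoff variants, the column with the highest
#' univariate R^2; ties are broken in favour of the smallest radius/cutoff
#' (preferring the more local variable), then by column name.
#'
#' @param y response vector.
#' @param table predictor table.
#' @param plan a [variable_plan()].
#' @param family family id.
#' @return the selected column name.
#' @export
select_best_per_family <- function(y, table, plan, family) {
  rows <- plan[plan$family == family, , drop = FALSE]
  if (nrow(rows) == 0L) stop_config("unknown family '%s'", family)
  r2 <- vapply(rows$column, function(cn) univariate_r2(y, table[[cn]]), numeric(1))
  scl <- ifelse(is.na(rows$scale), Inf, rows$scale)
  ord <- order(-r2, scl, rows$column)
  rows$column[ord[1]]
}

adj_r2 <- function(fit) summary(fit)$adj.r.squared

fit_ols <- function(y, table, vars) {
  df <- data.frame(.y = y, table[, vars, drop = FALSE], check.names = FALSE)
  stats::lm(.y ~ ., data = df)
}

signs_ok <- function(fit, vars, sign_map) {
  co <- stats::coef(fit)[-1]
  names(co) <- vars
  all(!is.na(co) & sign(co) == sign_map[vars])
}

#' Supervised forward selection
#'
#' @param y response (site annual mean concentrations).
#' @param table predictor table (no missing cells among candidate columns).
#' @param plan a [variable_plan()].
#' @param a_priori character vector of columns entered first and never removed
#'   (e.g., `"background_no2"`).
#' @param delta required adjusted-R^2 improvement in percentage points
#'   (default 1).
#' @param rank_on_residual rank candidates on the residual from the a priori
#'   model instead of the raw response (default `FALSE`).
#' @return a `lur_model`: selected variables in order, coefficients, fit
#'   statistics, the selection trace, and the fitting data.
#' @export
forward_build <- function(y, table, plan = variable_plan(table),
                          a_priori = character(), delta = 1.0,
                          rank_on_residual = FALSE) {
  sign_map <- stats::setNames(plan$sign, plan$column)
  sign_map[a_priori[!(a_priori %in% names(sign_map))]] <- 1
  selected <- a_priori
  fit <- if (length(selected)) fit_ols(y, table, selected) else
    stats::lm(y ~ 1)
  current_adj <- if (length(selected)) adj_r2(fit) else 0
  y_rank <- if (rank_on_residual && length(selected)) stats::resid(fit) else y
  trace <- list()
  note <- function(cand, dadj, sign_ok, verdict) {
    trace[[length(trace) + 1L]] <<- data.frame(
      candidate = cand, delta_adj_r2 = dadj, sign_ok = sign_ok,
      verdict = verdict, stringsAsFactors = FALSE)
  }
  groups <- sort(unique(plan$group[plan$group > 0L]))
  for (g in groups) {
    fams <- unique(plan$family[plan$group == g])
    cands <- vapply(fams, function(f) select_best_per_family(y_rank, table, plan, f),
                    character(1))
    cands <- setdiff(cands, selected)
    r2 <- vapply(cands, function(cn) univariate_r2(y_rank, table[[cn]]), numeric(1))
    for (cand in cands[order(-r2)]) {
      vars_new <- c(selected, cand)
      if (length(y) <= length(vars_new) + 1L) {
        warning(sprintf("skipping '%s': n <= p", cand))
        note(cand, NA_real_, NA, "skipped_n_le_p")
        next
      }
      fit_new <- fit_ols(y, table, vars_new)
      dadj <- adj_r2(fit_new) - current_adj
      ok_sign <- signs_ok(fit_new, vars_new, sign_map)
      if (dadj >= delta / 100 && ok_sign) {
        selected <- vars_new
        fit <- fit_new
        current_adj <- adj_r2(fit)
        note(cand, dadj, ok_sign, "accepted")
      } else {
        note(cand, dadj, ok_sign, "rejected")
      }
    }
  }
  new_lur_model(y, table, selected, a_priori, fit, plan, sign_map,
                do.call(rbind, trace) %||% data.frame())
}

new_lur_model <- function(y, table, selected, a_priori, fit, plan, sign_map, trace) {
  sm <- summary(fit)
  structure(list(variables = selected, a_priori = a_priori,
                 coefficients = stats::coef(fit),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 sigma = sm$sigma, fit = fit, plan = plan,
                 sign_map = sign_map, trace = trace,
                 data = table, y = y),
            class = "lur_model")
}

#' Backward pruning of a fitted LUR model
#'
#' Repeatedly removes the non-a-priori variable with the highest p-value as
#' long as its removal changes the adjusted R^2 by less than `delta`
#' percentage points; the reduced model is preferred. A priori variables are
#' never removed.
#'
#' @param model a `lur_model`.
#' @param delta adjusted-R^2 change threshold in percentage points.
#' @return the pruned `lur_model`.
#' @export
backward_prune <- function(model, delta = 1.0) {
  y <- model$y
  table <- model$data
  selected <- model$variables
  fit <- model$fit
  repeat {
    removable <- setdiff(selected, model$a_priori)
    if (length(removable) == 0L) break
    sm <- summary(fit)$coefficients
    pvals <- sm[match(make.names(removable), make.names(rownames(sm))), 4]
    worst <- removable[which.max(pvals)]
    reduced <- setdiff(selected, worst)
    fit_red <- if (length(reduced)) fit_ols(y, table, reduced) else stats::lm(y ~ 1)
    change <- abs(adj_r2(fit) - (if (length(reduced)) adj_r2(fit_red) else 0))
    if (change < delta / 100) {
      selected <- reduced
      fit <- fit_red
    } else break
  }
  new_lur_model(y, table, selected, model$a_priori, fit, model$plan,
                model$sign_map, model$trace)
}

#' Per-IQR effect report
#'
#' Rescales each raw coefficient (and its SE) by the predictor's empirical
#' interquartile range over the fitting sites -- the standard reporting unit
#' for LUR effects. A constant predictor (IQR 0) reports effect 0 with a
#' warning.
#'
#' @param model a `lur_model`.
#' @param table table over which IQRs are computed (default the fitting table).
#' @return data frame `variable, iqr, raw_coef, effect, se, p`.
#' @export
per_iqr_effects <- function(model, table = model$data) {
  sm <- summary(model$fit)$coefficients
  vars <- model$variables
  rows <- lapply(vars, function(v) {
    iqr <- unname(diff(stats::quantile(table[[v]], c(0.25, 0.75), na.rm = TRUE)))
    i <- match(make.names(v), make.names(rownames(sm)))
    if (iqr == 0) warning(sprintf("variable '%s' has IQR 0; effect set to 0", v))
    co <- sm[i, 1]
    eff <- if (iqr == 0 || is.na(co)) 0 else co * iqr
    data.frame(variable = v, iqr = iqr, raw_coef = co,
               effect = eff, se = sm[i, 2] * iqr, p = sm[i, 4],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predict concentrations from a LUR model
#'
#' Plain linear-model evaluation (no truncation). Errors if any model column
#' is absent from `newdata`.
#'
#' @param object a `lur_model`.
#' @param newdata predictor table containing all model columns.
#' @param ... unused.
#' @return numeric vector of predicted concentrations (ug/m3).
#' @export
predict.lur_model <- function(object, newdata = object$data, ...) {
  missing_cols <- setdiff(object$variables, names(newdata))
  if (length(missing_cols) > 0L)
    stop_config("newdata lacks model columns: %s",
                paste(missing_cols, collapse = ", "))
  co <- object$coefficients
  co[is.na(co)] <- 0  # aliased columns contribute nothing
  out <- rep(co[1], nrow(newdata))
  for (v in object$variables) {
    i <- match(make.names(v), make.names(names(co)))
    out <- out + co[i] * newdata[[v]]
  }
  unname(out)
}

#' @export
print.lur_model <- function(x, ...) {
  cat("Land-use regression model\n")
  cat(sprintf("  variables (%d): %s\n", length(x$variables),
              paste(x$variables, collapse = ", ")))
  if (length(x$a_priori))
    cat(sprintf("  a priori: %s\n", paste(x$a_priori, collapse = ", ")))
  cat(sprintf("  R2 = %.3f, adjusted R2 = %.3f, sigma = %.2f\n",
              x$r2, x$adj_r2, x$sigma))
  invisible(x)
}

#' Serialise a LUR model to JSON
#'
#' @param model a `lur_model`.
#' @param path output path.
#' @export
write_lur_json <- function(model, path) {
  obj <- list(variables = model$variables,
              a_priori = model$a_priori,
              coefficients = as.list(model$coefficients),
              r2 = model$r2, adj_r2 = model$adj_r2,
              per_iqr = per_iqr_effects(model),
              trace = model$trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
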