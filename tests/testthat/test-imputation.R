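make_campaign <- function(n = 40, k = 4, noise = 1, seed = 1) {
  set.seed(seed)
  type <- factor(sample(c("traffic", "urban_background", "rural"), n, TRUE,
                        prob = c(0.3, 0.5, 0.2)),
                 levels = lursim:::SITE_TYPES)
  base <- 20 + 8 * (type == "traffic") - 5 * (type == "rural") + rnorm(n, 0, 4)
  obs <- sapply(seq_len(k), function(p) base + rnorm(1, 0, 2) + rnorm(n, 0, noise))
  colnames(obs) <- sprintf("period_%d", seq_len(k))
  cbind(data.frame(id = sprintf("s%03d", seq_len(n)), x = 0, y = 0,
                   site_type = type, protocol = "facade"),
        as.data.frame(obs))
}

test_that("a complete table yields m identical completed tables", {
  tab <- make_campaign()
  imp <- impute_missing(tab, m = 10, seed = 3)
  expect_equal(imp$m, 10)
  for (k in 2:10) expect_identical(imp$tables[[k]], imp$tables[[1]])
  expect_identical(imp$tables[[1]][, imp$period_cols], tab[, imp$period_cols])
})

test_that("completed tables differ only at originally-missing cells", {
  tab <- make_campaign()
  tab <- apply_missingness(tab, 0.15, seed = 9)
  imp <- impute_missing(tab, m = 5, seed = 4)
  obs_mask <- !is.na(as.matrix(tab[, imp$period_cols]))
  for (k in 1:5) {
    comp <- as.matrix(imp$tables[[k]][, imp$period_cols])
    expect_equal(comp[obs_mask], as.matrix(tab[, imp$period_cols])[obs_mask])
    expect_true(all(is.finite(comp)))
  }
})

test_that("noise-free collinear periods impute deterministically with B ~ 0", {
  n <- 30
  set.seed(6)
  base <- rnorm(n, 25, 5)
  tab <- data.frame(id = sprintf("s%02d", 1:n), x = 0, y = 0,
                    site_type = factor("urban_background",
                                       levels = lursim:::SITE_TYPES),
                    protocol = "facade",
                    period_1 = base, period_2 = base + 2, period_3 = base - 1)
  truth <- tab$period_2[5]
  tab$period_2[5] <- NA
  imp <- impute_missing(tab, m = 10, seed = 11)
  vals <- vapply(imp$tables, function(t) t$period_2[5], numeric(1))
  expect_equal(vals, rep(truth, 10), tolerance = 1e-4)
  expect_lt(stats::var(vals), 1e-8)
})

test_that("imputed values are unbiased for the masked truth under the model", {
  errs <- vapply(1:60, function(s) {
    tab <- make_campaign(n = 50, seed = 100 + s)
    full <- as.matrix(tab[, sprintf("period_%d", 1:4)])
    masked <- apply_missingness(tab, 0.10, seed = 200 + s)
    miss <- is.na(as.matrix(masked[, sprintf("period_%d", 1:4)]))
    imp <- impute_missing(masked, m = 4, sweeps = 5, seed = 300 + s)
    imps <- sapply(imp$tables, function(t) {
      mean(as.matrix(t[, sprintf("period_%d", 1:4)])[miss])
    })
    mean(imps) - mean(full[miss])
  }, numeric(1))
  # mean bias across replicates within 3 SE of zero
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(length(errs)))
})

test_that("annual means are plain arithmetic means per imputation", {
  tab <- make_campaign(n = 10, k = 4)
  tab[1, sprintf("period_%d", 1:4)] <- c(10, 20, 30, 40)
  tab[2, sprintf("period_%d", 1:4)] <- 7
  imp <- impute_missing(tab, m = 2, seed = 1)
  ann <- annual_means(imp)
  expect_equal(ann$imp_1[1], 25)
  expect_equal(ann$mean[2], 7)
  # random rows equal an independent recomputation
  expect_equal(ann$imp_2,
               rowMeans(as.matrix(imp$tables[[2]][, sprintf("period_%d", 1:4)])))
})

test_that("Rubin's rules match hand-computed pooled quantities", {
  fits <- list(list(estimate = c(b = 1), se = c(b = 0)),
               list(estimate = c(b = 2), se = c(b = 0)),
               list(estimate = c(b = 3), se = c(b = 0)))
  out <- pool_estimates(fits)
  expect_equal(out$estimate, 2)
  expect_equal(out$W, 0)
  expect_equal(out$B, 1)
  expect_equal(out$T, 4 / 3)
  # identical fits: no between-imputation variance, T = W
  same <- replicate(5, list(estimate = c(a = 1.5, b = -2),
                            se = c(a = 0.3, b = 0.4)), simplify = FALSE)
  out2 <- pool_estimates(same)
  expect_equal(out2$estimate, c(1.5, -2))
  expect_equal(out2$B, c(0, 0))
  expect_equal(out2$T, out2$W)
  expect_equal(out2$W, c(0.09, 0.16))
})

test_that("total variance never falls below the within component", {
  set.seed(23)
  for (i in 1:50) {
    m <- sample(3:10, 1)
    fits <- lapply(seq_len(m), function(k) {
      list(estimate = c(x = rnorm(1), y = rnorm(1)),
           se = c(x = runif(1, 0.1, 2), y = runif(1, 0.1, 2)))
    })
    out <- pool_estimates(fits, dfcom = 50)
    expect_true(all(out$T >= out$W))
    expect_true(all(out$B >= 0))
    expect_true(all(out$df > 0))
  }
})

test_that("with no missing data the pooled fit equals the complete-data fit", {
  tab <- make_campaign(n = 45, seed = 77)
  imp <- impute_missing(tab, m = 3, seed = 5)
  y <- annual_means(imp)
  set.seed(8)
  xtab <- data.frame(x1 = rnorm(45), x2 = rnorm(45))
  fits <- lapply(imp$tables, function(t) {
    stats::lm(rowMeans(as.matrix(t[, sprintf("period_%d", 1:4)])) ~ x1 + x2,
              data = xtab)
  })
  pooled <- pool_estimates(fits, dfcom = 42)
  direct <- stats::lm(y$mean ~ x1 + x2, data = xtab)
  expect_equal(pooled$estimate, unname(coef(direct)), tolerance = 1e-12)
  expect_equal(pooled$B, rep(0, 3))
  expect_equal(sqrt(pooled$W), unname(summary(direct)$coefficients[, 2]),
               tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  tab <- make_campaign(n = 8)
  expect_error(impute_missing(tab, m = 1), "at least m = 2")
  tab$period_1 <- NA_real_
  expect_error(impute_missing(tab, m = 3), "fully missing")
})
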