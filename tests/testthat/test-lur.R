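# Synthetic regression tables with a known dictionary for selection tests.
lur_table <- function(n = 60, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    background_no2 = runif(n, 12, 25),
    traf_a = runif(n, 0, 3e5),
    traf_b = runif(n, 0, 3e5),
    logdist_busy = log(runif(n, 1, 1500)),
    lu_res_300 = runif(n), lu_res_1000 = runif(n),
    lu_green_300 = runif(n), pop_300 = runif(n, 0, 3000))
  plan <- variable_plan(
    columns = c("traf_a", "traf_b", "logdist_busy", "lu_res_300",
                "lu_res_1000", "lu_green_300", "pop_300"),
    family = c("traf_a", "traf_b", "logdist_busy", "lu_res", "lu_res",
               "lu_green", "population"),
    group = c(1, 1, 1, 3, 3, 4, 3),
    sign = c(1, 1, -1, 1, 1, -1, 1),
    scale = c(NA, NA, NA, 300, 1000, 300, 300))
  list(tab = tab, plan = plan)
}

test_that("univariate R2 equals squared Pearson correlation", {
  set.seed(2)
  y <- rnorm(100)
  expect_equal(univariate_r2(y, y), 1.0)
  x <- rnorm(100)
  expect_equal(univariate_r2(y, x), cor(y, x)^2)
  expect_lt(univariate_r2(y, x), 0.1)
  # hand-computed three-point case: r^2 = 81/84
  expect_equal(univariate_r2(c(2, 4, 5), c(1, 2, 3)), 81 / 84, tolerance = 1e-10)
  # zero-variance predictor scores zero instead of NA
  expect_equal(univariate_r2(y, rep(3, 100)), 0)
})

test_that("best-per-family selection takes the arg-max with small-radius ties", {
  f <- lur_table()
  y <- 2 + 10 * f$tab$lu_res_300 + rnorm(60, 0, 0.1)
  expect_equal(select_best_per_family(y, f$tab, f$plan, "lu_res"), "lu_res_300")
  # single-variant family returns that variant
  expect_equal(select_best_per_family(y, f$tab, f$plan, "lu_green"), "lu_green_300")
  # exact tie broken towards the smaller radius
  tab2 <- data.frame(lu_res_300 = f$tab$lu_res_300,
                     lu_res_1000 = f$tab$lu_res_300)
  expect_equal(select_best_per_family(y, tab2, f$plan[4:5, ], "lu_res"),
               "lu_res_300")
})

test_that("a synthetic truth driven by one buffer radius is found among its variants", {
  set.seed(5)
  n <- 80
  shared <- runif(n)
  tab <- data.frame(lu_res_300 = shared + rnorm(n, 0, 0.05),
                    lu_res_1000 = shared + rnorm(n, 0, 0.25),
                    lu_res_5000 = shared + rnorm(n, 0, 0.4))
  plan <- variable_plan(columns = names(tab), family = rep("lu_res", 3),
                        group = rep(3, 3), sign = rep(1, 3),
                        scale = c(300, 1000, 5000))
  y <- 5 + 8 * tab$lu_res_300 + rnorm(n, 0, 0.2)
  expect_equal(select_best_per_family(y, tab, plan, "lu_res"), "lu_res_300")
})

test_that("noise-free forward selection recovers exactly the generating variables", {
  f <- lur_table(seed = 3)
  y <- 4 + 1.0 * f$tab$background_no2 + 3e-5 * f$tab$traf_a
  # the exact fit makes summary.lm warn about perfect residuals; that is the point
  model <- suppressWarnings(
    forward_build(y, f$tab, f$plan, a_priori = "background_no2"))
  expect_setequal(model$variables, c("background_no2", "traf_a"))
  expect_gt(model$r2, 0.999999)
  # coefficients recovered
  co <- model$coefficients
  expect_equal(unname(co[match("traf_a", make.names(names(co)))]), 3e-5,
               tolerance = 1e-6)
})

test_that("candidates that flip a sign are rejected despite a large R2 gain", {
  set.seed(9)
  n <- 100
  x1 <- rnorm(n)
  # x2 genuinely improves the fit, but with a coefficient opposite to its
  # declared positive sign
  x2 <- rnorm(n)
  y <- 10 + 2 * x1 - 3 * x2 + rnorm(n, 0, 0.2)
  tab <- data.frame(x1 = x1, x2 = x2)
  plan <- variable_plan(columns = c("x1", "x2"), family = c("x1", "x2"),
                        group = c(1, 1), sign = c(1, 1))
  model <- forward_build(y, tab, plan)
  expect_true("x1" %in% model$variables)
  expect_false("x2" %in% model$variables)
  tr <- model$trace
  r2_gain <- tr$delta_adj_r2[tr$candidate == "x2"]
  expect_gte(r2_gain, 0.01)  # would clear the 1% rule on fit improvement alone
  expect_equal(tr$verdict[tr$candidate == "x2"], "rejected")
  expect_false(tr$sign_ok[tr$candidate == "x2"])
})

test_that("selection never worsens the a-priori-only adjusted R2 and keeps signs", {
  set.seed(12)
  for (rep in 1:5) {
    f <- lur_table(seed = 20 + rep)
    y <- 3 + f$tab$background_no2 + 2e-5 * f$tab$traf_a +
      6 * f$tab$lu_res_300 + rnorm(60, 0, 2)
    base <- summary(lm(y ~ background_no2, data = f$tab))$adj.r.squared
    model <- forward_build(y, f$tab, f$plan, a_priori = "background_no2")
    expect_gte(model$adj_r2, base)
    co <- model$coefficients[-1]
    names(co) <- model$variables
    sgn <- stats::setNames(c(1, f$plan$sign), c("background_no2", f$plan$column))
    expect_true(all(sign(co) == sgn[names(co)]))
  }
})

test_that("backward pruning drops noise variables but protects a priori terms", {
  set.seed(15)
  n <- 200
  bg <- runif(n, 10, 25)
  x <- runif(n, 0, 10)
  noise_var <- rnorm(n)
  y <- 5 + 0.05 * bg + 2 * x + rnorm(n, 0, 1)  # bg nearly irrelevant (high p)
  tab <- data.frame(background_no2 = bg, x = x, noise_var = noise_var)
  plan <- variable_plan(columns = c("x", "noise_var"),
                        family = c("x", "noise_var"), group = c(1, 1),
                        sign = c(1, 1))
  model <- forward_build(y, tab, plan, a_priori = "background_no2", delta = 0)
  model$variables <- union(model$variables, "noise_var")
  model <- lursim:::new_lur_model(y, tab, model$variables, "background_no2",
                                  lursim:::fit_ols(y, tab, model$variables),
                                  plan, model$sign_map, model$trace)
  pruned <- backward_prune(model)
  expect_false("noise_var" %in% pruned$variables)
  expect_true("background_no2" %in% pruned$variables)
  expect_true("x" %in% pruned$variables)
  # a model where every variable matters is left unchanged
  y2 <- 1 + 3 * tab$x + 8 * tab$noise_var + rnorm(n, 0, 0.5)
  m2 <- forward_build(y2, tab, plan)
  expect_identical(backward_prune(m2)$variables, m2$variables)
})

test_that("per-IQR effects rescale coefficients by the empirical IQR", {
  set.seed(18)
  n <- 50
  tab <- data.frame(a = runif(n, 0, 10), b = rnorm(n))
  y <- 2 + 0.773 * tab$a + rnorm(n, 0, 0.01)
  plan <- variable_plan(columns = c("a", "b"), family = c("a", "b"),
                        group = c(1, 1), sign = c(1, 1))
  model <- forward_build(y, tab, plan)
  eff <- per_iqr_effects(model)
  iqr_a <- unname(diff(quantile(tab$a, c(0.25, 0.75))))
  row_a <- eff[eff$variable == "a", ]
  expect_equal(row_a$iqr, iqr_a)
  expect_equal(row_a$effect, row_a$raw_coef * iqr_a)
  expect_equal(row_a$effect, 0.773 * iqr_a, tolerance = 0.01)
  # per-IQR on a constant column is 0 with a warning
  tab$c0 <- 5
  m2 <- model; m2$data <- tab; m2$variables <- c("a", "c0")
  m2$fit <- lursim:::fit_ols(y, tab, c("a", "c0"))
  expect_warning(e2 <- per_iqr_effects(m2), "IQR 0")
  expect_equal(e2$effect[e2$variable == "c0"], 0)
})

test_that("prediction honours OLS identities and errors on missing columns", {
  f <- lur_table(seed = 30)
  y <- 2 + f$tab$background_no2 + 4 * f$tab$lu_res_300 + rnorm(60)
  model <- forward_build(y, f$tab, f$plan, a_priori = "background_no2")
  pred <- predict(model)
  expect_equal(sum(y - pred), 0, tolerance = 1e-8)
  expect_equal(pred, unname(fitted(model$fit)))
  # evaluating at the fitting means returns the mean response
  at_means <- f$tab[1, , drop = FALSE]
  for (v in model$variables) at_means[[v]] <- mean(f$tab[[v]])
  expect_equal(predict(model, at_means), mean(y), tolerance = 1e-8)
  expect_error(predict(model, f$tab[, "traf_a", drop = FALSE]), "lacks")
})

test_that("n <= p candidates are skipped with a warning", {
  tab <- data.frame(a = c(1, 2, 4), b = c(2, 1, 5), c = c(0, 3, 1))
  plan <- variable_plan(columns = names(tab), family = names(tab),
                        group = c(1, 1, 1), sign = c(1, 1, 1))
  y <- c(1, 3, 4)
  warns <- capture_warnings(model <- forward_build(y, tab, plan))
  expect_true(any(grepl("n <= p", warns)))
  expect_lte(length(model$variables), 1)
})
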