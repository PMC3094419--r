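flat_truth <- function(b = 12, ...) {
  ground_truth(background_field = function(x, y) rep(b, length(x)), ...)
}

test_that("degenerate process reduces to intercept + background + land use", {
  net <- one_road_network()
  lu <- uniform_landuse(code = 1)  # everything "residential" code 1
  sites <- data.frame(id = c("a", "b"), x = c(400, 700), y = c(200, 300),
                      site_type = factor("urban_background",
                                         levels = lursim:::SITE_TYPES),
                      protocol = "facade")
  truth <- flat_truth(b = 5, traffic_gain = 0, noise_sd = 0, season_sd = 0,
                      landuse_effects = c(residential = 6))
  tab <- simulate_concentrations(sites, net, lu, truth, n_periods = 3, seed = 1)
  for (p in c("period_1", "period_2", "period_3")) {
    expect_equal(tab[[p]], rep(8 + 5 + 6, 2))  # beta0 + b + full residential buffer
  }
})

test_that("traffic contributions follow the exponential decay kernel", {
  net <- one_road_network(flow = 10000)
  truth <- flat_truth(traffic_gain = 1e-3, decay_length = 60)
  tr <- true_traffic_term(c(500, 500), c(60, 120), net, truth)
  expect_equal(tr[1] / tr[2], exp(-1) / exp(-2), tolerance = 1e-12)
  expect_equal(tr[1], 1e-3 * 10000 * exp(-1), tolerance = 1e-12)
})

test_that("simulated concentrations decompose exactly when noise is off", {
  region <- generate_region(small_region_config(), seed = 6)
  sites <- place_sites(region, site_config(counts = c(traffic = 4,
                                                      urban_background = 6,
                                                      rural = 2)),
                       "facade", seed = 6)
  truth <- ground_truth(noise_sd = 0, season_sd = 0)
  tab <- simulate_concentrations(sites, region$network, region$landuse, truth,
                                 n_periods = 2, seed = 1)
  comp <- attr(tab, "truth")$components
  expect_equal(tab$period_1, pmax(0, comp$background + comp$traffic + comp$landuse))
  expect_equal(tab$period_1, tab$period_2)
})

test_that("Monte-Carlo mean of simulated annual means matches the process mean", {
  net <- one_road_network(flow = 12000)
  lu <- uniform_landuse(code = 1)
  n <- 200
  set.seed(99)
  sites <- data.frame(id = sprintf("s%03d", 1:n),
                      x = runif(n, 100, 900), y = runif(n, 50, 500),
                      site_type = factor("urban_background",
                                         levels = lursim:::SITE_TYPES),
                      protocol = "facade")
  truth <- flat_truth(b = 8, traffic_gain = 5e-4, noise_sd = 1.5,
                      season_sd = 0, landuse_effects = c(residential = 4))
  k <- 4
  tab <- simulate_concentrations(sites, net, lu, truth, n_periods = k, seed = 123)
  analytic <- 8 + 8 + 4 +
    true_traffic_term(sites$x, sites$y, net, truth)
  ann <- rowMeans(as.matrix(tab[, sprintf("period_%d", 1:k)]))
  # mean over sites of (annual - analytic) should be ~ N(0, noise_sd/sqrt(nk))
  se <- 1.5 / sqrt(n * k)
  expect_lt(abs(mean(ann - analytic)), 3 * se)
})

test_that("missingness is MCAR at the configured rate and never empties a site", {
  net <- one_road_network()
  lu <- uniform_landuse(code = 1)
  sites <- data.frame(id = sprintf("s%02d", 1:60),
                      x = runif(60, 100, 900), y = runif(60, 50, 500),
                      site_type = factor("urban_background",
                                         levels = lursim:::SITE_TYPES),
                      protocol = "facade")
  tab <- simulate_concentrations(sites, net, lu, flat_truth(), 4, seed = 5)
  expect_identical(apply_missingness(tab, 0), tab)
  fracs <- vapply(1:300, function(s) {
    m <- apply_missingness(tab, 0.106, seed = s)
    obs <- as.matrix(m[, sprintf("period_%d", 1:4)])
    expect_true(all(rowSums(!is.na(obs)) > 0))
    mean(is.na(obs))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.106), 0.01)
  expect_error(apply_missingness(tab, 1), "rate")
})

test_that("city-scale missingness leaves at least one missing value", {
  # 62 sites x 13 periods at 3.7%: P(no loss) = (1-0.037)^806 ~ 6e-14
  net <- one_road_network()
  lu <- uniform_landuse(code = 1)
  sites <- data.frame(id = sprintf("s%02d", 1:62),
                      x = runif(62, 100, 900), y = runif(62, 50, 500),
                      site_type = factor("urban_background",
                                         levels = lursim:::SITE_TYPES),
                      protocol = "curbside")
  tab <- simulate_concentrations(sites, net, lu, flat_truth(), 13, seed = 8)
  m <- apply_missingness(tab, 0.037, seed = 21)
  expect_gt(sum(is.na(as.matrix(m[, sprintf("period_%d", 1:13)]))), 0)
})

test_that("site tables survive a CSV round trip with empty cells for missing", {
  net <- one_road_network()
  lu <- uniform_landuse(code = 1)
  sites <- data.frame(id = c("s1", "s2", "s3"), x = c(100, 300, 500),
                      y = c(100, 150, 200),
                      site_type = factor("urban_background",
                                         levels = lursim:::SITE_TYPES),
                      protocol = "facade")
  tab <- simulate_concentrations(sites, net, lu, flat_truth(), 4, seed = 2)
  tab$period_2[2] <- NA
  path <- tempfile(fileext = ".csv")
  write_sites_csv(tab, path)
  expect_true(any(grepl(",,", readLines(path))))
  back <- read_sites_csv(path)
  expect_equal(back$period_1, tab$period_1)
  expect_true(is.na(back$period_2[2]))
  expect_identical(levels(back$site_type), lursim:::SITE_TYPES)
})
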