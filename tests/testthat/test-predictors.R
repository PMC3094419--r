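test_that("nearest road returns the arg-min segment's attributes", {
  net <- one_road_network(flow = 8000, heavy = 0.2)
  # point on the line
  expect_equal(nearest_road(net, 500, 0, "all")$distance, 0)
  # perpendicular distance
  nr <- nearest_road(net, 0, 10, "all")
  expect_equal(nr$distance, 10)
  expect_equal(nr$flow, 8000)
  expect_equal(nr$heavy_flow, 1600)
  # absent class is explicit, never a silent zero
  nr_fw <- nearest_road(net, 0, 10, "freeway")
  expect_false(nr_fw$found)
  expect_identical(nr_fw$distance, Inf)
  expect_true(is.na(nr_fw$flow))
})

test_that("nearest-road distances match an independent minimisation oracle", {
  set.seed(77)
  for (i in 1:10) {
    net <- random_network(n = 12, size = 1500)
    for (j in 1:10) {
      x <- runif(1, 0, 1500); y <- runif(1, 0, 1500)
      cls <- sample(c("all", "busy"), 1)
      got <- nearest_road(net, x, y, cls)$distance
      expect_equal(got, oracle_nearest_distance(net, x, y, cls),
                   tolerance = 1e-6)
    }
  }
})

test_that("flow within a cutoff censors by the nearest road, not the largest", {
  net <- road_network(data.frame(
    road_id = 1:2, x0 = c(0, 0), y0 = c(20, 40), x1 = c(100, 100),
    y1 = c(20, 40), flow = c(6000, 20000), heavy_fraction = 0.1,
    authority = "municipal", has_count_data = TRUE),
    extent = c(0, 100, 0, 100))
  # nearest busy road at 20 m carries 6000, even though a larger one is at 40 m
  expect_equal(flow_within(net, 50, 0, "busy", 50), 6000)
  # a busy road beyond the cutoff contributes zero
  one <- one_road_network(flow = 7000)
  expect_equal(flow_within(one, 500, 60, "busy", 50), 0)
  expect_equal(flow_within(one, 500, 30, "busy", 50), 7000)
  # absent class contributes zero
  expect_equal(flow_within(one, 500, 30, "freeway", 500), 0)
})

test_that("buffer traffic equals flow times intersected length", {
  net <- one_road_network(flow = 5000)
  # chord through the centre of a long straight road: F * 2r
  expect_equal(buffer_traffic(net, 500, 0, 100), 5000 * 200)
  expect_equal(buffer_traffic(net, 500, 300, 100), 0)
  # heavy weighting scales by the heavy-duty fraction
  expect_equal(buffer_traffic(net, 500, 0, 100, "heavy"), 5000 * 0.1 * 200)
})

test_that("buffer fractions are exact for uniform and absent categories", {
  g <- uniform_landuse(code = 3)
  expect_equal(buffer_fraction(g, 700, 700, 250, 3), 1.0)
  expect_equal(buffer_fraction(g, 700, 700, 250, 1), 0.0)
  expect_error(buffer_fraction(g, 700, 700, 250, "nope"), "unknown")
  # tiny radius falls back to the containing cell
  expect_equal(buffer_fraction(g, 700, 700, 1, 3), 1.0)
})

test_that("buffer membership matches the whole-grid brute force", {
  set.seed(31)
  for (i in 1:10) {
    g <- random_landuse(nx = 25, ny = 20, cs = 40, k = 3)
    x <- runif(1, 100, 900); y <- runif(1, 100, 700); r <- runif(1, 60, 300)
    keep <- oracle_buffer_cells(g, x, y, r)
    for (code in 1:3) {
      expect_equal(buffer_fraction(g, x, y, r, code),
                   mean(g$values[keep] == code))
    }
    p <- population_grid(matrix(runif(500, 0, 50), 20, 25), c(0, 0), 40)
    expect_equal(buffer_population(p, x, y, r), sum(p$values[keep]))
  }
})

test_that("buffer population scales with disc area on a uniform raster", {
  p <- population_grid(matrix(10, 60, 60), c(0, 0), 50)  # uniform 10 per cell
  r <- 600
  got <- buffer_population(p, 1500, 1500, r)
  expect_lt(abs(got - 10 * pi * r^2 / 50^2) / (10 * pi * r^2 / 50^2), 0.02)
  # zero raster and single-cell cases
  z <- population_grid(matrix(0, 10, 10), c(0, 0), 50)
  expect_equal(buffer_population(z, 250, 250, 100), 0)
  one <- matrix(0, 11, 11); one[6, 6] <- 42
  p1 <- population_grid(one, c(0, 0), 50)
  expect_equal(buffer_population(p1, 275, 275, 20), 42)
})

test_that("buffer statistics are non-decreasing in radius", {
  set.seed(55)
  net <- random_network(n = 15, size = 1500)
  g <- random_landuse(nx = 30, ny = 30, cs = 50)
  p <- population_grid(matrix(runif(900, 0, 30), 30, 30), c(0, 0), 50)
  radii <- c(50, 100, 200, 400, 800)
  for (i in 1:10) {
    x <- runif(1, 200, 1300); y <- runif(1, 200, 1300)
    bt <- vapply(radii, function(r) buffer_traffic(net, x, y, r), numeric(1))
    bp <- vapply(radii, function(r) buffer_population(p, x, y, r), numeric(1))
    nfrac <- vapply(radii, function(r) {
      idx <- lursim:::buffer_cell_index(g, x, y, r)
      sum(g$values[idx] == 2)  # numerator of the category-2 fraction
    }, numeric(1))
    expect_true(all(diff(bt) >= 0))
    expect_true(all(diff(bp) >= 0))
    expect_true(all(diff(nfrac) >= 0))
  }
})

test_that("the predictor table applies the log clamp, censoring and column count", {
  region <- generate_region(small_region_config(
    road_density = c(national = 0, provincial = 0.5, municipal = 1.5)),
    seed = 13)
  net <- assign_minimal_flow(region$network)
  sites <- place_sites(region, site_config(counts = c(traffic = 4,
                                                      urban_background = 6,
                                                      rural = 2)),
                       "facade", seed = 13)
  cfg <- predictor_config(landuse_radii = c(300, 1000))
  tab <- build_predictor_table(sites, net, region$landuse_coarse,
                               region$population, config = cfg)
  # closed-form column count (plus the id column)
  expect_equal(ncol(tab) - 1L, predictor_column_count(cfg, 7))
  # no freeways in this region: distance censored at the diagonal, flow 0
  expect_equal(tab$logdist_freeway,
               rep(log(lursim:::network_diagonal(net)), nrow(tab)))
  expect_true(all(tab$flow_near_freeway == 0))
  expect_true(all(tab$flow_freeway_within_500 == 0))
  # a site sitting exactly on a road gets the clamped log distance
  on_road <- sites[1, ]
  on_road$x <- net$x0[1]; on_road$y <- net$y0[1]
  tab1 <- build_predictor_table(on_road, net, region$landuse_coarse,
                                region$population, config = cfg)
  expect_equal(tab1$logdist_all, log(1))
  # fractions live in [0, 1]; flows and populations are nonnegative
  lu_cols <- grep("^lu_", names(tab), value = TRUE)
  expect_true(all(as.matrix(tab[, lu_cols]) >= 0 & as.matrix(tab[, lu_cols]) <= 1))
  expect_true(all(as.matrix(tab[, grep("^pop_|^flow_|^traf_|^heavy",
                                       names(tab))]) >= 0))
})

test_that("sites outside raster coverage raise a coverage error", {
  region <- generate_region(small_region_config(), seed = 14)
  net <- assign_minimal_flow(region$network)
  sites <- data.frame(id = "out", x = -5000, y = -5000,
                      site_type = factor("urban_background",
                                         levels = lursim:::SITE_TYPES),
                      protocol = "facade")
  expect_error(build_predictor_table(sites, net, region$landuse_coarse,
                                     region$population),
               "coverage")
})
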