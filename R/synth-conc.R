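# Ground-truth concentration process and campaign simulation. The true annual
# surface decomposes additively into a regional background field, a local
# traffic contribution with exponential distance decay per road, and land-use
# terms; observed period concentrations add a per-period seasonal offset and
# Gaussian sampler noise, truncated at zero.

#' Default smooth regional background field
#'
#' A gentle west-east gradient with a low-frequency north-south ripple,
#' spanning roughly 6-16 ug/m3 across the default extent; with the default
#' process intercept this reproduces regional background levels in the
#' 10-25 ug/m3 range typical of rural Northwest-European NO2.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @return a function `f(x, y)` in ug/m3.
#' @export
default_background_field <- function(extent = c(0, 6000, 0, 6000)) {
  w <- extent[2] - extent[1]
  h <- extent[4] - extent[3]
  function(x, y) {
    6 + 7 * (x - extent[1]) / w + 3 * cos(2 * pi * (y - extent[3]) / (1.7 * h))
  }
}

#' Ground-truth process parameters
#'
#' @param beta0 process intercept (ug/m3).
#' @param background_field function `f(x, y)` giving the regional field (ug/m3).
#' @param traffic_gain ug/m3 per (vehicle/24 hr) at zero distance.
#' @param decay_length e-folding distance of the local traffic kernel (m).
#' @param landuse_effects named ug/m3 per unit land-use fraction (300 m buffer).
#' @param landuse_radius buffer radius used by the land-use terms (m).
#' @param season_sd SD of the additive per-period seasonal offset (ug/m3).
#' @param noise_sd SD of per-observation sampler noise (ug/m3).
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(beta0 = 8,
                         background_field = default_background_field(),
                         traffic_gain = 1.2e-3,
                         decay_length = 60,
                         landuse_effects = c(residential = 6, industry = 3,
                                             port = 2, transport = 2,
                                             green = -3, water = -2,
                                             agriculture = -2),
                         landuse_radius = 300,
                         season_sd = 2.5,
                         noise_sd = 2) {
  if (decay_length <= 0) stop_config("decay_length must be > 0")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(beta0 = beta0, background_field = background_field,
                 traffic_gain = traffic_gain, decay_length = decay_length,
                 landuse_effects = landuse_effects,
                 landuse_radius = landuse_radius,
                 season_sd = season_sd, noise_sd = noise_sd),
            class = "ground_truth")
}

#' True local traffic contribution at points
#'
#' Sum over roads of `flow * exp(-d / decay_length)` times the gain, with `d`
#' the distance from the point to the road polyline. Uses the network's true
#' flows (not the minimal-flow-filled data product).
#'
#' @param x,y point coordinate vectors.
#' @param network a `road_network`.
#' @param truth a [ground_truth()].
#' @return numeric vector (ug/m3).
#' @export
true_traffic_term <- function(x, y, network, truth) {
  if (nrow(network) == 0L) return(numeric(length(x)))
  roads <- split(seq_len(nrow(network)), network$road_id)
  out <- numeric(length(x))
  for (idx in roads) {
    fl <- network$flow[idx[1]]
    for (i in seq_along(x)) {
      d <- min(dist_point_segments(x[i], y[i], network$x0[idx], network$y0[idx],
                                   network$x1[idx], network$y1[idx]))
      out[i] <- out[i] + fl * exp(-d / truth$decay_length)
    }
  }
  truth$traffic_gain * out
}

true_landuse_term <- function(x, y, landuse, truth) {
  vapply(seq_along(x), function(i) {
    idx <- buffer_cell_index(landuse, x[i], y[i], truth$landuse_radius)
    if (nrow(idx) == 0L) return(0)  # outside coverage (external ring sites)
    codes <- landuse$values[idx]
    tot <- 0
    for (cat in names(truth$landuse_effects)) {
      code <- LANDUSE_CATEGORIES[[cat]]
      tot <- tot + truth$landuse_effects[[cat]] * mean(codes == code)
    }
    tot
  }, numeric(1))
}

#' Simulate a monitoring campaign from the ground truth
#'
#' Per-period concentration at a site is
#' `beta0 + background(x, y) + traffic + land-use + period offset + noise`,
#' truncated at zero. Period offsets (one draw per period) emulate seasonal
#' variation across a four-period or thirteen-period sampling schedule.
#'
#' @param sites site data frame from [place_sites()].
#' @param network a `road_network` (true flows).
#' @param landuse the fine `landuse_grid`.
#' @param truth a [ground_truth()].
#' @param n_periods number of sampling periods (4 emulates four one-week
#'   seasonal campaigns; 13 emulates thirteen 28-day exposures).
#' @param seed integer seed (optional).
#' @return the sites data frame with columns `period_1..period_k` appended;
#'   attribute `"truth"` holds the per-site additive decomposition
#'   (background, traffic, landuse, annual_true) and the period offsets.
#' @export
simulate_concentrations <- function(sites, network, landuse, truth = ground_truth(),
                                    n_periods = 4, seed = NULL) {
  if (n_periods < 1) stop_config("n_periods must be >= 1")
  with_seed(seed, {
    bg <- truth$beta0 + truth$background_field(sites$x, sites$y)
    tr <- true_traffic_term(sites$x, sites$y, network, truth)
    lu <- true_landuse_term(sites$x, sites$y, landuse, truth)
    value <- bg + tr + lu
    offsets <- stats::rnorm(n_periods, 0, truth$season_sd)
    obs <- matrix(NA_real_, nrow(sites), n_periods)
    for (p in seq_len(n_periods)) {
      obs[, p] <- pmax(0, value + offsets[p] +
                         stats::rnorm(nrow(sites), 0, truth$noise_sd))
    }
    colnames(obs) <- sprintf("period_%d", seq_len(n_periods))
    out <- cbind(sites, as.data.frame(obs))
    attr(out, "truth") <- list(
      components = data.frame(id = sites$id, background = bg, traffic = tr,
                              landuse = lu, annual_true = value),
      period_offsets = offsets)
    out
  })
}

period_columns <- function(table) grep("^period_", names(table), value = TRUE)

#' Apply MCAR sampler loss to a campaign table
#'
#' Each site-period observation is set missing independently with the given
#' probability; a site that would lose all its periods has its row mask
#' redrawn, so every site keeps at least one observation.
#'
#' @param table a campaign table from [simulate_concentrations()].
#' @param rate loss probability in `[0, 1)`.
#' @param seed integer seed (optional).
#' @return the table with `NA`s inserted.
#' @export
apply_missingness <- function(table, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop_config("missingness rate must be in [0, 1)")
  if (rate == 0) return(table)
  cols <- period_columns(table)
  with_seed(seed, {
    k <- length(cols)
    for (i in seq_len(nrow(table))) {
      repeat {
        mask <- stats::runif(k) < rate
        if (!all(mask)) break
      }
      for (j in which(mask)) table[i, cols[j]] <- NA_real_
    }
    table
  })
}

#' Write a campaign site table as CSV
#'
#' Missing observations are written as empty cells.
#'
#' @param table campaign table.
#' @param path output path.
#' @export
write_sites_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a campaign site table from CSV
#'
#' @param path CSV written by [write_sites_csv()].
#' @return a data frame with site_type as a factor over the standard levels.
#' @export
read_sites_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$site_type <- factor(out$site_type, levels = SITE_TYPES)
  out
}
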