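# Monitoring-site placement. Two placement protocols are supported: "facade"
# (samplers at the building line, ~10 m from the road centreline) and
# "curbside" (lamppost-style placement, ~3 m). Traffic sites are anchored to
# busy roads; candidate points where a second busy road runs close by are
# rejected, mirroring campaign practice of avoiding complicated multi-road
# hot spots.

SITE_TYPES <- c("traffic", "urban_background", "rural", "rural_external")

#' Site-placement configuration
#'
#' @param counts named integer vector over
#'   `traffic, urban_background, rural, rural_external`.
#' @param offsets named protocol offsets from the road centreline (m).
#' @param offset_jitter max uniform jitter added to the offset (m).
#' @param busy_exclusion reject traffic candidates with a second busy road
#'   within this distance (m).
#' @param ub_min_busy_dist minimum busy-road distance for urban background sites (m).
#' @param ub_min_res minimum residential fraction (300 m buffer) for urban
#'   background sites.
#' @param rural_min_road_dist minimum all-road distance for rural sites (m).
#' @param rural_max_res maximum residential fraction for rural sites.
#' @param external_margin rural_external sites are placed this far outside the
#'   region boundary, as a fraction of the extent.
#' @param traffic_weighting `"length"` anchors traffic sites to busy roads in
#'   proportion to road length (purpose-designed sampling); `"flow"` weights
#'   by flow times length, emulating a routine programme concentrated on the
#'   most heavily trafficked streets.
#' @param window optional `c(xmin, xmax, ymin, ymax)` restricting placement
#'   (used for the city-style campaign inside a larger region).
#' @return a `site_config` list.
#' @export
site_config <- function(counts = c(traffic = 18, urban_background = 34,
                                   rural = 8, rural_external = 8),
                        offsets = c(facade = 10, curbside = 3),
                        offset_jitter = 2,
                        busy_exclusion = 40,
                        ub_min_busy_dist = 75,
                        ub_min_res = 0.15,
                        rural_min_road_dist = 150,
                        rural_max_res = 0.05,
                        external_margin = c(0.05, 0.2),
                        traffic_weighting = c("length", "flow"),
                        window = NULL) {
  traffic_weighting <- match.arg(traffic_weighting)
  counts_full <- stats::setNames(integer(length(SITE_TYPES)), SITE_TYPES)
  counts_full[names(counts)] <- as.integer(counts)
  structure(list(counts = counts_full, offsets = offsets,
                 offset_jitter = offset_jitter, busy_exclusion = busy_exclusion,
                 ub_min_busy_dist = ub_min_busy_dist, ub_min_res = ub_min_res,
                 rural_min_road_dist = rural_min_road_dist,
                 rural_max_res = rural_max_res,
                 external_margin = external_margin,
                 traffic_weighting = traffic_weighting, window = window),
            class = "site_config")
}

res_fraction <- function(landuse, x, y, radius = 300) {
  idx <- buffer_cell_index(landuse, x, y, radius)
  if (nrow(idx) == 0L) return(0)
  mean(landuse$values[idx] == LANDUSE_CATEGORIES[["residential"]])
}

place_traffic_sites <- function(region, n, protocol, config, rule) {
  net <- region$network
  win <- config$window %||% region$extent
  busy <- net[edge_in_class(net, "busy", rule), , drop = FALSE]
  # only anchor to busy edges whose midpoint lies in the placement window
  mx <- (busy$x0 + busy$x1) / 2
  my <- (busy$y0 + busy$y1) / 2
  inside <- mx >= win[1] & mx <= win[2] & my >= win[3] & my <= win[4]
  busy <- busy[inside, , drop = FALSE]
  if (nrow(busy) == 0L)
    stop_config("site placement: no busy road in region/window for traffic sites")
  offset <- config$offsets[[protocol]]
  out <- vector("list", n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 500L * n)
      stop_config("site placement: could not place traffic sites (busy roads too sparse)")
    w <- if (config$traffic_weighting == "flow") busy$length * busy$flow else
      busy$length
    e <- busy[sample.int(nrow(busy), 1, prob = w), , drop = FALSE]
    t <- stats::runif(1)
    side <- sample(c(-1, 1), 1)
    jit <- stats::runif(1, 0, config$offset_jitter)
    fx <- e$x0 + t * (e$x1 - e$x0)
    fy <- e$y0 + t * (e$y1 - e$y0)
    nrm <- c(-(e$y1 - e$y0), e$x1 - e$x0) / e$length
    # protocol-independent screening at the foot point keeps facade/curbside
    # runs under the same seed paired site-for-site
    other <- busy[busy$road_id != e$road_id, , drop = FALSE]
    if (nrow(other) > 0) {
      d_other <- min(dist_point_segments(fx, fy, other$x0, other$y0,
                                         other$x1, other$y1))
      if (d_other < config$busy_exclusion) next
    }
    margin <- max(config$offsets) + config$offset_jitter
    if (fx < win[1] + margin || fx > win[2] - margin ||
        fy < win[3] + margin || fy > win[4] - margin) next
    placed <- placed + 1L
    out[[placed]] <- c(fx + side * nrm[1] * (offset + jit),
                       fy + side * nrm[2] * (offset + jit))
  }
  do.call(rbind, out)
}

place_area_sites <- function(region, n, accept, what) {
  win <- attr(accept, "window")
  out <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 2000L * n)
      stop_config("site placement: could not place %s sites", what)
    x <- stats::runif(1, win[1], win[2])
    y <- stats::runif(1, win[3], win[4])
    if (!accept(x, y)) next
    placed <- placed + 1L
    out[placed, ] <- c(x, y)
  }
  out
}

#' Place monitoring sites in a synthetic region
#'
#' Traffic sites are set at a protocol-dependent perpendicular offset from a
#' busy-road centreline; urban background sites require residential
#' surroundings away from busy roads; rural sites require open land away from
#' all roads; rural_external sites sit in a ring outside the region boundary
#' (they support background interpolation but are excluded from model fitting).
#'
#' @param region a `lur_region` from [generate_region()].
#' @param config a [site_config()].
#' @param protocol `"facade"` or `"curbside"`.
#' @param seed integer seed (optional).
#' @param rule a [road_class_rule()] defining busy roads.
#' @return a data frame of sites: `id, x, y, site_type, protocol`.
#' @export
place_sites <- function(region, config = site_config(),
                        protocol = c("facade", "curbside"), seed = NULL,
                        rule = road_class_rule()) {
  protocol <- match.arg(protocol)
  with_seed(seed, {
    net <- region$network
    win <- config$window %||% region$extent
    n <- config$counts
    xy <- list()
    if (n[["traffic"]] > 0) {
      xy$traffic <- place_traffic_sites(region, n[["traffic"]], protocol, config, rule)
    }
    if (n[["urban_background"]] > 0) {
      busy <- net[edge_in_class(net, "busy", rule), , drop = FALSE]
      acc <- function(x, y) {
        db <- if (nrow(busy)) min(dist_point_segments(x, y, busy$x0, busy$y0,
                                                      busy$x1, busy$y1)) else Inf
        db > config$ub_min_busy_dist &&
          res_fraction(region$landuse, x, y) >= config$ub_min_res
      }
      attr(acc, "window") <- win
      xy$urban_background <- place_area_sites(region, n[["urban_background"]],
                                              acc, "urban background")
    }
    if (n[["rural"]] > 0) {
      acc <- function(x, y) {
        dr <- if (nrow(net)) min(dist_point_segments(x, y, net$x0, net$y0,
                                                     net$x1, net$y1)) else Inf
        dr > config$rural_min_road_dist &&
          res_fraction(region$landuse, x, y) <= config$rural_max_res
      }
      attr(acc, "window") <- region$extent
      xy$rural <- place_area_sites(region, n[["rural"]], acc, "rural")
    }
    if (n[["rural_external"]] > 0) {
      w <- region$extent[2] - region$extent[1]
      h <- region$extent[4] - region$extent[3]
      k <- n[["rural_external"]]
      side <- sample(1:4, k, replace = TRUE)
      m <- stats::runif(k, config$external_margin[1], config$external_margin[2])
      along <- stats::runif(k)
      ex <- ifelse(side == 1, region$extent[1] - m * w,
            ifelse(side == 2, region$extent[2] + m * w, region$extent[1] + along * w))
      ey <- ifelse(side == 3, region$extent[3] - m * h,
            ifelse(side == 4, region$extent[4] + m * h, region$extent[3] + along * h))
      xy$rural_external <- cbind(ex, ey)
    }
    types <- rep(names(xy), vapply(xy, nrow, 1L))
    pts <- do.call(rbind, xy)
    data.frame(id = sprintf("site_%03d", seq_along(types)),
               x = pts[, 1], y = pts[, 2],
               site_type = factor(types, levels = SITE_TYPES),
               protocol = protocol,
               stringsAsFactors = FALSE)
  })
}
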