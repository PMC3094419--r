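# GIS predictor extraction: per-site traffic variables (buffer flows, log
# distance to and flow at the nearest road by class, distance-censored flow
# variables) and raster variables (land-use fractions and population counts in
# circular buffers). Distances to roads are log-transformed a priori, after
# clamping at a minimum distance, to allow for the roughly exponential decay
# of traffic-related concentrations with distance.

#' Nearest road of a class
#'
#' Minimum point-to-polyline distance over all roads of the class; flow and
#' heavy-duty flow are taken from the arg-min road. When the class is absent
#' from the network an explicit "no road" result is returned (distance `Inf`,
#' flows `NA`), never a silent zero.
#'
#' @param network a `road_network`.
#' @param x,y point coordinates (scalars, m).
#' @param class one of `"all", "busy", "main", "freeway"`.
#' @param rule a [road_class_rule()].
#' @return list with `distance`, `flow`, `heavy_flow`, `road_id`, `found`.
#' @export
nearest_road <- function(network, x, y, class = "all", rule = road_class_rule()) {
  keep <- which(edge_in_class(network, class, rule))
  if (length(keep) == 0L) {
    return(list(distance = Inf, flow = NA_real_, heavy_flow = NA_real_,
                road_id = NA_integer_, found = FALSE))
  }
  d <- dist_point_segments(x, y, network$x0[keep], network$y0[keep],
                           network$x1[keep], network$y1[keep])
  i <- keep[which.min(d)]
  list(distance = min(d),
       flow = network$flow[i],
       heavy_flow = network$flow[i] * network$heavy_fraction[i],
       road_id = network$road_id[i],
       found = TRUE)
}

#' Flow at the nearest road of a class within a distance cutoff
#'
#' The flow of the nearest road of the class if that road lies within the
#' cutoff, else 0 (also 0 when the class is absent).
#'
#' @inheritParams nearest_road
#' @param cutoff distance cutoff (m).
#' @param what `"flow"` (total) or `"heavy"` (heavy-duty flow).
#' @return vehicles/24 hr.
#' @export
flow_within <- function(network, x, y, class, cutoff, rule = road_class_rule(),
                        what = c("flow", "heavy")) {
  what <- match.arg(what)
  nr <- nearest_road(network, x, y, class, rule)
  if (!nr$found || nr$distance > cutoff) return(0)
  if (what == "flow") nr$flow else nr$heavy_flow
}

#' Flow-weighted road length in a circular buffer
#'
#' Sum over roads of flow times the length of the road inside the disc
#' (vehicle-metres per 24 hr) -- the standard length-weighted buffer traffic
#' construction.
#'
#' @inheritParams nearest_road
#' @param radius buffer radius (m).
#' @param what `"flow"` or `"heavy"` weighting.
#' @return vehicle-metres/24 hr.
#' @export
buffer_traffic <- function(network, x, y, radius, what = c("flow", "heavy")) {
  what <- match.arg(what)
  if (nrow(network) == 0L) return(0)
  len <- segment_disc_length(x, y, radius, network$x0, network$y0,
                             network$x1, network$y1)
  w <- if (what == "flow") network$flow else network$flow * network$heavy_fraction
  sum(w * len)
}

#' Land-use fraction in a circular buffer
#'
#' Share of cells of the category among cells whose centre lies in the disc
#' (cell-centre membership rule). When the disc captures no cell centre
#' (radius below half a cell), the cell containing the point is used.
#'
#' @param grid a `landuse_grid`.
#' @param x,y point (m).
#' @param radius buffer radius (m).
#' @param category category label (e.g., `"residential"`) or integer code.
#' @return proportion in `[0, 1]`.
#' @export
buffer_fraction <- function(grid, x, y, radius, category) {
  code <- if (is.character(category)) {
    hit <- names(grid$category_names)[grid$category_names == category]
    if (length(hit) == 0L) stop_config("unknown land-use category '%s'", category)
    as.integer(hit[1])
  } else as.integer(category)
  idx <- buffer_cell_index(grid, x, y, radius)
  if (nrow(idx) == 0L) idx <- cell_at(grid, x, y)
  if (is.null(idx) || nrow(idx) == 0L)
    stop_config("site (%.0f, %.0f) outside land-use coverage", x, y)
  mean(grid$values[idx] == code)
}

#' Population count in a circular buffer
#'
#' Sum of cell counts with cell centre in the disc (same membership rule as
#' [buffer_fraction()]).
#'
#' @param grid a `population_grid`.
#' @inheritParams buffer_fraction
#' @return inhabitants.
#' @export
buffer_population <- function(grid, x, y, radius) {
  idx <- buffer_cell_index(grid, x, y, radius)
  if (nrow(idx) == 0L) {
    idx <- cell_at(grid, x, y)
    if (is.null(idx)) return(0)
  }
  sum(grid$values[idx])
}

#' Predictor-extraction configuration
#'
#' @param traffic_buffer_radii radii for buffer traffic variables (m).
#' @param flow_cutoffs distance cutoffs for nearest-road flow variables (m).
#' @param landuse_radii buffer radii for land-use fractions (m). Defaults to
#'   the large-area dialect (300 m, 1 km, 5 km); the city dialect uses
#'   `c(25, 50, 100, 250, 500)`.
#' @param population_radii buffer radii for population counts (m).
#' @param d_min distance clamp before the log transform (m): sites at distance
#'   0 get `log(d_min)`.
#' @param censor_distance distance recorded when a road class is absent from
#'   the network (default the region diagonal); the matching flow is 0.
#' @return a `predictor_config` list.
#' @export
predictor_config <- function(traffic_buffer_radii = c(100, 250),
                             flow_cutoffs = c(25, 50, 100, 250, 500),
                             landuse_radii = c(300, 1000, 5000),
                             population_radii = c(100, 300, 1000, 5000),
                             d_min = 1,
                             censor_distance = NULL) {
  structure(list(traffic_buffer_radii = traffic_buffer_radii,
                 flow_cutoffs = flow_cutoffs,
                 landuse_radii = landuse_radii,
                 population_radii = population_radii,
                 d_min = d_min, censor_distance = censor_distance),
            class = "predictor_config")
}

#' Number of columns a predictor configuration generates
#'
#' Closed form: per road class one log-distance, one nearest flow, one nearest
#' heavy flow and one flow per cutoff; two buffer-traffic variables per
#' radius; one fraction per land-use category and radius; one population count
#' per radius.
#'
#' @param config a [predictor_config()].
#' @param n_categories number of land-use categories.
#' @return integer column count (excluding the site id).
#' @export
predictor_column_count <- function(config, n_categories = length(LANDUSE_CATEGORIES)) {
  length(ROAD_CLASSES) * (3 + length(config$flow_cutoffs)) +
    2 * length(config$traffic_buffer_radii) +
    n_categories * length(config$landuse_radii) +
    length(config$population_radii)
}

#' Build the per-site GIS predictor table
#'
#' Computes every traffic, land-use and population variable for every site.
#' Distance columns are stored as `log(max(d, d_min))`; absent road classes
#' are censored at `censor_distance` with flow 0, so the regression table has
#' no missing cells. Sites outside the raster coverage raise an error
#' (rural_external sites, which sit outside the region by construction, are
#' skipped and returned with `NA` rows -- they never enter model fitting).
#'
#' @param sites site data frame (id, x, y, site_type).
#' @param network a `road_network` with minimal flow already assigned.
#' @param landuse a `landuse_grid`.
#' @param population a `population_grid`.
#' @param rule a [road_class_rule()].
#' @param config a [predictor_config()].
#' @return data frame keyed by `id` with attribute `"dictionary"` describing
#'   each column (family, group, sign, scale) for the selection plan.
#' @export
build_predictor_table <- function(sites, network, landuse, population,
                                  rule = road_class_rule(),
                                  config = predictor_config()) {
  censor <- config$censor_distance %||% network_diagonal(network)
  cats <- grid_categories(landuse)
  cols <- list()
  dict <- list()
  add_col <- function(name, values, family, group, sign, scale = NA_real_) {
    cols[[name]] <<- values
    dict[[name]] <<- data.frame(column = name, family = family, group = group,
                                sign = sign, scale = scale)
  }

  inside <- sites$site_type != "rural_external"
  bad <- inside & !grid_covers(landuse, sites$x, sites$y)
  if (any(bad)) {
    stop_config("sites outside land-use coverage: %s",
                paste(sites$id[bad], collapse = ", "))
  }
  n <- nrow(sites)
  na_fill <- function(v) { v[!inside] <- NA_real_; v }

  # Road classes nest (all >= busy >= main), so class variants of one variable
  # type are overlapping categories: each variable type is one family and only
  # its best class/cutoff variant may enter the model.
  for (cls in ROAD_CLASSES) {
    nr <- lapply(seq_len(n), function(i) {
      if (!inside[i]) return(list(distance = NA, flow = NA, heavy_flow = NA))
      nearest_road(network, sites$x[i], sites$y[i], cls, rule)
    })
    d <- vapply(nr, function(z) as.numeric(z$distance), numeric(1))
    fl <- vapply(nr, function(z) as.numeric(z$flow), numeric(1))
    hv <- vapply(nr, function(z) as.numeric(z$heavy_flow), numeric(1))
    absent <- inside & !is.finite(d)
    d[absent] <- censor
    fl[absent] <- 0
    hv[absent] <- 0
    add_col(paste0("logdist_", cls), log(pmax(d, config$d_min)),
            family = "logdist", group = 1L, sign = -1)
    add_col(paste0("flow_near_", cls), fl,
            family = "flow_near", group = 1L, sign = 1, scale = Inf)
    add_col(paste0("heavyflow_near_", cls), hv,
            family = "heavyflow_near", group = 1L, sign = 1, scale = Inf)
    for (cut in config$flow_cutoffs) {
      v <- ifelse(is.finite(d) & d <= cut & !absent, fl, 0)
      v[!inside] <- NA_real_
      add_col(sprintf("flow_%s_within_%d", cls, cut), v,
              family = "flow_near", group = 1L, sign = 1, scale = cut)
    }
  }
  for (r in config$traffic_buffer_radii) {
    tb <- na_fill(vapply(seq_len(n), function(i) {
      if (!inside[i]) return(NA_real_)
      buffer_traffic(network, sites$x[i], sites$y[i], r, "flow")
    }, numeric(1)))
    hb <- na_fill(vapply(seq_len(n), function(i) {
      if (!inside[i]) return(NA_real_)
      buffer_traffic(network, sites$x[i], sites$y[i], r, "heavy")
    }, numeric(1)))
    add_col(sprintf("traf_buf_%d", r), tb, family = "buffer_traffic",
            group = 1L, sign = 1, scale = r)
    add_col(sprintf("heavy_buf_%d", r), hb, family = "buffer_heavy",
            group = 1L, sign = 1, scale = r)
  }
  lu_group <- landuse_group_map()
  lu_sign <- landuse_sign_map()
  for (cat in cats) {
    for (r in config$landuse_radii) {
      v <- vapply(seq_len(n), function(i) {
        if (!inside[i]) return(NA_real_)
        buffer_fraction(landuse, sites$x[i], sites$y[i], r, cat)
      }, numeric(1))
      add_col(sprintf("lu_%s_%d", cat, r), v, family = paste0("lu_", cat),
              group = lu_group[[cat]], sign = lu_sign[[cat]], scale = r)
    }
  }
  for (r in config$population_radii) {
    v <- vapply(seq_len(n), function(i) {
      if (!inside[i]) return(NA_real_)
      buffer_population(population, sites$x[i], sites$y[i], r)
    }, numeric(1))
    add_col(sprintf("pop_%d", r), v, family = "population",
            group = 3L, sign = 1, scale = r)
  }

  out <- data.frame(id = sites$id, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "dictionary") <- do.call(rbind, unname(dict))
  out
}

grid_categories <- function(landuse) unname(landuse$category_names)

# Variable-group assignment used by the supervised selection: (1) traffic,
# (2) traffic-related land use, (3) population-density-related land use,
# (4) other land use.
landuse_group_map <- function() {
  c(residential = 3L, industry = 4L, port = 4L, transport = 2L,
    green = 4L, water = 4L, agriculture = 4L, forest = 4L)
}

# A priori expected coefficient signs: built-up / source categories positive,
# open and vegetated categories negative.
landuse_sign_map <- function() {
  c(residential = 1, industry = 1, port = 1, transport = 1,
    green = -1, water = -1, agriculture = -1, forest = -1)
}

#' Write a predictor table with its column dictionary
#'
#' @param table predictor table from [build_predictor_table()].
#' @param path CSV output path; the dictionary is written next to it as
#'   `<path>.dict.json`.
#' @export
write_predictor_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  dict <- attr(table, "dictionary")
  jsonlite::write_json(dict, paste0(path, ".dict.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
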