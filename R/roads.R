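# Road network container. A network is a data frame of straight edges; a road
# (polyline) is the set of edges sharing one road_id, with per-road traffic
# attributes: flow (vehicles/24 hr), heavy-duty fraction, managing authority,
# and whether a traffic count was actually available for the road.

ROAD_AUTHORITIES <- c("national", "provincial", "municipal")
ROAD_CLASSES <- c("all", "busy", "main", "freeway")

#' Construct a road network
#'
#' @param edges data frame with columns `road_id, x0, y0, x1, y1, flow,
#'   heavy_fraction, authority, has_count_data`.
#' @param extent named numeric `c(xmin, xmax, ymin, ymax)` of the study region.
#' @return a `road_network` (data frame subclass).
#' @export
road_network <- function(edges, extent) {
  need <- c("road_id", "x0", "y0", "x1", "y1", "flow", "heavy_fraction",
            "authority", "has_count_data")
  if (!all(need %in% names(edges))) {
    stop_config("road network edges missing columns: %s",
                paste(setdiff(need, names(edges)), collapse = ", "))
  }
  if (nrow(edges) > 0) {
    stopifnot(all(edges$flow >= 0),
              all(edges$heavy_fraction >= 0 & edges$heavy_fraction <= 1),
              all(edges$authority %in% ROAD_AUTHORITIES))
  }
  edges$length <- segment_lengths(edges$x0, edges$y0, edges$x1, edges$y1)
  structure(edges, extent = as.numeric(extent),
            class = c("road_network", "data.frame"))
}

network_extent <- function(network) {
  e <- attr(network, "extent")
  names(e) <- c("xmin", "xmax", "ymin", "ymax")
  e
}

network_diagonal <- function(network) {
  e <- network_extent(network)
  sqrt((e["xmax"] - e["xmin"])^2 + (e["ymax"] - e["ymin"])^2)[[1]]
}

#' Road-class thresholds
#'
#' Busy and main roads are defined by traffic load cutoffs (>= 5,000 and
#' >= 10,000 vehicles/24 hr by default); freeways are identified by the
#' national managing authority.
#'
#' @param busy_threshold vehicles/24 hr (default 5000).
#' @param main_threshold vehicles/24 hr (default 10000), must be >= busy.
#' @return a `road_class_rule` list.
#' @export
road_class_rule <- function(busy_threshold = 5000, main_threshold = 10000) {
  if (!(main_threshold >= busy_threshold && busy_threshold > 0))
    stop_config("need main_threshold >= busy_threshold > 0")
  structure(list(busy_threshold = busy_threshold, main_threshold = main_threshold),
            class = "road_class_rule")
}

#' Classify one road segment into nested road classes
#'
#' Thresholds are applied as greater-or-equal, so a road at exactly 5,000
#' vehicles/24 hr counts as busy. Classes nest: main implies busy implies all.
#'
#' @param flow vehicles/24 hr.
#' @param authority one of "national", "provincial", "municipal".
#' @param rule a [road_class_rule()].
#' @return character vector of classes among `all, busy, main, freeway`.
#' @export
classify_road <- function(flow, authority = "municipal", rule = road_class_rule()) {
  cls <- "all"
  if (flow >= rule$busy_threshold) cls <- c(cls, "busy")
  if (flow >= rule$main_threshold) cls <- c(cls, "main")
  if (authority == "national") cls <- c(cls, "freeway")
  cls
}

# Logical mask of edges belonging to a class (vectorised classify_road).
edge_in_class <- function(network, class, rule) {
  switch(class,
    all = rep(TRUE, nrow(network)),
    busy = network$flow >= rule$busy_threshold,
    main = network$flow >= rule$main_threshold,
    freeway = network$authority == "national",
    stop_config("unknown road class '%s'", class)
  )
}

#' Assign the minimal flow to roads without count data
#'
#' Roads for which no traffic count was provided (quiet municipal streets,
#' typically) receive a fixed minimal flow; roads with data are untouched.
#'
#' @param network a `road_network`.
#' @param minimal vehicles/24 hr (default 1225).
#' @return the network with flows replaced on `has_count_data == FALSE` roads.
#' @export
assign_minimal_flow <- function(network, minimal = 1225) {
  if (minimal < 0) stop_config("minimal flow must be >= 0")
  network$flow[!network$has_count_data] <- minimal
  network
}

#' Write a road network as GeoJSON LineStrings
#'
#' One feature per road, vertices in edge order, properties flow,
#' heavy_fraction, authority, has_count_data.
#'
#' @param network a `road_network`.
#' @param path output path.
#' @export
write_roads_geojson <- function(network, path) {
  feats <- lapply(split(seq_len(nrow(network)), network$road_id), function(idx) {
    ed <- network[idx, , drop = FALSE]
    coords <- rbind(cbind(ed$x0, ed$y0), cbind(ed$x1[nrow(ed)], ed$y1[nrow(ed)]))
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(coords)),
                                           function(i) as.numeric(coords[i, ]))),
      properties = list(road_id = ed$road_id[1], flow = ed$flow[1],
                        heavy_fraction = ed$heavy_fraction[1],
                        authority = ed$authority[1],
                        has_count_data = ed$has_count_data[1])
    )
  })
  e <- network_extent(network)
  obj <- list(type = "FeatureCollection", bbox = as.numeric(e[c(1, 3, 2, 4)]),
              features = unname(feats))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road network from GeoJSON LineStrings
#'
#' @param path GeoJSON file written by [write_roads_geojson()] (or compatible).
#' @return a `road_network`.
#' @export
read_roads_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- lapply(obj$features, function(f) {
    cc <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    n <- nrow(cc) - 1
    p <- f$properties
    data.frame(road_id = p$road_id,
               x0 = cc[seq_len(n), 1], y0 = cc[seq_len(n), 2],
               x1 = cc[seq_len(n) + 1, 1], y1 = cc[seq_len(n) + 1, 2],
               flow = p$flow, heavy_fraction = p$heavy_fraction,
               authority = p$authority, has_count_data = p$has_count_data)
  })
  bb <- unlist(obj$bbox)
  road_network(do.call(rbind, rows), extent = bb[c(1, 3, 2, 4)])
}
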