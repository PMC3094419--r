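# Synthetic study-region generator. Emulates a densely populated lowland
# region: a mix of rural, suburban and urban terrain, a dense municipal street
# network plus provincial roads and national freeways, categorical land use on
# a fine grid (with a majority-aggregated coarse version emulating a 100 m
# class map), and a population raster tied to residential land use.

LANDUSE_CATEGORIES <- c(residential = 1, industry = 2, port = 3, transport = 4,
                        green = 5, water = 6, agriculture = 7)

#' Configuration for the synthetic region
#'
#' Defaults give a 6 x 6 km region with a 25 m land-use grid (coarsened by 4
#' to a 100 m product), a 100 m population raster, and road densities /
#' count-data availability chosen so that most municipal streets carry no
#' traffic count (and hence get the minimal-flow default downstream).
#'
#' @param width,height region extent in metres.
#' @param cell_size fine land-use cell size (m).
#' @param coarse_factor aggregation factor for the coarse land-use product.
#' @param pop_cell_size population raster cell size (m).
#' @param road_density named km of road per km^2 by authority.
#' @param count_prob named probability that a road has count data, by authority.
#' @param flow_meanlog,flow_sdlog lognormal flow parameters by authority.
#' @param flow_range named list of c(min, max) flow clamps by authority.
#' @param heavy_range named list of c(min, max) heavy-duty fraction by authority.
#' @param n_patches number of land-use patch seeds.
#' @param pop_density mean inhabitants per populated population-raster cell.
#' @return a `region_config` list.
#' @export
region_config <- function(width = 6000, height = 6000,
                          cell_size = 25, coarse_factor = 4,
                          pop_cell_size = 100,
                          road_density = c(national = 0.15, provincial = 0.5,
                                           municipal = 2.2),
                          count_prob = c(national = 0.94, provincial = 0.58,
                                         municipal = 0.48),
                          flow_meanlog = c(national = log(28000),
                                           provincial = log(9000),
                                           municipal = log(2800)),
                          flow_sdlog = c(national = 0.3, provincial = 0.5,
                                         municipal = 0.8),
                          flow_range = list(national = c(10000, 90000),
                                            provincial = c(2000, 35000),
                                            municipal = c(200, 18000)),
                          heavy_range = list(national = c(0.10, 0.25),
                                             provincial = c(0.06, 0.18),
                                             municipal = c(0.02, 0.12)),
                          n_patches = 140,
                          pop_density = 45) {
  if (width <= 0 || height <= 0) stop_config("region extent must be positive")
  if (cell_size <= 0 || pop_cell_size <= 0) stop_config("grid resolution must be positive")
  structure(list(width = width, height = height, cell_size = cell_size,
                 coarse_factor = coarse_factor, pop_cell_size = pop_cell_size,
                 road_density = road_density, count_prob = count_prob,
                 flow_meanlog = flow_meanlog, flow_sdlog = flow_sdlog,
                 flow_range = flow_range, heavy_range = heavy_range,
                 n_patches = n_patches, pop_density = pop_density),
            class = "region_config")
}

# One random polyline for an authority class, clamped to the extent.
random_polyline <- function(config, authority) {
  long <- authority == "national"
  n_edge <- if (long) sample(2:3, 1) else sample(2:5, 1)
  step <- if (long) stats::runif(n_edge, 1200, 3000) else stats::runif(n_edge, 300, 900)
  x <- stats::runif(1, 0, config$width)
  y <- stats::runif(1, 0, config$height)
  heading <- stats::runif(1, 0, 2 * pi)
  xs <- x; ys <- y
  for (k in seq_len(n_edge)) {
    heading <- heading + stats::runif(1, -pi / 6, pi / 6)
    x <- clamp(x + step[k] * cos(heading), 0, config$width)
    y <- clamp(y + step[k] * sin(heading), 0, config$height)
    xs <- c(xs, x); ys <- c(ys, y)
  }
  keep <- c(TRUE, sqrt(diff(xs)^2 + diff(ys)^2) > 1)
  cbind(xs[keep], ys[keep])
}

generate_roads <- function(config) {
  area_km2 <- config$width * config$height / 1e6
  rows <- list()
  road_id <- 0L
  for (auth in ROAD_AUTHORITIES) {
    target <- config$road_density[[auth]] * area_km2 * 1000  # metres
    total <- 0
    while (total < target) {
      pl <- random_polyline(config, auth)
      if (nrow(pl) < 2) next
      road_id <- road_id + 1L
      x0 <- pl[-nrow(pl), 1]; y0 <- pl[-nrow(pl), 2]
      x1 <- pl[-1, 1]; y1 <- pl[-1, 2]
      lens <- segment_lengths(x0, y0, x1, y1)
      # truncate the final polyline so class totals hit the target density
      cum <- total + cumsum(lens)
      if (cum[length(cum)] > target) {
        k <- which(cum > target)[1]
        excess <- cum[k] - target
        frac <- max(0.05, 1 - excess / lens[k])
        x1[k] <- x0[k] + frac * (x1[k] - x0[k])
        y1[k] <- y0[k] + frac * (y1[k] - y0[k])
        x0 <- x0[seq_len(k)]; y0 <- y0[seq_len(k)]
        x1 <- x1[seq_len(k)]; y1 <- y1[seq_len(k)]
        lens <- segment_lengths(x0, y0, x1, y1)
      }
      total <- total + sum(lens)
      fl <- clamp(stats::rlnorm(1, config$flow_meanlog[[auth]], config$flow_sdlog[[auth]]),
                  config$flow_range[[auth]][1], config$flow_range[[auth]][2])
      # counts exist preferentially for the busier roads: it is the quiet
      # streets that end up with the minimal-flow default downstream
      z <- (log(fl) - config$flow_meanlog[[auth]]) / config$flow_sdlog[[auth]]
      counted <- (z + stats::rnorm(1, 0, 0.35)) >
        stats::qnorm(1 - config$count_prob[[auth]])
      rows[[length(rows) + 1L]] <- data.frame(
        road_id = road_id, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
        flow = round(fl),
        heavy_fraction = stats::runif(1, config$heavy_range[[auth]][1],
                                      config$heavy_range[[auth]][2]),
        authority = auth,
        has_count_data = counted
      )
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(road_id = integer(), x0 = numeric(), y0 = numeric(),
               x1 = numeric(), y1 = numeric(), flow = numeric(),
               heavy_fraction = numeric(), authority = character(),
               has_count_data = logical())
  road_network(edges, extent = c(0, config$width, 0, config$height))
}

generate_landuse <- function(config) {
  nx <- ceiling(config$width / config$cell_size)
  ny <- ceiling(config$height / config$cell_size)
  sx <- stats::runif(config$n_patches, 0, config$width)
  sy <- stats::runif(config$n_patches, 0, config$height)
  # category probabilities shift towards residential/industrial near the core
  dc <- sqrt((sx - config$width / 2)^2 + (sy - config$height / 2)^2)
  w <- exp(-(dc / (0.35 * max(config$width, config$height)))^2)
  cats <- names(LANDUSE_CATEGORIES)
  seed_cat <- vapply(seq_len(config$n_patches), function(i) {
    p <- c(residential = 0.08 + 0.55 * w[i],
           industry = 0.04 + 0.06 * w[i],
           port = 0.02 + 0.04 * w[i],
           transport = 0.02 + 0.03 * w[i],
           green = 0.12,
           water = 0.08,
           agriculture = 0.60 * (1 - w[i]) + 0.04)
    sample(cats, 1, prob = p)
  }, character(1))
  cx <- (seq_len(nx) - 0.5) * config$cell_size
  cy <- (seq_len(ny) - 0.5) * config$cell_size
  best_d <- matrix(Inf, ny, nx)
  best_k <- matrix(1L, ny, nx)
  for (k in seq_len(config$n_patches)) {
    d <- outer((cy - sy[k])^2, (cx - sx[k])^2, "+")
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_k[upd] <- k
  }
  codes <- matrix(LANDUSE_CATEGORIES[seed_cat[best_k]], ny, nx)
  storage.mode(codes) <- "integer"
  landuse_grid(codes, origin = c(0, 0), cell_size = config$cell_size,
               category_names = stats::setNames(names(LANDUSE_CATEGORIES),
                                                LANDUSE_CATEGORIES))
}

generate_population <- function(config, landuse) {
  nx <- ceiling(config$width / config$pop_cell_size)
  ny <- ceiling(config$height / config$pop_cell_size)
  counts <- matrix(0, ny, nx)
  fac <- config$pop_cell_size / landuse$cell_size
  res_code <- LANDUSE_CATEGORIES[["residential"]]
  for (i in seq_len(ny)) {
    rows <- pmin(nrow(landuse$values), floor((i - 1) * fac) + seq_len(ceiling(fac)))
    for (j in seq_len(nx)) {
      cols <- pmin(ncol(landuse$values), floor((j - 1) * fac) + seq_len(ceiling(fac)))
      frac_res <- mean(landuse$values[rows, cols] == res_code)
      if (frac_res > 0) {
        counts[i, j] <- round(config$pop_density * frac_res *
                                stats::rlnorm(1, 0, 0.25))
      }
    }
  }
  population_grid(counts, origin = c(0, 0), cell_size = config$pop_cell_size)
}

#' Generate a synthetic study region
#'
#' Produces a road network with traffic attributes, a fine categorical
#' land-use grid plus a majority-aggregated coarse version, and a population
#' raster. Fully reproducible for a fixed seed.
#'
#' @param config a [region_config()].
#' @param seed integer seed (optional; caller may also set the RNG itself).
#' @return a `lur_region` list: `network`, `landuse` (fine), `landuse_coarse`,
#'   `population`, `extent`, `config`.
#' @export
generate_region <- function(config = region_config(), seed = NULL) {
  with_seed(seed, {
    network <- generate_roads(config)
    landuse <- generate_landuse(config)
    population <- generate_population(config, landuse)
    structure(list(network = network,
                   landuse = landuse,
                   landuse_coarse = coarsen_landuse(landuse, config$coarse_factor),
                   population = population,
                   extent = c(0, config$width, 0, config$height),
                   config = config),
              class = "lur_region")
  })
}
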