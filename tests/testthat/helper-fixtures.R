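# Shared fixtures, built in code at test time.

# A single horizontal road along the x-axis through (0,0)-(1000,0).
one_road_network <- function(flow = 8000, heavy = 0.1, authority = "provincial",
                             has_count_data = TRUE,
                             extent = c(-200, 1200, -600, 600)) {
  road_network(data.frame(road_id = 1L, x0 = 0, y0 = 0, x1 = 1000, y1 = 0,
                          flow = flow, heavy_fraction = heavy,
                          authority = authority,
                          has_count_data = has_count_data),
               extent = extent)
}

# n random straight roads inside [0, size]^2.
random_network <- function(n = 25, size = 2000, flow_range = c(500, 30000)) {
  x0 <- runif(n, 0, size); y0 <- runif(n, 0, size)
  ang <- runif(n, 0, 2 * pi)
  len <- runif(n, 200, 900)
  road_network(data.frame(
    road_id = seq_len(n),
    x0 = x0, y0 = y0,
    x1 = pmin(pmax(x0 + len * cos(ang), 0), size),
    y1 = pmin(pmax(y0 + len * sin(ang), 0), size),
    flow = runif(n, flow_range[1], flow_range[2]),
    heavy_fraction = runif(n, 0, 0.3),
    authority = sample(c("national", "provincial", "municipal"), n, TRUE),
    has_count_data = runif(n) < 0.7), extent = c(0, size, 0, size))
}

# Random categorical grid over [0, n*cs]^2 with codes 1..k.
random_landuse <- function(nx = 40, ny = 40, cs = 50, k = 3, origin = c(0, 0)) {
  codes <- matrix(sample.int(k, nx * ny, replace = TRUE), ny, nx)
  nm <- stats::setNames(paste0("cat", seq_len(k)), seq_len(k))
  landuse_grid(codes, origin, cs, nm)
}

uniform_landuse <- function(nx = 30, ny = 30, cs = 50, code = 1) {
  landuse_grid(matrix(as.integer(code), ny, nx), c(0, 0), cs,
               stats::setNames("only", code))
}

# Small region for generator-level tests (fast).
small_region_config <- function(...) {
  region_config(width = 3000, height = 3000, cell_size = 30, coarse_factor = 4,
                pop_cell_size = 120, n_patches = 60, ...)
}

# Independent nearest-distance oracle: per-edge 1-D minimisation of the
# distance along the segment parameter, then the minimum over edges.
oracle_nearest_distance <- function(network, x, y, class, rule = road_class_rule()) {
  keep <- which(lursim:::edge_in_class(network, class, rule))
  if (length(keep) == 0L) return(Inf)
  dmin <- Inf
  for (i in keep) {
    f <- function(t) {
      px <- network$x0[i] + t * (network$x1[i] - network$x0[i])
      py <- network$y0[i] + t * (network$y1[i] - network$y0[i])
      sqrt((px - x)^2 + (py - y)^2)
    }
    d <- min(f(0), f(1), stats::optimize(f, c(0, 1), tol = 1e-12)$objective)
    dmin <- min(dmin, d)
  }
  dmin
}

# Discretised line-integration oracle for buffer traffic.
oracle_buffer_traffic <- function(network, x, y, r, step = 0.1, what = "flow") {
  tot <- 0
  for (i in seq_len(nrow(network))) {
    len <- network$length[i]
    if (len == 0) next
    t <- seq(step / 2, len - step / 2, by = step) / len
    px <- network$x0[i] + t * (network$x1[i] - network$x0[i])
    py <- network$y0[i] + t * (network$y1[i] - network$y0[i])
    inside <- (px - x)^2 + (py - y)^2 <= r^2
    w <- if (what == "flow") network$flow[i] else
      network$flow[i] * network$heavy_fraction[i]
    tot <- tot + w * sum(inside) * step
  }
  tot
}

# Whole-grid brute force for the cell-centre membership rule.
oracle_buffer_cells <- function(grid, x, y, r) {
  cs <- grid$cell_size
  ny <- nrow(grid$values); nx <- ncol(grid$values)
  cx <- grid$origin[1] + (seq_len(nx) - 0.5) * cs
  cy <- grid$origin[2] + (seq_len(ny) - 0.5) * cs
  keep <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    keep[i, j] <- (cx[j] - x)^2 + (cy[i] - y)^2 <= r^2
  }
  keep
}

# Exhaustive forward-selection oracle: all offering orders of the candidate
# columns (one per family, one group), accept iff adjusted R^2 improves by
# >= delta points and all signs match; returns the set of reachable models.
oracle_forward_sets <- function(y, table, candidates, signs, a_priori = character(),
                                delta = 1.0) {
  fit_adj <- function(vars) {
    if (length(vars) == 0L) return(list(adj = 0, coefs = numeric()))
    X <- cbind(1, as.matrix(table[, vars, drop = FALSE]))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    n <- length(y); p <- length(vars)
    list(adj = 1 - (rss / (n - p - 1)) / (tss / (n - 1)),
         coefs = fit$coefficients[-1])
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  reachable <- character()
  for (ord in perms(candidates)) {
    sel <- a_priori
    cur <- fit_adj(sel)$adj
    for (cand in ord) {
      trial <- c(sel, cand)
      f <- fit_adj(trial)
      ok_sign <- all(sign(f$coefs) == signs[trial])
      if (f$adj - cur >= delta / 100 && ok_sign) {
        sel <- trial
        cur <- f$adj
      }
    }
    reachable <- union(reachable, paste(sort(sel), collapse = "|"))
  }
  reachable
}
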