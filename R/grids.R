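# Raster containers for categorical land use and population counts. A grid is
# a plain list: lower-left origin, square cell size, and a matrix of values
# indexed [row = y index from the bottom, col = x index]. ESRI ASCII files
# store rows top-down; the reader/writer flips accordingly.

new_grid <- function(values, origin, cell_size, class) {
  if (cell_size <= 0) stop_config("cell_size must be > 0")
  stopifnot(is.matrix(values))
  structure(
    list(values = values, origin = as.numeric(origin), cell_size = cell_size),
    class = unique(c(class, "spatial_grid"))
  )
}

#' Categorical land-use grid
#'
#' @param codes integer matrix of category codes, `[y from bottom, x]`.
#' @param origin lower-left corner `c(x, y)` in metres.
#' @param cell_size square cell edge in metres.
#' @param category_names named character vector mapping code (as name) to label.
#' @return a `landuse_grid` object.
#' @export
landuse_grid <- function(codes, origin, cell_size, category_names) {
  g <- new_grid(codes, origin, cell_size, "landuse_grid")
  if (!all(as.character(unique(as.vector(codes))) %in% names(category_names)))
    stop_config("every cell code must be present in category_names")
  g$category_names <- category_names
  g
}

#' Population-count grid
#'
#' @param counts numeric matrix of inhabitants per cell (>= 0).
#' @inheritParams landuse_grid
#' @return a `population_grid` object.
#' @export
population_grid <- function(counts, origin, cell_size) {
  if (any(counts < 0)) stop_config("population counts must be >= 0")
  new_grid(counts, origin, cell_size, "population_grid")
}

grid_extent <- function(grid) {
  c(xmin = grid$origin[1],
    xmax = grid$origin[1] + ncol(grid$values) * grid$cell_size,
    ymin = grid$origin[2],
    ymax = grid$origin[2] + nrow(grid$values) * grid$cell_size)
}

grid_covers <- function(grid, x, y) {
  e <- grid_extent(grid)
  x >= e["xmin"] & x <= e["xmax"] & y >= e["ymin"] & y <= e["ymax"]
}

# Indices of cells whose centre lies within the disc of radius r around (x, y).
# Returns a matrix index (row, col) restricted to the grid; may be empty.
buffer_cell_index <- function(grid, x, y, r) {
  cs <- grid$cell_size
  nx <- ncol(grid$values)
  ny <- nrow(grid$values)
  ix_lo <- max(1L, floor((x - r - grid$origin[1]) / cs) + 1L)
  ix_hi <- min(nx, ceiling((x + r - grid$origin[1]) / cs))
  iy_lo <- max(1L, floor((y - r - grid$origin[2]) / cs) + 1L)
  iy_hi <- min(ny, ceiling((y + r - grid$origin[2]) / cs))
  if (ix_lo > ix_hi || iy_lo > iy_hi) return(cbind(row = integer(), col = integer()))
  ix <- ix_lo:ix_hi
  iy <- iy_lo:iy_hi
  cxs <- grid$origin[1] + (ix - 0.5) * cs
  cys <- grid$origin[2] + (iy - 0.5) * cs
  dx2 <- outer(rep(1, length(iy)), (cxs - x)^2)
  dy2 <- outer((cys - y)^2, rep(1, length(ix)))
  keep <- which(dx2 + dy2 <= r * r, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(cbind(row = integer(), col = integer()))
  cbind(row = iy[keep[, 1]], col = ix[keep[, 2]])
}

# Cell containing the point, or NULL if outside coverage.
cell_at <- function(grid, x, y) {
  if (!grid_covers(grid, x, y)) return(NULL)
  ix <- min(ncol(grid$values), max(1L, floor((x - grid$origin[1]) / grid$cell_size) + 1L))
  iy <- min(nrow(grid$values), max(1L, floor((y - grid$origin[2]) / grid$cell_size) + 1L))
  cbind(row = iy, col = ix)
}

#' Aggregate a land-use grid to a coarser resolution
#'
#' Majority vote within non-overlapping `factor` x `factor` blocks, emulating
#' the derivation of a coarse land-use product (100 m class maps) from a
#' high-resolution one.
#'
#' @param grid a `landuse_grid`.
#' @param factor integer aggregation factor (>= 2).
#' @return a `landuse_grid` with cell size `factor * grid$cell_size`.
#' @export
coarsen_landuse <- function(grid, factor) {
  stopifnot(inherits(grid, "landuse_grid"), factor >= 2, factor == round(factor))
  v <- grid$values
  ny <- floor(nrow(v) / factor)
  nx <- floor(ncol(v) / factor)
  out <- matrix(0L, ny, nx)
  for (i in seq_len(ny)) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    for (j in seq_len(nx)) {
      cols <- ((j - 1) * factor + 1):(j * factor)
      block <- v[rows, cols]
      tab <- tabulate(block + 1L)
      out[i, j] <- which.max(tab) - 1L
    }
  }
  landuse_grid(out, grid$origin, grid$cell_size * factor, grid$category_names)
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid a `spatial_grid`.
#' @param path output file path.
#' @param nodata NODATA sentinel written in the header.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %s", format(nodata))
  )
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file path.
#' @param as one of "numeric" or "integer" for the value matrix.
#' @return a list with `values`, `origin`, `cell_size` (a bare `spatial_grid`).
#' @export
read_ascii_grid <- function(path, as = c("numeric", "integer")) {
  as <- match.arg(as)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(i) as.numeric(strsplit(trimws(hdr[i]), "\\s+")[[1]][2])
  ncols <- as.integer(val(1)); nrows <- as.integer(val(2))
  origin <- c(val(3), val(4)); cs <- val(5)
  nums <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(nums, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]
  if (as == "integer") storage.mode(m) <- "integer"
  new_grid(m, origin, cs, "spatial_grid")
}
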