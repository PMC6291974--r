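# Regular metric raster grid: the single container behind every stage-1
# layer (land-use screen, catchment masks, density, class, suitability).

#' Create a raster grid
#'
#' A regular planar grid with its origin at the lower-left corner, square
#' cells of `cell_size` meters and one value per cell sampled at the cell
#' center. Values are stored as a matrix whose first row is the *bottom*
#' (southernmost) row, so `values[r, c]` sits at
#' `origin + (c - 0.5, r - 0.5) * cell_size`. All layers entering an overlay
#' must share origin, cell size and shape.
#'
#' @param origin numeric length-2, lower-left corner (x, y) in meters.
#' @param cell_size cell edge length in meters, > 0.
#' @param values numeric matrix of cell values (bottom row first), or `NULL`
#'   to allocate a zero grid of `n_rows` x `n_cols`.
#' @param n_rows,n_cols grid shape, used when `values` is `NULL`.
#' @return an object of class `raster_grid`.
#' @export
#' @examples
#' g <- raster_grid(c(0, 0), 10, n_rows = 5, n_cols = 4)
#' dim(g$values)
raster_grid <- function(origin, cell_size, values = NULL, n_rows = NULL, n_cols = NULL) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 2, all(is.finite(origin)))
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be a single positive number (meters)", call. = FALSE)
  }
  if (is.null(values)) {
    if (is.null(n_rows) || is.null(n_cols)) {
      stop("provide either values or n_rows and n_cols", call. = FALSE)
    }
    values <- matrix(0, nrow = n_rows, ncol = n_cols)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("format error: raster grid must have at least one cell", call. = FALSE)
  }
  structure(
    list(origin = origin, cell_size = cell_size,
         n_rows = nrow(values), n_cols = ncol(values), values = values),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Cell-center coordinates of a raster grid
#'
#' @param grid a `raster_grid`.
#' @return a list with `x` (length `n_cols`), `y` (length `n_rows`) center
#'   coordinates, and `xy`, a two-column matrix of all centers in storage
#'   order (row-major over the value matrix, bottom row first).
#' @export
cell_centers <- function(grid) {
  x <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  y <- grid$origin[2] + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  list(x = x, y = y,
       xy = cbind(x = rep(x, each = grid$n_rows), y = rep(y, times = grid$n_cols)))
}

# note: grid$values is indexed [row, col] with row 1 at the bottom, so the
# storage-order vector as.numeric(values) walks columns bottom-to-top; the
# xy matrix above follows the same order.

#' Locate the cell containing a point
#'
#' Cells are half-open, `[x, x + cell) x [y, y + cell)`; points on the
#' extreme top/right edge of the grid belong to the last cell. Points
#' outside the extent map to `NA`.
#'
#' @param grid a `raster_grid`.
#' @param x,y numeric vectors of point coordinates.
#' @return a list with integer vectors `row` and `col` (NA outside).
#' @export
cell_of_point <- function(grid, x, y) {
  eps <- 1e-9 * grid$cell_size
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((y - grid$origin[2]) / grid$cell_size) + 1L
  xmax <- grid$origin[1] + grid$n_cols * grid$cell_size
  ymax <- grid$origin[2] + grid$n_rows * grid$cell_size
  col[col == grid$n_cols + 1L & abs(x - xmax) <= eps] <- grid$n_cols
  row[row == grid$n_rows + 1L & abs(y - ymax) <= eps] <- grid$n_rows
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Do two grids share geometry?
#' @param a,b `raster_grid` objects.
#' @return TRUE if origin, cell size and shape agree (1e-9 m tolerance).
#' @export
same_geometry <- function(a, b) {
  all(abs(a$origin - b$origin) <= 1e-9) &&
    abs(a$cell_size - b$cell_size) <= 1e-9 &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Write a raster grid to an ASCII grid file
#'
#' Plain-text ASCII grid dialect: a five-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`) followed by the rows of values
#' top-to-bottom. Values are written with 17 significant digits so the
#' round-trip is lossless at double precision.
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @export
write_raster <- function(grid, path) {
  if (!inherits(grid, "raster_grid")) grid <- do.call(raster_grid, grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", grid$origin[2]),
    sprintf("cellsize %.17g", grid$cell_size)
  ), con)
  for (r in rev(seq_len(grid$n_rows))) {
    writeLines(paste(sprintf("%.17g", grid$values[r, ]), collapse = " "), con)
  }
  invisible(NULL)
}

#' Read a raster grid from an ASCII grid file
#' @param path path to a file written by [write_raster()] (or any ASCII grid
#'   with the same five header keys).
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("format error: truncated ASCII grid", call. = FALSE)
  hdr <- list()
  for (i in 1:5) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2) stop("format error: malformed ASCII grid header", call. = FALSE)
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("format error: ASCII grid header missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (is.na(nc) || is.na(nr) || nc < 1 || nr < 1) {
    stop("format error: ASCII grid must have at least one cell", call. = FALSE)
  }
  vals <- scan(text = paste(lines[-(1:5)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nc * nr) {
    stop(sprintf("format error: expected %d values, found %d", nc * nr, length(vals)),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # rows as stored: top first
  raster_grid(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize,
              values = m[rev(seq_len(nr)), , drop = FALSE])
}

#' Rasterize land parcels to a binary developable-land screen
#'
#' Implements the land-use reclassification: a cell whose center falls
#' inside any parcel marked `used` gets 0 (not developable), every other
#' cell gets 1. Cells outside every parcel count as unused (1) by default;
#' set `outside_is_used = TRUE` to treat unparceled ground as unavailable.
#' Cell membership is decided at the cell center with boundary points
#' counting as inside.
#'
#' @param parcels a list of parcels, each `list(geometry = <2-col matrix>,
#'   used = <logical>)`, as returned by [read_vector_layer()] with the
#'   `landuse` schema.
#' @param template a `raster_grid` defining the output geometry.
#' @param outside_is_used treat cells outside all parcels as used (0)?
#' @return a binary `raster_grid` (1 = developable).
#' @export
rasterize_polygons <- function(parcels, template, outside_is_used = FALSE) {
  cc <- cell_centers(template)
  px <- cc$xy[, 1]; py <- cc$xy[, 2]
  in_used <- logical(length(px))
  in_any <- logical(length(px))
  for (p in parcels) {
    ring <- repair_ring(p$geometry)
    hit <- point_in_polygon(px, py, ring)
    in_any <- in_any | hit
    if (isTRUE(p$used)) in_used <- in_used | hit
  }
  v <- ifelse(in_used, 0, ifelse(in_any | !outside_is_used, 1, 0))
  raster_grid(template$origin, template$cell_size,
              values = matrix(v, nrow = template$n_rows, ncol = template$n_cols))
}
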