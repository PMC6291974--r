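# Stage 1: build the screening rasters (developable land, outside-catchment
# masks, elderly population density), reclassify, overlay into a suitability
# surface, and extract the candidate-site lattice.

#' Kernel density configuration
#'
#' @param bandwidth bandwidth h in meters, or `"auto"` to select by
#'   least-squares cross-validation over `bandwidth_grid`.
#' @param bandwidth_grid candidate h values searched when `bandwidth` is
#'   `"auto"`; `NULL` defers to the pipeline default (10 log-spaced values
#'   between the cell size and a quarter of the extent).
#' @return a `kde_config` list. The kernel is a fixed isotropic bivariate
#'   Gaussian.
#' @export
kde_config <- function(bandwidth = "auto", bandwidth_grid = NULL) {
  if (!identical(bandwidth, "auto")) {
    if (!is.numeric(bandwidth) || length(bandwidth) != 1 || bandwidth <= 0) {
      stop("bandwidth must be a positive number of meters or \"auto\"", call. = FALSE)
    }
  } else if (!is.null(bandwidth_grid) && (!is.numeric(bandwidth_grid) ||
                                          !length(bandwidth_grid) ||
                                          any(bandwidth_grid <= 0))) {
    stop("bandwidth_grid must be a non-empty vector of positive bandwidths", call. = FALSE)
  }
  structure(list(bandwidth = bandwidth, bandwidth_grid = bandwidth_grid),
            class = "kde_config")
}

#' Mask of ground beyond the catchment of every existing facility
#'
#' A cell scores 1 when its center lies strictly more than `radius` meters
#' (straight-line) from the nearest listed facility — i.e. the facility type
#' does not serve it — and 0 inside any catchment. With no facilities the
#' whole grid is unserved (all 1).
#'
#' @param facilities data frame with columns `x`, `y` (typically the subset
#'   of one `kind` from [read_vector_layer()]).
#' @param radius service radius in meters (> 0); 600 for healthcare centers,
#'   300 for clinics.
#' @param template a `raster_grid` defining the output geometry.
#' @return binary `raster_grid` (1 = unserved).
#' @export
buffer_uncovered_mask <- function(facilities, radius, template) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive", call. = FALSE)
  cc <- cell_centers(template)
  if (is.null(facilities) || nrow(facilities) == 0) {
    return(raster_grid(template$origin, template$cell_size,
                       values = matrix(1, template$n_rows, template$n_cols)))
  }
  mind2 <- rep(Inf, nrow(cc$xy))
  for (i in seq_len(nrow(facilities))) {
    d2 <- (cc$xy[, 1] - facilities$x[i])^2 + (cc$xy[, 2] - facilities$y[i])^2
    mind2 <- pmin(mind2, d2)
  }
  v <- as.numeric(mind2 > radius^2)
  raster_grid(template$origin, template$cell_size,
              values = matrix(v, template$n_rows, template$n_cols))
}

#' Weighted Gaussian kernel density surface
#'
#' Evaluates, at every cell center, the population-weighted bivariate
#' Gaussian kernel density
#' `f(x) = sum_i w_i * exp(-d_i^2 / (2 h^2)) / (2 * pi * h^2)`,
#' where `d_i` is the straight-line distance to point i. With this
#' normalisation the surface integrates (over the whole plane) to the total
#' weight, so density is in persons per square meter and total population is
#' conserved.
#'
#' @param points data frame with columns `x`, `y` and a weight column `w`
#'   (e.g. per-building elderly headcounts).
#' @param config a [kde_config()] with a numeric bandwidth, or a bare
#'   numeric bandwidth in meters.
#' @param template a `raster_grid` defining the evaluation grid.
#' @return `raster_grid` of densities (persons/m^2).
#' @export
kde_density <- function(points, config, template) {
  h <- if (inherits(config, "kde_config")) config$bandwidth else config
  if (!is.numeric(h) || length(h) != 1 || h <= 0) {
    stop("kde_density needs a concrete positive bandwidth; run select_bandwidth() first",
         call. = FALSE)
  }
  w <- points$w
  if (is.null(w)) stop("points must carry a weight column 'w'", call. = FALSE)
  if (!any(w > 0)) stop("degenerate input: total point weight is zero", call. = FALSE)
  cc <- cell_centers(template)
  acc <- numeric(nrow(cc$xy))
  norm <- 1 / (2 * pi * h^2)
  for (i in seq_len(nrow(points))) {
    if (w[i] == 0) next
    d2 <- (cc$xy[, 1] - points$x[i])^2 + (cc$xy[, 2] - points$y[i])^2
    acc <- acc + w[i] * norm * exp(-d2 / (2 * h^2))
  }
  raster_grid(template$origin, template$cell_size,
              values = matrix(acc, template$n_rows, template$n_cols))
}

#' Select the KDE bandwidth by least-squares cross-validation
#'
#' The classical bandwidth target is the minimiser of the mean integrated
#' squared error (MISE) of the density estimate; since the true density is
#' unknown, the unbiased least-squares cross-validation (LSCV) estimate is
#' minimised over a grid of candidate bandwidths instead. For the bivariate
#' Gaussian kernel the LSCV score has the closed form
#' `LSCV(h) = W^-2 sum_ij w_i w_j phi_{h sqrt 2}(d_ij)
#'   - 2 W^-1 sum_i w_i (W - w_i)^-1 sum_{j != i} w_j phi_h(d_ij)`,
#' with `phi_h(d) = exp(-d^2 / (2 h^2)) / (2 pi h^2)` and `W = sum w_i`;
#' weights act as multiplicities.
#'
#' @param points data frame with `x`, `y` and weights `w` (>= 5 points).
#' @param grid_of_h positive candidate bandwidths (meters).
#' @return the bandwidth minimising LSCV (first on ties).
#' @export
select_bandwidth <- function(points, grid_of_h) {
  if (nrow(points) < 5) stop("need at least 5 points to cross-validate", call. = FALSE)
  if (!is.numeric(grid_of_h) || !length(grid_of_h) || any(grid_of_h <= 0)) {
    stop("grid_of_h must be positive bandwidths", call. = FALSE)
  }
  w <- if (is.null(points$w)) rep(1, nrow(points)) else points$w
  W <- sum(w)
  if (W <= 0) stop("degenerate input: total point weight is zero", call. = FALSE)
  d2 <- as.matrix(stats::dist(cbind(points$x, points$y)))^2
  ww <- outer(w, w)
  scores <- vapply(grid_of_h, function(h) {
    phi <- function(dd2, hh) exp(-dd2 / (2 * hh^2)) / (2 * pi * hh^2)
    term1 <- sum(ww * phi(d2, h * sqrt(2))) / W^2
    k <- phi(d2, h); diag(k) <- 0
    loo <- as.numeric(k %*% w) / (W - w)     # f_{-i}(x_i)
    term1 - 2 * sum(w * loo) / W
  }, numeric(1))
  if (all(!is.finite(scores))) {
    stop("bandwidth selection failed: no finite LSCV score on the grid", call. = FALSE)
  }
  grid_of_h[which.min(scores)]
}

#' Reclassify a density raster into ordinal classes
#'
#' Equal-interval binning of `[min, max]` into `n_classes` categories:
#' `class = 1 + floor(n * (v - min) / (max - min))`, clamped to `n` at the
#' maximum; class 1 is the sparsest, class `n_classes` the densest. A
#' constant raster maps to class 1 everywhere. `method = "quantile"` bins by
#' empirical quantiles instead.
#'
#' @param density a `raster_grid` of finite, nonnegative values.
#' @param n_classes number of classes (default 10).
#' @param method `"equal"` (default) or `"quantile"`.
#' @return `raster_grid` of integer classes 1..n_classes.
#' @export
reclassify_density <- function(density, n_classes = 10, method = c("equal", "quantile")) {
  method <- match.arg(method)
  stopifnot(n_classes >= 2)
  v <- density$values
  if (any(!is.finite(v))) stop("density values must be finite", call. = FALSE)
  rng <- range(v)
  if (diff(rng) == 0) {
    cls <- matrix(1, nrow(v), ncol(v))
  } else if (method == "equal") {
    cls <- pmin(1 + floor(n_classes * (v - rng[1]) / diff(rng)), n_classes)
  } else {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_classes + 1)))
    cls <- matrix(as.integer(cut(v, breaks = br, include.lowest = TRUE)), nrow(v), ncol(v))
    cls <- pmin(cls * n_classes / (length(br) - 1), n_classes)  # stretch if ties collapsed bins
    cls <- pmax(1, round(cls))
  }
  raster_grid(density$origin, density$cell_size, values = cls)
}

#' Overlay the screening layers into a suitability raster
#'
#' Cellwise product of the three binary screens (developable land, outside
#' center catchments, outside clinic catchments) and the density class:
#' any failed screen zeroes the cell, otherwise suitability equals the
#' density class, so higher means denser unserved developable ground. With
#' the default 10 classes and candidate threshold 4, a cell qualifies
#' exactly when all screens pass and its density class is 5 or higher.
#'
#' @param land,center_mask,clinic_mask binary `raster_grid`s.
#' @param density_class `raster_grid` of classes from [reclassify_density()].
#' @return `raster_grid` of suitability scores 0..n_classes.
#' @export
overlay_suitability <- function(land, center_mask, clinic_mask, density_class) {
  layers <- list(land, center_mask, clinic_mask, density_class)
  for (l in layers[-1]) {
    if (!same_geometry(layers[[1]], l)) {
      stop("alignment error: overlay layers must share origin, cell size and shape",
           call. = FALSE)
    }
  }
  raster_grid(land$origin, land$cell_size,
              values = land$values * center_mask$values * clinic_mask$values *
                density_class$values)
}

#' Extract the candidate-site lattice
#'
#' Lays a square lattice of points with the given spacing, anchored at the
#' raster origin (covering the extent inclusively on both edges), and keeps
#' a point as a candidate exactly when the suitability of the cell
#' containing it is strictly greater than the threshold. Cell membership is
#' half-open, `[x, x + cell) x [y, y + cell)`, with the extreme top/right
#' edge assigned to the last cell.
#'
#' @param suitability a `raster_grid` from [overlay_suitability()].
#' @param spacing lattice spacing in meters (default 25).
#' @param threshold strict lower bound on suitability (default 4).
#' @return data frame of candidates `x`, `y`, `suitability`, ordered
#'   row-major (y ascending, then x ascending).
#' @export
extract_candidates <- function(suitability, spacing = 25, threshold = 4) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive", call. = FALSE)
  if (spacing < suitability$cell_size / 2) {
    warning("lattice spacing below half the cell size: candidates will repeat per cell")
  }
  ox <- suitability$origin[1]; oy <- suitability$origin[2]
  xmax <- ox + suitability$n_cols * suitability$cell_size
  ymax <- oy + suitability$n_rows * suitability$cell_size
  eps <- 1e-9 * spacing
  xs <- seq(ox, xmax + eps, by = spacing); xs <- xs[xs <= xmax + eps]
  ys <- seq(oy, ymax + eps, by = spacing); ys <- ys[ys <= ymax + eps]
  pts <- cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  idx <- cell_of_point(suitability, pts[, 1], pts[, 2])
  s <- suitability$values[cbind(idx$row, idx$col)]
  keep <- !is.na(s) & s > threshold
  out <- data.frame(x = pts[keep, 1], y = pts[keep, 2], suitability = s[keep])
  rownames(out) <- NULL
  out
}
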