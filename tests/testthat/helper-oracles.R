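# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive every quantity with plain loops, separate from the
# vectorised implementation paths they check.

make_grid <- function(nr = 10, nc = 10, cell = 10, origin = c(0, 0)) {
  raster_grid(origin, cell, n_rows = nr, n_cols = nc)
}

square_parcel <- function(x0, y0, x1, y1, used = TRUE) {
  list(geometry = rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)), used = used)
}

# slow even-odd point-in-polygon with boundary-inclusive rule
oracle_pip <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- ring[j, 1]; y1 <- ring[j, 2]; x2 <- ring[i, 1]; y2 <- ring[i, 2]
    # boundary check
    cr <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    if (abs(cr) <= 1e-9 && px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      if (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1)) inside <- !inside
    }
    j <- i
  }
  inside
}

# direct double-loop weighted bivariate Gaussian KDE
oracle_kde <- function(points, h, template) {
  cc <- cell_centers(template)
  out <- matrix(0, template$n_rows, template$n_cols)
  for (r in seq_len(template$n_rows)) {
    for (c in seq_len(template$n_cols)) {
      s <- 0
      for (i in seq_len(nrow(points))) {
        d2 <- (cc$x[c] - points$x[i])^2 + (cc$y[r] - points$y[i])^2
        s <- s + points$w[i] * exp(-d2 / (2 * h^2)) / (2 * pi * h^2)
      }
      out[r, c] <- s
    }
  }
  out
}

# exhaustive replay of the greedy loop: per round enumerate all remaining
# candidates, take max coverage, then min weighted distance, then input order
oracle_greedy <- function(candidates, demand, radius, min_pop = 0, max_sites = Inf) {
  cand_left <- rep(TRUE, nrow(candidates))
  dem_left <- rep(TRUE, nrow(demand))
  picks <- integer(0)
  while (any(dem_left) && any(cand_left) && length(picks) < max_sites) {
    best_pop <- -Inf; best_wd <- Inf; best_i <- NA
    for (i in which(cand_left)) {
      pop <- 0; wd <- 0
      for (k in which(dem_left)) {
        d <- sqrt((candidates$x[i] - demand$x[k])^2 + (candidates$y[i] - demand$y[k])^2)
        if (d <= radius) {
          pop <- pop + demand$pop[k]
          wd <- wd + demand$pop[k] * d
        }
      }
      if (pop > best_pop || (pop == best_pop && wd < best_wd)) {
        best_pop <- pop; best_wd <- wd; best_i <- i
      }
    }
    if (best_pop <= 0 || best_pop < min_pop) break
    picks <- c(picks, best_i)
    cand_left[best_i] <- FALSE
    for (k in which(dem_left)) {
      d <- sqrt((candidates$x[best_i] - demand$x[k])^2 +
                  (candidates$y[best_i] - demand$y[k])^2)
      if (d <= radius) dem_left[k] <- FALSE
    }
  }
  picks
}

random_demand <- function(n, extent = 1000, max_pop = 50) {
  data.frame(id = paste0("d", seq_len(n)),
             x = runif(n, 0, extent), y = runif(n, 0, extent),
             pop = as.numeric(rpois(n, max_pop / 2)),
             stringsAsFactors = FALSE)
}

random_buildings <- function(n, extent = 1000) {
  data.frame(id = paste0("b", seq_len(n)),
             x = runif(n, 0, extent), y = runif(n, 0, extent),
             floor_area = rlnorm(n, log(1500), 0.6),
             stringsAsFactors = FALSE)
}
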