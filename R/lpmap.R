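# Lactase-persistence phenotype-frequency surface: dominance transform and
# sample-size-weighted Gaussian kernel smoothing.

#' Lactase-persistence phenotype frequency under dominance
#'
#' Converts a combined causal-allele frequency `p` (sum of the known LP
#' enhancer variants, treated as allelic at one locus) to the expected
#' phenotype frequency under Hardy-Weinberg proportions with dominant
#' expression: `1 - (1 - p)^2`.
#'
#' @param p Allele frequency in `[0, 1]` (vectorised).
#' @return Phenotype frequency in `[0, 1]`.
#' @export
#' @examples
#' phenotype_freq(0.5)  # 0.75
phenotype_freq <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("allele frequency outside [0, 1]")
  1 - (1 - p)^2
}

#' Grid specification for an LP surface
#'
#' @param lon_range,lat_range Numeric ranges in decimal degrees.
#' @param nx,ny Number of grid cells along longitude/latitude.
#' @return List usable as the `grid` argument of [smooth_lp_surface()].
#' @export
lp_grid <- function(lon_range, lat_range, nx = 60L, ny = 60L) {
  stopifnot(nx >= 1L, ny >= 1L, diff(lon_range) >= 0, diff(lat_range) >= 0)
  list(lon = seq(lon_range[1], lon_range[2], length.out = nx),
       lat = seq(lat_range[1], lat_range[2], length.out = ny))
}

#' Smoothed LP phenotype-frequency surface
#'
#' Sample-size-weighted Nadaraya-Watson estimate on a regular lon/lat
#' lattice: each cell value is
#' `sum(w_i K(d_i/sigma) f_i) / sum(w_i K(d_i/sigma))` with Gaussian
#' kernel `K`, weights `w_i = sample_size`, planar degree distances `d_i`,
#' and `f_i` the phenotype frequency of point `i`. Cells whose relative
#' kernel mass falls below `mass_floor` are flagged unreliable (value kept,
#' never NaN-propagated, unless the mass is exactly zero, in which case the
#' cell is `NA` and flagged).
#'
#' @param points Data frame with columns `lon`, `lat`, `allele_freq`,
#'   `sample_size` (or a precomputed `phenotype_freq` column).
#' @param sigma Gaussian bandwidth in degrees (> 0).
#' @param grid Grid from [lp_grid()]; default spans the points with a 2
#'   degree margin.
#' @param mass_floor Minimum relative kernel mass (fraction of total
#'   weight) below which a cell is flagged unreliable. Default `1e-6`.
#' @return Object of class `lp_surface`: list with `grid`, `values`
#'   (`ny` x `nx` matrix), `reliable` (logical matrix), `sigma`, `points`.
#' @export
smooth_lp_surface <- function(points, sigma, grid = NULL, mass_floor = 1e-6) {
  stopifnot(nrow(points) >= 1L, sigma > 0)
  if (is.null(points$phenotype_freq)) {
    points$phenotype_freq <- phenotype_freq(points$allele_freq)
  }
  if (is.null(grid)) {
    grid <- lp_grid(range(points$lon) + c(-2, 2), range(points$lat) + c(-2, 2))
  }
  w <- points$sample_size
  stopifnot(all(w >= 1))
  f <- points$phenotype_freq
  nx <- length(grid$lon); ny <- length(grid$lat)
  vals <- matrix(NA_real_, ny, nx)
  rel <- matrix(FALSE, ny, nx)
  wtot <- sum(w)
  for (ix in seq_len(nx)) {
    dx2 <- (points$lon - grid$lon[ix])^2
    for (iy in seq_len(ny)) {
      d2 <- dx2 + (points$lat - grid$lat[iy])^2
      k <- w * exp(-d2 / (2 * sigma^2))
      mass <- sum(k)
      if (mass > 0) vals[iy, ix] <- sum(k * f) / mass
      rel[iy, ix] <- (mass / wtot) >= mass_floor
    }
  }
  structure(list(grid = grid, values = vals, reliable = rel, sigma = sigma,
                 mass_floor = mass_floor, points = points),
            class = "lp_surface")
}

#' Lowest bandwidth keeping kernel mass above the floor everywhere
#'
#' Walks a geometric ladder of bandwidths (`sigma0 * step^k`) and returns
#' the smallest sigma for which every grid cell's relative kernel mass
#' meets `mass_floor` — the "lowest non-overflowing" bandwidth for a
#' heterogeneous point set.
#'
#' @param points As in [smooth_lp_surface()].
#' @param grid Grid from [lp_grid()].
#' @param mass_floor Relative kernel-mass floor (default `1e-6`).
#' @param sigma0 Ladder start in degrees (default 0.25).
#' @param step Ladder ratio (default 1.25).
#' @param max_sigma Ladder end (default 90 degrees).
#' @return Selected sigma.
#' @export
lowest_safe_bandwidth <- function(points, grid, mass_floor = 1e-6,
                                  sigma0 = 0.25, step = 1.25, max_sigma = 90) {
  stopifnot(nrow(points) >= 1L)
  w <- points$sample_size
  wtot <- sum(w)
  # worst case is the grid cell farthest in kernel mass; evaluate all cells
  cells <- expand.grid(lon = grid$lon, lat = grid$lat)
  sigma <- sigma0
  while (sigma <= max_sigma) {
    ok <- TRUE
    for (i in seq_len(nrow(cells))) {
      d2 <- (points$lon - cells$lon[i])^2 + (points$lat - cells$lat[i])^2
      mass <- sum(w * exp(-d2 / (2 * sigma^2))) / wtot
      if (mass < mass_floor) { ok <- FALSE; break }
    }
    if (ok) return(sigma)
    sigma <- sigma * step
  }
  stop("no bandwidth on the ladder keeps kernel mass above the floor; ",
       "use a coarser grid or lower the mass floor")
}

#' @export
print.lp_surface <- function(x, ...) {
  cat("LP phenotype-frequency surface\n")
  cat("  grid:", length(x$grid$lon), "x", length(x$grid$lat),
      "cells; sigma =", x$sigma, "degrees\n")
  cat("  points:", nrow(x$points), "; value range",
      sprintf("[%.3f, %.3f]", min(x$values, na.rm = TRUE),
              max(x$values, na.rm = TRUE)), "\n")
  cat("  unreliable cells:", sum(!x$reliable), "\n")
  invisible(x)
}

#' @export
plot.lp_surface <- function(x, ...) {
  graphics::image(x$grid$lon, x$grid$lat, t(x$values),
                  xlab = "longitude", ylab = "latitude",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  graphics::contour(x$grid$lon, x$grid$lat, t(x$values), add = TRUE)
  graphics::points(x$points$lon, x$points$lat, pch = 20, cex = 0.6)
  invisible(x)
}

#' Write an LP surface to a gridded TSV
#'
#' @param surface An `lp_surface`.
#' @param path Output TSV (columns lon, lat, phenotype_freq, reliable).
#' @return `path`, invisibly.
#' @export
write_lp_surface <- function(surface, path) {
  g <- expand.grid(lat = surface$grid$lat, lon = surface$grid$lon)
  out <- data.frame(lon = g$lon, lat = g$lat,
                    phenotype_freq = as.vector(surface$values),
                    reliable = as.vector(surface$reliable))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read LP allele-frequency points from TSV
#'
#' Accepts either a combined `allele_freq` column or per-allele frequency
#' columns (names starting with `freq_`), which are summed (the causal
#' variants are treated as allelic at one locus).
#'
#' @param path TSV with `lat`, `lon`, `sample_size` and frequency columns.
#' @return Data frame with `lon`, `lat`, `allele_freq`, `sample_size`.
#' @export
read_lp_points <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lat", "lon", "sample_size") %in% names(tab)))
  if (is.null(tab$allele_freq)) {
    fc <- grep("^freq_", names(tab), value = TRUE)
    if (!length(fc)) stop("need an 'allele_freq' or per-allele 'freq_*' columns")
    tab$allele_freq <- rowSums(tab[, fc, drop = FALSE])
  }
  if (any(tab$allele_freq < 0 | tab$allele_freq > 1)) {
    stop("combined allele frequency outside [0, 1]")
  }
  if (any(abs(tab$lat) > 90) || any(abs(tab$lon) > 180)) {
    stop("coordinates outside valid ranges")
  }
  tab[, c("lon", "lat", "allele_freq", "sample_size")]
}
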