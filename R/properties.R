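#' Display property covariates
#'
#' The five covariates on which radial and tangential displays are matched:
#' mean eccentricity, mean spacing, convex-hull area, occupancy area, and
#' density. All operate on disc centers in degrees of visual angle.
#'
#' @name display-properties
NULL

.centers <- function(d) {
  if (inherits(d, "na_display")) as.matrix(d$discs[, c("x", "y")])
  else as.matrix(d)
}

#' Mean eccentricity of a display
#' @param d a `na_display` or an n x 2 matrix of centers.
#' @return mean disc-center eccentricity, degrees.
#' @export
mean_eccentricity <- function(d) {
  p <- .centers(d)
  if (nrow(p) < 1) stop("mean_eccentricity: empty display")
  mean(eccentricity(p[, 1], p[, 2]))
}

#' Mean spacing (nearest-neighbor definition)
#'
#' Mean over discs of the center distance to the nearest other disc. An
#' all-pairs variant is available via `method = "all_pairs"`.
#'
#' @param d a `na_display` or an n x 2 matrix of centers (n >= 2).
#' @param method `"nearest_neighbor"` (default) or `"all_pairs"`.
#' @return degrees.
#' @export
mean_spacing <- function(d, method = c("nearest_neighbor", "all_pairs")) {
  method <- match.arg(method)
  p <- .centers(d)
  if (nrow(p) < 2) stop("mean_spacing: need at least 2 discs")
  dm <- as.matrix(stats::dist(p))
  if (method == "all_pairs") return(mean(dm[upper.tri(dm)]))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

#' Convex-hull area of disc centers
#'
#' Shoelace area of the convex hull of the centers; 0 for collinear or
#' singleton sets. The hull is computed on centers, not disc outer edges.
#'
#' @param d a `na_display` or an n x 2 matrix of centers.
#' @return squared degrees.
#' @export
convex_hull_area <- function(d) {
  p <- .centers(d)
  if (nrow(p) < 1) stop("convex_hull_area: empty display")
  if (nrow(p) < 3) return(0)
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
}

#' Occupancy area
#'
#' Area of the union of disks of radius `occ_radius` centered on the disc
#' centers, estimated by rasterizing a grid of `grid_step` spacing over the
#' bounding box (a cell counts if its center is within `occ_radius` of any
#' disc center). Converges to n * pi * occ_radius^2 for well-separated
#' discs. The occupancy radius is a reporting parameter: the default 1
#' degree must be stated alongside any occupancy value.
#'
#' @param d a `na_display` or an n x 2 matrix of centers.
#' @param occ_radius disk radius, degrees (default 1).
#' @param grid_step raster resolution, degrees (default 0.02).
#' @return squared degrees.
#' @export
occupancy_area <- function(d, occ_radius = 1, grid_step = 0.02) {
  stopifnot(occ_radius > 0, grid_step > 0)
  p <- .centers(d)
  if (nrow(p) < 1) stop("occupancy_area: empty display")
  gx <- seq(min(p[, 1]) - occ_radius, max(p[, 1]) + occ_radius, by = grid_step)
  gy <- seq(min(p[, 2]) - occ_radius, max(p[, 2]) + occ_radius, by = grid_step)
  covered <- matrix(FALSE, length(gx), length(gy))
  r2 <- occ_radius^2
  for (i in seq_len(nrow(p))) {
    ix <- which(abs(gx - p[i, 1]) <= occ_radius)
    iy <- which(abs(gy - p[i, 2]) <= occ_radius)
    if (!length(ix) || !length(iy)) next
    dx2 <- (gx[ix] - p[i, 1])^2
    dy2 <- (gy[iy] - p[i, 2])^2
    covered[ix, iy] <- covered[ix, iy] | outer(dx2, dy2, "+") <= r2
  }
  sum(covered) * grid_step^2
}

#' Density (items per squared degree of convex hull)
#' @param d a `na_display` or an n x 2 matrix of centers.
#' @return numerosity / convex-hull area.
#' @export
display_density <- function(d) {
  p <- .centers(d)
  a <- convex_hull_area(p)
  if (a <= 0) stop("display_density: degenerate convex hull")
  nrow(p) / a
}

#' Compute the full property vector of a display
#'
#' @param d a `na_display`.
#' @param occ_radius,grid_step passed to [occupancy_area()].
#' @return one-row data.frame: numerosity plus the five matching covariates.
#' @export
display_properties <- function(d, occ_radius = 1, grid_step = 0.02) {
  data.frame(numerosity = d$numerosity,
             mean_eccentricity = mean_eccentricity(d),
             mean_spacing = mean_spacing(d),
             convex_hull_area = convex_hull_area(d),
             occupancy_area = occupancy_area(d, occ_radius, grid_step),
             density = display_density(d))
}
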