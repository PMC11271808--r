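#' Eccentricity of a point
#'
#' Euclidean distance of a point from fixation. The package works in a
#' fixation-centered frame: coordinates are degrees of visual angle, +x
#' rightward, +y upward, fixation at the origin.
#'
#' @param x,y coordinates in degrees of visual angle. Vectorized.
#' @return eccentricity in degrees (>= 0).
#' @examples
#' eccentricity(3, 4)  # 5
#' @export
eccentricity <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)))
  sqrt(x^2 + y^2)
}

#' Construct the radial and tangential interference zones of a disc
#'
#' Each disc location owns two concentric elliptical interference zones whose
#' size scales with eccentricity: a radially oriented zone (major axis along
#' the fixation-disc direction) and the same ellipse rotated 90 degrees
#' (tangential zone). The semi-axes are \code{major_factor * ecc} and
#' \code{minor_factor * ecc}. This semi-axis reading was calibrated against
#' the saturated packing counts the display design implies (see the methods
#' vignette).
#'
#' @param x,y zone center, degrees, fixation-origin frame.
#' @param major_factor,minor_factor eccentricity scaling of the semi-major
#'   and semi-minor axes (defaults 0.25 and 0.1).
#' @return list of two ellipse zones (`radial`, `tangential`), each a list
#'   with fields `cx`, `cy`, `a` (semi-major), `b` (semi-minor), `theta`
#'   (major-axis direction, radians, stored mod pi), `kind`.
#' @export
make_zones <- function(x, y, major_factor = 0.25, minor_factor = 0.1) {
  ecc <- eccentricity(x, y)
  if (ecc <= 0) {
    stop("degenerate zone: center at fixation has zero eccentricity")
  }
  stopifnot(minor_factor > 0, major_factor >= minor_factor)
  th <- atan2(y, x) %% pi
  list(
    radial = ellipse_zone(x, y, major_factor * ecc, minor_factor * ecc,
                          th, "radial"),
    tangential = ellipse_zone(x, y, major_factor * ecc, minor_factor * ecc,
                              (th + pi / 2) %% pi, "tangential")
  )
}

ellipse_zone <- function(cx, cy, a, b, theta, kind = c("radial", "tangential")) {
  stopifnot(a >= b, b > 0)
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta %% pi,
                 kind = match.arg(kind)),
            class = "na_ellipse")
}

#' Point-in-ellipse membership
#'
#' Tests whether points lie inside or on the boundary of an ellipse zone via
#' the canonical quadratic form after translating/rotating into the ellipse
#' frame.
#'
#' @param x,y point coordinates (vectorized).
#' @param z an ellipse zone from [make_zones()].
#' @return logical vector.
#' @export
point_in_ellipse <- function(x, y, z) {
  ct <- cos(z$theta); st <- sin(z$theta)
  dx <- x - z$cx; dy <- y - z$cy
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  (u / z$a)^2 + (v / z$b)^2 <= 1 + 1e-12
}

#' Polygonal approximation of an ellipse
#'
#' Regular inscribed polygon used by the overlap predicate and the packer.
#'
#' @param z ellipse zone.
#' @param n vertex count (default 64).
#' @return n x 2 matrix of vertices, counterclockwise.
#' @export
ellipse_polygon <- function(z, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(z$theta); st <- sin(z$theta)
  ex <- z$a * cos(t); ey <- z$b * sin(t)
  cbind(z$cx + ex * ct - ey * st, z$cy + ex * st + ey * ct)
}

#' Ellipse-ellipse overlap
#'
#' True iff the two elliptical regions intersect. Implemented by the
#' separating-axis test on 64-vertex polygonal approximations (exact for the
#' polygons; the approximation error is below the construction tolerances of
#' the displays). Symmetric and reflexive.
#'
#' @param z1,z2 ellipse zones.
#' @param n polygon vertex count (default 64).
#' @return logical scalar.
#' @export
ellipses_overlap <- function(z1, z2, n = 64L) {
  d <- sqrt((z1$cx - z2$cx)^2 + (z1$cy - z2$cy)^2)
  if (d > z1$a + z2$a) return(FALSE)   # separation bound
  if (d <= z1$b + z2$b) return(TRUE)   # inscribed circles intersect
  .convex_polys_overlap(ellipse_polygon(z1, n), ellipse_polygon(z2, n))
}

#' Membership in the lens where a disc's two zones overlap
#'
#' The central region belonging to both the radial and tangential zone of
#' the same base disc; flanking discs are never placed there.
#'
#' @param x,y point coordinates (vectorized).
#' @param zr,zt the radial and tangential zone of one base disc; must share
#'   a center.
#' @return logical vector.
#' @export
in_zone_overlap <- function(x, y, zr, zt) {
  if (abs(zr$cx - zt$cx) > 1e-9 || abs(zr$cy - zt$cy) > 1e-9) {
    stop("in_zone_overlap: zones must share the same center")
  }
  point_in_ellipse(x, y, zr) & point_in_ellipse(x, y, zt)
}
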