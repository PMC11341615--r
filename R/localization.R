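## 3D marker localization from projection lines.
##
## Two-view localization: the projection lines of the marker identified
## in two views would intersect at the marker in an ideal system; with
## identification noise and sequential (non-simultaneous) runs they are
## skew, so the marker is taken as the midpoint of the Nadir-point pair
## (the mutually closest points on the two lines). Single-view
## localization against a co-registered 3D reference takes the Nadir
## point of the reference on the single back-projected ray; its distance
## to the reference is the single-view error sample and, by construction,
## can only underestimate the true displacement (the component along the
## view axis is invisible).

#' Closest points between two skew projection lines
#'
#' Solves the 2x2 normal equations for the mutually closest points (Nadir
#' points) on two non-parallel lines, the gap between them and their
#' midpoint. The connecting segment is orthogonal to both lines.
#'
#' @param a,b [ProjectionLine-class] objects.
#' @return A [LinePairNadir-class].
#' @examples
#' a <- ProjectionLine(c(0, 0, 0), c(1, 0, 0))
#' b <- ProjectionLine(c(0, 1, 0), c(0, 0, 1))
#' closestPointsBetweenLines(a, b)  # gap 1 mm, midpoint (0, 0.5, 0)
#' @export
closestPointsBetweenLines <- function(a, b) {
  stopifnot(is(a, "ProjectionLine"), is(b, "ProjectionLine"))
  d1 <- a@direction
  d2 <- b@direction
  cr <- .cross3(d1, d2)
  sin_ang <- sqrt(sum(cr^2))
  if (sin_ang <= 1e-10) {
    ang <- asin(min(1, sin_ang)) * 180 / pi
    stop(sprintf(
      "degenerate configuration: projection lines (near-)parallel, angular separation %.2e deg",
      ang))
  }
  r <- b@origin - a@origin
  d12 <- sum(d1 * d2)
  den <- 1 - d12^2
  t1 <- (sum(r * d1) - d12 * sum(r * d2)) / den
  t2 <- (d12 * sum(r * d1) - sum(r * d2)) / den
  na <- a@origin + t1 * d1
  nb <- b@origin + t2 * d2
  new("LinePairNadir", nadir_a = na, nadir_b = nb,
      gap_mm = sqrt(sum((na - nb)^2)), midpoint = (na + nb) / 2)
}

#' Triangulate a marker from two views
#'
#' Back-projects the marker identified on two detectors and reconstructs
#' its 3D position as the midpoint of the Nadir-point pair of the two
#' projection lines. The angular separation of the two view axes is
#' recorded; separations below `warn_angle_deg` emit a warning because
#' localization precision degrades as the views become similar, and
#' separations below `min_angle_deg` are rejected as degenerate.
#'
#' @param geom1,geom2 [CArmGeometry-class] objects of the two views.
#' @param d1,d2 numeric(2) detector marker coordinates in each view (mm).
#' @param min_angle_deg hard lower bound on the view-axis separation
#'   (default 1 degree).
#' @param warn_angle_deg warning threshold (default 30 degrees; two-view
#'   reconstruction is commonly recommended at 35-145 degrees).
#' @return A [MarkerLocalization-class].
#' @examples
#' g1 <- CArmGeometry(label = "AP")
#' g2 <- CArmGeometry(label = "LAO60", primary_deg = 60)
#' p <- c(12, -7, 30)
#' loc <- triangulatePair(g1, projectPoint(g1, p), g2, projectPoint(g2, p))
#' loc@p_pair  # recovers p
#' @export
triangulatePair <- function(geom1, d1, geom2, d2, min_angle_deg = 1,
                            warn_angle_deg = 30) {
  w1 <- viewFrame(geom1)$view_axis
  w2 <- viewFrame(geom2)$view_axis
  ang <- acos(max(-1, min(1, sum(w1 * w2)))) * 180 / pi
  if (ang < min_angle_deg)
    stop(sprintf(
      "degenerate configuration: view axes separated by %.3f deg (< %.3f deg)",
      ang, min_angle_deg))
  if (ang < warn_angle_deg)
    warning(sprintf(
      "small angular separation (%.1f deg < %.1f deg): 3D localization is imprecise",
      ang, warn_angle_deg))
  nad <- closestPointsBetweenLines(backprojectPoint(geom1, d1),
                                   backprojectPoint(geom2, d2))
  new("MarkerLocalization", p_pair = nad@midpoint, nadirs = nad,
      angular_separation_deg = ang)
}

#' Re-projection error of a 3D position
#'
#' Projects a reconstructed 3D position onto a view and returns the
#' in-plane Euclidean distance (mm) to the marker location actually
#' identified on that detector — the image-plane consistency check of the
#' two-view reconstruction.
#'
#' @param geom a [CArmGeometry-class].
#' @param p numeric(3), reconstructed 3D position (mm).
#' @param d_observed numeric(2), identified detector position (mm).
#' @return Distance in mm in the detector plane.
#' @export
reprojectionError <- function(geom, p, d_observed) {
  stopifnot(.is_num(d_observed, 2L))
  sqrt(sum((projectPoint(geom, p) - d_observed)^2))
}

#' Nadir point of a 3D reference on a projection line
#'
#' The point on the line closest to `q` (orthogonal projection of `q`
#' onto the line). Used for single-view localization: the Nadir point of
#' the co-registered reference marker on the back-projected ray is the
#' single-view 3D marker estimate, and its distance to the reference is
#' the single-view error sample.
#'
#' @param line a [ProjectionLine-class].
#' @param q numeric(3), reference point (mm).
#' @return list with `nadir` (numeric(3)) and `distance_mm`.
#' @examples
#' l <- ProjectionLine(c(0, 0, 0), c(1, 0, 0))
#' nadirOnLine(l, c(3, 4, 0))  # nadir (3,0,0), distance 4
#' @export
nadirOnLine <- function(line, q) {
  stopifnot(is(line, "ProjectionLine"), .is_num(q, 3L))
  t <- sum((q - line@origin) * line@direction)
  nadir <- line@origin + t * line@direction
  list(nadir = nadir, distance_mm = sqrt(sum((q - nadir)^2)))
}
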