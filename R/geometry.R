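## Cone-beam view model.
##
## Patient coordinates: right-handed, origin at the isocenter, +x patient
## left, +y patient anterior, +z cranial. In the AP view the source sits
## posterior to the patient and the beam travels along +y; the primary
## angulation rotates the view axis about +z toward +x (LAO positive), the
## secondary angulation then tilts it toward +z (CRA positive). The
## detector v axis points cranially in the AP view, the u axis is w x v so
## that a patient-left displacement projects to positive u. All quantities
## the pipeline reports are relative distances, so any fixed consistent
## convention gives identical results.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Source/detector frame of a C-arm view
#'
#' Builds the 3D frame of a view from its angulations: the X-ray source
#' position, the detector center, the in-plane detector axes (u, v) and
#' the view axis w pointing from the source through the isocenter toward
#' the detector.
#'
#' @param geom a [CArmGeometry-class].
#' @return A list with elements `source`, `detector_center` (numeric(3),
#'   mm), and unit vectors `u_axis`, `v_axis`, `view_axis`.
#' @examples
#' f <- viewFrame(CArmGeometry(sid_mm = 1200, sod_mm = 800))
#' f$source          # (0, -800, 0)
#' f$detector_center # (0, 400, 0)
#' @export
viewFrame <- function(geom) {
  stopifnot(is(geom, "CArmGeometry"))
  validObject(geom)
  a <- geom@primary_deg * pi / 180
  b <- geom@secondary_deg * pi / 180
  w <- c(sin(a) * cos(b), cos(a) * cos(b), sin(b))
  v <- c(-sin(a) * sin(b), -cos(a) * sin(b), cos(b))
  u <- .cross3(w, v)
  list(source = -geom@sod_mm * w,
       detector_center = (geom@sid_mm - geom@sod_mm) * w,
       u_axis = u, v_axis = v, view_axis = w)
}

#' Project a 3D point onto the detector
#'
#' Intersects the ray from the X-ray source through `p` with the detector
#' plane and returns in-plane coordinates in mm, origin at the principal
#' point (detector center).
#'
#' @param geom a [CArmGeometry-class].
#' @param p numeric(3), point in patient space (mm).
#' @return numeric(2) `(u_mm, v_mm)`.
#' @examples
#' g <- CArmGeometry(sid_mm = 1200, sod_mm = 800)
#' projectPoint(g, c(0, 0, 0))   # (0, 0): the principal ray
#' projectPoint(g, c(10, 0, 0))  # (15, 0): magnified by 1.5
#' @export
projectPoint <- function(geom, p) {
  stopifnot(.is_num(p, 3L))
  f <- viewFrame(geom)
  rel <- p - f$source
  depth <- sum(rel * f$view_axis)
  if (depth <= 1e-9)
    stop("degenerate projection: point at or behind the source plane")
  c(u_mm = geom@sid_mm * sum(rel * f$u_axis) / depth,
    v_mm = geom@sid_mm * sum(rel * f$v_axis) / depth)
}

#' Back-project a detector point to its projection line
#'
#' Returns the ray from the X-ray source through the 3D location of a
#' detector point: the projection line along which every 3D point maps to
#' that detector position.
#'
#' @param geom a [CArmGeometry-class].
#' @param d numeric(2), detector coordinates `(u_mm, v_mm)`.
#' @return A [ProjectionLine-class].
#' @examples
#' g <- CArmGeometry(sid_mm = 1200, sod_mm = 800)
#' backprojectPoint(g, c(0, 0))  # the central ray through the isocenter
#' @export
backprojectPoint <- function(geom, d) {
  stopifnot(.is_num(d, 2L))
  f <- viewFrame(geom)
  on_det <- f$source + geom@sid_mm * f$view_axis +
    d[1] * f$u_axis + d[2] * f$v_axis
  ProjectionLine(origin = f$source, direction = on_det - f$source)
}
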