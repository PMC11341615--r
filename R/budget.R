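## Closed-form accuracy estimation.
##
## Identification of a marker in an image cannot be more accurate than
## half the diagonal of the underlying pixel (2D) or voxel (3D). The
## detector-plane identification error scaled to the isocenter combines
## (root-sum-square) with the intrinsic geometry error of the C-arm into
## the two-view 3D localization error; re-projected onto the image plane
## it gives the expected image-plane consistency error; combined with the
## 3D reference identification error it gives the total budget. The
## printed chain of the reference analysis rounds every intermediate to
## 0.1 mm before reuse; both modes are supported and both full-precision
## and display-rounded values are always reported.

#' Half-diagonal identification error of a pixel or voxel
#'
#' @param edge_mm pixel/voxel edge length in mm.
#' @param dims 2 (pixel) or 3 (voxel).
#' @return `edge_mm * sqrt(dims) / 2`.
#' @examples
#' halfDiagonal(1.3, 3)  # 1.1258 -> 1.1 mm displayed
#' @export
halfDiagonal <- function(edge_mm, dims) {
  stopifnot(is.numeric(edge_mm), edge_mm > 0)
  if (!length(dims) == 1 || !dims %in% c(2, 3))
    stop("dims must be 2 (pixel) or 3 (voxel)")
  edge_mm * sqrt(dims) / 2
}

#' Propagate the marker-localization error budget
#'
#' Chains the identification errors into the total budget:
#' \deqn{\epsilon_{2DXR} = \mathrm{halfDiagonal}(p_{XR}, 2),\quad
#'       \epsilon_{CMR} = \mathrm{halfDiagonal}(v, 3)}
#' \deqn{\epsilon_{2DXR,iso} = \epsilon_{2DXR}/M,\quad
#'       \epsilon_{3DXR} = \sqrt{\epsilon_{2DXR,iso}^2 + \epsilon_{geo}^2}}
#' \deqn{\epsilon_{2DXR,proj} = \epsilon_{3DXR} \cdot M,\quad
#'       \epsilon_{tot} = \sqrt{\epsilon_{3DXR}^2 + \epsilon_{CMR}^2}}
#' With `round_intermediates = TRUE` every chained value is rounded to
#' 0.1 mm before entering the next formula (reproducing printed budget
#' chains); full-precision values are always computed alongside.
#' Single-view localization degrades accuracy but adds no term here: it
#' does not enter the two-view total.
#'
#' @param cmr_voxel_mm isotropic reconstructed reference voxel edge (mm).
#' @param xr_pixel_mm detector pixel edge (mm); the default gives a 0.2 mm
#'   half-diagonal 2D identification error.
#' @param geo_error_mm intrinsic C-arm geometry error (mm), default 0.2.
#' @param magnification detector/isocenter scale factor, default 1.5.
#' @param round_intermediates logical; round each chained value to 0.1 mm
#'   before reuse (default `TRUE`).
#' @param eps_2dxr_mm optionally fix the 2D identification error directly
#'   instead of deriving it from `xr_pixel_mm`.
#' @return An [ErrorBudget-class].
#' @examples
#' propagateBudget()  # 0.2 / 1.1 / 0.1 / 0.2 / 0.3 / 1.1 mm chain
#' @export
propagateBudget <- function(cmr_voxel_mm = 1.3, xr_pixel_mm = 0.2 * sqrt(2),
                            geo_error_mm = 0.2, magnification = 1.5,
                            round_intermediates = TRUE,
                            eps_2dxr_mm = NULL) {
  stopifnot(cmr_voxel_mm > 0, xr_pixel_mm > 0, geo_error_mm >= 0,
            magnification > 1)
  chain <- function(round_fun) {
    e2d <- round_fun(if (is.null(eps_2dxr_mm)) halfDiagonal(xr_pixel_mm, 2)
                     else eps_2dxr_mm)
    ecmr <- round_fun(halfDiagonal(cmr_voxel_mm, 3))
    egeo <- round_fun(geo_error_mm)
    eiso <- round_fun(e2d / magnification)
    e3d <- round_fun(sqrt(eiso^2 + egeo^2))
    eproj <- round_fun(e3d * magnification)
    etot <- round_fun(sqrt(e3d^2 + ecmr^2))
    c(eps_2dxr_mm = e2d, eps_cmr_mm = ecmr, eps_2dxr_iso_mm = eiso,
      eps_xr_geo_mm = egeo, eps_3dxr_mm = e3d, eps_2dxr_proj_mm = eproj,
      eps_tot_mm = etot)
  }
  full <- chain(identity)
  display <- if (round_intermediates) chain(function(x) round(x, 1))
             else round(full, 1)
  new("ErrorBudget", full = full, display = display,
      params = list(cmr_voxel_mm = cmr_voxel_mm, xr_pixel_mm = xr_pixel_mm,
                    geo_error_mm = geo_error_mm,
                    magnification = magnification,
                    round_intermediates = round_intermediates,
                    eps_2dxr_mm = eps_2dxr_mm))
}

#' Write an error budget as JSON
#'
#' Emits both the full-precision and the display-rounded chain together
#' with the input parameters.
#'
#' @param budget an [ErrorBudget-class].
#' @param path output JSON path.
#' @return The budget, invisibly.
#' @export
writeBudget <- function(budget, path) {
  stopifnot(is(budget, "ErrorBudget"))
  jsonlite::write_json(list(full = as.list(budget@full),
                            display = as.list(budget@display),
                            params = budget@params),
                       path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(budget)
}
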