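#' @import methods
NULL

.is_num <- function(x, n) is.numeric(x) && length(x) == n && all(is.finite(x))

#' C-arm view geometry
#'
#' One fluoroscopic view of a cone-beam C-arm: source-to-image distance
#' (SID), source-to-isocenter distance (SOD), primary (RAO/LAO) and
#' secondary (CRA/CAU) angulations and detector pixel spacing. The origin
#' of patient space is the isocenter; all central rays pass through it.
#' Structures at the isocenter are magnified by SID/SOD on the detector.
#'
#' @slot sid_mm source-to-image (detector) distance in mm.
#' @slot sod_mm source-to-isocenter distance in mm.
#' @slot primary_deg primary angulation in degrees, LAO positive, RAO
#'   negative.
#' @slot secondary_deg secondary angulation in degrees, CRA positive, CAU
#'   negative.
#' @slot pixel_spacing_mm detector pixel edge length in mm.
#' @slot label free-text view name.
#' @export
setClass("CArmGeometry",
  slots = c(
    sid_mm = "numeric",
    sod_mm = "numeric",
    primary_deg = "numeric",
    secondary_deg = "numeric",
    pixel_spacing_mm = "numeric",
    label = "character"
  ),
  prototype = prototype(
    sid_mm = 1200, sod_mm = 800, primary_deg = 0, secondary_deg = 0,
    pixel_spacing_mm = 0.2 * sqrt(2), label = "AP"
  )
)

setValidity("CArmGeometry", function(object) {
  msg <- character()
  for (s in c("sid_mm", "sod_mm", "primary_deg", "secondary_deg",
              "pixel_spacing_mm")) {
    if (!.is_num(slot(object, s), 1L))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  }
  if (length(msg) == 0L) {
    if (!(object@sod_mm > 0 && object@sod_mm < object@sid_mm))
      msg <- c(msg, "need 0 < sod_mm < sid_mm (magnification sid/sod > 1)")
    if (object@pixel_spacing_mm <= 0)
      msg <- c(msg, "pixel_spacing_mm must be > 0")
  }
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a C-arm view geometry
#'
#' @param sid_mm source-to-image distance in mm.
#' @param sod_mm source-to-isocenter distance in mm; must satisfy
#'   `0 < sod_mm < sid_mm`.
#' @param primary_deg primary angulation (LAO positive, RAO negative).
#' @param secondary_deg secondary angulation (CRA positive, CAU negative).
#' @param pixel_spacing_mm detector pixel edge in mm (I/O-level only; all
#'   detector coordinates in this package are mm at the detector plane).
#' @param label view name.
#' @return A [CArmGeometry-class] object.
#' @examples
#' CArmGeometry(label = "LAO60", primary_deg = 60)
#' @export
CArmGeometry <- function(sid_mm = 1200, sod_mm = 800, primary_deg = 0,
                         secondary_deg = 0, pixel_spacing_mm = 0.2 * sqrt(2),
                         label = "view") {
  new("CArmGeometry", sid_mm = as.numeric(sid_mm), sod_mm = as.numeric(sod_mm),
      primary_deg = as.numeric(primary_deg),
      secondary_deg = as.numeric(secondary_deg),
      pixel_spacing_mm = as.numeric(pixel_spacing_mm), label = label)
}

setMethod("show", "CArmGeometry", function(object) {
  cat(sprintf(
    "CArmGeometry '%s': SID %.0f mm, SOD %.0f mm (magnification %.3f)\n",
    object@label, object@sid_mm, object@sod_mm,
    object@sid_mm / object@sod_mm))
  cat(sprintf("  angulation: primary %+.1f deg, secondary %+.1f deg; pixel %.3f mm\n",
              object@primary_deg, object@secondary_deg,
              object@pixel_spacing_mm))
})

#' X-ray projection line
#'
#' A back-projected ray: the X-ray source position and a unit direction
#' pointing from the source through a detector location.
#'
#' @slot origin numeric(3), the source position in mm (isocenter origin).
#' @slot direction numeric(3), unit vector.
#' @export
setClass("ProjectionLine",
  slots = c(origin = "numeric", direction = "numeric"))

setValidity("ProjectionLine", function(object) {
  msg <- character()
  if (!.is_num(object@origin, 3L)) msg <- c(msg, "origin must be numeric(3)")
  if (!.is_num(object@direction, 3L)) {
    msg <- c(msg, "direction must be numeric(3)")
  } else if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-12) {
    msg <- c(msg, "direction must be a unit vector (within 1e-12)")
  }
  if (length(msg)) msg else TRUE
})

ProjectionLine <- function(origin, direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("projection line direction must be non-zero")
  new("ProjectionLine", origin = as.numeric(origin),
      direction = as.numeric(direction) / nrm)
}

setMethod("show", "ProjectionLine", function(object) {
  cat(sprintf("ProjectionLine: origin (%.2f, %.2f, %.2f) mm, direction (%.4f, %.4f, %.4f)\n",
              object@origin[1], object@origin[2], object@origin[3],
              object@direction[1], object@direction[2], object@direction[3]))
})

#' Closest-point (Nadir) pair between two skew projection lines
#'
#' @slot nadir_a numeric(3), the point on line A closest to line B.
#' @slot nadir_b numeric(3), the point on line B closest to line A.
#' @slot gap_mm distance between the two Nadir points.
#' @slot midpoint numeric(3), arithmetic mean of the Nadir points.
#' @export
setClass("LinePairNadir",
  slots = c(nadir_a = "numeric", nadir_b = "numeric",
            gap_mm = "numeric", midpoint = "numeric"))

setValidity("LinePairNadir", function(object) {
  msg <- character()
  if (!.is_num(object@nadir_a, 3L) || !.is_num(object@nadir_b, 3L) ||
      !.is_num(object@midpoint, 3L) || !.is_num(object@gap_mm, 1L))
    return("nadir_a, nadir_b, midpoint must be numeric(3); gap_mm scalar")
  if (object@gap_mm < 0) msg <- c(msg, "gap_mm must be >= 0")
  if (max(abs(object@midpoint - (object@nadir_a + object@nadir_b) / 2)) > 1e-9)
    msg <- c(msg, "midpoint must be the mean of the Nadir points")
  if (length(msg)) msg else TRUE
})

#' Two-view 3D marker localization
#'
#' The reconstructed 3D marker position from two fluoroscopic views: the
#' midpoint of the Nadir-point pair on the two back-projected rays, the
#' Nadir pair itself (whose gap measures how far the rays are from
#' intersecting), and the angular separation of the two view axes.
#'
#' @slot p_pair numeric(3), reconstructed 3D marker position in mm.
#' @slot nadirs a [LinePairNadir-class].
#' @slot angular_separation_deg angle between the two view axes in degrees.
#' @export
setClass("MarkerLocalization",
  slots = c(p_pair = "numeric", nadirs = "LinePairNadir",
            angular_separation_deg = "numeric"))

setValidity("MarkerLocalization", function(object) {
  msg <- character()
  if (max(abs(object@p_pair - object@nadirs@midpoint)) > 1e-9)
    msg <- c(msg, "p_pair must equal the Nadir midpoint")
  if (!(object@angular_separation_deg >= 0 &&
        object@angular_separation_deg <= 180))
    msg <- c(msg, "angular_separation_deg must lie in [0, 180]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkerLocalization", function(object) {
  cat(sprintf("MarkerLocalization: p_pair (%.3f, %.3f, %.3f) mm\n",
              object@p_pair[1], object@p_pair[2], object@p_pair[3]))
  cat(sprintf("  ray gap %.4f mm, angular separation %.1f deg\n",
              object@nadirs@gap_mm, object@angular_separation_deg))
})

#' A timed fluoroscopic run with ECG
#'
#' An ordered sequence of frames under one C-arm geometry. Each frame
#' carries the 2D marker detector coordinates (mm, origin at the detector
#' center) and a cranio-caudal diaphragm-surrogate position at detector
#' scale (mm, larger = more inspiratory displacement), plus the R-peak
#' times of the simultaneously recorded ECG.
#'
#' @slot frames data.frame with columns `frame`, `t_s`, `marker_u_mm`,
#'   `marker_v_mm`, `diaphragm_mm`; `t_s` non-decreasing.
#' @slot r_peaks_s strictly increasing ECG R-peak times in seconds.
#' @slot fps frame rate in Hz.
#' @slot geometry the [CArmGeometry-class] of the run.
#' @export
setClass("XRRun",
  slots = c(frames = "data.frame", r_peaks_s = "numeric", fps = "numeric",
            geometry = "CArmGeometry"))

.run_cols <- c("frame", "t_s", "marker_u_mm", "marker_v_mm", "diaphragm_mm")

setValidity("XRRun", function(object) {
  msg <- character()
  missing <- setdiff(.run_cols, names(object@frames))
  if (length(missing))
    return(sprintf("frames lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  t <- object@frames$t_s
  if (length(t) && any(diff(t) < 0)) {
    row <- which(diff(t) < 0)[1] + 1L
    msg <- c(msg, sprintf("frame times t_s decrease at row %d", row))
  }
  if (length(object@r_peaks_s) && any(diff(object@r_peaks_s) <= 0))
    msg <- c(msg, "r_peaks_s must be strictly increasing")
  if (!.is_num(object@fps, 1L) || object@fps <= 0)
    msg <- c(msg, "fps must be a positive scalar")
  if (length(msg)) msg else TRUE
})

XRRun <- function(frames, r_peaks_s, fps, geometry) {
  new("XRRun", frames = as.data.frame(frames),
      r_peaks_s = as.numeric(r_peaks_s), fps = as.numeric(fps),
      geometry = geometry)
}

setMethod("show", "XRRun", function(object) {
  cat(sprintf("XRRun '%s': %d frames at %.0f fps (%.1f s), %d R-peaks\n",
              object@geometry@label, nrow(object@frames), object@fps,
              if (nrow(object@frames)) diff(range(object@frames$t_s)) else 0,
              length(object@r_peaks_s)))
})

#' Closed-form accuracy (error) budget
#'
#' Root-sum-square identification-error budget of marker localization:
#' half-diagonal pixel/voxel identification errors, isocenter scaling of
#' the detector-plane error, chaining with the intrinsic geometry error
#' into the two-view 3D error, its re-projection onto the image plane, and
#' the total error including the 3D reference modality.
#'
#' @slot full named numeric of the budget quantities at full precision.
#' @slot display the same quantities rounded for display (0.1 mm); when
#'   the budget was propagated with `round_intermediates = TRUE` these are
#'   the values of the rounded chain (each rounded value feeding the next
#'   formula).
#' @slot params the input parameter list.
#' @export
setClass("ErrorBudget",
  slots = c(full = "numeric", display = "numeric", params = "list"))

.budget_terms <- c("eps_2dxr_mm", "eps_cmr_mm", "eps_2dxr_iso_mm",
                   "eps_xr_geo_mm", "eps_3dxr_mm", "eps_2dxr_proj_mm",
                   "eps_tot_mm")

setValidity("ErrorBudget", function(object) {
  msg <- character()
  if (!all(.budget_terms %in% names(object@full)) ||
      !all(.budget_terms %in% names(object@display)))
    return("budget must contain all chained error terms")
  if (any(object@full < 0)) msg <- c(msg, "all error terms must be >= 0")
  f <- object@full
  if (f["eps_tot_mm"] < max(f["eps_3dxr_mm"], f["eps_cmr_mm"]) - 1e-12)
    msg <- c(msg, "eps_tot must dominate eps_3dxr and eps_cmr")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ErrorBudget", function(object) {
  cat("Error budget (mm):\n")
  lab <- c(eps_2dxr_mm = "2D XR identification (half pixel diagonal)",
           eps_cmr_mm = "3D reference identification (half voxel diagonal)",
           eps_2dxr_iso_mm = "2D XR at isocenter scale",
           eps_xr_geo_mm = "intrinsic XR geometry",
           eps_3dxr_mm = "two-view 3D localization",
           eps_2dxr_proj_mm = "3D error re-projected to image plane",
           eps_tot_mm = "total 3D (XR + reference)")
  for (k in .budget_terms)
    cat(sprintf("  %-48s %4.1f  (%.4f)\n", lab[[k]], object@display[[k]],
                object@full[[k]]))
})

#' Cardiorespiratory motion parameters for the synthetic phantom
#'
#' Parameters of the simulated marker motion: a periodic cardiac bump
#' (raised cosine in cardiac phase, emulating the atrial-systolic
#' contraction that displaces the left atrial appendage) plus a slow
#' quasi-periodic respiratory displacement with an end-expiratory dwell
#' (even-power sinusoid), imaged with beat-to-beat RR variability,
#' detector identification noise and a diaphragm surrogate of larger
#' amplitude than the marker's own respiratory excursion.
#'
#' @slot baseline numeric(3) marker rest position in mm.
#' @slot cardiac_amp numeric(3) peak cardiac displacement vector in mm.
#' @slot cardiac_center_pct,cardiac_width_pct location and half-width of
#'   the cardiac bump in percent of the RR interval.
#' @slot resp_amp numeric(3) marker respiratory displacement at
#'   end-inspiration in mm.
#' @slot resp_period_s respiratory period in seconds.
#' @slot resp_exponent even integer >= 2 shaping the end-expiratory dwell.
#' @slot rr_mean_s,rr_sd_s mean and SD of the RR interval in seconds.
#' @slot diaphragm_amp_mm surrogate amplitude at isocenter scale in mm.
#' @slot detector_noise_sd_mm isotropic 2D identification noise SD in mm.
#' @slot trace_noise_sd_mm noise SD of the diaphragm trace (detector
#'   scale) in mm.
#' @slot seed integer seed making the study reproducible.
#' @export
setClass("MotionParams",
  slots = c(baseline = "numeric", cardiac_amp = "numeric",
            cardiac_center_pct = "numeric", cardiac_width_pct = "numeric",
            resp_amp = "numeric", resp_period_s = "numeric",
            resp_exponent = "numeric", rr_mean_s = "numeric",
            rr_sd_s = "numeric", diaphragm_amp_mm = "numeric",
            detector_noise_sd_mm = "numeric", trace_noise_sd_mm = "numeric",
            seed = "numeric"))

setValidity("MotionParams", function(object) {
  msg <- character()
  if (!.is_num(object@baseline, 3L) || !.is_num(object@cardiac_amp, 3L) ||
      !.is_num(object@resp_amp, 3L))
    msg <- c(msg, "baseline, cardiac_amp, resp_amp must be finite numeric(3)")
  if (object@resp_exponent < 2 || object@resp_exponent %% 2 != 0)
    msg <- c(msg, "resp_exponent must be an even integer >= 2")
  if (!(object@rr_sd_s == 0 ||
        (object@rr_sd_s > 0 && object@rr_mean_s > 3 * object@rr_sd_s)))
    msg <- c(msg, "need rr_mean_s > 3*rr_sd_s > 0, or rr_sd_s = 0")
  if (object@resp_period_s <= 0) msg <- c(msg, "resp_period_s must be > 0")
  if (object@detector_noise_sd_mm < 0 || object@trace_noise_sd_mm < 0 ||
      object@diaphragm_amp_mm < 0)
    msg <- c(msg, "amplitudes and noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname MotionParams-class
#' @param baseline,cardiac_amp,cardiac_center_pct,cardiac_width_pct,resp_amp
#'   see slots.
#' @param resp_period_s,resp_exponent,rr_mean_s,rr_sd_s see slots.
#' @param diaphragm_amp_mm,detector_noise_sd_mm,trace_noise_sd_mm,seed see
#'   slots.
#' @return A validated `MotionParams` object.
#' @export
motionParams <- function(baseline = c(0, 0, 0),
                         cardiac_amp = 4 * c(1, 1, 1) / sqrt(3),
                         cardiac_center_pct = 85, cardiac_width_pct = 15,
                         resp_amp = c(0, 0, 2.5), resp_period_s = 4,
                         resp_exponent = 4, rr_mean_s = 0.9, rr_sd_s = 0.05,
                         diaphragm_amp_mm = 12, detector_noise_sd_mm = 0.1,
                         trace_noise_sd_mm = 0.3, seed = 1) {
  new("MotionParams", baseline = as.numeric(baseline),
      cardiac_amp = as.numeric(cardiac_amp),
      cardiac_center_pct = cardiac_center_pct,
      cardiac_width_pct = cardiac_width_pct, resp_amp = as.numeric(resp_amp),
      resp_period_s = resp_period_s, resp_exponent = resp_exponent,
      rr_mean_s = rr_mean_s, rr_sd_s = rr_sd_s,
      diaphragm_amp_mm = diaphragm_amp_mm,
      detector_noise_sd_mm = detector_noise_sd_mm,
      trace_noise_sd_mm = trace_noise_sd_mm, seed = seed)
}

#' Synthetic cardiorespiratory study with ground truth
#'
#' One or two simulated fluoroscopic runs, the reference 3D marker
#' position ("postprocedural" reference acquired at a fixed cardiac phase
#' in expiration, offset by a known injected co-registration error), and
#' the per-frame ground truth (true 3D positions, true cardiac phase, true
#' respiratory state).
#'
#' @slot runs list of [XRRun-class] objects, one per geometry.
#' @slot cmr_marker numeric(3), the reference 3D marker position in mm
#'   (true reference position + registration error, exactly).
#' @slot truth list with one data.frame per run (aligned 1:1 with its
#'   frames), plus `registration_error_mm` and `reference_true_mm`.
#' @slot params list recording the simulation inputs.
#' @export
setClass("SyntheticStudy",
  slots = c(runs = "list", cmr_marker = "numeric", truth = "list",
            params = "list"))

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  if (!.is_num(object@cmr_marker, 3L))
    msg <- c(msg, "cmr_marker must be numeric(3)")
  tr <- object@truth
  if (!all(c("per_run", "registration_error_mm", "reference_true_mm") %in%
           names(tr)))
    return("truth must contain per_run, registration_error_mm, reference_true_mm")
  if (length(tr$per_run) != length(object@runs))
    msg <- c(msg, "truth$per_run must align with runs")
  else for (i in seq_along(object@runs))
    if (nrow(tr$per_run[[i]]) != nrow(object@runs[[i]]@frames))
      msg <- c(msg, sprintf("truth for run %d does not align with frames", i))
  if (length(msg) == 0L &&
      max(abs(object@cmr_marker -
              (tr$reference_true_mm + tr$registration_error_mm))) > 0)
    msg <- c(msg, "cmr_marker must equal reference_true + registration error")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy: %d run(s), reference marker (%.2f, %.2f, %.2f) mm\n",
              length(object@runs), object@cmr_marker[1], object@cmr_marker[2],
              object@cmr_marker[3]))
  for (r in object@runs) show(r)
})

#' A loaded study ready for analysis
#'
#' The file-level counterpart of [SyntheticStudy-class]: runs, reference
#' marker, optional ground truth, and the (defaulted) classification and
#' analysis configuration.
#'
#' @slot runs list of [XRRun-class].
#' @slot cmr_marker numeric(3) reference marker in mm.
#' @slot truth list (possibly empty) of ground-truth tables.
#' @slot config complete configuration list after defaulting.
#' @slot provenance list of source paths / seed.
#' @export
setClass("StudyBundle",
  slots = c(runs = "list", cmr_marker = "numeric", truth = "list",
            config = "list", provenance = "list"))

setValidity("StudyBundle", function(object) {
  if (!length(object@runs)) return("bundle must contain at least one run")
  if (!all(vapply(object@runs, is, logical(1), "XRRun")))
    return("all runs must be XRRun objects")
  if (!.is_num(object@cmr_marker, 3L)) return("cmr_marker must be numeric(3)")
  TRUE
})

setMethod("show", "StudyBundle", function(object) {
  cat(sprintf("StudyBundle: %d run(s), truth %s\n", length(object@runs),
              if (length(object@truth)) "available" else "absent"))
})

#' Motion-category accuracy report
#'
#' Per-category (c1 motion-synchronized, c2 respiratory off-phase, c3
#' cardiac off-phase, c4 both off-phase) sample sizes, averaged Euclidean
#' distance (AED) with SD, Shapiro-Wilk normality p, and Welch's test of
#' each category against c1; plus the pair-based (two-view triangulation)
#' block with per-pair 3D distances and re-projection errors.
#'
#' @slot categories data.frame with one row per category.
#' @slot pairs data.frame of per-pair triangulation results (0 rows when
#'   the pair analysis was not possible).
#' @slot pair_summary list of pair-block summary statistics.
#' @slot per_source data.frame of per-source (run) category breakdowns.
#' @slot alpha significance level.
#' @export
setClass("AccuracyReport",
  slots = c(categories = "data.frame", pairs = "data.frame",
            pair_summary = "list", per_source = "data.frame",
            alpha = "numeric"))

setValidity("AccuracyReport", function(object) {
  msg <- character()
  d <- object@categories
  need <- c("category", "n", "aed_mm", "sd_mm", "normality_p", "welch_p_vs_c1",
            "stars")
  if (!all(need %in% names(d)))
    return(sprintf("categories lacks column(s): %s",
                   paste(setdiff(need, names(d)), collapse = ", ")))
  if (any(d$aed_mm < 0, na.rm = TRUE) || any(d$sd_mm < 0, na.rm = TRUE))
    msg <- c(msg, "AED and SD must be >= 0")
  p <- c(d$normality_p, d$welch_p_vs_c1)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AccuracyReport", function(object) {
  cat("Accuracy report (distances to the co-registered reference, mm)\n")
  d <- object@categories
  cat(sprintf("  %-4s %4s %8s %8s %10s %6s\n",
              "cat", "n", "AED", "SD", "p_vs_c1", ""))
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-4s %4d %8.2f %8.2f %10s %6s\n", d$category[i], d$n[i],
                d$aed_mm[i], d$sd_mm[i],
                ifelse(is.na(d$welch_p_vs_c1[i]), "-",
                       sprintf("%.4f", d$welch_p_vs_c1[i])), d$stars[i]))
  if (nrow(object@pairs)) {
    s <- object@pair_summary
    cat(sprintf(
      "  pair block: %d pairs, 3D AED %.2f (%.2f) mm, reprojection AED %.2f (%.2f) mm, separation %.1f deg\n",
      nrow(object@pairs), s$aed_mm, s$sd_mm, s$reproj_aed_mm, s$reproj_sd_mm,
      s$angular_separation_deg))
  }
})
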