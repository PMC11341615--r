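## Synthetic cardiorespiratory motion phantom.
##
## A point marker moves as baseline + cardiac bump + respiratory
## displacement. The respiratory waveform is an even power of a sinusoid,
## which dwells near end-expiration (the physiological plateau that makes
## expiratory gating effective); the cardiac waveform is a raised-cosine
## bump in cardiac phase, emulating the atrial-systolic contraction late
## in the RR interval. The phantom images the marker at a fixed frame
## rate under one or two C-arm geometries, adds detector identification
## noise, records a diaphragm surrogate of larger amplitude than the
## marker's own respiratory excursion (plus trace noise), draws RR
## intervals with beat-to-beat variability, and produces a reference 3D
## marker at a chosen cardiac phase in end-expiration offset by a known,
## injected co-registration error. All ground truth is stored.

#' Respiratory displacement waveform with end-expiratory dwell
#'
#' `amplitude * sin(pi t / period)^exponent`: zero (end-expiration) at
#' t = 0, maximal (end-inspiration) at t = period/2, periodic with the
#' given period. Larger even exponents lengthen the expiratory plateau.
#'
#' @param t_s time(s) in seconds (vectorized).
#' @param period_s respiratory period (s).
#' @param amplitude_mm end-inspiratory displacement (mm).
#' @param exponent even integer >= 2.
#' @return displacement in mm.
#' @export
respiratoryWaveform <- function(t_s, period_s, amplitude_mm, exponent) {
  if (exponent < 2 || exponent %% 2 != 0)
    stop("exponent must be an even integer >= 2")
  stopifnot(period_s > 0)
  amplitude_mm * sin(pi * t_s / period_s)^exponent
}

#' Cardiac displacement waveform (atrial-systolic bump)
#'
#' A raised-cosine bump in cardiac phase: maximal at `center_pct`,
#' falling to zero at a circular phase distance of `width_pct`, zero
#' elsewhere. Phase distance is circular in percent RR (0 and 100 are
#' the same phase).
#'
#' @param phase_pct cardiac phase(s) in percent RR (vectorized).
#' @param amplitude_mm peak displacement (mm).
#' @param center_pct bump center in percent RR.
#' @param width_pct half-width in percent RR (> 0).
#' @return displacement in mm.
#' @export
cardiacWaveform <- function(phase_pct, amplitude_mm, center_pct, width_pct) {
  stopifnot(width_pct > 0)
  d <- abs(phase_pct - center_pct) %% 100
  d <- pmin(d, 100 - d)
  ifelse(d <= width_pct,
         amplitude_mm * 0.5 * (1 + cos(pi * d / width_pct)),
         0)
}

#' Simulate ECG R-peak times
#'
#' Cumulative sums of RR intervals drawn from a normal distribution
#' truncated at +/- 3 SD; the first peak is at t = 0. Reproducible for a
#' given seed.
#'
#' @param n_beats number of R-peaks (>= 2).
#' @param rr_mean_s,rr_sd_s RR interval mean and SD (s).
#' @param seed optional integer seed (`NULL` = use the current RNG state).
#' @return numeric vector of R-peak times, first element 0.
#' @export
simulateRPeaks <- function(n_beats, rr_mean_s, rr_sd_s, seed = NULL) {
  stopifnot(n_beats >= 2, rr_mean_s > 0, rr_sd_s >= 0)
  if (!is.null(seed)) set.seed(seed)
  rr <- .rtruncnorm(n_beats - 1, rr_mean_s, rr_sd_s, 3)
  c(0, cumsum(rr))
}

## normal draws truncated at +/- k SD, by rejection (deterministic under
## the current RNG state)
.rtruncnorm <- function(n, mean, sd, k) {
  if (sd == 0 || n == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[abs(x - mean) <= k * sd])
  }
  out[seq_len(n)]
}

#' Simulate a complete study with known ground truth
#'
#' Generates one [XRRun-class] per geometry (each with its own ECG and
#' frame clock starting at the beginning of the run), the reference 3D
#' marker (marker position at the reference cardiac phase in
#' end-expiration, plus the injected registration error), and per-frame
#' ground truth: true 3D positions, noiseless detector track, true
#' cardiac phase and true respiratory state.
#'
#' @param motion a [MotionParams-class] (see [motionParams()]).
#' @param geometries list of [CArmGeometry-class] objects (>= 1).
#' @param fps frame rate (Hz), default 15.
#' @param duration_s run duration (s); must cover >= 2 respiratory
#'   periods.
#' @param registration_error numeric(3), injected co-registration error
#'   (mm) added to the true reference position.
#' @param reference_cardiac_pct cardiac phase of the reference
#'   acquisition in percent RR (default 35, i.e. inside the 30-40%
#'   window, in expiration).
#' @param truth_window_mm acceptance window used to record the true
#'   respiratory state (default 3 mm, evaluated against the noiseless
#'   surrogate: expiration within the window of 0, inspiration within
#'   the window of the surrogate amplitude).
#' @return A [SyntheticStudy-class].
#' @examples
#' study <- simulateStudy(motionParams(seed = 7), duration_s = 20)
#' study
#' @export
simulateStudy <- function(motion = motionParams(),
                          geometries = list(CArmGeometry(label = "AP")),
                          fps = 15, duration_s = 60,
                          registration_error = c(0, 0, 0),
                          reference_cardiac_pct = 35,
                          truth_window_mm = 3) {
  stopifnot(is(motion, "MotionParams"), length(geometries) >= 1,
            .is_num(registration_error, 3L))
  validObject(motion)
  if (duration_s < 2 * motion@resp_period_s)
    stop("duration_s must cover at least 2 respiratory periods")
  set.seed(motion@seed)

  unit_or_zero <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) c(0, 0, 0) else v / n
  }
  c_hat <- unit_or_zero(motion@cardiac_amp)
  c_amp <- sqrt(sum(motion@cardiac_amp^2))
  r_hat <- unit_or_zero(motion@resp_amp)
  r_amp <- sqrt(sum(motion@resp_amp^2))

  marker_at <- function(t, pct) {
    resp_shape <- respiratoryWaveform(t, motion@resp_period_s, 1,
                                      motion@resp_exponent)
    card <- cardiacWaveform(pct, c_amp, motion@cardiac_center_pct,
                            motion@cardiac_width_pct)
    sweep(outer(card, c_hat) + outer(r_amp * resp_shape, r_hat), 2,
          motion@baseline, "+")
  }

  n_beats <- ceiling(duration_s /
                       max(0.2, motion@rr_mean_s - 3 * motion@rr_sd_s)) + 3

  runs <- vector("list", length(geometries))
  per_run <- vector("list", length(geometries))
  for (i in seq_along(geometries)) {
    geom <- geometries[[i]]
    peaks <- simulateRPeaks(n_beats, motion@rr_mean_s, motion@rr_sd_s)
    t <- seq(0, duration_s, by = 1 / fps)
    t <- t[t < peaks[length(peaks)]]
    pct <- cardiacPhasePercent(t, peaks)
    truth_xyz <- marker_at(t, pct)
    det <- t(apply(truth_xyz, 1, function(p) projectPoint(geom, p)))
    resp_shape <- respiratoryWaveform(t, motion@resp_period_s, 1,
                                      motion@resp_exponent)
    dia_iso <- motion@diaphragm_amp_mm * resp_shape
    resp_state <- rep("unclassified", length(t))
    resp_state[dia_iso <= truth_window_mm] <- "expiration"
    resp_state[dia_iso >= motion@diaphragm_amp_mm - truth_window_mm] <-
      "inspiration"
    if (motion@diaphragm_amp_mm <= 2 * truth_window_mm)
      resp_state <- rep("expiration", length(t))
    mag <- magnification(geom)
    frames <- data.frame(
      frame = seq_along(t) - 1L,
      t_s = t,
      marker_u_mm = det[, 1] +
        stats::rnorm(length(t), 0, motion@detector_noise_sd_mm),
      marker_v_mm = det[, 2] +
        stats::rnorm(length(t), 0, motion@detector_noise_sd_mm),
      diaphragm_mm = dia_iso * mag +
        stats::rnorm(length(t), 0, motion@trace_noise_sd_mm))
    runs[[i]] <- XRRun(frames, peaks, fps, geom)
    per_run[[i]] <- data.frame(
      frame = frames$frame, t_s = t,
      x_mm = truth_xyz[, 1], y_mm = truth_xyz[, 2], z_mm = truth_xyz[, 3],
      u_true_mm = det[, 1], v_true_mm = det[, 2],
      cardiac_pct = pct, resp_state = resp_state,
      resp_disp_mm = r_amp * resp_shape, diaphragm_iso_mm = dia_iso,
      stringsAsFactors = FALSE)
  }

  reference_true <- drop(marker_at(0, reference_cardiac_pct))
  cmr <- reference_true + registration_error
  new("SyntheticStudy", runs = runs, cmr_marker = cmr,
      truth = list(per_run = per_run,
                   registration_error_mm = as.numeric(registration_error),
                   reference_true_mm = reference_true),
      params = list(motion = motion, fps = fps, duration_s = duration_s,
                    reference_cardiac_pct = reference_cardiac_pct,
                    truth_window_mm = truth_window_mm,
                    n_geometries = length(geometries)))
}
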