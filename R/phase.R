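## Cardiac and respiratory phase assignment.
##
## Cardiac phase is the elapsed fraction of the current RR interval in
## percent, from the simultaneously recorded ECG R-peaks. Respiratory
## state is derived from a diaphragm-surrogate trace: low-pass filtered
## (Savitzky-Golay), converted to isocenter scale by the view
## magnification, and gated with an acceptance window around the
## end-expiratory and end-inspiratory reference levels. Frames are then
## binned into the four motion categories:
##   c1 expiration, 30-40% RR (motion-synchronized with the reference)
##   c2 inspiration, 30-40% RR
##   c3 expiration, 80-90% RR (atrial systole)
##   c4 inspiration, 80-90% RR

#' Cardiac phase of a time point in percent of the RR interval
#'
#' Linearly interpolates each acquisition time within its enclosing RR
#' interval: `100 * (t - t_prev) / (t_next - t_prev)`. Times before the
#' first or at/after the last R-peak are unclassifiable and return `NA`
#' (such frames are excluded, not extrapolated).
#'
#' @param t_s numeric vector of acquisition times (s).
#' @param r_peaks_s strictly increasing R-peak times (s), length >= 2.
#' @return numeric vector of phases in `[0, 100)`, `NA` outside the span.
#' @examples
#' cardiacPhasePercent(1.35, c(0, 1, 2))  # 35
#' @export
cardiacPhasePercent <- function(t_s, r_peaks_s) {
  stopifnot(is.numeric(t_s), is.numeric(r_peaks_s))
  if (length(r_peaks_s) < 2 || any(diff(r_peaks_s) <= 0))
    stop("r_peaks_s must contain >= 2 strictly increasing R-peak times")
  idx <- findInterval(t_s, r_peaks_s)
  ok <- idx >= 1L & idx < length(r_peaks_s)
  pct <- rep(NA_real_, length(t_s))
  i <- idx[ok]
  pct[ok] <- 100 * (t_s[ok] - r_peaks_s[i]) / (r_peaks_s[i + 1L] - r_peaks_s[i])
  pct
}

#' Savitzky-Golay smoothing of a respiratory surrogate trace
#'
#' Low-pass filters the tracked diaphragm/lung-structure trace with a
#' Savitzky-Golay filter. The window is given in seconds and converted to
#' the nearest odd sample count at the run's frame rate; edges are
#' handled by the filter's truncated-window polynomial fits, so the
#' output has the same length as the input.
#'
#' @param raw numeric trace (mm).
#' @param fps frame rate (Hz).
#' @param window_s filter window in seconds (default 0.7 s: passes
#'   respiration at ~0.2-0.3 Hz while suppressing cardiac-frequency
#'   contamination and tracking jitter).
#' @param polyorder polynomial order (default 3).
#' @return Smoothed trace, same length as `raw`.
#' @export
smoothRespiratoryTrace <- function(raw, fps, window_s = 0.7, polyorder = 3) {
  stopifnot(is.numeric(raw), fps > 0, window_s > 0)
  n <- round(window_s * fps)
  n <- max(n, polyorder + 2)   # window must cover an odd count >= polyorder+2
  if (n %% 2 == 0) n <- n + 1
  if (length(raw) < n)
    stop(sprintf(
      "trace too short for the filter window: %d samples < window of %d",
      length(raw), n))
  as.numeric(signal::sgolayfilt(raw, p = polyorder, n = n))
}

#' Respiratory gating of a filtered isocenter-scale trace
#'
#' Estimates the end-expiratory and end-inspiratory reference levels from
#' the trace (5th and 95th percentiles: end-expiration is a plateau, the
#' percentiles are robust to outliers) and labels each sample
#' `expiration` if it lies within `window_mm` of the expiratory level,
#' `inspiration` if within `window_mm` of the inspiratory level, and
#' `unclassified` otherwise. If the two reference levels are closer than
#' twice the window the respiratory phases are indistinguishable and a
#' shallow-respiration error is raised (runs with too-shallow breathing
#' cannot be gated and must be excluded).
#'
#' @param trace_iso_mm filtered trace at isocenter scale (mm; already
#'   divided by the view magnification), increasing values = inspiratory.
#' @param window_mm acceptance window at the isocenter (default 3 mm,
#'   matching the respiratory-navigated reference acquisition).
#' @return character vector of labels.
#' @export
respiratoryLabels <- function(trace_iso_mm, window_mm = 3) {
  stopifnot(is.numeric(trace_iso_mm), length(trace_iso_mm) >= 1,
            window_mm > 0)
  ref <- stats::quantile(trace_iso_mm, c(0.05, 0.95), names = FALSE,
                         na.rm = FALSE)
  ref_exp <- ref[1]
  ref_insp <- ref[2]
  if (ref_insp - ref_exp < 2 * window_mm)
    stop(sprintf(
      paste0("shallow respiration: reference level separation %.2f mm < %.2f mm;",
             " respiratory phases are indistinguishable"),
      ref_insp - ref_exp, 2 * window_mm))
  labels <- rep("unclassified", length(trace_iso_mm))
  labels[trace_iso_mm <= ref_exp + window_mm] <- "expiration"
  labels[trace_iso_mm >= ref_insp - window_mm] <- "inspiration"
  labels
}

#' Default classification configuration
#'
#' @return list of classification parameters: respiratory acceptance
#'   window (mm, isocenter scale), cardiac windows (percent RR, half-open
#'   `[lo, hi)`), Savitzky-Golay settings and trace-orientation flag.
#' @export
classificationConfig <- function() {
  list(window_mm = 3,
       cardiac_window_a = c(30, 40),
       cardiac_window_b = c(80, 90),
       sg_window_s = 0.7,
       sg_polyorder = 3,
       flip_trace = FALSE,
       min_angle_deg = 1,
       warn_angle_deg = 30,
       alpha = 0.05)
}

.complete_config <- function(config) {
  base <- classificationConfig()
  base[names(config)] <- config
  base
}

.in_window <- function(pct, w) !is.na(pct) & pct >= w[1] & pct < w[2]

#' Classify the frames of a run into motion categories
#'
#' Assigns every frame its cardiac phase (percent RR), respiratory label
#' (from the filtered, isocenter-scaled surrogate trace) and motion
#' category: c1 expiration + cardiac window A, c2 inspiration + A, c3
#' expiration + B, c4 inspiration + B, otherwise `none`. Cardiac windows
#' are half-open (`[30,40)`, `[80,90)` by default) so the categories
#' partition the frames. Frames outside the R-peak span are excluded
#' (category `none`, `NA` phase) and counted in a message.
#'
#' @param run an [XRRun-class].
#' @param config list overriding [classificationConfig()] entries.
#' @return data.frame with columns `frame`, `t_s`, `cardiac_pct`,
#'   `resp_label`, `category`.
#' @export
categorizeFrames <- function(run, config = list()) {
  stopifnot(is(run, "XRRun"))
  validObject(run)
  cfg <- .complete_config(config)
  fr <- run@frames
  if (length(run@r_peaks_s) < 2)
    stop("run has fewer than 2 R-peaks: cardiac phase is unclassifiable")
  pct <- cardiacPhasePercent(fr$t_s, run@r_peaks_s)
  if (anyNA(pct))
    message(sprintf("%d frame(s) outside the R-peak span excluded", sum(is.na(pct))))
  raw <- fr$diaphragm_mm * if (isTRUE(cfg$flip_trace)) -1 else 1
  smooth <- smoothRespiratoryTrace(raw, run@fps, cfg$sg_window_s,
                                   cfg$sg_polyorder)
  resp <- respiratoryLabels(smooth / magnification(run@geometry),
                            cfg$window_mm)
  category <- rep("none", nrow(fr))
  in_a <- .in_window(pct, cfg$cardiac_window_a)
  in_b <- .in_window(pct, cfg$cardiac_window_b)
  category[in_a & resp == "expiration"] <- "c1"
  category[in_a & resp == "inspiration"] <- "c2"
  category[in_b & resp == "expiration"] <- "c3"
  category[in_b & resp == "inspiration"] <- "c4"
  data.frame(frame = fr$frame, t_s = fr$t_s, cardiac_pct = pct,
             resp_label = resp, category = category,
             stringsAsFactors = FALSE)
}
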