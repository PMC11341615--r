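## Plain-text study round-trip.
##
## A study directory holds: study.json (manifest: fps, file names, seed),
## geometry_<i>.json per view, run_<i>.csv (frame,t_s,marker_u_mm,
## marker_v_mm,diaphragm_mm), rpeaks_<i>.csv (t_s), cmr_marker.json and,
## when available, truth_<i>.csv plus the injected registration error in
## the manifest. Loading validates everything and reports violations
## with file / row context.

#' Write a C-arm geometry to JSON
#'
#' @param geom a [CArmGeometry-class].
#' @param path output path.
#' @return The geometry, invisibly.
#' @export
writeGeometry <- function(geom, path) {
  stopifnot(is(geom, "CArmGeometry"))
  jsonlite::write_json(list(label = geom@label, sid_mm = geom@sid_mm,
                            sod_mm = geom@sod_mm,
                            primary_deg = geom@primary_deg,
                            secondary_deg = geom@secondary_deg,
                            pixel_spacing_mm = geom@pixel_spacing_mm),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(geom)
}

#' Read a C-arm geometry from JSON
#'
#' @param path geometry JSON path.
#' @return A [CArmGeometry-class]; invalid geometries (e.g. `sod_mm >=
#'   sid_mm`) raise a descriptive error naming the file.
#' @export
readGeometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sid_mm", "sod_mm", "primary_deg", "secondary_deg",
            "pixel_spacing_mm")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop(sprintf("%s: geometry lacks field(s) %s", path,
                 paste(miss, collapse = ", ")))
  tryCatch(
    CArmGeometry(sid_mm = g$sid_mm, sod_mm = g$sod_mm,
                 primary_deg = g$primary_deg,
                 secondary_deg = g$secondary_deg,
                 pixel_spacing_mm = g$pixel_spacing_mm,
                 label = if (is.null(g$label)) "view" else g$label),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}

#' Write a study to a directory of plain-text files
#'
#' @param study a [SyntheticStudy-class] or [StudyBundle-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "SyntheticStudy") || is(study, "StudyBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- study@runs
  truth <- study@truth
  manifest <- list(n_runs = length(runs),
                   fps = vapply(runs, function(r) r@fps, numeric(1)),
                   cmr_marker = "cmr_marker.json",
                   has_truth = length(truth) > 0)
  for (i in seq_along(runs)) {
    writeGeometry(runs[[i]]@geometry,
                  file.path(dir, sprintf("geometry_%d.json", i)))
    utils::write.csv(runs[[i]]@frames,
                     file.path(dir, sprintf("run_%d.csv", i)),
                     row.names = FALSE)
    utils::write.csv(data.frame(t_s = runs[[i]]@r_peaks_s),
                     file.path(dir, sprintf("rpeaks_%d.csv", i)),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(cmr_marker_mm = study@cmr_marker),
                       file.path(dir, "cmr_marker.json"), digits = 10)
  if (length(truth)) {
    for (i in seq_along(truth$per_run))
      utils::write.csv(truth$per_run[[i]],
                       file.path(dir, sprintf("truth_%d.csv", i)),
                       row.names = FALSE)
    manifest$registration_error_mm <- truth$registration_error_mm
    manifest$reference_true_mm <- truth$reference_true_mm
  }
  jsonlite::write_json(manifest, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}

.read_run_csv <- function(path, geom, peaks, fps) {
  fr <- utils::read.csv(path)
  miss <- setdiff(.run_cols, names(fr))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  bad <- which(diff(fr$t_s) < 0)
  if (length(bad))
    stop(sprintf("%s: frame times decrease at row %d", path, bad[1] + 1L))
  XRRun(fr, peaks, fps, geom)
}

#' Load a study directory into a validated bundle
#'
#' Reads the manifest, geometries, runs, R-peaks, reference marker and
#' (when present) ground truth written by [writeStudy()]. Malformed
#' input raises descriptive errors naming the offending file and row.
#'
#' @param dir study directory.
#' @param config optional list overriding [classificationConfig()]
#'   entries; stored (completed) in the bundle.
#' @return A [StudyBundle-class].
#' @export
loadStudy <- function(dir, config = list()) {
  mpath <- file.path(dir, "study.json")
  if (!file.exists(mpath)) stop(sprintf("missing manifest: %s", mpath))
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  n <- man$n_runs
  if (is.null(n) || n < 1) stop(sprintf("%s: invalid n_runs", mpath))
  fps <- rep_len(man$fps, n)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    gpath <- file.path(dir, sprintf("geometry_%d.json", i))
    rpath <- file.path(dir, sprintf("run_%d.csv", i))
    ppath <- file.path(dir, sprintf("rpeaks_%d.csv", i))
    for (p in c(gpath, rpath, ppath))
      if (!file.exists(p)) stop(sprintf("missing study file: %s", p))
    peaks <- utils::read.csv(ppath)$t_s
    if (is.null(peaks) || (length(peaks) > 1 && any(diff(peaks) <= 0)))
      stop(sprintf("%s: R-peak times must be strictly increasing", ppath))
    runs[[i]] <- .read_run_csv(rpath, readGeometry(gpath), peaks, fps[i])
  }
  cpath <- file.path(dir, "cmr_marker.json")
  if (!file.exists(cpath)) stop(sprintf("missing study file: %s", cpath))
  cmr <- unlist(jsonlite::read_json(cpath, simplifyVector = TRUE)$cmr_marker_mm)
  truth <- list()
  if (isTRUE(man$has_truth)) {
    per_run <- lapply(seq_len(n), function(i) {
      tpath <- file.path(dir, sprintf("truth_%d.csv", i))
      if (!file.exists(tpath)) stop(sprintf("missing study file: %s", tpath))
      utils::read.csv(tpath, stringsAsFactors = FALSE)
    })
    truth <- list(per_run = per_run,
                  registration_error_mm = unlist(man$registration_error_mm),
                  reference_true_mm = unlist(man$reference_true_mm))
  }
  new("StudyBundle", runs = runs, cmr_marker = as.numeric(cmr),
      truth = truth, config = .complete_config(config),
      provenance = list(dir = normalizePath(dir)))
}

#' Wrap an in-memory study as an analysis bundle
#'
#' @param study a [SyntheticStudy-class].
#' @param config optional list overriding [classificationConfig()].
#' @return A [StudyBundle-class] sharing the study's runs, reference
#'   marker and ground truth.
#' @export
asStudyBundle <- function(study, config = list()) {
  stopifnot(is(study, "SyntheticStudy"))
  new("StudyBundle", runs = study@runs, cmr_marker = study@cmr_marker,
      truth = study@truth, config = .complete_config(config),
      provenance = list(source = "in-memory simulation",
                        seed = study@params$motion@seed))
}
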