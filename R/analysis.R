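## End-to-end orchestration of the two analyses:
##  (a) motion-synchronized pair accuracy — frames matching the reference
##      phase (cardiac window A, expiration) are selected in two runs,
##      paired greedily by nearest cardiac phase (the runs are sequential,
##      not simultaneous), triangulated, checked by re-projection and
##      compared in 3D against the co-registered reference marker;
##  (b) single-view category analysis — every categorized frame of the
##      first run contributes the distance between the reference marker
##      and its Nadir point on the frame's back-projected marker ray,
##      pooled into categories c1-c4 and summarized with Welch's test
##      against c1.

#' Single-view distances of categorized frames
#'
#' For every frame of a run with category c1-c4, back-projects the
#' identified marker and computes the perpendicular distance from the
#' co-registered reference marker to the ray (the distance to the
#' reference's Nadir point, the single-view 3D marker estimate).
#'
#' @param run an [XRRun-class].
#' @param cmr_marker numeric(3) reference position (mm).
#' @param config list overriding [classificationConfig()].
#' @return data.frame with `frame`, `t_s`, `cardiac_pct`, `resp_label`,
#'   `category`, `distance_mm`.
#' @export
singleViewDistances <- function(run, cmr_marker, config = list()) {
  stopifnot(is(run, "XRRun"), .is_num(cmr_marker, 3L))
  cls <- categorizeFrames(run, config)
  keep <- cls$category %in% c("c1", "c2", "c3", "c4")
  cls$distance_mm <- NA_real_
  if (any(keep)) {
    fr <- run@frames[keep, , drop = FALSE]
    cls$distance_mm[keep] <- vapply(seq_len(nrow(fr)), function(j) {
      line <- backprojectPoint(run@geometry,
                               c(fr$marker_u_mm[j], fr$marker_v_mm[j]))
      nadirOnLine(line, cmr_marker)$distance_mm
    }, numeric(1))
  }
  cls[keep, , drop = FALSE]
}

#' Motion-synchronized two-view pair analysis
#'
#' Selects the motion-synchronized (c1) frames of two runs under
#' different angulations, pairs them greedily by nearest cardiac phase
#' (each frame used at most once), triangulates each pair, and reports
#' per pair: the ray gap, the per-view re-projection errors, the 3D
#' distance to the co-registered reference marker, and the single-view
#' distances of the two contributing frames.
#'
#' @param run1,run2 [XRRun-class] objects with distinct view axes.
#' @param cmr_marker numeric(3) reference position (mm).
#' @param config list overriding [classificationConfig()].
#' @return list with `pairs` (data.frame, possibly `NULL` when either run
#'   has no motion-synchronized frame) and `summary` (list).
#' @export
pairAnalysis <- function(run1, run2, cmr_marker, config = list()) {
  cfg <- .complete_config(config)
  cls1 <- categorizeFrames(run1, cfg)
  cls2 <- categorizeFrames(run2, cfg)
  s1 <- which(cls1$category == "c1")
  s2 <- which(cls2$category == "c1")
  if (length(s1) == 0 || length(s2) == 0) {
    warning("no motion-synchronized frames in at least one run: pair analysis skipped")
    return(list(pairs = NULL, summary = list()))
  }
  pct1 <- cls1$cardiac_pct[s1]
  pct2 <- cls2$cardiac_pct[s2]
  names(pct1) <- s1
  names(pct2) <- s2
  cost <- abs(outer(pct1, pct2, "-"))
  rownames(cost) <- s1
  colnames(cost) <- s2
  idx <- .match_pairs_named(cost)
  f1 <- run1@frames
  f2 <- run2@frames
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    d1 <- c(f1$marker_u_mm[i], f1$marker_v_mm[i])
    d2 <- c(f2$marker_u_mm[j], f2$marker_v_mm[j])
    loc <- triangulatePair(run1@geometry, d1, run2@geometry, d2,
                           cfg$min_angle_deg, cfg$warn_angle_deg)
    l1 <- backprojectPoint(run1@geometry, d1)
    l2 <- backprojectPoint(run2@geometry, d2)
    data.frame(
      frame1 = f1$frame[i], frame2 = f2$frame[j],
      cardiac_pct1 = cls1$cardiac_pct[i], cardiac_pct2 = cls2$cardiac_pct[j],
      gap_mm = loc@nadirs@gap_mm,
      angular_separation_deg = loc@angular_separation_deg,
      reproj1_mm = reprojectionError(run1@geometry, loc@p_pair, d1),
      reproj2_mm = reprojectionError(run2@geometry, loc@p_pair, d2),
      dist3d_mm = sqrt(sum((loc@p_pair - cmr_marker)^2)),
      single1_mm = nadirOnLine(l1, cmr_marker)$distance_mm,
      single2_mm = nadirOnLine(l2, cmr_marker)$distance_mm,
      cmr_to_nadir_a_mm = sqrt(sum((loc@nadirs@nadir_a - cmr_marker)^2)),
      cmr_to_nadir_b_mm = sqrt(sum((loc@nadirs@nadir_b - cmr_marker)^2)))
  })
  pairs <- do.call(rbind, rows)
  a <- suppressMessages(aed(pairs$dist3d_mm))
  rp <- suppressMessages(aed(c(pairs$reproj1_mm, pairs$reproj2_mm)))
  list(pairs = pairs,
       summary = list(n_pairs = nrow(pairs), aed_mm = a$mean_mm,
                      sd_mm = a$sd_mm, reproj_aed_mm = rp$mean_mm,
                      reproj_sd_mm = rp$sd_mm,
                      angular_separation_deg =
                        pairs$angular_separation_deg[1]))
}

## greedy 1:1 matching on a |phase difference| cost matrix whose dimnames
## are frame row indices; each frame used at most once
.match_pairs_named <- function(cost) {
  out <- matrix(integer(0), ncol = 2)
  while (nrow(cost) > 0 && ncol(cost) > 0) {
    k <- arrayInd(which.min(cost), dim(cost))
    out <- rbind(out, c(as.integer(rownames(cost)[k[1]]),
                        as.integer(colnames(cost)[k[2]])))
    cost <- cost[-k[1], -k[2], drop = FALSE]
  }
  out
}

#' Run the full accuracy analysis of a study
#'
#' Performs, on a loaded or simulated study, (a) the motion-synchronized
#' two-view pair analysis when two runs with distinct angulations are
#' present, and (b) the single-view category analysis on the first run,
#' and assembles the [AccuracyReport-class] (per-category AED/SD/n,
#' normality p, Welch p versus c1, significance stars, Holm column, pair
#' block). Per-stage frame counts are logged as messages so exclusions
#' are auditable.
#'
#' @param bundle a [StudyBundle-class] or [SyntheticStudy-class].
#' @param config list overriding the bundle's configuration.
#' @return An [AccuracyReport-class].
#' @examples
#' study <- simulateStudy(motionParams(seed = 3), duration_s = 40)
#' rep <- suppressMessages(analyzeStudy(study))
#' categoryTable(rep)
#' @export
analyzeStudy <- function(bundle, config = list()) {
  if (is(bundle, "SyntheticStudy")) bundle <- asStudyBundle(bundle)
  stopifnot(is(bundle, "StudyBundle"))
  validObject(bundle)
  cfg <- .complete_config(utils::modifyList(bundle@config, config))
  pair_block <- NULL
  if (length(bundle@runs) >= 2) {
    pair_block <- pairAnalysis(bundle@runs[[1]], bundle@runs[[2]],
                               bundle@cmr_marker, cfg)
    if (!is.null(pair_block$pairs))
      message(sprintf("pair analysis: %d matched frame pairs",
                      nrow(pair_block$pairs)))
  }
  singles <- singleViewDistances(bundle@runs[[1]], bundle@cmr_marker, cfg)
  counts <- table(factor(singles$category, levels = c("c1", "c2", "c3", "c4")))
  message(sprintf("single-view categorization: %s",
                  paste(sprintf("%s=%d", names(counts), counts),
                        collapse = ", ")))
  by_cat <- split(singles$distance_mm, singles$category)
  per_source <- do.call(rbind, lapply(names(by_cat), function(cat) {
    a <- suppressMessages(aed(by_cat[[cat]]))
    data.frame(source = bundle@runs[[1]]@geometry@label, category = cat,
               n = a$n, aed_mm = a$mean_mm, sd_mm = a$sd_mm,
               stringsAsFactors = FALSE)
  }))
  buildAccuracyReport(by_cat, pair_block, per_source, alpha = cfg$alpha)
}

#' Box-plot of per-category distances
#'
#' A minimal graphics helper comparing the motion categories' distance
#' distributions (the motion-synchronized category c1 versus the
#' off-phase categories).
#'
#' @param singles data.frame from [singleViewDistances()].
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
categoryBoxplot <- function(singles, ...) {
  stopifnot(all(c("category", "distance_mm") %in% names(singles)))
  invisible(graphics::boxplot(
    distance_mm ~ factor(category, levels = c("c1", "c2", "c3", "c4")),
    data = singles, xlab = "motion category", ylab = "distance to reference (mm)",
    ...))
}
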