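## Accuracy statistics: AED +/- SD per motion category, normality check,
## Welch's unequal-variance t test of each off-phase category against the
## motion-synchronized category c1.

#' Averaged Euclidean distance with standard deviation
#'
#' @param distances_mm numeric vector of non-negative distances.
#' @return list with `mean_mm`, `sd_mm` (sample SD, n-1 denominator; 0
#'   with a message for a single sample) and `n`.
#' @examples
#' aed(c(1, 2, 3))  # mean 2, sd 1
#' @export
aed <- function(distances_mm) {
  if (length(distances_mm) < 1) stop("aed() needs at least one distance")
  stopifnot(is.numeric(distances_mm), all(distances_mm >= 0))
  s <- if (length(distances_mm) == 1L) {
    message("single sample: SD reported as 0")
    0
  } else {
    stats::sd(distances_mm)
  }
  list(mean_mm = mean(distances_mm), sd_mm = s, n = length(distances_mm))
}

#' Welch's unequal-variance two-sample t test
#'
#' The statistic `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution. Used to compare each off-phase motion category
#' against the motion-synchronized category.
#'
#' @param a,b numeric samples, each of length >= 2; at least one must
#'   have positive variance.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
#' @export
welchTTest <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2 || length(b) < 2)
    stop("Welch's test needs n >= 2 in both samples")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0)
    stop("degenerate samples: both have zero variance")
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Shapiro-Wilk normality p-value
#'
#' @param samples numeric vector, 3 <= n <= 5000, non-constant.
#' @return The Shapiro-Wilk p-value.
#' @export
normalityCheck <- function(samples) {
  if (length(samples) < 3)
    stop("normality check needs at least 3 samples")
  if (stats::sd(samples) == 0)
    stop("normality check undefined for a constant sample")
  stats::shapiro.test(samples)$p.value
}

.stars <- function(p, alpha) {
  if (is.na(p)) return("")
  if (p < alpha / 5) return("**")   # alpha 0.05 -> 0.01
  if (p < alpha) return("*")
  ""
}

#' Build the per-category accuracy report
#'
#' Aggregates pooled per-frame distances of the motion categories into
#' AED +/- SD with sample size, Shapiro-Wilk normality p, Welch's test of
#' each category against c1 with significance stars (* p < 0.05,
#' ** p < 0.01 at the default alpha), and a Holm-adjusted column
#' (an extra safeguard over the three raw comparisons). A pair-based
#' triangulation block and a per-source breakdown may be attached.
#'
#' @param by_category named list of numeric distance vectors; `c1` must
#'   be present with n >= 2. Missing or empty categories yield `n = 0`
#'   rows without tests.
#' @param pair_block optional list with `pairs` (data.frame) and
#'   `summary` (list), as produced by the pair analysis.
#' @param per_source optional data.frame of per-source breakdowns.
#' @param alpha significance level (default 0.05).
#' @return An [AccuracyReport-class].
#' @export
buildAccuracyReport <- function(by_category, pair_block = NULL,
                                per_source = NULL, alpha = 0.05) {
  if (is.null(by_category$c1) || length(by_category$c1) < 2)
    stop("category c1 (motion-synchronized) with n >= 2 is required")
  cats <- c("c1", "c2", "c3", "c4")
  rows <- lapply(cats, function(cat) {
    d <- by_category[[cat]]
    if (is.null(d) || length(d) == 0L)
      return(data.frame(category = cat, n = 0L, aed_mm = NA_real_,
                        sd_mm = NA_real_, normality_p = NA_real_,
                        welch_p_vs_c1 = NA_real_, stars = "",
                        stringsAsFactors = FALSE))
    a <- suppressMessages(aed(d))
    norm_p <- if (length(d) >= 3 && stats::sd(d) > 0) normalityCheck(d)
              else NA_real_
    wp <- if (cat != "c1" && length(d) >= 2 &&
              (stats::var(d) + stats::var(by_category$c1)) > 0)
      welchTTest(d, by_category$c1)$p else NA_real_
    data.frame(category = cat, n = a$n, aed_mm = a$mean_mm, sd_mm = a$sd_mm,
               normality_p = norm_p, welch_p_vs_c1 = wp,
               stars = .stars(wp, alpha), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$holm_p_vs_c1 <- NA_real_
  has_p <- !is.na(tab$welch_p_vs_c1)
  if (any(has_p))
    tab$holm_p_vs_c1[has_p] <- stats::p.adjust(tab$welch_p_vs_c1[has_p],
                                               method = "holm")
  pairs <- if (!is.null(pair_block) && !is.null(pair_block$pairs))
    pair_block$pairs else data.frame()
  psum <- if (!is.null(pair_block) && !is.null(pair_block$summary))
    pair_block$summary else list()
  if (is.null(per_source)) per_source <- data.frame()
  new("AccuracyReport", categories = tab, pairs = pairs,
      pair_summary = psum, per_source = per_source, alpha = alpha)
}

#' Write an accuracy report as CSV / JSON
#'
#' The CSV holds the per-category table (rows = categories; columns n,
#' AED, SD, p vs c1, stars); the JSON additionally carries the pair block
#' and per-source breakdown.
#'
#' @param report an [AccuracyReport-class].
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
writeAccuracyReport <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(is(report, "AccuracyReport"))
  if (!is.null(csv_path))
    utils::write.csv(report@categories, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- list(categories = report@categories,
                    pairs = report@pairs,
                    pair_summary = report@pair_summary,
                    per_source = report@per_source,
                    alpha = report@alpha)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = 10,
                         null = "null", na = "null")
  }
  invisible(report)
}
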