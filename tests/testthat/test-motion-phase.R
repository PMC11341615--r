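test_that("cardiac phase interpolates linearly within the RR interval", {
  expect_equal(cardiacPhasePercent(1.35, c(0, 1, 2)), 35)
  expect_equal(cardiacPhasePercent(1, c(0, 1, 2)), 0)
  expect_equal(cardiacPhasePercent(0.85, c(0, 1)), 85)
  # unequal RR intervals: the phase is relative to the enclosing beat
  expect_equal(cardiacPhasePercent(c(0.45, 1.6), c(0, 0.9, 2.1)), c(50, 700 / 12))
  # outside the R-peak span: unclassifiable, not extrapolated
  expect_true(is.na(cardiacPhasePercent(-0.1, c(0, 1))))
  expect_true(is.na(cardiacPhasePercent(1.0, c(0, 1))))
  expect_error(cardiacPhasePercent(0.5, c(1, 1)), "strictly increasing")
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials", {
  expect_equal(smoothRespiratoryTrace(rep(2.5, 40), fps = 15), rep(2.5, 40))
  t <- seq(0, 3, by = 1 / 15)
  cubic <- 1 + 2 * t - 0.5 * t^2 + 0.1 * t^3
  sm <- smoothRespiratoryTrace(cubic, fps = 15, window_s = 0.7, polyorder = 3)
  interior <- 8:(length(t) - 7)
  expect_equal(sm[interior], cubic[interior], tolerance = 1e-9)
  expect_error(smoothRespiratoryTrace(1:5, fps = 15, window_s = 1), "too short")
})

test_that("smoothing suppresses white noise on a respiratory sinusoid", {
  set.seed(7)
  t <- seq(0, 20, by = 1 / 15)
  clean <- 6 * (1 - cos(2 * pi * t / 4)) / 2
  noisy <- clean + rnorm(length(t), 0, 0.5)
  sm <- smoothRespiratoryTrace(noisy, fps = 15)
  rmse <- function(x) sqrt(mean((x - clean)^2))
  expect_lt(rmse(sm), rmse(noisy))
  expect_lt(rmse(sm), 0.35)
})

test_that("respiratory gating labels with the acceptance window", {
  trace <- seq(0, 12, length.out = 400)
  lab <- respiratoryLabels(trace, window_mm = 3)
  value_at <- function(v) lab[which.min(abs(trace - v))]
  expect_equal(value_at(1.5), "expiration")
  expect_equal(value_at(10.0), "inspiration")
  expect_equal(value_at(6.0), "unclassified")
  # shallow respiration: phases indistinguishable
  expect_error(respiratoryLabels(seq(0, 4, length.out = 100), window_mm = 3),
               "shallow respiration")
  expect_error(respiratoryLabels(rep(5, 100), window_mm = 3),
               "shallow respiration")
})

test_that("frames are categorized into c1-c4 by cardiac window and respiration", {
  # two beats per second of frames; diaphragm alternates slow deep breaths
  fps <- 15
  t <- seq(0, 30, by = 1 / fps)
  peaks <- seq(0, 31, by = 1)
  dia_iso <- 12 * sin(pi * t / 4)^4
  run <- make_run(t, peaks, dia_iso * 1.5)  # detector scale, magnification 1.5
  cls <- categorizeFrames(run)
  expect_true(all(cls$category %in% c("c1", "c2", "c3", "c4", "none")))
  expect_equal(nrow(cls), length(t))

  pick <- function(pct_target, resp) {
    i <- which(abs(cls$cardiac_pct - pct_target) < 3 & cls$resp_label == resp)
    if (length(i)) cls$category[i[1]] else NA_character_
  }
  expect_equal(pick(35, "expiration"), "c1")
  expect_equal(pick(85, "inspiration"), "c4")
  expect_equal(pick(55, "expiration"), "none")

  # half-open windows: phase exactly 40 is outside window A, 30 inside
  # (edge frames in the first beat so the phase is computed without
  # cancellation: 0.3 s into a 1 s beat is exactly 30%)
  t_edge <- c(0.30, 0.40, seq(1, 13, by = 1 / 15))
  run_edge <- make_run(t_edge, 0:14, 12 * sin(pi * t_edge / 4)^4 * 1.5)
  cls_edge <- categorizeFrames(run_edge)
  expect_equal(cls_edge$cardiac_pct[1:2], c(30, 40))
  expect_equal(cls_edge$resp_label[1:2], c("expiration", "expiration"))
  expect_equal(cls_edge$category[1], "c1")   # 30% inclusive
  expect_equal(cls_edge$category[2], "none") # 40% excluded
})

test_that("every frame gets exactly one category and windows act monotonically", {
  study <- simulateStudy(motionParams(seed = 5), duration_s = 40)
  run <- runs(study)[[1]]
  cls <- categorizeFrames(run)
  expect_equal(nrow(cls), nrow(frames(run)))
  expect_true(all(cls$category %in% c("c1", "c2", "c3", "c4", "none")))

  n_labeled <- vapply(c(2, 3, 4, 5), function(w) {
    sum(categorizeFrames(run, list(window_mm = w))$resp_label != "unclassified")
  }, numeric(1))
  expect_true(all(diff(n_labeled) >= 0))
})

test_that("frames outside the R-peak span are excluded with a message", {
  t <- seq(0, 10, by = 1 / 15)
  dia <- 12 * sin(pi * t / 4)^4 * 1.5
  run <- make_run(t, seq(0.5, 9.5, by = 1), dia)
  expect_message(cls <- categorizeFrames(run), "outside the R-peak span")
  expect_true(all(is.na(cls$cardiac_pct[run@frames$t_s < 0.5])))
  expect_true(all(cls$category[is.na(cls$cardiac_pct)] == "none"))
})

test_that("classification recovers ground truth away from window boundaries", {
  study <- simulateStudy(motionParams(seed = 12), duration_s = 60)
  run <- runs(study)[[1]]
  tru <- studyTruth(study)$per_run[[1]]
  cls <- categorizeFrames(run)

  win <- function(p, w) p >= w[1] & p < w[2]
  true_cat <- rep("none", nrow(tru))
  a <- win(tru$cardiac_pct, c(30, 40)); b <- win(tru$cardiac_pct, c(80, 90))
  true_cat[a & tru$resp_state == "expiration"] <- "c1"
  true_cat[a & tru$resp_state == "inspiration"] <- "c2"
  true_cat[b & tru$resp_state == "expiration"] <- "c3"
  true_cat[b & tru$resp_state == "inspiration"] <- "c4"

  # frames comfortably inside both windows
  away_cardiac <- sapply(tru$cardiac_pct, function(p)
    min(abs(p - c(30, 40, 80, 90))) >= 1)
  amp <- motionParams()@diaphragm_amp_mm
  away_resp <- tru$diaphragm_iso_mm <= 3 - 0.5 |
    (tru$diaphragm_iso_mm >= amp - 3 + 0.5) |
    (tru$diaphragm_iso_mm >= 3 + 0.5 & tru$diaphragm_iso_mm <= amp - 3 - 0.5)
  sel <- away_cardiac & away_resp
  expect_gt(sum(sel), 200)
  expect_gte(mean(cls$category[sel] == true_cat[sel]), 0.95)
})
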