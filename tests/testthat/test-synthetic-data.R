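test_that("respiratory waveform dwells at end-expiration and is periodic", {
  expect_equal(respiratoryWaveform(0, 4, 2.5, 4), 0)
  expect_equal(respiratoryWaveform(2, 4, 2.5, 4), 2.5)
  t <- seq(0, 4, by = 0.1)
  expect_equal(respiratoryWaveform(t, 4, 2.5, 4),
               respiratoryWaveform(t + 4, 4, 2.5, 4), tolerance = 1e-12)
  expect_error(respiratoryWaveform(1, 4, 2.5, 3), "even")
  # larger even exponents spend more time near end-expiration
  frac_low <- function(k) mean(respiratoryWaveform(t, 4, 1, k) < 0.1)
  expect_gt(frac_low(8), frac_low(2))
})

test_that("cardiac waveform is a circularly symmetric bump", {
  expect_equal(cardiacWaveform(85, 4, 85, 15), 4)
  expect_equal(cardiacWaveform(70, 4, 85, 15), 0)
  expect_equal(cardiacWaveform(55, 4, 85, 15), 0)
  for (d in c(3, 7, 12))
    expect_equal(cardiacWaveform(85 + d, 4, 85, 15),
                 cardiacWaveform(85 - d, 4, 85, 15))
  # circular phase distance: 0% and 100% are the same phase
  expect_equal(cardiacWaveform(2, 4, 95, 15), cardiacWaveform(92, 4, 85, 15))
})

test_that("simulated R-peaks are reproducible with the requested moments", {
  expect_equal(simulateRPeaks(5, 0.9, 0, seed = 1), seq(0, 3.6, by = 0.9))
  expect_identical(simulateRPeaks(40, 0.9, 0.05, seed = 3),
                   simulateRPeaks(40, 0.9, 0.05, seed = 3))
  peaks <- simulateRPeaks(1001, 0.9, 0.05, seed = 4)
  rr <- diff(peaks)
  expect_lt(abs(mean(rr) - 0.9), 0.01)
  expect_lt(abs(sd(rr) - 0.05), 0.01)
  expect_true(all(abs(rr - 0.9) <= 3 * 0.05 + 1e-12))
})

test_that("a static noiseless study yields zero distances everywhere", {
  study <- simulateStudy(static_motion(), geometries = ap_lao60(),
                         duration_s = 20)
  cmr <- cmrMarker(study)
  expect_equal(cmr, c(0, 0, 0))
  for (run in runs(study)) {
    fr <- frames(run)
    for (j in seq_len(nrow(fr))) {
      line <- backprojectPoint(geometry(run),
                               c(fr$marker_u_mm[j], fr$marker_v_mm[j]))
      expect_lt(nadirOnLine(line, cmr)$distance_mm, 1e-9)
    }
  }
  r1 <- runs(study)[[1]]; r2 <- runs(study)[[2]]
  loc <- triangulatePair(geometry(r1),
                         c(frames(r1)$marker_u_mm[1], frames(r1)$marker_v_mm[1]),
                         geometry(r2),
                         c(frames(r2)$marker_u_mm[1], frames(r2)$marker_v_mm[1]))
  expect_lt(sqrt(sum((loc@p_pair - cmr)^2)), 1e-9)
})

test_that("the stored truth reproduces the noiseless detector track", {
  study <- simulateStudy(motionParams(seed = 9, detector_noise_sd_mm = 0,
                                      trace_noise_sd_mm = 0),
                         duration_s = 20)
  run <- runs(study)[[1]]
  tru <- studyTruth(study)$per_run[[1]]
  expect_equal(nrow(tru), nrow(frames(run)))
  for (j in seq(1, nrow(tru), by = 17)) {
    d <- projectPoint(geometry(run), c(tru$x_mm[j], tru$y_mm[j], tru$z_mm[j]))
    expect_equal(unname(d), c(tru$u_true_mm[j], tru$v_true_mm[j]),
                 tolerance = 1e-12)
    expect_equal(unname(d),
                 c(frames(run)$marker_u_mm[j], frames(run)$marker_v_mm[j]),
                 tolerance = 1e-12)
  }
  # diaphragm surrogate and marker respiratory displacement share the
  # waveform: perfectly correlated by construction
  expect_equal(cor(tru$diaphragm_iso_mm, tru$resp_disp_mm), 1,
               tolerance = 1e-12)
  expect_equal(frames(run)$diaphragm_mm,
               tru$diaphragm_iso_mm * magnification(geometry(run)),
               tolerance = 1e-12)
})

test_that("a pure perpendicular registration offset appears in every c1 distance", {
  study <- simulateStudy(static_motion(seed = 2), duration_s = 20,
                         registration_error = c(2, 0, 0))
  expect_equal(cmrMarker(study),
               studyTruth(study)$reference_true_mm + c(2, 0, 0))
  singles <- singleViewDistances(runs(study)[[1]], cmrMarker(study))
  d_c1 <- singles$distance_mm[singles$category == "c1"]
  expect_gt(length(d_c1), 5)
  expect_true(all(abs(d_c1 - 2) < 1e-6))
})

test_that("studies are deterministic functions of parameters and seed", {
  s1 <- simulateStudy(motionParams(seed = 33), duration_s = 16)
  s2 <- simulateStudy(motionParams(seed = 33), duration_s = 16)
  expect_identical(frames(runs(s1)[[1]]), frames(runs(s2)[[1]]))
  expect_identical(rPeaks(runs(s1)[[1]]), rPeaks(runs(s2)[[1]]))
  d1 <- tempfile(); d2 <- tempfile()
  writeStudy(s1, d1); writeStudy(s2, d2)
  for (fn in list.files(d1)) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
  unlink(c(d1, d2), recursive = TRUE)
  s3 <- simulateStudy(motionParams(seed = 34), duration_s = 16)
  expect_false(identical(frames(runs(s1)[[1]]), frames(runs(s3)[[1]])))
})

test_that("motion parameter invariants are enforced", {
  expect_error(motionParams(resp_exponent = 3), "even")
  expect_error(motionParams(rr_mean_s = 0.1, rr_sd_s = 0.05), "rr_mean_s")
  expect_error(motionParams(detector_noise_sd_mm = -1), ">= 0")
  expect_error(simulateStudy(motionParams(), duration_s = 5),
               "respiratory periods")
})
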