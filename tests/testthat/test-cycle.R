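make_curve <- function(v, frame_rate = 25) {
  lvecho:::as_volume_curve(
    tibble::tibble(
      frame = seq_along(v),
      time_s = (seq_along(v) - 1) / frame_rate,
      volume_ml = v
    ),
    frame_rate
  )
}

test_that("build_curve stamps times and volumes per frame", {
  circ <- circle_contour(20, cx = 40, cy = 40)
  curve <- build_curve(list(circ, circ), pixel_spacing = 1, frame_rate = 10)
  expect_equal(curve$time_s, c(0, 0.1))
  expect_equal(curve$volume_ml[1], curve$volume_ml[2])
  expect_error(build_curve(list(circ), 1, 10), "at least 2")
  bad <- list(circ, data.frame(x = c(1, 1, 1), y = c(2, 2, 2)))
  expect_error(build_curve(bad, 1, 10), "frame 2")
})

test_that("moving-average smoothing obeys its contracts", {
  cv <- make_curve(c(0, 10, 0, 5, 3, 8, 2, 9, 4, 1))
  expect_identical(smooth_curve(cv, 1), cv)
  expect_error(smooth_curve(cv, 2), "odd")
  expect_error(smooth_curve(cv, 11), "window")
  cv3 <- make_curve(c(0, 10, 0, rep(5, 7)))
  expect_equal(smooth_curve(cv3, 3)$volume_ml[2], 10 / 3)
  # circular moving average conserves the total of a periodic curve, and the
  # truncated version agrees with it on all interior (full-window) points
  n <- 40
  v <- 100 + 20 * cos(2 * pi * (seq_len(n) - 1) / n)
  circ <- vapply(seq_len(n), function(i) {
    mean(v[((c(i - 2, i - 1, i)) %% n) + 1]) # i-1, i, i+1 wrapped
  }, numeric(1))
  sm <- smooth_curve(make_curve(v), 3)$volume_ml
  expect_equal(sum(circ), sum(v), tolerance = 1e-9)
  expect_equal(sm[2:(n - 1)], circ[2:(n - 1)])
  # brute-force truncated-window oracle over the whole curve
  oracle <- vapply(seq_len(n), function(i) {
    mean(v[max(1, i - 1):min(n, i + 1)])
  }, numeric(1))
  expect_equal(sm, oracle)
})

test_that("ED/ES detection recovers the phantom ground truth exactly", {
  ph <- generate_phantom(phantom_params())
  cv <- make_curve(ph$truth$frames$volume_ml, 25)
  det <- detect_ed_es(cv, 3)
  expect_identical(det$ed_frames, ph$truth$ed_frames)
  expect_identical(det$es_frames, ph$truth$es_frames)
  expect_equal(det$cycle_spans$start, c(1L, 21L, 41L))
  expect_equal(det$cycle_spans$end, c(21L, 41L, 61L))
})

test_that("detection handles boundary extrema and monotone curves", {
  # one cosine cycle starting at its maximum
  n <- 24
  v <- 100 + 20 * cos(2 * pi * (seq_len(n) - 1) / n)
  det <- detect_ed_es(make_curve(v), 1)
  expect_equal(det$ed_frames, 1L)
  expect_equal(det$es_frames, which.min(v))
  # strictly monotone curves carry no complete cycle
  expect_error(detect_ed_es(make_curve(seq(50, 120, length.out = 20)), 1),
               "no complete cycle")
  expect_error(detect_ed_es(make_curve(seq(120, 50, length.out = 20)), 1),
               "no complete cycle")
  expect_error(detect_ed_es(make_curve(c(1, 2, 3)), 1), "at least 8")
})

test_that("near-flat plateaus resolve to their first frame", {
  v <- c(100, 100.2, 99.9, 80, 60, 50.1, 49.9, 50.0, 70, 90, 100.1)
  det <- detect_ed_es(make_curve(v), 1, plateau_tol = 0.015, median_window = 1)
  expect_equal(det$ed_frames, 1L)
  expect_equal(det$es_frames, 6L)
})

test_that("cardiac indices follow the SV/EF/CO formulas", {
  # EDV 120, ESV 50, HR 70 -> SV 70, EF 58.33%, CO 4900
  v <- c(120, 120, 100, 70, 50, 50, 60, 80, 100, 119)
  det <- detect_ed_es(make_curve(v, 10), 1, median_window = 1)
  idx <- cardiac_indices(make_curve(v, 10), det, hr_bpm = 70)
  expect_equal(idx$sv_ml, 70)
  expect_equal(idx$ef_percent, 70 / 120 * 100, tolerance = 1e-10)
  expect_equal(idx$co_ml_per_min, 4900)
  # EDV = ESV -> SV = 0, EF = 0; ESV = 0 -> EF = 100
  cv0 <- make_curve(v, 10)
  det0 <- detect_ed_es(cv0, 1, median_window = 1)
  cv_eq <- cv0; cv_eq$volume_ml[det0$es_frames] <- cv_eq$volume_ml[det0$ed_frames]
  expect_equal(cardiac_indices(cv_eq, det0)$ef_percent, 0)
  cv_z <- cv0; cv_z$volume_ml[det0$es_frames] <- 0
  expect_equal(cardiac_indices(cv_z, det0)$ef_percent, 100)
  # HR from the detected cycle length
  ph <- generate_phantom(phantom_params())
  cvp <- make_curve(ph$truth$frames$volume_ml, 25)
  idxp <- cardiac_indices(cvp, detect_ed_es(cvp, 3))
  expect_equal(idxp$hr_bpm, rep(60 * 25 / 20, 3))
  expect_equal(glance(idxp)$co_ml_per_min, 70 * 75)
})

test_that("EF and detected frames are scale-equivariant", {
  ph <- generate_phantom(phantom_params())
  v <- ph$truth$frames$volume_ml
  for (c_scale in c(0.5, 3)) {
    d1 <- detect_ed_es(make_curve(v), 3)
    d2 <- detect_ed_es(make_curve(v * c_scale), 3)
    expect_identical(d1$ed_frames, d2$ed_frames)
    expect_identical(d1$es_frames, d2$es_frames)
    i1 <- cardiac_indices(make_curve(v), d1)
    i2 <- cardiac_indices(make_curve(v * c_scale), d2)
    expect_equal(i2$ef_percent, i1$ef_percent)
    expect_equal(i2$sv_ml, i1$sv_ml * c_scale)
    expect_equal(i2$edv_ml, i1$edv_ml * c_scale)
    expect_equal(i2$co_ml_per_min, i1$co_ml_per_min * c_scale)
  }
})

test_that("measured volume curve tracks the phantom ground truth within 5%", {
  run <- noiseless_run()
  vt <- noiseless_phantom()$truth$frames$volume_ml
  expect_true(all(abs(run$curve$volume_ml - vt) / vt < 0.05))
})
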