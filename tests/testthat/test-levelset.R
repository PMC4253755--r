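test_that("image energy matches gradient-of-Gaussian closed forms", {
  expect_equal(image_energy(matrix(0.42, 32, 32), 2), matrix(0, 32, 32))
  # vertical step edge: maximum lies on the step columns
  fr <- matrix(0, 32, 64); fr[, 33:64] <- 1
  e <- image_energy(fr, 1)
  expect_true(all(which(e == max(e), arr.ind = TRUE)[, 2] %in% 32:33))
  # 1-px ramp of height h: peak gradient h / (sigma sqrt(2 pi)) within 5%
  h <- 0.8
  fr2 <- matrix(0, 32, 64); fr2[, 33] <- h / 2; fr2[, 34:64] <- h
  e2 <- image_energy(fr2, 3)
  expect_lt(abs(max(e2) - h / (3 * sqrt(2 * pi))) / (h / (3 * sqrt(2 * pi))), 0.05)
  expect_error(image_energy(matrix(c(1, NA, 1, 1), 2, 2), 1), "non-finite")
})

test_that("stopping map is exp(-gain * energy), monotone in the gain", {
  expect_equal(stopping_map(matrix(0, 4, 4), 1), matrix(1, 4, 4))
  expect_equal(stopping_map(matrix(log(2), 1, 1), 1)[1, 1], 0.5)
  expect_equal(stopping_map(matrix(10, 1, 1), 1)[1, 1], exp(-10))
  expect_lt(abs(stopping_map(matrix(10, 1, 1), 1)[1, 1] - 4.54e-5), 1e-6)
  e <- image_energy(noiseless_phantom()$sequence$frames[[1]], 1.5)
  k_lo <- stopping_map(e, 20); k_hi <- stopping_map(e, 40)
  expect_true(all(k_hi <= k_lo))
  expect_true(all(k_lo > 0 & k_lo <= 1))
  expect_error(stopping_map(e, 0), "edge_gain")
})

test_that("init_phi produces a signed distance field", {
  phi <- init_phi(c(64.5, 64.5), c(128, 128), radius = 10)
  expect_equal(phi[64, 64], sqrt(0.5) - 10, tolerance = 0.01)
  expect_lt(abs(min(phi) + 10), 0.8)
  # zero level set within a pixel of the requested boundary
  ring <- abs(sqrt((col(phi) - 64.5)^2 + (row(phi) - 64.5)^2) - 10) < 0.5
  expect_lt(max(abs(phi[ring])), 1)
  # mask seed vs O(N^2) exhaustive boundary-pixel distance oracle on 64x64
  mask <- (circle_sdf(12, 64, 64) < 0)
  phi_m <- init_phi(mask, c(64, 64))
  oracle <- brute_force_sdf(mask)
  expect_lt(max(abs(phi_m - oracle)), 1)
  expect_error(init_phi(matrix(FALSE, 8, 8), c(8, 8)), "empty")
  expect_error(init_phi(c(200, 5), c(64, 64)), "outside")
})

test_that("mean curvature matches analytic curvatures", {
  xg <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  expect_equal(mean_curvature(xg)[5:60, 5:60], matrix(0, 56, 56))
  for (r in c(10, 20, 30)) {
    phi <- circle_sdf(r)
    k <- mean_curvature(phi)
    on_zero <- abs(phi) < 0.5
    expect_lt(abs(mean(k[on_zero]) - 1 / r) / (1 / r), 0.1)
  }
  # ellipse a = 30 (x), b = 15 (y): curvature b/a^2 at the co-vertex
  # (minor-axis end), a/b^2 at the vertex (major-axis end)
  phi_e <- ellipse_sdf(30, 15)
  k_e <- mean_curvature(phi_e)
  expect_lt(abs(mean(k_e[79:80, 64:65]) - 15 / 30^2) / (15 / 30^2), 0.15)
  expect_lt(abs(mean(k_e[64:65, 94:95]) - 30 / 15^2) / (30 / 15^2), 0.15)
})

test_that("evolution advects the front at the prescribed normal speed", {
  phi0 <- circle_sdf(20)
  k1 <- matrix(1, 128, 128)
  p <- level_set_params(v0 = 1, eps_curv = 0, dt = 0.4)
  # zero stopping map freezes the field
  expect_identical(evolve_step(phi0, matrix(0, 128, 128), p), phi0)
  # constant-speed growth: r(t) = r0 + v0 t
  phi <- phi0
  r_prev <- 20
  for (i in 1:50) {
    phi <- evolve_step(phi, k1, p)
    if (i %% 20 == 0) phi <- reinitialize(phi)
    if (i <= 3) {
      cc <- extract_contour(phi)
      r_now <- mean(sqrt((cc$x - 64.5)^2 + (cc$y - 64.5)^2))
      expect_lt(abs((r_now - r_prev) - 0.4) / 0.4, 0.2)
      r_prev <- r_now
    }
  }
  cc <- extract_contour(phi)
  r50 <- mean(sqrt((cc$x - 64.5)^2 + (cc$y - 64.5)^2))
  expect_lt(abs(r50 - (20 + 0.4 * 50)) / (20 + 0.4 * 50), 0.05)
  # curvature flow strictly shrinks a convex region
  p2 <- level_set_params(v0 = 0, eps_curv = 0.5, dt = 0.4)
  phi2 <- phi0
  areas <- sum(phi2 < 0)
  for (i in 1:20) {
    phi2 <- evolve_step(phi2, k1, p2)
    areas <- c(areas, sum(phi2 < 0))
  }
  expect_lt(areas[length(areas)], areas[1])
  expect_true(all(diff(areas) <= 0))
  # CFL contract
  expect_error(
    evolve_step(phi0, k1, level_set_params(v0 = 2, eps_curv = 0, dt = 0.4)),
    "CFL"
  )
})

test_that("reinitialization restores a signed distance function", {
  phi <- circle_sdf(20)
  expect_lt(max(abs(reinitialize(phi) - phi)), 0.1) # idempotence
  # scaled field: same zero set, unit gradient restored
  r3 <- reinitialize(phi * 3)
  expect_lt(max(abs(r3 - phi)), 0.5)
  # steepened (cubed, sign-preserving) field
  rc <- reinitialize(sign(phi) * abs(phi)^3)
  expect_lt(max(abs(rc - phi)), 0.5)
  g <- lvecho:::grad_central(rc)
  gn <- sqrt(g$gx^2 + g$gy^2)
  band <- abs(phi) < 6
  expect_gte(mean(gn[band] >= 0.8 & gn[band] <= 1.2), 0.95)
  expect_error(reinitialize(matrix(1, 16, 16)), "collapsed")
})

test_that("extract_contour returns the longest closed zero isocontour", {
  phi <- circle_sdf(20)
  cc <- extract_contour(phi)
  r <- sqrt((cc$x - 64.5)^2 + (cc$y - 64.5)^2)
  expect_true(all(abs(r - 20) < 0.5))
  expect_lt(abs(polygon_area(cc) - 400 * pi) / (400 * pi), 0.01)
  # two disjoint circles: only the large one is returned
  phi2 <- pmin(circle_sdf(20, cx = 40, cy = 64.5), circle_sdf(5, cx = 100, cy = 64.5))
  cc2 <- extract_contour(phi2)
  r2 <- sqrt((cc2$x - 40)^2 + (cc2$y - 64.5)^2)
  expect_true(all(abs(r2 - 20) < 0.5))
  expect_error(extract_contour(matrix(1, 16, 16)), "no zero level set")
})

test_that("segment_frame honours the iteration cap on a blank frame", {
  blank <- matrix(0.5, 64, 64)
  p <- level_set_params(v0 = 0.5, eps_curv = 0, dt = 0.5, max_iters = 10,
                        snap_to_edge = FALSE)
  res <- segment_frame(blank, init_phi(c(32, 32), c(64, 64)), p)
  expect_equal(res$iterations, 10)
  expect_false(res$converged)
})

test_that("single-frame segmentation recovers the phantom border", {
  ph <- noiseless_phantom()
  res <- segment_frame(ph$sequence$frames[[1]],
                       init_phi(c(64.5, 64.5), c(128, 128)),
                       level_set_params())
  expect_true(res$converged)
  expect_lte(hausdorff_distance(res$contour, ph$truth$contours[[1]]), 2)
  # heavier speckle, relaxed tolerance
  ph2 <- generate_phantom(phantom_params(speckle_sigma = 0.15, blur_sigma = 1,
                                         n_cycles = 1))
  res2 <- segment_frame(ph2$sequence$frames[[1]],
                        init_phi(c(64.5, 64.5), c(128, 128)),
                        level_set_params())
  expect_lte(hausdorff_distance(res2$contour, ph2$truth$contours[[1]]), 4)
})

test_that("segmentation is deterministic", {
  ph <- speckle_phantom()
  p <- level_set_params()
  a <- segment_frame(ph$sequence$frames[[1]], init_phi(c(64.5, 64.5), c(128, 128)), p)
  b <- segment_frame(ph$sequence$frames[[1]], init_phi(c(64.5, 64.5), c(128, 128)), p)
  expect_identical(a$phi, b$phi)
  expect_identical(a$contour, b$contour)
})

test_that("sequence segmentation propagates across frames", {
  run <- noiseless_run()
  ph <- noiseless_phantom()
  hd <- vapply(seq_along(run$contours), function(i) {
    hausdorff_distance(run$contours[[i]], ph$truth$contours[[i]])
  }, numeric(1))
  expect_true(all(hd <= 2))
  # front confinement: no vertex more than 3 px outside the true ellipse
  for (i in seq(1, 60, by = 7)) {
    gt <- ph$truth$contours[[i]]
    cc <- run$contours[[i]]
    d <- lvecho:::point_segment_dist(cbind(cc$x, cc$y),
                                     lvecho:::contour_segments(gt))
    vol <- ph$truth$frames$volume_ml[i]
    b_px <- sqrt(3 * vol * 1000 / (4 * pi * 44.8))
    outside <- ((cc$x - 64.5) / b_px)^2 + ((cc$y - 64.5) / 44.8)^2 > 1
    expect_true(all(d[outside] <= 3))
  }
  # per-frame areas track ground-truth cavity areas
  areas <- vapply(run$contours, polygon_area, numeric(1))
  gt_areas <- vapply(ph$truth$contours, polygon_area, numeric(1))
  expect_gte(cor(areas, gt_areas), 0.99)
})

test_that("a frozen sequence yields mutually consistent contours", {
  ph <- noiseless_phantom()
  frames <- rep(ph$sequence$frames[1], 20)
  seqc <- new_sequence(frames, 25, 1)
  cons <- segment_sequence(seqc, c(64.5, 64.5), level_set_params())
  for (i in 2:20) {
    expect_lt(hausdorff_distance(cons[[i]], cons[[1]]), 1)
  }
})

test_that("a reversed sequence yields the reversed contours", {
  ph <- noiseless_phantom()
  fwd <- noiseless_run()$contours
  rseq <- new_sequence(rev(ph$sequence$frames), 25, 1)
  bwd <- segment_sequence(rseq, c(64.5, 64.5), level_set_params())
  n <- length(fwd)
  hd <- vapply(seq_len(n), function(i) {
    hausdorff_distance(bwd[[n + 1 - i]], fwd[[i]])
  }, numeric(1))
  expect_true(all(hd <= 2))
})
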