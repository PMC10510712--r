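test_that("background subtraction flattens uniform images", {
  img <- matrix(50, 64, 64)
  out <- subtract_background(img)
  expect_true(all(out >= 0))
  expect_lt(max(out), 1e-6)
})

test_that("background subtraction keeps spots and removes gradients", {
  ## broad linear gradient plus one narrow spot
  nr <- 64
  grad <- outer(seq(0, 40, length.out = nr), rep(1, nr))
  spot <- oracle_spot_image(nr, nr, 31.3, 40.7, sigma_px = 1.1, photons = 2000)
  img <- grad + spot
  out <- subtract_background(img, 5)
  peak_before <- max(spot)
  peak_after <- max(out[38:44, 29:34])
  expect_gt(peak_after, 0.5 * peak_before)
  ## away from the spot and the borders, the gradient is gone
  far <- out[8:20, 8:20]
  expect_lt(max(far), 0.05 * max(grad))
  expect_error(subtract_background(matrix(c(1, NA, 3, 4), 2)), "non-finite")
  expect_error(subtract_background(img, 0), "blur_radius_px")
})

test_that("noise-only frames yield no detections at sufficient quality", {
  set.seed(3)
  img <- matrix(abs(rnorm(64 * 64, 10, 3)), 64, 64)
  det <- detect_particles(img, pitch_nm = 120, expected_diameter_nm = 520,
                          min_quality = 30)
  expect_identical(nrow(det), 0L)
})

test_that("well-separated spots are each localized to subpixel accuracy", {
  ## image built by an independent Riemann-integration oracle
  sigma_px <- 130 / 120
  truth <- rbind(c(20.37, 25.81), c(20.37 + 5 * sigma_px * 2, 25.81))
  img <- oracle_spot_image(48, 48, truth[1, 1], truth[1, 2], sigma_px, 3000) +
    oracle_spot_image(48, 48, truth[2, 1], truth[2, 2], sigma_px, 3000)
  det <- detect_particles(img, pitch_nm = 120, expected_diameter_nm = 520,
                          min_quality = 10)
  expect_identical(nrow(det), 2L)
  det <- det[order(det$x_nm), ]
  for (i in 1:2) {
    expect_lt(abs(det$x_nm[i] / 120 - truth[i, 1]), 0.1)
    expect_lt(abs(det$y_nm[i] / 120 - truth[i, 2]), 0.1)
  }
  ## the isolated-spot case meets the tighter 0.05 px bound
  one <- oracle_spot_image(32, 32, 15.43, 16.79, sigma_px, 3000)
  d1 <- detect_particles(one, 120, 520, min_quality = 10)
  expect_identical(nrow(d1), 1L)
  expect_lt(abs(d1$x_nm / 120 - 15.43), 0.05)
  expect_lt(abs(d1$y_nm / 120 - 16.79), 0.05)
})

test_that("detection is equivariant under integer translations", {
  sigma_px <- 1.1
  base <- oracle_spot_image(40, 40, 14.37, 17.62, sigma_px, 3000)
  shifted <- matrix(0, 40, 40)
  shifted[1:34 + 6, 1:37 + 3] <- base[1:34, 1:37]  # shift +6 rows, +3 cols
  d0 <- detect_particles(base, 100, 450, min_quality = 10)
  d1 <- detect_particles(shifted, 100, 450, min_quality = 10)
  expect_identical(nrow(d0), 1L)
  expect_identical(nrow(d1), 1L)
  expect_equal(d1$x_nm - d0$x_nm, 3 * 100, tolerance = 1e-6)
  expect_equal(d1$y_nm - d0$y_nm, 6 * 100, tolerance = 1e-6)
})

test_that("raising min_quality never adds detections", {
  sc <- .static_scene()
  img <- sc$noisy$data[1, 1, 2, , ]
  qs <- c(0, 5, 20, 80, 320)
  counts <- vapply(qs, function(q)
    nrow(detect_particles(img, sc$cfg$pitch_nm, 520, min_quality = q)),
    integer(1))
  expect_true(all(diff(counts) <= 0))
  ## and the surviving sets are nested
  d_lo <- detect_particles(img, sc$cfg$pitch_nm, 520, min_quality = 5)
  d_hi <- detect_particles(img, sc$cfg$pitch_nm, 520, min_quality = 80)
  expect_true(all(round(d_hi$x_nm) %in% round(d_lo$x_nm)))
})

test_that("unresolvable expected diameters are rejected", {
  expect_error(detect_particles(matrix(0, 8, 8), 120, 120), "unresolvable")
})

test_that("detections on the simulator fixture match truth positions", {
  sc <- .static_scene()
  det <- detect_movie(sc$clean, expected_diameter_nm = 520, min_quality = 5)
  truth <- sc$log$frames
  for (i in seq_len(nrow(det))) {
    tf <- truth[truth$frame == det$frame[i], ]
    d <- sqrt((tf$x_nm - det$x_nm[i])^2 + (tf$y_nm - det$y_nm[i])^2)
    expect_lt(min(d), 40)   # well under half a pixel
  }
  ## background subtraction at the default radius does not displace them
  det_bg <- detect_movie(sc$clean, expected_diameter_nm = 520,
                         min_quality = 5, background_radius_px = 5)
  expect_identical(nrow(det_bg), nrow(det))
  expect_equal(det_bg$x_nm, det$x_nm, tolerance = 5)
  expect_equal(det_bg$y_nm, det$y_nm, tolerance = 5)
})
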