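test_that("the separation threshold is pitch times pixels", {
  expect_identical(compute_separation_threshold(120, 2), 240)
  expect_identical(compute_separation_threshold(45, 2), 90)
  expect_identical(compute_separation_threshold(120, 1.5), 180)
  expect_error(compute_separation_threshold(0, 2), "pixel_pitch_nm")
  expect_error(compute_separation_threshold(120, -1), "k_pixels")
})

test_that("a circular membrane is traced to subpixel accuracy with radial normals", {
  sc <- .static_scene()
  mem <- sc$clean$data[1, 1, 1, , ]
  ctr <- extract_membrane_contour(mem, sc$cfg$pitch_nm)
  ## the cell is a circle of radius 4 um about (6, 6) um
  r <- sqrt((ctr$points$x_nm - 6000)^2 + (ctr$points$y_nm - 6000)^2)
  expect_lt(max(abs(r - 4000)), 0.5 * sc$cfg$pitch_nm)
  rad <- cbind(ctr$points$x_nm - 6000, ctr$points$y_nm - 6000)
  rad <- rad / sqrt(rowSums(rad^2))
  cosang <- ctr$points$nx * rad[, 1] + ctr$points$ny * rad[, 2]
  expect_lt(max(acos(pmin(1, cosang))) * 180 / pi, 5)
  ## interior mask is the filled cell
  expect_true(ctr$interior[50, 50])       # centre (6 um / 0.12 = px 50)
  expect_false(ctr$interior[5, 5])
})

test_that("a blank membrane frame raises a no-cell error", {
  expect_error(extract_membrane_contour(matrix(0, 64, 64), 120), "no cell")
  expect_error(extract_membrane_contour(matrix(rnorm(64^2, 10, 1), 64), 120),
               "no cell|cell boundary")
})

test_that("line profiles recover signed separations at sampling resolution", {
  sc <- .static_scene()
  mem <- sc$clean$data[1, 1, 1, , ]
  par <- sc$clean$data[1, 1, 2, , ]
  ctr <- extract_membrane_contour(mem, sc$cfg$pitch_nm)
  truth <- sc$log$frames[sc$log$frames$frame == 0, ]
  step <- sc$cfg$pitch_nm / 3
  ## particle rendered exactly on the ridge: d = 0 within one step
  on_ridge <- truth[sc$depths == 0, ]
  pr <- sample_normal_profile(mem, par, ctr, c(on_ridge$x_nm, on_ridge$y_nm))
  expect_identical(pr$status, "ok")
  expect_lt(abs(pr$d_nm), step)
  ## particle 300 nm inside: d = +300 within one step
  inside <- truth[sc$depths == 300, ]
  pr3 <- sample_normal_profile(mem, par, ctr, c(inside$x_nm, inside$y_nm))
  expect_lt(abs(pr3$d_nm - 300), step)
  ## far particle: not membrane-proximal
  prf <- sample_normal_profile(mem, par, ctr, c(6000, 6000),
                               half_length_nm = 1000)
  expect_identical(prf$status, "not_membrane_proximal")
})

test_that("an interior vesicle never captures the membrane peak", {
  cfg <- scene_cfg()
  log <- static_depth_log(cfg, 1500, theta = 0)  # particle 1.5 um inside
  st <- render_movie(log, cfg, noise = FALSE)
  mem <- st$data[1, 1, 1, , ]
  par <- st$data[1, 1, 2, , ]
  ## add a brighter vesicle ring around the particle, stained like membrane
  ves_cfg <- scene_cfg(cell_center_um = c(6 + (4 - 1.5), 6),
                       cell_radii_um = c(0.5, 0.5),
                       membrane_peak_photons = 450)
  ves <- render_movie(static_depth_log(ves_cfg, integer(0)), ves_cfg,
                      noise = FALSE)
  mem_v <- mem + ves$data[1, 1, 1, , ]
  ctr <- extract_membrane_contour(mem, cfg$pitch_nm)
  p <- log$frames[1, ]
  pr_plain <- sample_normal_profile(mem, par, ctr, c(p$x_nm, p$y_nm))
  pr_ves <- sample_normal_profile(mem_v, par, ctr, c(p$x_nm, p$y_nm))
  expect_identical(pr_ves$status, "ok")
  ## membrane peak = outermost peak: unchanged by the vesicle
  expect_lt(abs(pr_ves$membrane_peak_nm - pr_plain$membrane_peak_nm),
            cfg$pitch_nm / 3)
  expect_lt(abs(pr_ves$d_nm - 1500), 100)
  ## the profile does see the vesicle as additional interior peaks
  expect_gt(length(nanodwell:::find_peaks(pr_ves$membrane,
                                          0.2 * diff(range(pr_ves$membrane)))),
            length(nanodwell:::find_peaks(pr_plain$membrane,
                                          0.2 * diff(range(pr_plain$membrane)))))
})

test_that("separations are invariant under integer-pixel scene translation", {
  sc <- .static_scene()
  mem <- sc$clean$data[1, 1, 1, , ]
  par <- sc$clean$data[1, 1, 2, , ]
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  mem2 <- shift(mem, 4, 7); par2 <- shift(par, 4, 7)
  ctr1 <- extract_membrane_contour(mem, sc$cfg$pitch_nm)
  ctr2 <- extract_membrane_contour(mem2, sc$cfg$pitch_nm)
  truth <- sc$log$frames[sc$log$frames$frame == 0, ]
  step <- sc$cfg$pitch_nm / 3
  for (depth in c(0, 300)) {
    p <- truth[sc$depths == depth, ]
    d1 <- sample_normal_profile(mem, par, ctr1, c(p$x_nm, p$y_nm))$d_nm
    d2 <- sample_normal_profile(mem2, par2, ctr2,
                                c(p$x_nm + 7 * 120, p$y_nm + 4 * 120))$d_nm
    expect_lt(abs(d1 - d2), step)
  }
})

test_that("the overlap mask keeps only membrane common to before and after", {
  sc <- .static_scene()
  mem <- sc$clean$data[1, 1, 1, , ]
  bin <- nanodwell:::binarize_membrane(mem)
  expect_identical(overlap_mask(mem, mem), bin)
  ## disjoint membranes: empty mask
  far <- matrix(0, nrow(mem), ncol(mem))
  far[2:6, 2:6] <- 400
  expect_false(any(overlap_mask(mem, far)))
  ## 1 px shift at 1 px tolerance keeps >= 90% of the membrane
  mem_sh <- rbind(0, mem[-nrow(mem), ])
  kept <- overlap_mask(mem, mem_sh, tolerance_px = 1)
  expect_gt(sum(kept & bin) / sum(bin), 0.9)
  expect_error(overlap_mask(mem, matrix(0, 3, 3)), "same shape")
})
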