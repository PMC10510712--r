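test_that("kinetics simulation is deterministic and respects zero hazards", {
  cfg <- simulation_config(mode = "confocal2d", n_frames = 20, seed = 7,
                           arrival_rate_per_um_s = 0.05)
  log1 <- simulate_kinetics(cfg)
  log2 <- simulate_kinetics(cfg)
  expect_identical(log1, log2)

  cfg0 <- simulation_config(mode = "confocal2d", n_frames = 20, seed = 7,
                            k_int = 0, arrival_rate_per_um_s = 0.05)
  log0 <- simulate_kinetics(cfg0)
  expect_false(any(log0$episodes$outcome == "internalize"))
  expect_false(any(log0$frames$state == "internalized"))
})

test_that("dwell times are exponential with the configured mean", {
  ## ~1e4 episodes; closed-form mean of Exp(1/3 s^-1) is 3 s
  cfg <- simulation_config(mode = "confocal2d", n_frames = 2, dt_s = 10,
                           k_off = 1/3, k_int = 0,
                           arrival_rate_per_um_s = 10, seed = 21)
  log <- simulate_kinetics(cfg)
  n <- nrow(log$episodes)
  expect_gt(n, 5000)
  expect_lt(abs(mean(log$episodes$dwell_s) - 3), 3 * 3 / sqrt(n))
})

test_that("outcome fractions match the competing-risks ratio", {
  cfg <- simulation_config(mode = "confocal2d", n_frames = 2, dt_s = 10,
                           k_off = 0.3, k_int = 0.1,
                           arrival_rate_per_um_s = 10, seed = 22)
  log <- simulate_kinetics(cfg)
  ep <- log$episodes
  n <- nrow(ep)
  expect_gt(n, 5000)
  p <- 0.1 / 0.4
  completed <- ep[ep$outcome != "censored", ]
  frac <- mean(completed$outcome == "internalize")
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / nrow(completed)))
})

test_that("state sequences contain no forbidden transitions", {
  cfg <- simulation_config(mode = "confocal2d", n_frames = 60, seed = 23,
                           arrival_rate_per_um_s = 0.05, exit_hazard_per_s = 0.05)
  log <- simulate_kinetics(cfg)
  rank <- c(adsorbed = 1, free = 2, internalized = 2, exited = 3)
  for (tr in split(log$frames, log$frames$particle_id)) {
    st <- tr$state[order(tr$frame)]
    expect_identical(st[1], "adsorbed")
    ## once a particle leaves the adsorbed state it never returns, and
    ## exited is absorbing
    expect_true(all(diff(rank[st]) >= 0))
    ## desorbed particles never internalize and vice versa
    expect_false(all(c("free", "internalized") %in% st))
  }
  ## frame-quantized episode durations track the continuous dwell
  ep <- log$episodes[log$episodes$observable & log$episodes$outcome != "censored", ]
  quant <- (ep$last_frame - ep$first_frame) * cfg$dt_s
  expect_true(all(abs(quant - ep$dwell_s) < 2 * cfg$dt_s))
})

test_that("extending the movie completes censored episodes without touching others", {
  mk <- function(n) simulation_config(mode = "confocal2d", n_frames = n,
                                      seed = 13, arrival_rate_per_um_s = 0.05)
  e1 <- simulate_kinetics(mk(30))$episodes
  e2 <- simulate_kinetics(mk(150))$episodes
  pre <- e2[seq_len(nrow(e1)), ]
  expect_equal(e1$t_adsorb_s, pre$t_adsorb_s)
  expect_equal(e1$dwell_s, pre$dwell_s)
  cen <- e1$outcome == "censored"
  expect_gt(sum(cen), 0)
  expect_true(all(pre$outcome[cen] != "censored"))
  comp <- !cen & e1$observable
  expect_identical(e1$first_frame[comp], pre$first_frame[comp])
  expect_identical(e1$last_frame[comp], pre$last_frame[comp])
  expect_identical(e1$outcome[comp], pre$outcome[comp])
})

test_that("rendering is linear in the photon budget and dark without light", {
  sc <- .static_scene()
  cfg0 <- sc$cfg; cfg0$photon_scale <- 0; cfg0$read_noise_sd <- 0
  dark <- render_movie(sc$log, cfg0)
  expect_true(all(dark$data == 0))

  cfg2 <- sc$cfg; cfg2$photon_scale <- 2
  clean2 <- render_movie(sc$log, cfg2, noise = FALSE)
  expect_equal(clean2$data, 2 * sc$clean$data, tolerance = 1e-12)
})

test_that("a static particle renders at its own pixel with an accurate centroid", {
  sc <- .static_scene()
  truth <- sc$log$frames[sc$log$frames$frame == 0, ]
  deep <- truth[which.max(sc$depths), ]  # far from the membrane ridge
  for (t in 0:(sc$cfg$n_frames - 1)) {
    img <- sc$clean$data[t + 1, 1, 2, , ]
    ## blank out everything except the neighbourhood of the deep particle
    r0 <- round(deep$y_nm / sc$cfg$pitch_nm) + 1
    c0 <- round(deep$x_nm / sc$cfg$pitch_nm) + 1
    win <- img[r0 + (-6:6), c0 + (-6:6)]
    peak <- which(win == max(win), arr.ind = TRUE)
    expect_equal(unname(peak[1, ]), c(7, 7))
    ## intensity-weighted centroid within 0.05 px of the true position
    wy <- rowSums(win); wx <- colSums(win)
    cy <- sum((-6:6) * wy) / sum(wy); cx <- sum((-6:6) * wx) / sum(wx)
    expect_lt(abs((r0 - 1 + cy) * sc$cfg$pitch_nm - deep$y_nm),
              0.05 * sc$cfg$pitch_nm)
    expect_lt(abs((c0 - 1 + cx) * sc$cfg$pitch_nm - deep$x_nm),
              0.05 * sc$cfg$pitch_nm)
  }
})

test_that("undersampled rendering warns", {
  cfg <- scene_cfg(psf_sigma_particle_nm = 20)
  log <- static_depth_log(cfg, 0)
  expect_warning(render_movie(log, cfg, noise = FALSE), "undersampled")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(k_off = -1), "k_off")
  expect_error(simulation_config(dt_s = 0), "dt_s")
  expect_error(simulation_config(pitch_nm = -5), "pitch_nm")
  expect_error(simulation_config(n_z = 2), "n_z")
})
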