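test_that("one moving detection per frame yields a single gapless track", {
  d <- data.frame(frame = 0:9, x_nm = (0:9) * 300, y_nm = rep(0, 10))
  tr <- link_tracks(d, tracker_config(100), dt_s = 1.25)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(tr$frame, 0:9)
  expect_equal(tr$t_s, (0:9) * 1.25)
})

test_that("steps beyond the linking cap split the trajectory", {
  d <- data.frame(frame = 0:3, x_nm = c(0, 300, 2500, 2800), y_nm = 0)
  tr <- link_tracks(d, tracker_config(100))  # cap 1400 nm
  expect_identical(length(unique(tr$track_id)), 2L)
  expect_identical(tr$track_id[tr$frame <= 1], rep(tr$track_id[1], 2))
})

test_that("crossing particles get the minimum-cost assignment", {
  set.seed(8)
  for (rep in 1:25) {
    a <- matrix(runif(4, 0, 1000), 2)
    b <- matrix(runif(4, 0, 1000), 2)
    m <- nanodwell:::match_points(a, b, cap = 5000)
    ## brute force over the two possible pairings
    c_id <- sum((a - b)^2)
    c_sw <- sum((a - b[2:1, ])^2)
    best <- if (c_id <= c_sw) c(1L, 2L) else c(2L, 1L)
    expect_identical(m, best)
  }
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(9)
  d <- do.call(rbind, lapply(0:5, function(f)
    data.frame(frame = f, x_nm = runif(6, 0, 20000) , y_nm = runif(6, 0, 20000))))
  cfg <- tracker_config(max_link_nm = 3000)
  tr1 <- link_tracks(d, cfg)
  d2 <- do.call(rbind, lapply(split(d, d$frame), function(x) x[sample(nrow(x)), ]))
  tr2 <- link_tracks(d2, cfg)
  key <- function(tr) {
    sets <- split(paste(tr$frame, round(tr$x_nm, 6), round(tr$y_nm, 6)),
                  tr$track_id)
    sort(vapply(sets, paste, character(1), collapse = "|"))
  }
  expect_identical(unname(key(tr1)), unname(key(tr2)))
})

test_that("sparse ground-truth trajectories are recovered exactly", {
  cfg <- simulation_config(mode = "confocal2d", n_frames = 40, seed = 31,
                           arrival_rate_per_um_s = 0.01)
  log <- simulate_kinetics(cfg)
  vis <- log$frames[log$frames$state %in% c("adsorbed", "internalized"), ]
  expect_gt(nrow(vis), 20)
  det <- data.frame(frame = vis$frame, x_nm = vis$x_nm, y_nm = vis$y_nm,
                    particle_id = vis$particle_id)
  tr <- link_tracks(det, tracker_config(40))
  ## every recovered track contains exactly one true particle and spans
  ## all of its visible frames
  per_track <- split(tr$particle_id, tr$track_id)
  expect_true(all(vapply(per_track, function(p) length(unique(p)), 1L) == 1L))
  expect_identical(length(per_track), length(unique(vis$particle_id)))
})

test_that("z-plane detections of one object merge into one", {
  det <- data.frame(frame = 0L, z = c(0L, 1L, 2L, 1L),
                    x_nm = c(1000, 1010, 990, 8000),
                    y_nm = c(2000, 2005, 1995, 9000),
                    intensity = c(50, 100, 40, 80),
                    quality = c(5, 10, 4, 8))
  m <- merge_z_detections(det, z_merge_nm = 400, z_spacing_nm = 450, n_z = 3)
  expect_identical(nrow(m), 2L)
  obj <- m[which.max(m$intensity), ]
  expect_equal(obj$intensity, 190)
  expect_equal(obj$x_nm, sum(c(1000, 1010, 990) * c(50, 100, 40)) / 190)
  ## weighted plane position: plane 1 (z = 0) dominates
  expect_lt(abs(obj$z_nm), 450 / 4)
})

test_that("empty input passes through", {
  d <- data.frame(frame = integer(0), x_nm = numeric(0), y_nm = numeric(0))
  expect_identical(nrow(link_tracks(d, tracker_config(100))), 0L)
})
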