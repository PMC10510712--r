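st <- function(states, id = 1L)
  data.frame(track_id = id, frame = seq_along(states) - 1L, state = states)

test_that("the three canonical timelines produce the stated events", {
  ## adsorbed for one frame, internalized in the next: a 1.25 s event
  e1 <- extract_events(st(c("free", "adsorbed", "internalized")), dt_s = 1.25)
  expect_identical(e1$type, "internalization")
  expect_equal(e1$duration_s, 1.25)
  ## a single adsorbed frame between free frames is below the two-point
  ## minimum: no desorption event
  e2 <- extract_events(st(c("free", "adsorbed", "free")), dt_s = 1.25)
  expect_identical(e2$type, "sub_minimum")
  expect_false("desorption" %in% e2$type)
  ## still adsorbed when the movie ends: censored, no duration
  e3 <- extract_events(st(c("free", "adsorbed", "adsorbed", "adsorbed")),
                       dt_s = 1.25, end_frame = 3L)
  expect_identical(e3$type, "censored")
  expect_true(is.na(e3$duration_s))
})

test_that("desorption is timed first-to-last adsorbed frame", {
  e <- extract_events(st(c("free", "adsorbed", "adsorbed", "adsorbed", "free")),
                      dt_s = 15, end_frame = 10L)
  expect_identical(e$type, "desorption")
  expect_equal(e$duration_s, 2 * 15)
  ## a track that simply vanishes mid-movie also desorbed
  ev <- extract_events(st(c("adsorbed", "adsorbed")), dt_s = 15, end_frame = 10L)
  expect_identical(ev$type, "desorption")
  expect_equal(ev$duration_s, 15)
})

test_that("internalization may follow a single adsorbed frame but needs one", {
  e <- extract_events(st(c("adsorbed", "internalized", "internalized")),
                      dt_s = 1.25, end_frame = 5L)
  expect_identical(e$type, "internalization")
  expect_equal(e$duration_s, 1.25)
  ## internalized-only track: no adsorption, no event
  e0 <- extract_events(st(c("internalized", "internalized")), dt_s = 1.25,
                       end_frame = 5L)
  expect_identical(nrow(e0), 0L)
})

test_that("re-adsorption after desorption opens a new episode; return from internalized does not", {
  e <- extract_events(st(c("adsorbed", "adsorbed", "free", "adsorbed",
                           "adsorbed", "free")), dt_s = 1, end_frame = 9L)
  expect_identical(e$type, c("desorption", "desorption"))
  expect_equal(e$t_start_s, c(0, 3))
  ## an adsorbed run right after internalized frames is not a new episode
  e2 <- extract_events(st(c("adsorbed", "internalized", "adsorbed",
                            "adsorbed", "free")), dt_s = 1, end_frame = 9L)
  expect_identical(e2$type, "internalization")
  expect_identical(nrow(e2), 1L)
})

test_that("a one-frame flicker splits an episode unless bridging is on", {
  states <- st(c("adsorbed", "adsorbed", "free", "adsorbed", "adsorbed",
                 "adsorbed", "free"))
  split_ev <- extract_events(states, dt_s = 1, end_frame = 9L)
  expect_identical(split_ev$type, c("desorption", "desorption"))
  expect_equal(split_ev$duration_s, c(1, 2))
  bridged <- extract_events(states, dt_s = 1, end_frame = 9L,
                            bridge_flickers = TRUE)
  expect_identical(bridged$type, "desorption")
  expect_equal(bridged$duration_s, 5)
})

test_that("every adsorbed frame belongs to exactly one episode", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    states <- sample(c("free", "adsorbed", "internalized", "undefined"),
                     n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
    df <- st(states)
    ev <- extract_events(df, dt_s = 1, end_frame = n - 1L)
    ## count adsorbed frames covered by episodes (internalization episodes
    ## cover first..terminal-1; others first..terminal)
    covered <- sum(vapply(seq_len(nrow(ev)), function(i) {
      last <- if (ev$type[i] == "internalization")
        ev$terminal_frame[i] - 1L else ev$terminal_frame[i]
      sum(df$state[df$frame %in% ev$first_frame[i]:last] == "adsorbed")
    }, numeric(1)))
    ## adsorbed frames not in any episode are exactly those continuing an
    ## internalized residence
    runs <- rle(states == "adsorbed")
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    ignored <- sum(runs$lengths[runs$values][
      vapply(which(runs$values), function(k)
        starts[k] > 1 && states[starts[k] - 1] == "internalized", logical(1))])
    expect_equal(covered + ignored, sum(states == "adsorbed"))
  }
})

test_that("unsorted frames are rejected", {
  bad <- data.frame(track_id = 1L, frame = c(2L, 1L, 3L),
                    state = rep("adsorbed", 3))
  expect_error(extract_events(bad, dt_s = 1), "strictly increasing")
})
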