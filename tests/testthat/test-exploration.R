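test_that("interindividual distance: dyads, triads, degenerate cases", {
  tr <- trial("t", list(trajectory_series("a", 0, 0),
                        trajectory_series("b", 3, 4)))
  expect_equal(interindividual_distance(tr)$x, 5)
  tri <- trial("t3", list(trajectory_series("a", 0, 0),
                          trajectory_series("b", 6, 0),
                          trajectory_series("c", 3, 0)))
  expect_equal(interindividual_distance(tri)$x, mean(c(6, 3, 3)))
  co <- trial("t0", list(trajectory_series("a", 1, 1),
                         trajectory_series("b", 1, 1)))
  expect_equal(interindividual_distance(co)$x, 0)
  single <- trial("t1", list(trajectory_series("a", 0:2 / 10, 0:2 / 10)))
  expect_error(interindividual_distance(single),
               class = "fishsde_not_applicable")
})

test_that("episode detection on the constructed three-phase fixture", {
  x <- distance_series(c(rep(2, 150), rep(12, 120), rep(2, 150)), 1 / 30, "t")
  ep <- detect_episodes(x)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_frame, 150)
  expect_equal(ep$end_frame, 270)
  expect_equal(ep$duration_s, 4)
  expect_equal(ep$amplitude_cm, 12)
})

test_that("duration and proximity preconditions are strict", {
  dt <- 1 / 30
  # exactly 90 frames = 3.0 s is rejected (strictly greater than required)
  x90 <- distance_series(c(rep(2, 30), rep(12, 90), rep(2, 30)), dt, "t")
  expect_equal(nrow(detect_episodes(x90)), 0)
  x91 <- distance_series(c(rep(2, 30), rep(12, 91), rep(2, 30)), dt, "t")
  expect_equal(nrow(detect_episodes(x91)), 1)
  # never below threshold -> no prior close proximity -> no episodes
  xhigh <- distance_series(rep(12, 600), dt, "t")
  expect_equal(nrow(detect_episodes(xhigh)), 0)
  # value exactly at threshold does not count as above (strict >)
  xeq <- distance_series(c(rep(2, 10), rep(9, 200)), dt, "t")
  expect_equal(nrow(detect_episodes(xeq)), 0)
})

test_that("amplitude modes: mean default, median option", {
  x <- distance_series(c(rep(2, 100), c(rep(10, 60), rep(11, 30), rep(18, 30)),
                         rep(2, 50)), 1 / 30, "t")
  ep <- detect_episodes(x)
  expect_equal(ep$amplitude_cm, mean(c(rep(10, 60), rep(11, 30), rep(18, 30))))
  expect_equal(episode_amplitude(x, ep[1, ], mode = "median"), 10.5)
  ep_med <- detect_episodes(x, amplitude_mode = "median")
  expect_equal(ep_med$amplitude_cm, 10.5)
})

test_that("detection agrees with a brute-force scan on random fixtures", {
  set.seed(33)
  dt <- 1 / 30
  for (rep in 1:30) {
    # piecewise-constant series flipping around the threshold
    lens <- rpois(12, 60) + 1
    vals <- sample(c(2, 12), 12, replace = TRUE)
    x <- rep(vals, lens)
    got <- detect_episodes(distance_series(x, dt, "r"), 9, 3)
    want <- episode_scan_oracle(x, dt, 9, 3)
    expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
    if (!is.null(want)) {
      expect_equal(got$start_frame, unname(want[, "start"]))
      expect_equal(got$end_frame - got$start_frame, unname(want[, "len"]))
    }
  }
})

test_that("scaling distances and threshold together preserves episodes", {
  set.seed(5)
  x <- abs(10 + cumsum(rnorm(2000, 0, 0.5)))
  ds <- distance_series(x, 1 / 30, "s")
  base <- detect_episodes(ds, threshold = 9)
  for (c_ in c(0.5, 2, 7)) {
    scaled <- detect_episodes(distance_series(c_ * x, 1 / 30, "s"),
                              threshold = 9 * c_)
    expect_equal(nrow(scaled), nrow(base))
    expect_equal(scaled$start_frame, base$start_frame)
    expect_equal(scaled$duration_s, base$duration_s)
    expect_equal(scaled$amplitude_cm, c_ * base$amplitude_cm,
                 tolerance = 1e-12)
  }
})

test_that("episodes are disjoint, ordered and complement reconstructs the series", {
  set.seed(8)
  x <- abs(8 + cumsum(rnorm(5000, 0, 0.6)))
  ds <- distance_series(x, 1 / 30, "s")
  ep <- detect_episodes(ds)
  if (nrow(ep) > 1) {
    expect_true(all(diff(ep$start_frame) > 0))
    expect_true(all(ep$start_frame[-1] >= ep$end_frame[-nrow(ep)]))
  }
  covered <- unlist(Map(seq, ep$start_frame + 1, ep$end_frame))
  expect_true(all(x[covered] > 9))
})

test_that("per-trial episode statistics summarise and flag zero-episode trials", {
  dt <- 1 / 30
  d1 <- distance_series(c(rep(2, 60), rep(12, 120), rep(2, 60),
                          rep(12, 180), rep(2, 60)), dt, "a",
                        illumination = "bright", group_size = 2L)
  d2 <- distance_series(rep(2, 480), dt, "b",
                        illumination = "dark", group_size = 2L)
  st <- trial_episode_stats(list(d1, d2))
  expect_equal(nrow(st), 2)
  expect_equal(st$n_episodes, c(2, 0))
  expect_equal(st$mean_T[1], mean(c(4, 6)))
  expect_true(is.na(st$mean_T[2]))
  expect_equal(st$has_episodes, c(TRUE, FALSE))
})
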