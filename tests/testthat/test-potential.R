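p_ref <- potential_params(0, -0.01, 5, 20)

test_that("potential evaluation matches hand computations", {
  expect_equal(potential_value(p_ref, 5), 0)
  expect_equal(potential_value(p_ref, 20), 0)
  expect_equal(potential_value(p_ref, 12.5), 31.640625)
  # beta = 0 degenerates to a pure tilt
  tilt <- potential_params(2, 0, 5, 20)
  expect_equal(potential_value(tilt, c(0, 1, 3)), c(0, -2, -6))
})

test_that("drift coefficients from the potential match the symbolic expansion", {
  cf <- drift_from_potential(p_ref)
  expect_equal(unname(cf), c(50, -16.5, 1.5, -0.04), tolerance = 1e-12)
  # numerical gradient check at several points
  xs <- c(3, 7.7, 12.5, 18, 24)
  h <- 1e-6
  numgrad <- -(potential_value(p_ref, xs + h) -
                 potential_value(p_ref, xs - h)) / (2 * h)
  expect_equal(poly_at(unname(cf), xs), numgrad, tolerance = 1e-6,
               ignore_attr = TRUE)
  # alpha = 0: drift roots exactly {xl, midpoint, xh}
  r <- sort(Re(polyroot(unname(cf))))
  expect_equal(r, c(5, 12.5, 20), tolerance = 1e-9)
})

test_that("potential parameters invert the cubic in closed form", {
  p <- potential_from_drift(c(50, -16.5, 1.5, -0.04))
  expect_equal(unclass(p)[c("alpha", "beta", "xl", "xh")],
               list(alpha = 0, beta = -0.01, xl = 5, xh = 20),
               tolerance = 1e-9)
  expect_error(potential_from_drift(c(1, 2, 3, 0)),
               class = "fishsde_not_cubic")
  # complex well pair -> monostable error
  p_mono <- drift_from_potential(potential_params(0, -0.01, 5, 20))
  bad <- c(60, -1, 0.1, -0.04)  # z^2 - s z + q with negative discriminant
  expect_error(potential_from_drift(bad), class = "fishsde_monostable")
})

test_that("params -> cubic -> params is the identity on random bistable sets", {
  set.seed(12)
  for (i in 1:100) {
    p <- potential_params(runif(1, -0.5, 0.5), -10^runif(1, -4, -1),
                          runif(1, 1, 10), runif(1, 12, 28))
    back <- potential_from_drift(unname(drift_from_potential(p)))
    expect_equal(unclass(back), unclass(p), tolerance = 1e-9)
  }
})

test_that("empirical potential integrates binned drift by trapezoid", {
  # constant drift c -> linear potential with slope -c
  bk <- structure(data.frame(bin_centre = seq(1, 5, by = 0.1),
                             mean_drift = 2, mean_diff2 = 1, count = 50L),
                  class = c("binned_km", "data.frame"), bin_width = 0.1)
  vp <- empirical_potential(bk)
  expect_equal(vp$V, -2 * (vp$x - vp$x[1]), tolerance = 1e-12)
  # sampled cubic drift reproduces the analytic quartic potential
  xs <- seq(2, 23, by = 0.1)
  bk2 <- structure(data.frame(bin_centre = xs,
                              mean_drift = poly_at(c(50, -16.5, 1.5, -0.04), xs),
                              mean_diff2 = 1, count = 50L),
                   class = c("binned_km", "data.frame"), bin_width = 0.1)
  vp2 <- empirical_potential(bk2)
  truth <- potential_value(p_ref, xs) - potential_value(p_ref, xs[1])
  # cumulative trapezoid error is h^2/12 * (F'(x) - F'(a)), at most
  # 0.01/12 * 13.25 = 0.011 on this quartic
  expect_lt(max(abs(vp2$V - truth)), 0.012)
  expect_error(empirical_potential(bk2[1, ]),
               class = "fishsde_insufficient_data")
})

test_that("empirical potential converges at second order in bin width", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    xs <- seq(2, 23, by = h)
    bk <- structure(data.frame(bin_centre = xs,
                               mean_drift = poly_at(c(50, -16.5, 1.5, -0.04), xs),
                               mean_diff2 = 1, count = 50L),
                    class = c("binned_km", "data.frame"), bin_width = h)
    vp <- empirical_potential(bk)
    max(abs(vp$V - (potential_value(p_ref, xs) - potential_value(p_ref, xs[1]))))
  }, numeric(1))
  # halving h divides the error by about 4
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("bistability report classifies wells, barrier, and tilt", {
  m <- sde_model(p_ref, diffusion = c(0.53125, 0.075, -0.003))
  rep_ <- bistability_report(m)
  expect_true(rep_$bistable)
  expect_equal(rep_$wells, c(5, 20), tolerance = 1e-9)
  expect_equal(rep_$barrier_x, 12.5, tolerance = 1e-9)
  expect_equal(rep_$barrier_height, 31.640625, tolerance = 1e-9)
  expect_equal(rep_$tilt_direction, "none")
  # small positive alpha under the literal sign convention lowers the
  # potential at large x: the far well becomes the deeper one
  m2 <- sde_model(potential_params(0.05, -0.01, 5, 20),
                  diffusion = c(0.53125, 0.075, -0.003))
  rep2 <- bistability_report(m2)
  expect_equal(rep2$tilt_direction, "toward_far")
  expect_lt(rep2$barrier_height, 31.640625)
  # a3 > 0 is flagged non-attracting
  rep3 <- bistability_report(c(0, 1, 0, 0.01))
  expect_false(rep3$attracting)
})
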