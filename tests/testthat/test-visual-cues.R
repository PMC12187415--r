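cfg_rear <- visual_field_config()
gamma <- cfg_rear$blind_angle

test_that("subtended shade follows circle-tangent geometry", {
  sh <- subtended_shade(focal_pose(c(0, 0), 0), c(3, 0), 1.5)
  expect_equal(sh$centre, 0)
  expect_equal(sh$halfwidth, asin(0.5), tolerance = 1e-12)  # pi/6
  # rotation equivariance: same width, centre at +pi/2
  sh2 <- subtended_shade(focal_pose(c(0, 0), 0), c(0, 3), 1.5)
  expect_equal(sh2$centre, pi / 2, tolerance = 1e-12)
  expect_equal(sh2$halfwidth, sh$halfwidth)
  # width shrinks to zero with distance
  sh3 <- subtended_shade(focal_pose(c(0, 0), 0), c(1e6, 0), 1.5)
  expect_lt(sh3$halfwidth, 1e-5)
  expect_error(subtended_shade(focal_pose(c(0, 0), 0), c(1, 0), 1.5),
               class = "fishsde_overlap_error")
})

test_that("opacity matches the worked frontal-conspecific geometry", {
  o <- opacity(focal_pose(c(0, 0), 0), list(c(3, 0)), cfg_rear)
  expect_equal(o, (pi / 3) / (2 * pi - gamma), tolerance = 1e-9)
  expect_equal(o, 0.17700, tolerance = 1e-4)
})

test_that("opacity limiting cases: empty field, blind zone, saturation", {
  expect_equal(opacity(focal_pose(c(0, 0), 0), list(), cfg_rear), 0)
  # conspecific dead behind the fish sits in the rear blind zone -> partial
  # shade only outside the blind wedge; a tight rear cone is fully blind
  o_rear <- opacity(focal_pose(c(0, 0), 0), list(c(-30, 0)), cfg_rear)
  expect_equal(o_rear, 0, tolerance = 1e-12)
  # under the front convention the same scene is fully visible
  cfg_front <- visual_field_config(blind_zone_centre = "front")
  expect_gt(opacity(focal_pose(c(0, 0), 0), list(c(-30, 0)), cfg_front), 0)
  # surround of overlapping discs covers the whole field
  ring <- lapply(seq(0, 2 * pi, length.out = 13)[-13],
                 function(a) 1.8 * c(cos(a), sin(a)))
  expect_equal(opacity(focal_pose(c(0, 0), 0), ring, cfg_rear), 1,
               tolerance = 1e-9)
})

test_that("analytic opacity agrees with the ray-cast oracle on random scenes", {
  fixtures <- generate_visual_fixtures(200, seed = 99, n_rays = 3600)
  devs <- vapply(fixtures, function(fx)
    abs(opacity(fx$focal, fx$others, cfg_rear) - fx$expected_opacity),
    numeric(1))
  expect_lt(max(devs), 2 * pi / 3600 + 1e-9)
})

test_that("opacity uses union semantics and is monotone in distance", {
  f <- focal_pose(c(0, 0), 0)
  one <- opacity(f, list(c(4, 1)), cfg_rear)
  twice <- opacity(f, list(c(4, 1), c(4, 1)), cfg_rear)
  expect_equal(twice, one, tolerance = 1e-12)
  ds <- seq(3.2, 25, by = 0.5)
  os <- vapply(ds, function(d) opacity(f, list(c(d, 0)), cfg_rear), numeric(1))
  expect_true(all(diff(os) <= 1e-12))
})

test_that("visual cues are invariant under global rigid motion", {
  set.seed(7)
  for (rep in 1:25) {
    f0 <- focal_pose(runif(2, -5, 5), runif(1, -pi, pi))
    f1 <- focal_pose(f0$position + runif(2, -0.2, 0.2),
                     f0$heading + runif(1, -0.2, 0.2))
    o0 <- matrix(runif(4, 4, 12) * sample(c(-1, 1), 4, TRUE), 2)
    o1 <- o0 + matrix(runif(4, -0.3, 0.3), 2)
    phi <- runif(1, -pi, pi); tr <- runif(2, -8, 8)
    Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    move_pose <- function(p) focal_pose(drop(Rm %*% p$position) + tr,
                                        p$heading + phi)
    move_pts <- function(m) t(Rm %*% t(m)) + rep(tr, each = nrow(m))
    expect_equal(opacity(move_pose(f0), move_pts(o0), cfg_rear),
                 opacity(f0, o0, cfg_rear), tolerance = 1e-9)
    expect_equal(
      optic_flow(move_pose(f0), move_pose(f1), move_pts(o0), move_pts(o1),
                 cfg_rear),
      optic_flow(f0, f1, o0, o1, cfg_rear), tolerance = 1e-9)
  }
})

test_that("optic flow reproduces the hand-worked single-conspecific case", {
  d <- 3  # shade half-width asin(1.5/3) = pi/6, width pi/3, fully visible
  f <- focal_pose(c(0, 0), 0)
  bearing_shift <- 0.05236
  flow <- optic_flow(f, f,
                     matrix(c(d, 0), 1),
                     matrix(d * c(cos(bearing_shift), sin(bearing_shift)), 1),
                     cfg_rear, dt = 1 / 30)
  expect_equal(flow, (bearing_shift * 30) * (pi / 3), tolerance = 1e-3)
})

test_that("optic flow is zero for static scenes and blind-zone objects, and time-symmetric", {
  f <- focal_pose(c(0, 0), 0)
  still <- matrix(c(5, 2), 1)
  expect_equal(optic_flow(f, f, still, still, cfg_rear), 0)
  behind0 <- matrix(c(-20, 0.0), 1)
  behind1 <- matrix(c(-20, 0.3), 1)
  expect_equal(optic_flow(f, f, behind0, behind1, cfg_rear), 0)
  a <- matrix(c(4, 1), 1); b <- matrix(c(4.5, 0.2), 1)
  fwd <- optic_flow(f, f, a, b, cfg_rear)
  expect_gte(fwd, 0)
  # |W| is even: reversing time changes the shade width factor to that of
  # the other frame, so compare against the reversed-frame computation
  rev_ <- optic_flow(f, f, b, a, cfg_rear)
  expect_gte(rev_, 0)
})

test_that("mismatched conspecific ids are an integrity error", {
  f <- focal_pose(c(0, 0), 0)
  d0 <- data.frame(id = c("a", "b"), x = c(4, -4), y = c(0, 1))
  d1 <- data.frame(id = c("a", "c"), x = c(4, -4), y = c(0.2, 1))
  expect_error(optic_flow(f, f, d0, d1, cfg_rear),
               class = "fishsde_integrity_error")
})

test_that("per-trial visual cue series has one row per frame per fish", {
  tr <- make_dyad_trial(n = 6)
  cues <- visual_cue_series(tr)
  expect_equal(nrow(cues), 12)
  expect_true(all(cues$opacity >= 0 & cues$opacity <= 1))
  expect_true(all(is.na(cues$optic_flow) | cues$optic_flow >= 0))
  expect_true(all(is.na(cues$optic_flow[cues$frame == 5])))
})
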