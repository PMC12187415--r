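test_that("pointwise Kramers-Moyal estimates on deterministic series", {
  dt <- 1 / 30
  ramp <- distance_series((0:99) * 0.5 * dt, dt, "r")
  km <- km_point_estimates(ramp)
  expect_equal(km$drift_hat, rep(0.5, 99))
  expect_equal(km$diff2_hat, rep(0.25 * dt, 99), tolerance = 1e-12)
  expect_equal(km$y, ramp$x[-100])
  flat <- km_point_estimates(distance_series(rep(4, 50), dt, "c"))
  expect_true(all(flat$drift_hat == 0) && all(flat$diff2_hat == 0))
})

test_that("OU conditional moments are recovered from simulated paths", {
  # dx = -theta (x - mu) dt + sigma dW: binned drift is linear with slope
  # -theta and intercept theta*mu; E[dx^2]/dt = sigma^2
  paths <- simulate_trials(ou_model(), sim_config(n_steps = 18000,
                                                  n_trials = 10),
                           master_seed = 42)
  km <- pool_km(lapply(paths, km_point_estimates))
  b <- bin_average(km)
  fit <- linear_regression(b$bin_centre, b$mean_drift)
  expect_equal(fit$slope, -1, tolerance = 0.1)
  expect_equal(fit$intercept, 12, tolerance = 1.2)
  expect_equal(mean(km$diff2_hat), 1, tolerance = 0.1)
})

test_that("bin averaging follows the binning convention and drop rule", {
  km <- structure(data.frame(y = c(0.01, 0.09, 0.45, 0.45, 0.45),
                             drift_hat = c(1, 3, 5, 6, 7),
                             diff2_hat = c(1, 1, 2, 2, 2)),
                  class = c("km_estimates", "data.frame"), dt = 1 / 30)
  b <- bin_average(km, bin_width = 0.1, min_count = 2L)
  expect_equal(b$bin_centre, c(0.05, 0.45))
  expect_equal(b$mean_drift, c(2, 6))
  expect_equal(b$count, c(2L, 3L))
  # min_count drops sparse bins
  b10 <- bin_average(km, bin_width = 0.1, min_count = 3L)
  expect_equal(b10$bin_centre, 0.45)
  # pooling identical trials doubles counts, means unchanged
  b2 <- bin_average(list(km, km), bin_width = 0.1, min_count = 2L)
  expect_equal(b2$mean_drift, b$mean_drift)
  expect_equal(b2$count, 2L * b$count)
})

test_that("polynomial library has the right columns and standardisation round-trips", {
  Th <- build_library(2, 3)
  expect_equal(drop(Th), c(1, 2, 4, 8), ignore_attr = TRUE)
  expect_equal(drop(build_library(5, 0)), 1, ignore_attr = TRUE)
  # de-standardisation: lasso at lambda ~ 0 on a noiseless cubic equals OLS
  set.seed(2)
  y <- runif(300, 0, 10)
  Y <- 1 - 2 * y + 0.3 * y^3
  Th5 <- build_library(y, 5)
  cf <- lasso_cd(Th5, Y, 1e-10)
  expect_equal(unname(cf[1:4]), c(1, -2, 0, 0.3), tolerance = 1e-6)
})

test_that("LASSO limiting cases: OLS at lambda 0, null fit above lambda_max", {
  set.seed(3)
  y <- runif(400, 0, 10)
  Y <- 2 + 0.5 * y - 0.03 * y^3 + rnorm(400, 0, 0.05)
  Th <- build_library(y, 5)
  cf0 <- lasso_cd(Th, Y, 0)
  expect_equal(as.numeric(cf0), unname(qr.solve(Th, Y)), tolerance = 1e-8,
               ignore_attr = TRUE)
  lam_max <- fishsde:::lambda_max_of(Th, Y)
  cfm <- lasso_cd(Th, Y, lam_max * 1.001)
  expect_equal(unname(cfm[-1]), rep(0, 5))
  expect_equal(unname(cfm[1]), mean(Y), tolerance = 1e-9)
  # KKT: just below lambda_max at least one coefficient activates
  cfa <- lasso_cd(Th, Y, lam_max * 0.99)
  expect_gt(sum(cfa[-1] != 0), 0)
})

test_that("LASSO coordinate descent agrees with glmnet along the path", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  y <- runif(500, 0, 10)
  Y <- 2 + 0.5 * y - 0.03 * y^3 + rnorm(500, 0, 0.2)
  Th <- build_library(y, 4)
  lam_max <- fishsde:::lambda_max_of(Th, Y)
  for (frac in c(0.2, 0.05, 0.01)) {
    lam <- frac * lam_max
    ours <- lasso_cd(Th, Y, lam)
    g <- glmnet::glmnet(Th[, -1], Y, lambda = lam / nrow(Th),
                        standardize = TRUE, thresh = 1e-14)
    theirs <- as.numeric(stats::coef(g))
    # conventions differ in the standardisation denominator (n vs n-1);
    # agreement is to a small relative tolerance
    expect_equal(as.numeric(ours), theirs, tolerance = 5e-3,
                 ignore_attr = TRUE)
  }
})

test_that("SSR recovers a sparse cubic from noiseless bin-level data", {
  y <- seq(2, 22, by = 0.1)
  Y <- 50 - 16.5 * y + 1.5 * y^2 - 0.04 * y^3
  bk <- structure(data.frame(bin_centre = y, mean_drift = Y,
                             mean_diff2 = 1, count = 100L),
                  class = c("binned_km", "data.frame"),
                  bin_width = 0.1, dt = 1 / 30)
  res <- ssr_fit(bk, "drift", ssr_config(seed = 1))
  expect_equal(res$model$degree, 3)
  expect_equal(res$model$coefficients[1:4], c(50, -16.5, 1.5, -0.04),
               tolerance = 1e-3)
  expect_equal(res$model$coefficients[5:6], c(0, 0))
})

test_that("SSR history never grows and cross-validated error is tracked", {
  set.seed(10)
  y <- runif(3000, 2, 22)
  Y <- 50 - 16.5 * y + 1.5 * y^2 - 0.04 * y^3 + rnorm(3000, 0, 2)
  km <- structure(data.frame(y = y, drift_hat = Y, diff2_hat = 1),
                  class = c("km_estimates", "data.frame"), dt = 1 / 30)
  res <- ssr_fit(km, "drift", ssr_config(seed = 2))
  expect_true(all(diff(res$history$n_terms) < 0))
  expect_lte(res$history$n_terms[1], 6)
  # error history non-increasing up to the paired-comparison resolution
  expect_true(all(res$history$cv_error <=
                    cummin(res$history$cv_error) * 1.2 + 1e-9))
  expect_gte(res$cv_error, 0)
  expect_equal(res$model$degree, 3)
})

test_that("a cross-validated MSE at the truth approximates the noise variance", {
  set.seed(11)
  y <- runif(4000, 2, 22)
  sigma <- 1.5
  Y <- 5 - 0.2 * y + rnorm(4000, 0, sigma)
  km <- structure(data.frame(y = y, drift_hat = Y, diff2_hat = 1),
                  class = c("km_estimates", "data.frame"), dt = 1 / 30)
  res <- ssr_fit(km, "drift", ssr_config(seed = 3))
  expect_equal(res$cv_error, sigma^2, tolerance = 0.1)
})
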