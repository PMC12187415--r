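# Fixtures and independent oracles shared across the suite.

# a small dyad trial built by hand
make_dyad_trial <- function(n = 10, trial_id = "t1") {
  t_ <- seq_len(n) - 1
  trial(trial_id,
        list(trajectory_series("f1", 0.1 * t_, rep(0, n)),
             trajectory_series("f2", 0.1 * t_ + 3, rep(1, n))),
        illumination = "bright", frame_rate = 30)
}

# brute-force episode scan: walk the series frame by frame
episode_scan_oracle <- function(x, dt, threshold, min_duration) {
  out <- NULL
  i <- 1
  n <- length(x)
  seen_below <- FALSE
  while (i <= n) {
    if (x[i] <= threshold) {
      seen_below <- TRUE
      i <- i + 1
    } else {
      j <- i
      while (j <= n && x[j] > threshold) j <- j + 1
      len <- j - i
      if (seen_below && len * dt > min_duration)
        out <- rbind(out, c(start = i - 1, end = j - 1, len = len))
      i <- j
    }
  }
  out
}

# brute-force two-way ANOVA decomposition for balanced designs via direct
# sums of squares over cell/marginal means
anova_ss_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cells <- interaction(A, B)
  cell_means <- tapply(y, cells, mean)
  ss_cells <- sum(table(cells) * (cell_means - gm)^2)
  ssab <- ss_cells - ssa - ssb
  ss_res <- sum((y - cell_means[cells])^2)
  list(A = ssa, B = ssb, AB = ssab, residuals = ss_res,
       total = sum((y - gm)^2))
}

# slope/intercept by explicit normal equations
normal_eq_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

ou_model <- function(theta = 1, mu = 12, sigma = 1)
  sde_model(drift = c(theta * mu, -theta), diffusion = sigma,
            domain = c(0, 57))

# evaluate ascending-degree coefficients
poly_at <- function(coef_asc, x) {
  y <- rep(0, length(x))
  for (j in rev(seq_along(coef_asc))) y <- y * x + coef_asc[j]
  y
}
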