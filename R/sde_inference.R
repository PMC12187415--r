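# Kramers-Moyal estimation and stepwise sparse regression (SSR).
#
# The drift and squared diffusion of dx = F(x) dt + G(x) dW are estimated
# pointwise from first and second conditional moments of the increments,
# bin-averaged across trials for visualisation and potential reconstruction,
# and given a sparse polynomial form by LASSO-initialised stepwise pruning
# with K-fold cross-validation.

#' Pointwise Kramers-Moyal estimates
#'
#' First and second conditional moments of the increments per unit time:
#' `drift_hat(t) = (x(t+dt) - x(t)) / dt` estimates the drift F, and
#' `diff2_hat(t) = (x(t+dt) - x(t))^2 / dt` estimates the squared diffusion
#' G^2 (up to an O(dt) drift contribution). Each estimate is paired with the
#' state `y = x(t)` it conditions on.
#'
#' @param x a [distance_series()] (uniform dt), or a plain numeric series
#'   together with `dt`.
#' @param dt time step, only needed when `x` is a bare numeric vector.
#' @return an object of class `km_estimates`: a data.frame with columns `y`,
#'   `drift_hat`, `diff2_hat` and attribute `dt`.
#' @export
km_point_estimates <- function(x, dt = NULL) {
  if (inherits(x, "distance_series")) {
    dt <- x$dt
    x <- x$x
  }
  if (is.null(dt) || dt <= 0) fs_abort("dt must be > 0", "parameter_error")
  if (length(x) < 2L)
    fs_abort("need at least 2 samples", "insufficient_data")
  inc <- diff(x)
  out <- data.frame(y = x[-length(x)], drift_hat = inc / dt,
                    diff2_hat = inc^2 / dt)
  class(out) <- c("km_estimates", "data.frame")
  attr(out, "dt") <- dt
  out
}

#' Pool Kramers-Moyal estimates across trials
#'
#' @param est_list list of `km_estimates` (equal `dt`).
#' @return a single pooled `km_estimates` object.
#' @export
pool_km <- function(est_list) {
  dts <- vapply(est_list, attr, numeric(1), "dt")
  if (length(unique(signif(dts, 12))) != 1L)
    fs_abort("cannot pool estimates with different dt", "parameter_error")
  out <- do.call(rbind, lapply(est_list, as.data.frame))
  class(out) <- c("km_estimates", "data.frame")
  attr(out, "dt") <- dts[1]
  out
}

#' Bin-average pointwise estimates over the state
#'
#' Averages `drift_hat` and `diff2_hat` over fixed-width state bins (default
#' 0.1 cm, bins `[k*w, (k+1)*w)`), pooling all supplied samples. Bins with
#' fewer than `min_count` samples are dropped: their means are dominated by
#' noise and would destabilise the empirical potential.
#'
#' @param est a `km_estimates` object or a list of them (pooled first).
#' @param bin_width bin width in cm (default 0.1).
#' @param min_count minimum samples for a bin to be retained (default 10).
#' @return an object of class `binned_km`: data.frame with `bin_centre`,
#'   `mean_drift`, `mean_diff2`, `count`, sorted by centre.
#' @export
bin_average <- function(est, bin_width = 0.1, min_count = 10L) {
  if (bin_width <= 0) fs_abort("bin_width must be > 0", "parameter_error")
  if (is.list(est) && !is.data.frame(est)) est <- pool_km(est)
  empty <- data.frame(bin_centre = numeric(0), mean_drift = numeric(0),
                      mean_diff2 = numeric(0), count = integer(0))
  class(empty) <- c("binned_km", "data.frame")
  attr(empty, "bin_width") <- bin_width
  if (nrow(est) == 0L) return(empty)
  idx <- floor(est$y / bin_width)
  agg <- data.frame(
    bin_centre = (sort(unique(idx)) + 0.5) * bin_width,
    mean_drift = tapply(est$drift_hat, idx, mean)[as.character(sort(unique(idx)))],
    mean_diff2 = tapply(est$diff2_hat, idx, mean)[as.character(sort(unique(idx)))],
    count = as.integer(table(idx)[as.character(sort(unique(idx)))])
  )
  rownames(agg) <- NULL
  agg <- agg[agg$count >= min_count, , drop = FALSE]
  class(agg) <- c("binned_km", "data.frame")
  attr(agg, "bin_width") <- bin_width
  attr(agg, "dt") <- attr(est, "dt")
  agg
}

#' Polynomial design library
#'
#' Columns are powers of the state from degree 0 to `max_degree`.
#'
#' @param y numeric state values.
#' @param max_degree highest polynomial degree (>= 0).
#' @return a numeric matrix with `max_degree + 1` columns named `deg0..`.
#' @export
build_library <- function(y, max_degree) {
  if (max_degree < 0) fs_abort("max_degree must be >= 0", "parameter_error")
  Theta <- outer(as.numeric(y), 0:max_degree, `^`)
  colnames(Theta) <- paste0("deg", 0:max_degree)
  Theta
}

# ---- LASSO by cyclic coordinate descent -------------------------------------
# objective (standardised predictors, centred response):
#   (1/2) ||Yc - Xs b||^2 + lambda ||b||_1
# so lambda_max = max |Xs' Yc| zeroes every penalised coefficient.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# identify the intercept-like (constant) columns of a library matrix
const_cols <- function(X) {
  apply(X, 2, function(col) diff(range(col)) < 1e-12)
}

# standardise the penalised columns; returns the pieces needed to fit and to
# map standardised coefficients back to the raw scale. Observation weights
# (e.g. bin counts, making a bin-level fit equivalent to the pooled
# per-sample regression) enter through weighted moments and inner products.
lasso_prep <- function(X, Y, weights = NULL) {
  w <- weights %||% rep(1, length(Y))
  w <- w / mean(w)
  cc <- const_cols(X)
  pred <- which(!cc)
  wmean <- function(v) sum(w * v) / sum(w)
  centres <- apply(X[, pred, drop = FALSE], 2, wmean)
  sds <- sqrt(apply(X[, pred, drop = FALSE], 2,
                    function(v) sum(w * (v - wmean(v))^2) / (sum(w) - 1)))
  usable <- sds > 1e-14
  pred <- pred[usable]; centres <- centres[usable]; sds <- sds[usable]
  Xs <- sweep(sweep(X[, pred, drop = FALSE], 2, centres), 2, sds, "/")
  ybar <- wmean(Y)
  list(pred = pred, const = which(cc), centres = centres, sds = sds,
       Xs = Xs, w = w, ybar = ybar, Yc = Y - ybar,
       const_val = if (any(cc)) X[1, which(cc)[1]] else NA_real_)
}

# exact LASSO for small p by orthant enumeration: the global minimiser is
# stationary on its own orthant, so solving the stationarity system for every
# sign pattern and keeping the best sign-consistent candidate is exact -- no
# iterative tolerance involved. Used as a guaranteed-termination fallback
# when coordinate descent stalls on a severely collinear library.
lasso_enumerate <- function(XtX, Xty, lambda) {
  p <- length(Xty)
  if (p > 12L) return(NULL)
  best <- NULL
  best_obj <- Inf
  objective <- function(b)
    0.5 * drop(crossprod(b, XtX %*% b)) - sum(Xty * b) + lambda * sum(abs(b))
  for (mask in 0:(2^p - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    n_act <- length(act)
    if (n_act == 0L) {
      if (0 < best_obj) { best_obj <- 0; best <- numeric(p) }
      next
    }
    sign_grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_act)))
    for (r in seq_len(nrow(sign_grid))) {
      s <- sign_grid[r, ]
      sol <- tryCatch(
        solve(XtX[act, act, drop = FALSE], Xty[act] - lambda * s),
        error = function(e) NULL)
      if (is.null(sol) || any(sign(sol) * s < 0)) next
      b <- numeric(p)
      b[act] <- sol
      o <- objective(b)
      if (o < best_obj) { best_obj <- o; best <- b }
    }
  }
  best
}

cd_solve <- function(XtX, Xty, lambda, b = NULL, tol = 1e-9, max_iter = 1e5) {
  p <- length(Xty)
  if (p == 0L) return(list(b = numeric(0), iter = 0L, converged = TRUE))
  if (is.null(b)) b <- numeric(p)
  scale <- max(abs(Xty), lambda, 1)
  # Cyclic coordinate descent identifies the active set; because polynomial
  # libraries are severely collinear, sweeps alone converge too slowly, so
  # every few sweeps the KKT conditions are checked for an exact solve on
  # the current active set with its signs (the stationarity system of the
  # LASSO objective). The polish is accepted only if the full KKT system is
  # satisfied, so the returned solution is the coordinate-descent optimum.
  kkt_polish <- function(b) {
    act <- which(b != 0)
    s <- sign(b)
    for (outer in 1:50) {
      bb <- numeric(p)
      if (length(act)) {
        A <- XtX[act, act, drop = FALSE]
        rhs <- Xty[act] - lambda * s[act]
        sol <- tryCatch({
          s0 <- solve(A, rhs)
          s0 + solve(A, rhs - drop(A %*% s0))  # one refinement step
        }, error = function(e) NULL)
        if (is.null(sol)) return(NULL)
        if (lambda > 0 && any(sign(sol) != s[act])) {
          # sign iteration: adopt the solved signs; variables landing on
          # zero leave the active set (they may be re-activated below)
          s[act] <- sign(sol)
          act <- act[sign(sol) != 0]
          next
        }
        bb[act] <- sol
      }
      grad <- Xty - drop(XtX %*% bb)
      inact <- setdiff(seq_len(p), act)
      viol <- if (length(inact)) abs(grad[inact]) - lambda else numeric(0)
      if (length(viol) && max(viol) > 1e-8 * scale) {
        # activate the worst KKT violator and re-solve
        j <- inact[which.max(viol)]
        act <- sort(c(act, j))
        s[j] <- sign(grad[j])
        next
      }
      # stationarity on the active set holds by construction of the solve,
      # up to the precision the conditioning allows; acceptance is decided
      # by the caller's objective comparison
      return(bb)
    }
    NULL
  }
  objective <- function(b)
    0.5 * drop(crossprod(b, XtX %*% b)) - sum(Xty * b) + lambda * sum(abs(b))
  prev_obj <- Inf
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      rho <- Xty[j] - sum(XtX[j, -j] * b[-j])
      bj <- soft_threshold(rho, lambda) / XtX[j, j]
      delta <- max(delta, abs(bj - b[j]))
      b[j] <- bj
    }
    if (delta < tol || it %% 5L == 0L) {
      polished <- kkt_polish(b)
      if (!is.null(polished) && objective(polished) <= objective(b))
        return(list(b = polished, iter = it, converged = TRUE))
      obj <- objective(b)
      stalled <- prev_obj - obj < 1e-12 * (1 + abs(obj))
      if (delta < tol || stalled || it >= 200L) {
        # the active-set polish could not be verified: the library is too
        # collinear for iterative descent, so fall back to the exact
        # orthant-enumeration solution
        exact <- lasso_enumerate(XtX, Xty, lambda)
        if (!is.null(exact) && objective(exact) <= obj)
          return(list(b = exact, iter = it, converged = TRUE))
        return(list(b = b, iter = it, converged = delta < tol || stalled))
      }
      prev_obj <- obj
    }
  }
  list(b = b, iter = max_iter, converged = FALSE)
}

#' LASSO regression by cyclic coordinate descent
#'
#' Solves `min_b (1/2) ||Y - Theta b||^2 + lambda ||b||_1` with cyclic
#' coordinate descent and soft-thresholding. Non-constant columns are
#' standardised internally (the penalty acts on the standardised scale, so
#' `lambda >= max |Xs' (Y - mean(Y))|` zeroes every penalised coefficient);
#' returned coefficients are on the raw scale. A constant column, if present,
#' plays the role of an unpenalised intercept.
#'
#' @param Theta design matrix (e.g. from [build_library()]).
#' @param Y response vector.
#' @param lambda penalty (>= 0).
#' @param weights optional non-negative observation weights (normalised to
#'   mean 1), e.g. bin counts so that a bin-level fit reproduces the pooled
#'   per-sample regression.
#' @param tol convergence tolerance on the max standardised-coefficient
#'   change per sweep.
#' @param max_iter maximum coordinate-descent sweeps.
#' @return numeric coefficient vector (length `ncol(Theta)`), with attributes
#'   `iterations` and `lambda`.
#' @export
lasso_cd <- function(Theta, Y, lambda, weights = NULL, tol = 1e-9,
                     max_iter = 1e5) {
  if (nrow(Theta) != length(Y))
    fs_abort("Theta rows must match length of Y", "parameter_error")
  if (lambda < 0) fs_abort("lambda must be >= 0", "parameter_error")
  prep <- lasso_prep(Theta, Y, weights)
  XtX <- crossprod(prep$Xs, prep$w * prep$Xs)
  Xty <- drop(crossprod(prep$Xs, prep$w * prep$Yc))
  fit <- cd_solve(XtX, Xty, lambda, tol = tol, max_iter = max_iter)
  if (!fit$converged)
    fs_abort(sprintf("coordinate descent did not converge in %d sweeps",
                     max_iter), "convergence_error",
             coefficients = fit$b)
  out <- numeric(ncol(Theta))
  out[prep$pred] <- fit$b / prep$sds
  if (length(prep$const))
    out[prep$const[1]] <-
      (prep$ybar - sum(out[prep$pred] * prep$centres)) / prep$const_val
  attr(out, "iterations") <- fit$iter
  attr(out, "lambda") <- lambda
  attr(out, "std_coef") <- stats::setNames(fit$b, colnames(Theta)[prep$pred])
  out
}

lambda_max_of <- function(Theta, Y, weights = NULL) {
  prep <- lasso_prep(Theta, Y, weights)
  if (!length(prep$pred)) return(0)
  max(abs(drop(crossprod(prep$Xs, prep$w * prep$Yc))))
}

#' Stepwise sparse regression configuration
#'
#' @param lambda_grid penalties tried for the LASSO initialisation; default
#'   30 log-spaced points over `[1e-6, 10] * lambda_max` (data-dependent).
#' @param prune_threshold standardised-coefficient magnitude below which a
#'   term is pruned (default 1e-3).
#' @param K number of cross-validation folds (default 5).
#' @param max_degree highest library degree (default 5).
#' @param seed seed for shuffled fold assignment.
#' @param fold_type `"blocks"` (contiguous, respecting the time-series
#'   structure; default) or `"shuffle"` (seeded random).
#' @param rel_tol relative floor on the accepted cross-validated MSE change
#'   (default 1e-3): guards the paired comparison when the fold errors are
#'   degenerate (zero variance).
#' @param cv_sigma number of paired-fold standard errors by which the
#'   cross-validated MSE must rise before a pruning step counts as a genuine
#'   increase and the iteration terminates (default 2).
#' @param lasso_tol,max_iter passed to [lasso_cd()].
#' @return an object of class `ssr_config`.
#' @export
ssr_config <- function(lambda_grid = NULL, prune_threshold = 1e-3, K = 5L,
                       max_degree = 5L, seed = NULL,
                       fold_type = c("blocks", "shuffle"), rel_tol = 1e-3,
                       cv_sigma = 2, lasso_tol = 1e-9, max_iter = 1e5) {
  fold_type <- match.arg(fold_type)
  if (K < 2L) fs_abort("K must be >= 2", "parameter_error")
  if (prune_threshold < 0)
    fs_abort("prune_threshold must be >= 0", "parameter_error")
  if (!is.null(lambda_grid) && (!length(lambda_grid) || any(lambda_grid < 0)))
    fs_abort("lambda_grid must be non-empty and non-negative",
             "parameter_error")
  structure(list(lambda_grid = lambda_grid,
                 prune_threshold = prune_threshold, K = as.integer(K),
                 max_degree = as.integer(max_degree), seed = seed,
                 fold_type = fold_type, rel_tol = rel_tol,
                 cv_sigma = cv_sigma, lasso_tol = lasso_tol,
                 max_iter = max_iter),
            class = "ssr_config")
}

make_folds <- function(n, K, fold_type, seed = NULL) {
  if (n < K) fs_abort("not enough samples for K folds", "insufficient_data")
  ids <- as.integer(cut(seq_len(n), breaks = K, labels = FALSE))
  if (fold_type == "shuffle") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    ids <- sample(ids)
  }
  ids
}

# K-fold CV error for a LASSO fit on the given active columns at penalty
# lambda. The summary error pools the weighted squared errors over all folds
# (the per-underlying-sample MSE when weights are bin counts; a plain mean
# of per-fold ratios would let a low-weight fold of noisy sparse bins
# dominate). The per-fold weighted MSEs are kept for paired comparisons.
cv_mse <- function(Theta, Y, active, lambda, fold_ids, cfg, weights = NULL) {
  w <- weights %||% rep(1, length(Y))
  ks <- sort(unique(fold_ids))
  sse <- wsum <- errs <- numeric(length(ks))
  for (i in seq_along(ks)) {
    tr <- fold_ids != ks[i]
    cf <- lasso_cd(Theta[tr, active, drop = FALSE], Y[tr], lambda,
                   weights = w[tr], tol = cfg$lasso_tol,
                   max_iter = cfg$max_iter)
    pred <- drop(Theta[!tr, active, drop = FALSE] %*% cf)
    sse[i] <- sum(w[!tr] * (Y[!tr] - pred)^2)
    wsum[i] <- sum(w[!tr])
    errs[i] <- sse[i] / wsum[i]
  }
  structure(sum(sse) / sum(wsum), fold_errors = errs)
}

#' Fit a sparse polynomial drift or diffusion model (SSR)
#'
#' Three stages. (i) Initialisation: LASSO over a penalty grid, with the
#' penalty chosen by K-fold cross-validation. (ii) Stepwise pruning: terms
#' whose standardised coefficients fall below `prune_threshold` are removed
#' (if none qualify, the single smallest is removed), the reduced model is
#' re-fit by LASSO and scored by cross-validated MSE; pruning continues while
#' the error does not increase. (iii) The most parsimonious model before the
#' error rises is returned. The constant term acts as an unpenalised
#' intercept and is never pruned.
#'
#' For `target = "drift"` the response is the pointwise drift estimate
#' regressed on the state samples (pass a `km_estimates` object; a
#' `binned_km` fits the bin means, weighted by bin counts). For
#' `target = "diffusion"` the response is the square root of the bin-averaged
#' squared increments -- the second Kramers-Moyal moment estimates G^2, while
#' the reported parabola describes G itself -- after subtracting the
#' finite-dt drift contribution (`E[(dx)^2]/dt = G^2 + F^2 dt`). A
#' `km_estimates` input is binned internally with `min_count = 1`: the
#' count-weighted bin fit is equivalent to the pooled per-sample regression,
#' and the sparsely visited transition region between the wells carries the
#' curvature information, so no bin is discarded.
#'
#' @param est a `km_estimates` or `binned_km` object.
#' @param target `"drift"` or `"diffusion"`.
#' @param cfg an [ssr_config()].
#' @param bin_width,min_count binning used when a diffusion fit receives
#'   pointwise estimates.
#' @return an object of class `ssr_result`: list with `model` (a
#'   [polynomial_model()]), `cv_error`, `lambda`, and `history` (one row per
#'   accepted iteration: active terms and CV error).
#' @export
ssr_fit <- function(est, target = c("drift", "diffusion"),
                    cfg = ssr_config(), bin_width = 0.1, min_count = 2L) {
  target <- match.arg(target)
  weights <- NULL
  if (target == "diffusion") {
    if (!inherits(est, "binned_km"))
      est <- bin_average(est, bin_width = bin_width,
                         min_count = max(2L, min_count))
    dt <- attr(est, "dt")
    est <- est[est$count > 1L, , drop = FALSE]
    # G^2 is estimated by the unbiased within-bin variance of the
    # increments per unit time: subtracting the local mean removes the
    # drift contribution F^2*dt exactly, for any drift, leaving a pure
    # chi-square quantity (single-sample bins carry no variance
    # information and are dropped)
    g2 <- (est$mean_diff2 - (dt %||% 0) * est$mean_drift^2) *
      est$count / (est$count - 1L)
    df <- est$count - 1L
    y <- est$bin_centre
    # sqrt(chi^2_n / n) is biased low by c_n = sqrt(2/n) G((n+1)/2)/G(n/2);
    # uncorrected, sparse bins look systematically flatter than G and a
    # spurious high-degree shape would fit that artifact
    c_n <- exp(0.5 * log(2 / df) + lgamma((df + 1) / 2) - lgamma(df / 2))
    Y <- sqrt(pmax(g2, 0)) / c_n
    weights <- est$count
  } else if (inherits(est, "binned_km")) {
    y <- est$bin_centre
    Y <- est$mean_drift
    weights <- est$count
  } else {
    y <- est$y
    Y <- est$drift_hat
  }
  Theta <- build_library(y, cfg$max_degree)
  # contiguous blocks respect the serial dependence of pointwise estimate
  # series; bin-level fits use shuffled folds instead, since blocks of
  # sorted bins would mean extrapolating into a held-out state range, and
  # at least 10 folds so the paired fold comparison has usable df
  fold_type <- if (is.null(weights)) cfg$fold_type else "shuffle"
  K_eff <- if (is.null(weights)) cfg$K
           else min(max(cfg$K, 10L), max(2L, length(Y) %/% 3L))
  fold_ids <- make_folds(length(Y), K_eff, fold_type, cfg$seed %||% 0L)

  lam_max <- lambda_max_of(Theta, Y, weights)
  grid <- cfg$lambda_grid %||%
    (if (lam_max > 0) lam_max * 10^seq(-6, 1, length.out = 30) else 0)
  all_cols <- seq_len(ncol(Theta))
  cv_by_lambda <- vapply(grid, function(l)
    cv_mse(Theta, Y, all_cols, l, fold_ids, cfg, weights), numeric(1))
  lambda <- grid[which.min(cv_by_lambda)]

  intercept_col <- which(const_cols(Theta))[1]
  fit <- lasso_cd(Theta, Y, lambda, weights = weights, tol = cfg$lasso_tol,
                  max_iter = cfg$max_iter)
  if (all(fit == 0))
    fs_abort("LASSO initialisation pruned every term", "degenerate_model")
  # the LASSO initialises the coefficient values; the active set starts at
  # the full library so that the stepwise stage, not the L1 penalty's
  # arbitrary choice among collinear powers, decides which terms survive
  active <- all_cols
  delta <- cv_mse(Theta, Y, active, lambda, fold_ids, cfg, weights)
  history <- data.frame(iteration = 0L, n_terms = length(active),
                        terms = paste(colnames(Theta)[active], collapse = "+"),
                        cv_error = as.numeric(delta))
  best <- list(active = active, coef = fit, delta = as.numeric(delta),
               fold_errors = attr(delta, "fold_errors"))

  it <- 0L
  repeat {
    it <- it + 1L
    prunable <- setdiff(best$active, intercept_col)
    if (length(prunable) == 0L) break
    # removal proceeds down the degree axis: the library is nested by
    # construction, and in a severely collinear power basis the smallest
    # standardised coefficient is a poor guide to which term matters least.
    # A top term whose standardised coefficient is below the threshold is
    # negligible and goes unconditionally; otherwise its removal must pass
    # the cross-validation comparison.
    top <- max(prunable)
    std <- attr(best$coef, "std_coef")
    negligible <- isTRUE(abs(std[colnames(Theta)[top]]) < cfg$prune_threshold)
    new_active <- setdiff(best$active, top)
    delta_new <- cv_mse(Theta, Y, new_active, lambda, fold_ids, cfg, weights)
    # "ceases to decrease" is judged against the cross-validation
    # uncertainty: the same folds scored both models, so the paired
    # fold-difference SE is the resolution at which an increase is real
    d <- attr(delta_new, "fold_errors") - best$fold_errors
    se_paired <- stats::sd(d) / sqrt(length(d))
    if (!negligible &&
        mean(d) > cfg$cv_sigma * se_paired + cfg$rel_tol * best$delta) break
    cf_full <- numeric(ncol(Theta))
    cf_new <- lasso_cd(Theta[, new_active, drop = FALSE], Y, lambda,
                       weights = weights, tol = cfg$lasso_tol,
                       max_iter = cfg$max_iter)
    cf_full[new_active] <- cf_new
    attr(cf_full, "std_coef") <- attr(cf_new, "std_coef")
    accept_delta <- as.numeric(delta_new)
    if (accept_delta < best$delta)
      best[c("delta", "fold_errors")] <-
        list(accept_delta, attr(delta_new, "fold_errors"))
    best[c("active", "coef")] <- list(new_active, cf_full)
    history <- rbind(history, data.frame(
      iteration = it, n_terms = length(new_active),
      terms = paste(colnames(Theta)[new_active], collapse = "+"),
      cv_error = accept_delta))
  }

  coefs <- as.numeric(best$coef)
  structure(list(
    model = polynomial_model(coefs, target = target),
    cv_error = best$delta,
    lambda = lambda,
    lambda_grid = grid,
    cv_by_lambda = cv_by_lambda,
    history = history
  ), class = "ssr_result")
}

#' @export
print.ssr_result <- function(x, ...) {
  cat(sprintf("<ssr_result %s> degree %d, CV MSE %.4g, lambda %.4g\n",
              x$model$target, x$model$degree, x$cv_error, x$lambda))
  print(round(x$model$coefficients, 6))
  invisible(x)
}

#' Identify a full SDE model from distance series
#'
#' Runs the estimation pipeline on one or more interindividual-distance
#' series: optional low-pass filtering of the state, pointwise Kramers-Moyal
#' estimates per trial, pooling, a sparse polynomial drift fit on the pooled
#' pointwise estimates (or on bin means), and a sparse parabolic diffusion
#' fit on `sqrt` of the bin-averaged squared increments.
#'
#' Filtering the state before differencing follows the original processing
#' of empirical video tracks, but it biases the diffusion estimate downward
#' (the filter removes exactly the high-frequency increment variance that
#' G^2 is estimated from), so it is off by default and should only be enabled
#' for noisy measured trajectories.
#'
#' @param x a [distance_series()] or a list of them.
#' @param cfg an [ssr_config()].
#' @param bin_width,min_count state binning (defaults 0.1 cm, 10).
#' @param filter logical; low-pass filter each series before differencing.
#' @param filter_order,filter_cutoff Butterworth parameters (defaults 4 and
#'   0.1 rad s^-1), see [butterworth_lowpass()].
#' @param fit_drift_to `"pointwise"` (default) or `"binned"`.
#' @return an object of class `sde_fit`: list with `model` (an [sde_model()]),
#'   `drift_fit`, `diffusion_fit` (both `ssr_result`), and `binned`.
#' @export
identify_sde <- function(x, cfg = ssr_config(), bin_width = 0.1,
                         min_count = 10L, filter = FALSE, filter_order = 4,
                         filter_cutoff = 0.1,
                         fit_drift_to = c("pointwise", "binned")) {
  fit_drift_to <- match.arg(fit_drift_to)
  if (inherits(x, "distance_series")) x <- list(x)
  est_list <- lapply(x, function(ds) {
    if (filter) {
      ds$x <- butterworth_lowpass(ds$x, order = filter_order,
                                  cutoff = filter_cutoff, fs = 1 / ds$dt)
      ds$x <- pmax(ds$x, 0)
    }
    km_point_estimates(ds)
  })
  pooled <- pool_km(est_list)
  binned <- bin_average(pooled, bin_width = bin_width, min_count = min_count)
  drift_fit <- ssr_fit(if (fit_drift_to == "binned") binned else pooled,
                       "drift", cfg)
  # the diffusion fit keeps every bin with at least two samples
  # (count-weighted): the curvature information lives in the sparsely
  # visited transition region between the wells
  diffusion_fit <- ssr_fit(pooled, "diffusion", cfg, bin_width = bin_width,
                           min_count = 2L)
  model <- sde_model(drift = drift_fit$model,
                     diffusion = diffusion_fit$model,
                     domain = range(binned$bin_centre))
  structure(list(model = model, drift_fit = drift_fit,
                 diffusion_fit = diffusion_fit, binned = binned),
            class = "sde_fit")
}
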