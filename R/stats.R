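# Statistical summaries for the in-silico harness: two-way ANOVA with
# eta-squared, IQR outlier removal, simple linear regression.

#' Two-way ANOVA with eta-squared effect sizes
#'
#' Fixed-effects two-way ANOVA of `values` on two categorical factors and
#' their interaction. Sums of squares are Type II (each main effect adjusted
#' for the other, the interaction adjusted for both), computed by nested
#' model comparisons with [stats::lm()]; for balanced designs these coincide
#' with the classical sequential decomposition and are exactly additive.
#' Effect sizes are `eta^2 = SS_effect / SS_total`.
#'
#' @param values numeric response.
#' @param factorA,factorB factor labels (coerced to factor); each needs >= 2
#'   levels and every cell of the cross-classification >= 1 observation.
#' @param factor_names length-2 character, names used in the output.
#' @return an object of class `anova_table`: data.frame with one row per
#'   effect (`A`, `B`, `A:B`) plus residuals, columns `effect`, `df`,
#'   `sum_sq`, `F`, `p`, `eta_sq`.
#' @export
two_way_anova <- function(values, factorA, factorB,
                          factor_names = c("A", "B")) {
  A <- factor(factorA)
  B <- factor(factorB)
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    fs_abort("each factor needs at least 2 levels", "parameter_error")
  tab <- table(A, B)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1, ]
    fs_abort(sprintf("empty cell: %s = %s, %s = %s",
                     factor_names[1], levels(A)[empty[1]],
                     factor_names[2], levels(B)[empty[2]]),
             "parameter_error")
  }
  y <- as.numeric(values)
  d <- data.frame(y = y, A = A, B = B)
  rss <- function(formula) sum(resid(lm(formula, data = d))^2)
  rss_A <- rss(y ~ A); rss_B <- rss(y ~ B); rss_AB <- rss(y ~ A + B)
  rss_full <- rss(y ~ A * B)
  ss <- c(rss_B - rss_AB,   # A adjusted for B
          rss_A - rss_AB,   # B adjusted for A
          rss_AB - rss_full)
  ss <- pmax(ss, 0)
  df <- c(nlevels(A) - 1L, nlevels(B) - 1L,
          (nlevels(A) - 1L) * (nlevels(B) - 1L))
  df_res <- length(y) - nlevels(A) * nlevels(B)
  ss_total <- sum((y - mean(y))^2)
  ms_res <- if (df_res > 0) rss_full / df_res else NaN
  Fstat <- (ss / df) / ms_res
  # degenerate case: zero within-cell variance
  if (is.finite(ms_res) && ms_res <= 1e-12 * max(ss_total, 1)) {
    Fstat <- ifelse(ss > 1e-12 * max(ss_total, 1), Inf, 0)
  }
  p <- ifelse(is.infinite(Fstat), 0, pf(Fstat, df, df_res, lower.tail = FALSE))
  out <- data.frame(
    effect = c(factor_names[1], factor_names[2],
               paste(factor_names, collapse = ":"), "residuals"),
    df = c(df, df_res),
    sum_sq = c(ss, rss_full),
    F = c(Fstat, NA),
    p = c(p, NA),
    eta_sq = c(ss, rss_full) / ss_total)
  class(out) <- c("anova_table", "data.frame")
  attr(out, "ss_total") <- ss_total
  out
}

#' Interquartile-range outlier filter
#'
#' Tukey's rule: values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are removed.
#' Quartiles use the linear-interpolation method (`quantile type 7`, R's
#' default); the fences depend on this choice, so it is fixed and documented.
#' The rule is applied once, not iterated: kept values lie inside the fences
#' that produced them, but re-estimating fences on the reduced sample could
#' flag further points. Fewer than 4 values are passed through unchanged
#' with a warning.
#'
#' @param values numeric vector (`NA`s are kept, ignored for the fences).
#' @return a list with `kept`, `removed`, `removed_idx` (indices into the
#'   input) and `fences`.
#' @export
iqr_outlier_filter <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) {
    warning("fewer than 4 values; IQR filter passes data through")
    return(list(kept = values, removed = numeric(0),
                removed_idx = integer(0), fences = c(-Inf, Inf)))
  }
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  out_idx <- which(ok & (values < fences[1] | values > fences[2]))
  list(kept = values[setdiff(seq_along(values), out_idx)],
       removed = values[out_idx],
       removed_idx = out_idx,
       fences = fences)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with the Pearson correlation and the
#' t-test p-value on the slope.
#'
#' @param x,y numeric vectors, >= 3 points, `var(x) > 0`.
#' @return a list with `slope`, `intercept`, `R` (Pearson), `r_squared`, `p`.
#' @export
linear_regression <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) fs_abort("need at least 3 points", "insufficient_data")
  if (var(x) == 0) fs_abort("x has zero variance", "parameter_error")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate input
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       R = cor(x, y),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]))
}
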