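# The tilted double-well potential, its cubic drift, and empirical
# potential reconstruction.
#
# The model potential is V(x) = -alpha*x - beta*(x - xl)^2*(x - xh)^2 with
# drift F = -dV/dx. Under this form the wells at xl and xh are stable for
# beta < 0; beta is accepted signed and the geometry is checked by
# bistability_report() rather than by a sign convention.

#' Parameters of the tilted double-well potential
#'
#' @param alpha tilt in cm s^-1; `alpha = 0` is an unbiased double well.
#' @param beta signed quartic coefficient in cm^-2 s^-1; its magnitude sets
#'   the barrier height between the wells (wells are stable for `beta < 0`).
#' @param xl,xh well locations in cm (`xl < xh`): close-proximity swimming
#'   and far-distance exploration.
#' @return an object of class `potential_params`.
#' @export
potential_params <- function(alpha, beta, xl, xh) {
  if (!all(is.finite(c(alpha, beta, xl, xh))))
    fs_abort("potential parameters must be finite", "parameter_error")
  if (xl >= xh) fs_abort("xl must be < xh", "parameter_error")
  structure(list(alpha = alpha, beta = beta, xl = xl, xh = xh),
            class = "potential_params")
}

#' Evaluate the model potential
#'
#' `V(x) = -alpha*x - beta*(x - xl)^2*(x - xh)^2`, in cm^2 s^-1.
#'
#' @param p a [potential_params()].
#' @param x numeric, cm.
#' @return potential values.
#' @examples
#' p <- potential_params(0, -0.01, 5, 20)
#' potential_value(p, 12.5)  # 31.640625
#' @export
potential_value <- function(p, x) {
  -p$alpha * x - p$beta * (x - p$xl)^2 * (x - p$xh)^2
}

#' Cubic drift coefficients from potential parameters
#'
#' Symbolic expansion of `F(x) = -dV/dx`:
#' `a3 = 4*beta`, `a2 = -6*beta*(xl + xh)`,
#' `a1 = 2*beta*((xl + xh)^2 + 2*xl*xh)`,
#' `a0 = alpha - 2*beta*xl*xh*(xl + xh)`.
#'
#' @param p a [potential_params()].
#' @return numeric `c(a0, a1, a2, a3)` (ascending degree).
#' @examples
#' drift_from_potential(potential_params(0, -0.01, 5, 20))
#' # (50, -16.5, 1.5, -0.04)
#' @export
drift_from_potential <- function(p) {
  s <- p$xl + p$xh
  q <- p$xl * p$xh
  c(a0 = p$alpha - 2 * p$beta * s * q,
    a1 = 2 * p$beta * (s^2 + 2 * q),
    a2 = -6 * p$beta * s,
    a3 = 4 * p$beta)
}

#' Potential parameters from a cubic drift
#'
#' Closed-form inverse of [drift_from_potential()]: `beta = a3/4`,
#' `s = -a2/(6*beta)`, `q = (a1/(2*beta) - s^2)/2`,
#' `alpha = a0 + 2*beta*s*q`, and `xl, xh` are the roots of
#' `z^2 - s*z + q = 0`. Exact round trip with [drift_from_potential()].
#'
#' @param cubic numeric `c(a0, a1, a2, a3)` with `a3 != 0`.
#' @return a [potential_params()].
#' @export
potential_from_drift <- function(cubic) {
  if (length(cubic) < 4L || cubic[4] == 0)
    fs_abort("drift is not cubic (a3 = 0)", "not_cubic")
  a0 <- cubic[1]; a1 <- cubic[2]; a2 <- cubic[3]; a3 <- cubic[4]
  beta <- a3 / 4
  s <- -a2 / (6 * beta)
  q <- (a1 / (2 * beta) - s^2) / 2
  alpha <- a0 + 2 * beta * s * q
  disc <- s^2 - 4 * q
  if (disc < 0)
    fs_abort(sprintf(
      "no real well pair: discriminant (xl+xh)^2 - 4*xl*xh = %.4g < 0", disc),
      "monostable")
  xl <- (s - sqrt(disc)) / 2
  xh <- (s + sqrt(disc)) / 2
  potential_params(unname(alpha), unname(beta), unname(xl), unname(xh))
}

#' Sparse polynomial model
#'
#' Coefficient container for a fitted drift or diffusion polynomial,
#' coefficients in ascending degree with pruned terms exactly zero.
#'
#' @param coefficients numeric vector `c0, c1, ...`.
#' @param target `"drift"` or `"diffusion"`.
#' @return an object of class `polynomial_model` with fields `coefficients`,
#'   `degree`, `target`.
#' @export
polynomial_model <- function(coefficients, target = c("drift", "diffusion")) {
  target <- match.arg(target)
  if (!all(is.finite(coefficients)))
    fs_abort("coefficients must be finite", "parameter_error")
  nz <- which(coefficients != 0)
  structure(list(coefficients = as.numeric(coefficients),
                 degree = if (length(nz)) max(nz) - 1L else 0L,
                 target = target),
            class = "polynomial_model")
}

#' @export
predict.polynomial_model <- function(object, newdata, ...) {
  polyval_asc(object$coefficients, newdata)
}

#' Stochastic model of the interindividual distance
#'
#' The 1-D SDE `dx = F(x) dt + G(x) dW`. The drift may be given either as a
#' cubic-coefficient vector / [polynomial_model()] or as [potential_params()]
#' (converted through [drift_from_potential()]); the diffusion as a
#' coefficient vector `c(b0, b1, b2)` or [polynomial_model()]. The diffusion
#' is floored at `diffusion_floor` inside the simulator domain so that a
#' fitted parabola crossing zero at the domain edges cannot produce a
#' negative noise amplitude.
#'
#' @param drift drift specification (see above).
#' @param diffusion diffusion specification (see above).
#' @param domain working domain `c(lo, hi)` in cm (default `c(0, 57)`: tank
#'   diameter minus one body length).
#' @param diffusion_floor minimum diffusion in cm s^-1/2 (default 1e-3).
#' @return an object of class `sde_model` with fields `drift`, `diffusion`
#'   (both `polynomial_model`), `potential` (a `potential_params` or `NULL`
#'   when the drift is not a bistable cubic), `domain`, `diffusion_floor`.
#' @export
sde_model <- function(drift, diffusion, domain = c(0, 57),
                      diffusion_floor = 1e-3) {
  if (inherits(drift, "potential_params")) {
    pot <- drift
    drift <- polynomial_model(unname(drift_from_potential(drift)), "drift")
  } else {
    if (!inherits(drift, "polynomial_model"))
      drift <- polynomial_model(as.numeric(drift), "drift")
    pot <- tryCatch(potential_from_drift(drift$coefficients[1:4]),
                    fishsde_error = function(e) NULL,
                    error = function(e) NULL)
  }
  if (!inherits(diffusion, "polynomial_model"))
    diffusion <- polynomial_model(as.numeric(diffusion), "diffusion")
  if (length(domain) != 2L || domain[1] >= domain[2])
    fs_abort("domain must be c(lo, hi) with lo < hi", "parameter_error")
  structure(list(drift = drift, diffusion = diffusion, potential = pot,
                 domain = as.numeric(domain),
                 diffusion_floor = diffusion_floor),
            class = "sde_model")
}

#' @export
print.sde_model <- function(x, ...) {
  cat("<sde_model>\n  drift  F(x):", signif(x$drift$coefficients, 5),
      "\n  diff   G(x):", signif(x$diffusion$coefficients, 5),
      "\n  domain:", x$domain, "cm\n")
  if (!is.null(x$potential))
    cat(sprintf("  potential: alpha=%.4g beta=%.4g xl=%.3f xh=%.3f\n",
                x$potential$alpha, x$potential$beta, x$potential$xl,
                x$potential$xh))
  invisible(x)
}

drift_fun <- function(model) {
  cf <- model$drift$coefficients
  function(x) polyval_asc(cf, x)
}

diffusion_fun <- function(model) {
  cf <- model$diffusion$coefficients
  floor_ <- model$diffusion_floor
  function(x) pmax(polyval_asc(cf, x), floor_)
}

#' Empirical potential by trapezoidal integration
#'
#' Reconstructs the potential from bin-averaged drift estimates as
#' `V(x) = -integral of mean drift`, using the trapezoidal rule over bin
#' centres and anchoring the first retained bin at zero.
#'
#' @param binned a `binned_km` (from [bin_average()]) with >= 2 bins.
#' @return a data.frame with columns `x` (bin centres, sorted ascending) and
#'   `V` (cm^2 s^-1).
#' @export
empirical_potential <- function(binned) {
  if (nrow(binned) < 2L)
    fs_abort("need at least 2 retained bins", "insufficient_data")
  o <- order(binned$bin_centre)
  x <- binned$bin_centre[o]
  f <- binned$mean_drift[o]
  data.frame(x = x, V = -pracma::cumtrapz(x, f)[, 1])
}

#' Well structure of a fitted model
#'
#' Locates the real roots of the cubic drift, classifies them by the sign of
#' `F'` (stable wells vs unstable barrier), and evaluates the analytic
#' potential `V(x) = -(a0*x + a1*x^2/2 + a2*x^3/3 + a3*x^4/4)` to report the
#' barrier height above the shallower well and the tilt direction.
#'
#' @param model an [sde_model()] (or a drift coefficient vector).
#' @return a list with `wells` (stable roots, ascending), `barrier_x`,
#'   `barrier_height` (`V(barrier) - V(shallower well)`), `tilt_direction`
#'   (`"toward_near"`, `"toward_far"` or `"none"`), `bistable` (logical) and
#'   `attracting` (`FALSE` when `a3 > 0`, i.e. no global confinement).
#' @export
bistability_report <- function(model) {
  cf <- if (inherits(model, "sde_model")) model$drift$coefficients
        else as.numeric(model)
  cf <- c(cf, rep(0, max(0, 4 - length(cf))))[1:4]
  Vfun <- function(x) -(cf[1] * x + cf[2] * x^2 / 2 + cf[3] * x^3 / 3 +
                          cf[4] * x^4 / 4)
  dF <- function(x) cf[2] + 2 * cf[3] * x + 3 * cf[4] * x^2
  if (cf[4] == 0)
    fs_abort("drift is not cubic; no well analysis", "not_cubic")
  roots <- polyroot(cf)
  real <- sort(Re(roots[abs(Im(roots)) < 1e-8 * max(1, Mod(roots))]))
  stable <- real[dF(real) < 0]
  unstable <- real[dF(real) >= 0]
  bistable <- length(stable) == 2L
  attracting <- cf[4] < 0
  if (bistable) {
    barrier_x <- unstable[unstable > min(stable) & unstable < max(stable)][1]
    Vw <- Vfun(stable)
    shallow <- stable[which.max(Vw)]
    out <- list(wells = stable, barrier_x = barrier_x,
                barrier_height = Vfun(barrier_x) - max(Vw),
                tilt_direction =
                  if (abs(diff(Vw)) < 1e-12) "none"
                  else if (Vw[1] > Vw[2]) "toward_far" else "toward_near",
                bistable = TRUE, attracting = attracting)
  } else {
    out <- list(wells = stable, barrier_x = NA_real_,
                barrier_height = NA_real_, tilt_direction = NA_character_,
                bistable = FALSE, attracting = attracting)
  }
  out
}
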