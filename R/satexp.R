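# Saturating-exponential fitting: the assay's workhorse model
#   y(x) = A * (1 - exp(-x / s))
# describes invasion distance vs time (H0, tau), CIMI vs time (Psi0, tau_Psi),
# CIMI vs distance (Psi_h, h_Psi) and, reparameterised with rate k = 1/s,
# CIMI vs drug concentration.

satexp_model <- function(x, amplitude, scale) amplitude * (1 - exp(-x / scale))

# Profile least squares: for fixed s the amplitude is linear, so the scale is
# found by 1-D minimisation of the profiled SSR, then polished with LM.
profile_amplitude <- function(x, y, scale) {
  g <- 1 - exp(-x / scale)
  sg2 <- sum(g^2)
  if (sg2 == 0) return(0)
  sum(y * g) / sg2
}

#' Fit a saturating-exponential model
#'
#' Least-squares fit of `y = A (1 - exp(-x/s))` to non-negative covariate
#' data: invasion distance or CIMI versus time, CIMI versus distance, or (via
#' [fit_dose_response()]) CIMI versus drug concentration. The scale is found
#' by profiling the (conditionally linear) amplitude over a log-spaced scale
#' grid followed by 1-D minimisation and a Levenberg-Marquardt polish, which
#' makes the fit deterministic for identical input.
#'
#' @param x covariate values (time in min, distance in um, ...), non-negative.
#' @param y response values (CIMI or distance).
#' @param fix_scale optional positive scale; when supplied only the amplitude
#'   is estimated (used when a common time constant, e.g. 100 min, is imposed
#'   across treatment groups).
#' @param axis_kind optional label (`"time_min"`, `"distance_um"`,
#'   `"concentration_nM"`) carried into the result.
#' @return Object of class `"satexp_fit"`: `amplitude`, `scale`,
#'   `r_squared`, `fixed_scale`, `converged`, plus the data and fitted values.
#'   `converged = FALSE` flags non-saturating data (the scale escaping to the
#'   top of its search range, i.e. the data look linear in `x`).
#' @examples
#' x <- seq(0, 180, 10)
#' y <- 0.63 * (1 - exp(-x / 100))
#' fit <- fit_saturating_exp(x, y)
#' coef(fit)
#' @export
fit_saturating_exp <- function(x, y, fix_scale = NULL, axis_kind = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points to fit the model")
  if (any(x < 0)) stop("covariate values must be non-negative")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")

  span <- max(x) - min(x)
  if (span <= 0) stop("covariate values must not be all equal")

  if (!is.null(fix_scale)) {
    if (!is.finite(fix_scale) || fix_scale <= 0)
      stop("fix_scale must be positive")
    s_hat <- fix_scale
    a_hat <- profile_amplitude(x, y, s_hat)
    converged <- TRUE
  } else {
    s_lo <- span / 1e3
    s_hi <- span * 1e3
    ssr_of <- function(log_s) {
      s <- exp(log_s)
      a <- profile_amplitude(x, y, s)
      sum((y - satexp_model(x, a, s))^2)
    }
    # coarse log grid guards against local minima of the profiled SSR
    grid <- seq(log(s_lo), log(s_hi), length.out = 60)
    vals <- vapply(grid, ssr_of, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(k - 1, 1)]; hi <- grid[min(k + 1, length(grid))]
    opt <- stats::optimize(ssr_of, lower = lo, upper = hi, tol = 1e-12)
    s_hat <- exp(opt$minimum)
    a_hat <- profile_amplitude(x, y, s_hat)
    # LM polish on (A, s) for machine-precision minima
    pol <- tryCatch(minpack.lm::nls.lm(
      par = c(A = a_hat, s = s_hat),
      lower = c(-Inf, s_lo / 10), upper = c(Inf, s_hi * 10),
      fn = function(p) y - satexp_model(x, p[1], p[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(pol) &&
        sum(pol$fvec^2) <= sum((y - satexp_model(x, a_hat, s_hat))^2)) {
      a_hat <- unname(pol$par[1]); s_hat <- unname(pol$par[2])
    }
    converged <- s_hat < 0.95 * s_hi
  }

  if (a_hat < 0) {
    a_hat <- 0
    converged <- FALSE
  }
  fitted_y <- satexp_model(x, a_hat, s_hat)
  ss_res <- sum((y - fitted_y)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  structure(list(amplitude = a_hat, scale = s_hat, r_squared = r2,
                 fixed_scale = !is.null(fix_scale), converged = converged,
                 x = x, y = y, fitted = fitted_y,
                 axis_kind = axis_kind, call = match.call()),
            class = "satexp_fit")
}

#' @export
print.satexp_fit <- function(x, ...) {
  cat(sprintf(
    "Saturating-exponential fit: y = %.4g * (1 - exp(-x / %.4g))%s\n",
    x$amplitude, x$scale, if (x$fixed_scale) "  [scale fixed]" else ""))
  cat(sprintf("  n = %d, R^2 = %s%s\n", length(x$x),
              formatC(x$r_squared, digits = 4),
              if (!x$converged) "  [non-saturating data]" else ""))
  invisible(x)
}

#' @export
coef.satexp_fit <- function(object, ...) {
  c(amplitude = object$amplitude, scale = object$scale)
}

#' @export
predict.satexp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  satexp_model(x, object$amplitude, object$scale)
}

#' @export
fitted.satexp_fit <- function(object, ...) object$fitted

#' @export
residuals.satexp_fit <- function(object, ...) object$y - object$fitted

#' @export
summary.satexp_fit <- function(object, ...) {
  rate <- steady_state_and_initial_rate(object)
  structure(list(coef = coef(object), r_squared = object$r_squared,
                 plateau = rate[["plateau"]],
                 initial_rate = rate[["initial_rate"]],
                 n = length(object$x), fixed_scale = object$fixed_scale,
                 converged = object$converged),
            class = "summary.satexp_fit")
}

#' @export
print.summary.satexp_fit <- function(x, ...) {
  cat("Saturating-exponential fit\n")
  cat(sprintf("  amplitude (plateau) : %.4g\n", x$coef[["amplitude"]]))
  cat(sprintf("  scale               : %.4g%s\n", x$coef[["scale"]],
              if (x$fixed_scale) " (fixed)" else ""))
  cat(sprintf("  initial rate A/s    : %.4g\n", x$initial_rate))
  cat(sprintf("  R^2                 : %s on %d points\n",
              formatC(x$r_squared, digits = 4), x$n))
  invisible(x)
}

#' @export
plot.satexp_fit <- function(x, xlab = x$axis_kind, ylab = "response", ...) {
  if (is.null(xlab)) xlab <- "x"
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = 2)
  invisible(x)
}

#' @export
simulate.satexp_fit <- function(object, nsim = 1, seed = NULL,
                                noise_sd = NULL, ...) {
  if (is.null(noise_sd))
    noise_sd <- stats::sd(residuals(object))
  if (!is.null(seed)) {
    out <- with_seed(seed, simulate.satexp_fit(object, nsim = nsim,
                                               noise_sd = noise_sd))
    attr(out, "seed") <- seed
    return(out)
  }
  mu <- fitted(object)
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, noise_sd)))
}

#' Plateau and initial rate of a saturating-exponential fit
#'
#' For `y = A (1 - exp(-x/s))` the plateau is `A` (the steady-state response
#' as `x -> Inf`) and the derivative at `x = 0` is `A / s` — the two summaries
#' used to rank treatment groups by their early invasion dynamics.
#'
#' @param fit a [fit_saturating_exp()] result.
#' @return Named numeric vector `c(plateau, initial_rate)`.
#' @export
steady_state_and_initial_rate <- function(fit) {
  if (!inherits(fit, "satexp_fit")) stop("fit must be a satexp_fit")
  c(plateau = fit$amplitude, initial_rate = fit$amplitude / fit$scale)
}

#' Fit the single-exponential dose-response model
#'
#' Fits `Psi(c) = A (1 - exp(-k c))` to CIMI values normalised to the
#' zero-dose control, and reports the half-maximal effective concentration in
#' closed form, `EC50 = ln(2) / k` (the concentration at which the response
#' reaches `A / 2`).
#'
#' @param concentrations doses in nM, at least 3 values including 0.
#' @param psi CIMI responses normalised to the control group.
#' @return Object of class `c("dose_response", "satexp_fit")` with the
#'   additional elements `rate` (k, per nM) and `ec50` (nM).
#' @examples
#' conc <- c(0, 1, 2, 4, 10, 20)
#' psi <- 0.22 * (1 - exp(-0.63 * conc))
#' fit <- fit_dose_response(conc, psi)
#' fit$ec50   # ln(2) / 0.63 = 1.1 nM
#' @export
fit_dose_response <- function(concentrations, psi) {
  if (length(concentrations) < 3)
    stop("need at least 3 concentrations")
  if (!any(concentrations == 0))
    stop("the design must include the zero-dose control")
  if (length(unique(psi)) == 1)
    stop("all responses equal; no dose-response can be fitted")
  fit <- fit_saturating_exp(concentrations, psi,
                            axis_kind = "concentration_nM")
  fit$rate <- 1 / fit$scale
  fit$ec50 <- log(2) * fit$scale
  class(fit) <- c("dose_response", class(fit))
  fit
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "Dose-response fit: Psi(c) = %.4g * (1 - exp(-%.4g c))\n",
    x$amplitude, x$rate))
  cat(sprintf("  EC50 = %.4g nM (ln 2 / k), R^2 = %s\n", x$ec50,
              formatC(x$r_squared, digits = 4)))
  invisible(x)
}

#' @export
coef.dose_response <- function(object, ...) {
  c(amplitude = object$amplitude, rate = object$rate, ec50 = object$ec50)
}
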