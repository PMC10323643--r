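# Constrained complex nonlinear least squares for the equivalent circuit.
#
# The cost is sum_i |Z_i - Z(w_i, p)|^2, minimised as stacked real/imaginary
# residuals (identical by Pythagoras). Positive parameters are optimised in
# log10 space so the search spans decades without negative excursions; the CPA
# exponent n stays linear with box constraint [0, 1].
#
# Identifiability note: the cell block equals 1/(jwC_cell + 1/R_seal +
# 1/R_cell), so spectra determine only the PARALLEL conductance of R_seal and
# R_cell, never the split. The fitter surfaces this through huge uncertainty
# proxies on the degenerate direction, and `fix`/`fix_seal_cell_ratio` pin it
# when absolute values are required.

#' Default box constraints for circuit fitting
#'
#' @return A list with `lower` and `upper` named vectors over the nine
#'   parameters.
#' @export
default_circuit_bounds <- function() {
  lower <- c(R_ccm = 1e-2, R_ECM = 1e-2, C_ECM = 1e-15, R_seal = 1e-2,
             R_cell = 1e-2, C_cell = 1e-15, R_ct = 1e-2, Q = 1e-12, n = 0)
  upper <- c(R_ccm = 1e9, R_ECM = 1e9, C_ECM = 1e-3, R_seal = 1e9,
             R_cell = 1e9, C_cell = 1e-3, R_ct = 1e12, Q = 1, n = 1)
  list(lower = lower, upper = upper)
}

circuit_cost <- function(spectrum, params) {
  zf <- circuit_impedance(2 * pi * spectrum$frequencies_hz, params)
  sum(Mod(spectrum$z - zf)^2)
}

# log10 transform for the eight positive parameters; n passes through.
theta_from_params <- function(p) {
  c(log10(unclass(p)[1:8]), unclass(p)[9])
}
params_from_theta <- function(theta) {
  p <- c(10^theta[1:8], min(max(theta[9], 0), 1))
  names(p) <- circuit_param_names()
  structure(p, class = "circuit_params")
}

#' Heuristic initial circuit parameters from a spectrum
#'
#' When no starting point is supplied, the fitter seeds the medium resistance
#' from the high-frequency magnitude (where all capacitive blocks short), and
#' splits the remaining low-frequency magnitude between the interface, matrix
#' and cell resistances. Capacitances start at 1 nF, the CPA at `Q = 1e-8`,
#' `n = 0.8`.
#'
#' @param spectrum an [impedance_spectrum()].
#' @return A [circuit_params()] vector.
#' @export
init_circuit_params <- function(spectrum) {
  mag <- Mod(spectrum$z)
  r_hf <- max(mag[length(mag)], 1)
  excess <- max(mag[1] - r_hf, 10)
  third <- excess / 3
  circuit_params(R_ccm = r_hf, R_ECM = third, C_ECM = 1e-9,
                 R_seal = 2 * third, R_cell = 2 * third, C_cell = 1e-9,
                 R_ct = third, Q = 1e-8, n = 0.8)
}

#' Fit the equivalent circuit to a measured spectrum
#'
#' Estimates the nine circuit parameters by constrained Levenberg-Marquardt
#' minimisation of the least-squares cost `sum_i |Z_i - Z(w_i, p)|^2` over the
#' sweep grid, with optional `1/|Z_i|` residual weighting. The returned cost is
#' always the unweighted least-squares value and is guaranteed not to exceed
#' the cost at the supplied start.
#'
#' The seal and cell resistances enter their block only through the parallel
#' conductance `1/R_seal + 1/R_cell`, so their split is structurally
#' unidentifiable from a spectrum: both uncertainty proxies then exceed 100%
#' and a degeneracy warning is emitted. Pass `fix_seal_cell_ratio` (or pin one
#' of them via `fix`) when absolute values are needed.
#'
#' @param spectrum an [impedance_spectrum()] with at least 9 points.
#' @param init optional [circuit_params()] start; a heuristic start is derived
#'   from the spectrum when omitted (see [init_circuit_params()]).
#' @param bounds list with `lower`/`upper` named vectors
#'   (default [default_circuit_bounds()]).
#' @param weighting `"none"` (the plain cost) or `"inv-magnitude"`
#'   (residuals scaled by `1/|Z_i|`).
#' @param fix optional named numeric vector of parameters to hold fixed at
#'   the given values, e.g. `c(R_seal = 3000)`.
#' @param fix_seal_cell_ratio optional positive number; when given,
#'   `R_seal = ratio * R_cell` is enforced and only `R_cell` is free.
#' @param multistart logical; when `TRUE` (default if no `init` is given) an
#'   8-point grid over `(n, Q)` is tried and the best solution kept.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return An object of class `"circuit_fit"` with elements `params`, `cost`,
#'   `converged`, `n_iterations`, `covariance_proxy` (per-parameter relative
#'   standard errors — absolute for `n`; possibly `NA`),
#'   `degenerate_seal_cell`, `spectrum`.
#' @examples
#' p <- default_circuit_params()
#' f <- default_frequency_grid()
#' sp <- impedance_spectrum(f, circuit_impedance(2 * pi * f, p))
#' fit <- fit_circuit(sp, init = p)
#' coef(fit)
#' @export
fit_circuit <- function(spectrum, init = NULL, bounds = default_circuit_bounds(),
                        weighting = c("none", "inv-magnitude"),
                        fix = NULL, fix_seal_cell_ratio = NULL,
                        multistart = is.null(init), max_iter = 1000L) {
  weighting <- match.arg(weighting)
  if (!inherits(spectrum, "impedance_spectrum"))
    stop("spectrum must be an impedance_spectrum")
  n_t <- length(spectrum$z)
  if (n_t < 9)
    stop("under-determined fit: ", n_t,
         " frequency points for 9 parameters (need >= 9)")
  if (any(!is.finite(spectrum$z))) stop("non-finite impedance values")
  if (is.null(init)) init <- init_circuit_params(spectrum)
  init <- as_circuit_params(init)
  lo <- bounds$lower[circuit_param_names()]
  hi <- bounds$upper[circuit_param_names()]
  if (any(unclass(init) < lo | unclass(init) > hi))
    stop("init outside bounds for: ",
         paste(circuit_param_names()[unclass(init) < lo | unclass(init) > hi],
               collapse = ", "))

  omega <- 2 * pi * spectrum$frequencies_hz
  w <- if (weighting == "inv-magnitude") 1 / Mod(spectrum$z) else rep(1, n_t)
  ratio <- fix_seal_cell_ratio
  if (!is.null(ratio) && (!is.finite(ratio) || ratio <= 0))
    stop("fix_seal_cell_ratio must be a positive number")
  fixed_idx <- integer(0)
  fixed_theta <- numeric(0)
  if (!is.null(fix)) {
    bad <- setdiff(names(fix), circuit_param_names())
    if (length(bad)) stop("unknown parameter(s) in fix: ",
                          paste(bad, collapse = ", "))
    fixed_idx <- match(names(fix), circuit_param_names())
    fixed_theta <- ifelse(fixed_idx <= 8, log10(fix), fix)
  }
  drop_idx <- fixed_idx
  if (!is.null(ratio)) drop_idx <- union(drop_idx, 4L)   # R_seal follows R_cell
  free_idx <- setdiff(1:9, drop_idx)
  if (length(free_idx) == 0) stop("no free parameters left to fit")

  expand_theta <- function(th_free) {
    th <- numeric(9)
    th[free_idx] <- th_free
    th[fixed_idx] <- fixed_theta
    if (!is.null(ratio) && !(4L %in% fixed_idx))
      th[4] <- th[5] + log10(ratio)
    th
  }
  resid_fn <- function(th_free) {
    p <- params_from_theta(expand_theta(th_free))
    zf <- circuit_impedance(omega, p)
    d <- (spectrum$z - zf) * w
    c(Re(d), Im(d))
  }

  th_lo <- c(log10(lo[1:8]), 0)
  th_hi <- c(log10(hi[1:8]), 1)
  run_lm <- function(start_params) {
    th0 <- theta_from_params(start_params)[free_idx]
    minpack.lm::nls.lm(
      par = pmin(pmax(th0, th_lo[free_idx]), th_hi[free_idx]),
      lower = th_lo[free_idx], upper = th_hi[free_idx], fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = min(max_iter, 1024L), ftol = 1e-15, ptol = 1e-13))
  }

  starts <- list(init)
  if (multistart) {
    grid <- expand.grid(n = c(0.6, 0.95), Q = 10^c(-9, -8, -7, -6))
    for (k in seq_len(nrow(grid))) {
      s <- unclass(init)
      s["n"] <- grid$n[k]; s["Q"] <- grid$Q[k]
      starts <- c(starts, list(structure(s, class = "circuit_params")))
    }
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(run_lm(s), error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("circuit fit failed from every start")
  # one restart from the incumbent: resets the trust region and often walks
  # out of the shallow valleys this very anisotropic cost surface produces
  res <- tryCatch(run_lm(params_from_theta(expand_theta(best$par))),
                  error = function(e) NULL)
  if (!is.null(res) && res$deviance < best$deviance) best <- res

  params_hat <- params_from_theta(expand_theta(best$par))
  cost_hat <- circuit_cost(spectrum, params_hat)
  cost_init <- circuit_cost(spectrum, init)
  scale_sq <- sum(Mod(spectrum$z)^2)
  converged <- best$info %in% 1:4 ||
    cost_hat <= 1e-20 * scale_sq          # residuals at numerical zero
  if (cost_hat > cost_init + 1e-18 * scale_sq) {
    # never return a point meaningfully worse than the start
    params_hat <- init
    cost_hat <- cost_init
    converged <- FALSE
  }

  # Relative standard errors from the LM Jacobian via SVD pseudo-inverse, so
  # a rank-deficient (degenerate) direction yields very large, finite proxies
  # rather than a failed solve. The delta method unwinds the log10 transform
  # (sd_p / p = ln(10) * sd_theta for log-scale parameters).
  rel_se <- rep(NA_real_, 9)
  names(rel_se) <- circuit_param_names()
  se_th <- tryCatch({
    jtj <- best$hessian
    dof <- max(2 * n_t - length(free_idx), 1)
    s2 <- best$deviance / dof
    sv <- svd(jtj)
    keep <- sv$d > max(sv$d) * 1e-10
    pinv_diag <- rowSums(sweep(sv$v[, keep, drop = FALSE]^2, 2,
                               sv$d[keep], "/"))
    se <- sqrt(pmax(pinv_diag, 0) * s2)
    # a null direction of the normal matrix means the parameters carrying it
    # are undetermined no matter how small the residuals are
    for (k in which(!keep)) se[abs(sv$v[, k]) > 0.3] <- Inf
    se
  }, error = function(e) NULL)
  if (!is.null(se_th) && !anyNA(se_th)) {
    tmp <- rep(0, 9); tmp[free_idx] <- se_th
    if (!is.null(ratio) && !(4L %in% fixed_idx)) tmp[4] <- tmp[5]
    rel_se[1:8] <- log(10) * tmp[1:8]
    rel_se[9] <- tmp[9]                       # absolute for n
  }
  degenerate <- isTRUE(rel_se[["R_seal"]] > 1 && rel_se[["R_cell"]] > 1)
  if (degenerate)
    warning("R_seal and R_cell are weakly identified (relative uncertainty ",
            "> 100%): only their parallel conductance is constrained by the ",
            "spectrum; consider fix_seal_cell_ratio")

  structure(list(params = params_hat, cost = cost_hat, converged = converged,
                 n_iterations = best$niter, covariance_proxy = rel_se,
                 degenerate_seal_cell = degenerate, weighting = weighting,
                 spectrum = spectrum, call = match.call()),
            class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat(sprintf("Equivalent-circuit fit (%s, t = %g min): cost %.4g Ohm^2, %s in %d iterations\n",
              x$spectrum$chamber_id, x$spectrum$time_min, x$cost,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(format(unclass(x$params), digits = 4), quote = FALSE)
  invisible(x)
}

#' @export
coef.circuit_fit <- function(object, ...) unclass(object$params)

#' @export
predict.circuit_fit <- function(object, frequencies_hz = NULL, ...) {
  f <- if (is.null(frequencies_hz)) object$spectrum$frequencies_hz else
    frequencies_hz
  circuit_impedance(2 * pi * f, object$params)
}

#' @export
residuals.circuit_fit <- function(object, ...) {
  object$spectrum$z - predict(object)
}

#' @export
fitted.circuit_fit <- function(object, ...) predict(object)

#' @export
summary.circuit_fit <- function(object, ...) {
  out <- data.frame(estimate = unclass(object$params),
                    rel_se = object$covariance_proxy)
  structure(list(table = out, cost = object$cost,
                 converged = object$converged,
                 degenerate_seal_cell = object$degenerate_seal_cell),
            class = "summary.circuit_fit")
}

#' @export
print.summary.circuit_fit <- function(x, ...) {
  cat(sprintf("Equivalent-circuit fit: cost %.4g Ohm^2 (%s)\n", x$cost,
              if (x$converged) "converged" else "not converged"))
  print(x$table, digits = 4)
  if (isTRUE(x$degenerate_seal_cell))
    cat("note: only the parallel conductance of R_seal and R_cell is identified\n")
  invisible(x)
}

#' @export
plot.circuit_fit <- function(x, ...) {
  f <- x$spectrum$frequencies_hz
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(f, Mod(x$spectrum$z), log = "xy", xlab = "frequency (Hz)",
                 ylab = "|Z| (Ohm)", main = "magnitude", ...)
  graphics::lines(f, Mod(predict(x)), col = 2)
  graphics::plot(f, Arg(x$spectrum$z) * 180 / pi, log = "x",
                 xlab = "frequency (Hz)", ylab = "phase (deg)",
                 main = "phase", ...)
  graphics::lines(f, Arg(predict(x)) * 180 / pi, col = 2)
  invisible(x)
}

#' Track circuit parameters over a spectrum time series
#'
#' Fits each spectrum in an ordered series, warm-starting every fit from the
#' previous solution, and fits straight lines to the fitted `R_cell(t)` and
#' `R_seal(t)` — the parameters whose drift tracks cell departure from the
#' electrodes — as well as to the parallel conductance
#' `G(t) = 1/R_seal + 1/R_cell`.
#'
#' Because a spectrum constrains only `G`, the seal/cell split must be
#' resolved by convention: with `hold = "R_seal"` (default) the seal
#' resistance is frozen at its first-fit value and all conductance drift is
#' attributed to the cell resistance; `hold = "ratio"` pins `R_seal/R_cell`
#' at its first-fit value; `hold = "none"` leaves both free (their individual
#' trends are then arbitrary along the degenerate manifold, but the `G` trend
#' remains meaningful).
#'
#' @param spectra list of [impedance_spectrum()] with strictly increasing
#'   `time_min` and a shared frequency grid.
#' @param init optional starting [circuit_params()] for the first fit.
#' @param hold identifiability convention for the seal/cell split, see
#'   Details.
#' @param ... passed to [fit_circuit()].
#' @return An object of class `"circuit_trajectory"`: `time_min`, a
#'   `params` matrix (time by parameter), `g_parallel` (S), `converged`
#'   flags, and `linear_trends` — slope, intercept and R-squared of linear
#'   fits to `R_cell`, `R_seal` and `g_parallel` over the converged entries
#'   (R-squared is `NA` when the response is constant).
#' @export
track_parameters <- function(spectra, init = NULL,
                             hold = c("R_seal", "ratio", "none"), ...) {
  hold <- match.arg(hold)
  if (length(spectra) < 2) stop("need at least 2 spectra to track parameters")
  times <- vapply(spectra, function(s) s$time_min, numeric(1))
  if (any(diff(times) <= 0)) stop("time_min must be strictly increasing")
  f0 <- spectra[[1]]$frequencies_hz
  same <- vapply(spectra, function(s)
    isTRUE(all.equal(s$frequencies_hz, f0)), logical(1))
  if (!all(same)) stop("all spectra must share one frequency grid")

  n <- length(spectra)
  pmat <- matrix(NA_real_, n, 9, dimnames = list(NULL, circuit_param_names()))
  conv <- logical(n)
  warm <- init
  fix <- NULL; ratio <- NULL
  for (i in seq_len(n)) {
    fit <- tryCatch(suppressWarnings(
      fit_circuit(spectra[[i]], init = warm, fix = fix,
                  fix_seal_cell_ratio = ratio, ...)),
      error = function(e) NULL)
    if (is.null(fit)) { conv[i] <- FALSE; next }
    pmat[i, ] <- unclass(fit$params)
    conv[i] <- fit$converged
    if (fit$converged) {
      warm <- fit$params
      if (i == 1) {
        if (hold == "R_seal") fix <- c(R_seal = unname(fit$params["R_seal"]))
        if (hold == "ratio")
          ratio <- unname(fit$params["R_seal"] / fit$params["R_cell"])
      }
    }
  }
  g <- 1 / pmat[, "R_seal"] + 1 / pmat[, "R_cell"]

  trend <- function(y) {
    ok <- conv & !is.na(y)
    if (sum(ok) < 2)
      return(c(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
    fit <- stats::lm(y[ok] ~ times[ok])
    r2 <- if (stats::var(y[ok]) == 0) NA_real_ else summary(fit)$r.squared
    c(slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]), r_squared = r2)
  }
  structure(list(time_min = times, params = pmat, g_parallel = g,
                 converged = conv, hold = hold,
                 linear_trends = list(R_cell = trend(pmat[, "R_cell"]),
                                      R_seal = trend(pmat[, "R_seal"]),
                                      g_parallel = trend(g))),
            class = "circuit_trajectory")
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("Circuit parameter trajectory: %d time points, %d converged (hold = %s)\n",
              length(x$time_min), sum(x$converged), x$hold))
  for (nm in names(x$linear_trends)) {
    tr <- x$linear_trends[[nm]]
    cat(sprintf("  %-10s slope %.4g /min, intercept %.4g, R^2 %s\n",
                nm, tr[["slope"]], tr[["intercept"]],
                formatC(tr[["r_squared"]], digits = 4)))
  }
  invisible(x)
}

#' @export
plot.circuit_trajectory <- function(x, parameters = c("R_cell", "R_seal"), ...) {
  op <- graphics::par(mfrow = c(1, length(parameters)))
  on.exit(graphics::par(op))
  for (nm in parameters) {
    graphics::plot(x$time_min, x$params[, nm], xlab = "time (min)",
                   ylab = paste(nm, "(Ohm)"), ...)
    tr <- x$linear_trends[[nm]]
    if (!is.null(tr) && is.finite(tr[["slope"]]))
      graphics::abline(tr[["intercept"]], tr[["slope"]], col = 2)
  }
  invisible(x)
}
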