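# The cell invasion/migration index (CIMI).
#
# Psi = max over the sweep grid of |Z_t(w) - Z_0(w)| / |Z_0(w)|: the largest
# relative change of the complex impedance between time t and baseline. The
# maximum over frequency (not the maximising frequency itself) is what every
# downstream kinetic and dose-response analysis consumes; normalising by the
# baseline removes chamber-to-chamber differences in cell density, morphology
# and adhesion.

#' Cell invasion/migration index from a spectrum pair
#'
#' Computes `Psi = max_w |Z_t(w) - Z_0(w)| / |Z_0(w)|` over a shared frequency
#' grid. `mode = "complex-diff"` (default) takes the modulus of the complex
#' difference; `"magnitude-diff"` compares magnitudes only,
#' `| |Z_t| - |Z_0| | / |Z_0|`.
#'
#' @param z0 baseline [impedance_spectrum()] (time 0).
#' @param zt [impedance_spectrum()] at time t, same frequency grid.
#' @param mode relative-change definition, see Details.
#' @return Psi, a dimensionless non-negative scalar.
#' @examples
#' f <- default_frequency_grid()
#' z <- circuit_impedance(2 * pi * f, default_circuit_params())
#' s0 <- impedance_spectrum(f, z)
#' st <- impedance_spectrum(f, 1.3 * z, time_min = 30)
#' compute_cimi(s0, st)   # 0.3
#' @export
compute_cimi <- function(z0, zt, mode = c("complex-diff", "magnitude-diff")) {
  mode <- match.arg(mode)
  if (!inherits(z0, "impedance_spectrum") || !inherits(zt, "impedance_spectrum"))
    stop("z0 and zt must be impedance_spectrum objects")
  if (!isTRUE(all.equal(z0$frequencies_hz, zt$frequencies_hz)))
    stop("frequency grids of z0 and zt differ")
  m0 <- Mod(z0$z)
  if (any(m0 == 0)) stop("zero baseline magnitude at some frequency")
  rel <- switch(mode,
                "complex-diff" = Mod(zt$z - z0$z) / m0,
                "magnitude-diff" = abs(Mod(zt$z) - m0) / m0)
  max(rel)
}

#' CIMI trace container
#'
#' CIMI values indexed by time, distance or concentration.
#'
#' @param axis_kind one of `"time_min"`, `"distance_um"`,
#'   `"concentration_nM"`.
#' @param axis_values ordered non-negative covariate values.
#' @param psi_values CIMI per covariate point.
#' @param replicate_id optional replicate label.
#' @return A data frame of class `"cimi_trace"` with columns `replicate_id`,
#'   `axis_kind`, `axis_value`, `psi`.
#' @export
cimi_trace <- function(axis_kind, axis_values, psi_values, replicate_id = "r1") {
  axis_kind <- match.arg(axis_kind,
                         c("time_min", "distance_um", "concentration_nM"))
  if (length(axis_values) != length(psi_values))
    stop("axis_values and psi_values must have equal length")
  if (any(axis_values < 0)) stop("axis values must be non-negative")
  if (any(diff(axis_values) <= 0))
    stop("axis values must be strictly increasing within a replicate")
  if (any(psi_values < 0)) stop("Psi must be non-negative")
  out <- data.frame(replicate_id = as.character(replicate_id),
                    axis_kind = axis_kind,
                    axis_value = as.numeric(axis_values),
                    psi = as.numeric(psi_values),
                    stringsAsFactors = FALSE)
  class(out) <- c("cimi_trace", class(out))
  out
}

#' CIMI time series from a spectrum series
#'
#' Applies [compute_cimi()] with the first spectrum as the baseline, yielding
#' one Psi per time point (the first is exactly 0).
#'
#' @param spectra ordered list of [impedance_spectrum()] sharing one grid.
#' @param mode passed to [compute_cimi()].
#' @return A [cimi_trace()] on the time axis.
#' @export
cimi_timeseries <- function(spectra, mode = c("complex-diff", "magnitude-diff")) {
  mode <- match.arg(mode)
  if (length(spectra) < 2) stop("need at least 2 spectra")
  times <- vapply(spectra, function(s) s$time_min, numeric(1))
  if (any(diff(times) <= 0)) stop("time_min must be strictly increasing")
  psi <- vapply(spectra, function(s) compute_cimi(spectra[[1]], s, mode = mode),
                numeric(1))
  cimi_trace("time_min", times, psi,
             replicate_id = spectra[[1]]$chamber_id)
}

#' @export
print.cimi_trace <- function(x, ...) {
  cat(sprintf("CIMI trace (%s): %d points, Psi in [%.4g, %.4g]\n",
              x$axis_kind[1], nrow(x), min(x$psi), max(x$psi)))
  NextMethod()
}

#' Mean invasion velocity per time bin
#'
#' Converts an invasion-distance time series into average velocities over
#' consecutive fixed-width bins (30 min by default, the confocal acquisition
#' cadence), `v_i = (H_i - H_{i-1}) / (t_i - t_{i-1})` in um/min.
#'
#' @param times_min strictly increasing times aligned to bin boundaries
#'   (multiples of `bin_min`).
#' @param distances_um invasion distances H at those times, um.
#' @param bin_min bin width, minutes.
#' @return Object of class `"velocity_profile"`: `interval_labels`,
#'   `velocities_um_min`.
#' @examples
#' interval_velocities(c(0, 30, 60), c(0, 30, 50))
#' @export
interval_velocities <- function(times_min, distances_um, bin_min = 30) {
  if (length(times_min) != length(distances_um))
    stop("times and distances must have equal length")
  if (length(times_min) < 2) stop("need at least 2 samples")
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  off <- abs(times_min / bin_min - round(times_min / bin_min)) > 1e-9
  if (any(off))
    stop("times not aligned to ", bin_min, "-min bin boundaries: ",
         paste(times_min[off], collapse = ", "))
  v <- diff(distances_um) / diff(times_min)
  labels <- sprintf("%g-%g min", times_min[-length(times_min)],
                    times_min[-1])
  structure(list(interval_labels = labels, velocities_um_min = v),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat("Mean invasion/migration velocities (um/min):\n")
  print(stats::setNames(round(x$velocities_um_min, 4), x$interval_labels))
  invisible(x)
}

#' Lost and reserved CIMI under a treatment
#'
#' Splits the control plateau into the part retained under treatment
#' (`reserved`, the treated plateau) and the part abolished by it
#' (`lost = control - treated`, floored at 0 with a warning when the treated
#' plateau exceeds the control's).
#'
#' @param control_fit,treated_fit [fit_saturating_exp()] results on the same
#'   axis kind.
#' @return Named numeric vector `c(lost, reserved)`.
#' @export
lost_reserved_cimi <- function(control_fit, treated_fit) {
  if (!inherits(control_fit, "satexp_fit") ||
      !inherits(treated_fit, "satexp_fit"))
    stop("both arguments must be satexp_fit objects")
  if (!is.null(control_fit$axis_kind) && !is.null(treated_fit$axis_kind) &&
      !identical(control_fit$axis_kind, treated_fit$axis_kind))
    stop("fits are on different axis kinds")
  reserved <- treated_fit$amplitude
  lost <- control_fit$amplitude - treated_fit$amplitude
  if (lost < 0) {
    warning("treated plateau exceeds control plateau; lost CIMI floored at 0")
    lost <- 0
  }
  c(lost = lost, reserved = reserved)
}
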