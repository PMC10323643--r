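# Confocal z-stack invasion profiling.
#
# Collectively migrating, fluorescently labelled cells form a Gaussian-like
# plume whose z position advances as H(t) = H0 (1 - exp(-t/tau)). The stack's
# per-plane intensity distribution summarises the plume; the invasion distance
# is the rise of its intensity-weighted centroid over baseline.

#' Volumetric image stack
#'
#' @param voxels 3D numeric array indexed `(z, y, x)`; z index 1 is the
#'   electrode plane (stack bottom) and intensities must be non-negative.
#' @param voxel_size_um voxel pitches `(z, y, x)` in um.
#' @param time_min acquisition time, minutes.
#' @param chamber_id chamber identifier.
#' @return Object of class `"volumetric_stack"`.
#' @export
volumetric_stack <- function(voxels, voxel_size_um = c(5, 1, 1),
                             time_min = 0, chamber_id = "A1") {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array (z, y, x)")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0))
    stop("voxel_size_um must be 3 positive pitches (z, y, x)")
  structure(list(voxels = voxels, voxel_size_um = as.numeric(voxel_size_um),
                 time_min = as.numeric(time_min),
                 chamber_id = as.character(chamber_id)),
            class = "volumetric_stack")
}

#' @export
print.volumetric_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Volumetric stack %d x %d x %d (z,y,x), z pitch %g um, t = %g min\n",
              d[1], d[2], d[3], x$voxel_size_um[1], x$time_min))
  invisible(x)
}

#' z-resolved fluorescence profile of an invasion stack
#'
#' Sums intensity per z plane, normalises to a unit-mass distribution, and
#' summarises it by the intensity-weighted mean height plus an optional
#' single-Gaussian fit. Plane heights sit at voxel centres, `(i - 1) * pitch`
#' with z = 0 at the electrode plane.
#'
#' @param stack a [volumetric_stack()] with at least 2 planes.
#' @param bg_subtract subtract the per-plane median (floored at 0) before
#'   profiling; off by default so that spatially uniform intensity is
#'   preserved.
#' @param fit_gaussian fit `a * exp(-(z - mu)^2 / (2 sd^2))` to the profile.
#' @return Object of class `"invasion_profile"`: `z_um`, `intensity_fraction`
#'   (sums to 1), `mean_um`, and when fitted `gaussian_mean_um`,
#'   `gaussian_sd_um`, `gaussian_rss`.
#' @export
z_profile <- function(stack, bg_subtract = FALSE, fit_gaussian = TRUE) {
  if (!inherits(stack, "volumetric_stack"))
    stop("stack must be a volumetric_stack")
  v <- stack$voxels
  if (dim(v)[1] < 2) stop("need at least 2 z planes")
  if (bg_subtract) {
    med <- apply(v, 1, stats::median)
    v <- sweep(v, 1, med)
    v[v < 0] <- 0
  }
  sums <- apply(v, 1, sum)
  total <- sum(sums)
  if (total <= 0) stop("zero total intensity; nothing to profile")
  frac <- sums / total
  z_um <- (seq_along(frac) - 1) * stack$voxel_size_um[1]
  mean_um <- sum(frac * z_um)

  g_mean <- g_sd <- g_rss <- NA_real_
  if (fit_gaussian) {
    sd0 <- sqrt(max(sum(frac * (z_um - mean_um)^2), 1e-12))
    fit <- tryCatch(minpack.lm::nls.lm(
      par = c(a = max(frac), mu = mean_um, sd = sd0),
      lower = c(0, min(z_um) - diff(range(z_um)), 1e-6),
      upper = c(Inf, max(z_um) + diff(range(z_um)), 10 * diff(range(z_um))),
      fn = function(p) frac - p[1] * exp(-(z_um - p[2])^2 / (2 * p[3]^2)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      g_mean <- unname(fit$par["mu"])
      g_sd <- unname(fit$par["sd"])
      g_rss <- fit$deviance
    }
  }
  structure(list(z_um = z_um, intensity_fraction = frac, mean_um = mean_um,
                 gaussian_mean_um = g_mean, gaussian_sd_um = g_sd,
                 gaussian_rss = g_rss, time_min = stack$time_min,
                 chamber_id = stack$chamber_id),
            class = "invasion_profile")
}

#' @export
print.invasion_profile <- function(x, ...) {
  cat(sprintf("Invasion z-profile (t = %g min): weighted mean %.2f um",
              x$time_min, x$mean_um))
  if (is.finite(x$gaussian_mean_um))
    cat(sprintf(", Gaussian fit mu = %.2f um, sd = %.2f um",
                x$gaussian_mean_um, x$gaussian_sd_um))
  cat("\n")
  invisible(x)
}

#' @export
plot.invasion_profile <- function(x, ...) {
  graphics::plot(x$z_um, x$intensity_fraction, type = "h",
                 xlab = "height above electrodes (um)",
                 ylab = "intensity fraction", ...)
  graphics::abline(v = x$mean_um, col = 2, lty = 2)
  invisible(x)
}

#' Invasion distance between two profiles
#'
#' `H = ` weighted-mean height at time t minus the baseline weighted-mean
#' height, in um. Small negative values (noise pushing the early centroid
#' below baseline) are clipped to 0 with a warning.
#'
#' @param profile_t,profile_0 [z_profile()] results on the same z grid.
#' @return Invasion distance H in um.
#' @export
invasion_distance <- function(profile_t, profile_0) {
  if (!inherits(profile_t, "invasion_profile") ||
      !inherits(profile_0, "invasion_profile"))
    stop("arguments must be invasion_profile objects")
  if (!isTRUE(all.equal(profile_t$z_um, profile_0$z_um)))
    stop("z grids differ between profiles")
  h <- profile_t$mean_um - profile_0$mean_um
  if (h < 0) {
    warning("negative invasion distance (", signif(h, 3), " um) clipped to 0")
    h <- 0
  }
  h
}

#' Fit invasion kinetics H(t) = H0 (1 - exp(-t/tau))
#'
#' @param times_min at least 3 times starting at 0, minutes.
#' @param H_um invasion distances, um.
#' @param fix_scale optional fixed tau, minutes.
#' @return A [fit_saturating_exp()] result (`amplitude` = H0 in um,
#'   `scale` = tau in min).
#' @export
invasion_kinetics <- function(times_min, H_um, fix_scale = NULL) {
  if (length(times_min) < 3) stop("need at least 3 time points")
  if (times_min[1] != 0) stop("the series must start at t = 0")
  fit_saturating_exp(times_min, H_um, fix_scale = fix_scale,
                     axis_kind = "time_min")
}
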