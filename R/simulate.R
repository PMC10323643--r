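# Seeded generators for every input the pipeline consumes: drifting-circuit
# impedance spectra, fibril-network images with controllable pore scale,
# invading Gaussian cell plumes, and CIMI tables. All generators restore the
# caller's RNG state and are bit-reproducible for a fixed seed.

#' Simulate a drifting-circuit spectrum time series
#'
#' Generates spectra from the forward equivalent circuit with the cell and
#' seal resistances drifting linearly in time — the signature of cells lifting
#' off and migrating away from the electrodes — plus optional complex Gaussian
#' noise scaled by the local impedance magnitude.
#'
#' @param base_params [circuit_params()] at time 0.
#' @param rcell_slope,rseal_slope linear drifts of `R_cell`, `R_seal`, Ohm/min.
#' @param times_min sampling times, minutes.
#' @param frequencies_hz sweep grid, Hz.
#' @param noise_sd_rel relative noise SD; real and imaginary parts receive
#'   independent Gaussian noise with SD `noise_sd_rel * |Z|`.
#' @param seed integer seed (optional).
#' @param chamber_id chamber label.
#' @return List of [impedance_spectrum()].
#' @export
simulate_spectra_series <- function(base_params = default_circuit_params(),
                                    rcell_slope = 10, rseal_slope = 5,
                                    times_min = seq(0, 180, 30),
                                    frequencies_hz = default_frequency_grid(),
                                    noise_sd_rel = 0, seed = NULL,
                                    chamber_id = "A1") {
  base_params <- as_circuit_params(base_params)
  if (noise_sd_rel < 0) stop("noise_sd_rel must be non-negative")
  with_seed(seed, {
    lapply(times_min, function(t) {
      p <- unclass(base_params)
      p["R_cell"] <- p["R_cell"] + rcell_slope * t
      p["R_seal"] <- p["R_seal"] + rseal_slope * t
      if (p["R_cell"] <= 0 || p["R_seal"] <= 0)
        stop("parameter drift drives R_cell/R_seal non-positive at t = ",
             t, " min")
      z <- circuit_impedance(2 * pi * frequencies_hz,
                             structure(p, class = "circuit_params"))
      if (noise_sd_rel > 0) {
        sd <- noise_sd_rel * Mod(z)
        z <- z + complex(real = stats::rnorm(length(z), 0, sd),
                         imaginary = stats::rnorm(length(z), 0, sd))
      }
      impedance_spectrum(frequencies_hz, z, chamber_id = chamber_id,
                         time_min = t)
    })
  })
}

# One realisation of a random-chord fibril mask: n_chords thick lines with
# random orientation and offset; extra chords are appended one at a time until
# the fibril density target is reached.
draw_chord_mask <- function(size_px, half_width, n_chords, density_target) {
  xs <- seq_len(size_px) - (size_px + 1) / 2
  grid_x <- matrix(xs, size_px, size_px)
  grid_y <- matrix(xs, size_px, size_px, byrow = TRUE)
  mask <- matrix(FALSE, size_px, size_px)
  rho_max <- size_px / sqrt(2)
  add_chord <- function(mask) {
    theta <- stats::runif(1, 0, pi)
    rho <- stats::runif(1, -rho_max, rho_max)
    mask | (abs(grid_x * cos(theta) + grid_y * sin(theta) - rho) <= half_width)
  }
  for (i in seq_len(n_chords)) mask <- add_chord(mask)
  guard <- 0
  while (mean(mask) < density_target && guard < 10 * n_chords + 200) {
    mask <- add_chord(mask)
    guard <- guard + 1
  }
  mask
}

#' Simulate a fluorescent fibril-network image
#'
#' Draws random straight fibril segments (full-width chords of controllable
#' thickness) until the fibril area density reaches its target, while a small
#' calibration loop adjusts the fibril thickness so that the pipeline's own
#' 50%-rule mean pore diameter of the noiseless mask matches the requested
#' pore scale. Returns both the ground-truth mask and a Poisson-Gaussian noisy
#' image of it.
#'
#' @param size_px image side length, px.
#' @param fibril_density_target fibril area fraction in \[0, 1).
#' @param pore_diameter_target_px target mean pore diameter, px.
#' @param seed integer seed (optional).
#' @param fibril_level,background_level mean photon counts of the two phases.
#' @param gaussian_sd read-noise SD added on top of Poisson shot noise.
#' @param pixel_size_um physical pitch, um/px.
#' @param max_attempts calibration iterations before declaring the
#'   density/pore combination infeasible.
#' @return List with `image` (numeric matrix), `mask` (a [network_mask()]
#'   of the noiseless ground truth), `fibril_density`,
#'   `mean_pore_diameter_px`, `seed`.
#' @export
simulate_network_image <- function(size_px = 192,
                                   fibril_density_target = 0.12,
                                   pore_diameter_target_px = 15,
                                   seed = NULL, fibril_level = 200,
                                   background_level = 10, gaussian_sd = 5,
                                   pixel_size_um = 0.5, max_attempts = 6) {
  if (fibril_density_target < 0 || fibril_density_target >= 1)
    stop("fibril_density_target must be in [0, 1)")
  with_seed(seed, {
    noisy_image <- function(mask) {
      lambda <- ifelse(mask, fibril_level, background_level)
      img <- stats::rpois(length(lambda), lambda) +
        stats::rnorm(length(lambda), 0, gaussian_sd)
      matrix(pmax(img, 0), nrow(lambda), ncol(lambda))
    }
    if (fibril_density_target == 0) {
      mask <- matrix(FALSE, size_px, size_px)
      return(list(image = noisy_image(mask),
                  mask = network_mask(mask, pixel_size_um),
                  fibril_density = 0, mean_pore_diameter_px = NA_real_,
                  seed = seed))
    }
    half_width <- max(0.5,
                      fibril_density_target * pore_diameter_target_px / 4)
    measured <- NA_real_
    mask <- NULL
    for (attempt in seq_len(max_attempts)) {
      w <- 2 * half_width
      n_chords <- max(2, floor(0.9 * (-size_px / w) *
                                 log(1 - fibril_density_target)))
      mask <- draw_chord_mask(size_px, half_width, n_chords,
                              fibril_density_target)
      dmax <- max(7, 2 * ceiling(1.5 * pore_diameter_target_px))
      ladder <- unique(c(1, seq(3, dmax, 2)))
      mpd <- tryCatch(
        mean_pore_diameter(ladder, eroded_pore_area(
          network_mask(mask, pixel_size_um), ladder)),
        error = function(e) NA_real_)
      measured <- mpd
      if (is.finite(mpd) &&
          abs(mpd - pore_diameter_target_px) <=
            0.1 * pore_diameter_target_px) break
      adj <- if (is.finite(mpd)) pore_diameter_target_px / mpd else 1.5
      half_width <- min(max(half_width * adj, 0.5), size_px / 4)
      if (attempt == max_attempts &&
          (!is.finite(measured) ||
           abs(measured - pore_diameter_target_px) >
             0.3 * pore_diameter_target_px))
        stop("infeasible density/pore-size combination after ",
             max_attempts, " calibration attempts (last pore size: ",
             signif(measured, 3), " px)")
    }
    list(image = noisy_image(mask),
         mask = network_mask(mask, pixel_size_um),
         fibril_density = mean(mask), mean_pore_diameter_px = measured,
         seed = seed)
  })
}

#' Simulate invading Gaussian cell plumes as volumetric stacks
#'
#' Places `n_cells` point sources per time with heights drawn from a Gaussian
#' centred at `base_um + H(t)`, `H(t) = H0 (1 - exp(-t/tau))`, truncated to
#' the stack, and renders each as a Gaussian-blurred spot along z at a random
#' lateral position.
#'
#' @param H0_um plateau invasion distance, um.
#' @param tau_min characteristic time, min (may be `Inf` for a stationary
#'   plume).
#' @param sd_um plume SD along z, um.
#' @param n_cells number of labelled cells per stack.
#' @param times_min acquisition times, min.
#' @param stack_shape `(z, y, x)` voxel counts.
#' @param voxel_size_um `(z, y, x)` pitches, um.
#' @param base_um plume centre height at t = 0, um.
#' @param psf_sd_um axial blur SD, um.
#' @param seed integer seed (optional).
#' @param chamber_id chamber label.
#' @return List of [volumetric_stack()].
#' @export
simulate_invasion_stacks <- function(H0_um = 100, tau_min = 100, sd_um = 10,
                                     n_cells = 200,
                                     times_min = seq(0, 180, 30),
                                     stack_shape = c(31, 32, 32),
                                     voxel_size_um = c(5, 1, 1),
                                     base_um = 20, psf_sd_um = 2,
                                     seed = NULL, chamber_id = "A1") {
  z_max <- (stack_shape[1] - 1) * voxel_size_um[1]
  h_of <- function(t) if (is.infinite(tau_min)) 0 else
    H0_um * (1 - exp(-t / tau_min))
  centres <- base_um + vapply(times_min, h_of, numeric(1))
  if (any(centres < 0 | centres > z_max))
    stop("plume centre exceeds the stack (0-", z_max, " um) at t = ",
         times_min[which(centres < 0 | centres > z_max)[1]], " min")
  z_planes <- (seq_len(stack_shape[1]) - 1) * voxel_size_um[1]
  with_seed(seed, {
    lapply(seq_along(times_min), function(i) {
      vox <- array(0, dim = stack_shape)
      if (n_cells > 0) {
        # truncated-normal heights keep every cell inside the stack
        lo <- stats::pnorm(0, centres[i], sd_um)
        hi <- stats::pnorm(z_max, centres[i], sd_um)
        z_cells <- stats::qnorm(stats::runif(n_cells, lo, hi),
                                centres[i], sd_um)
        y_cells <- sample.int(stack_shape[2], n_cells, replace = TRUE)
        x_cells <- sample.int(stack_shape[3], n_cells, replace = TRUE)
        for (k in seq_len(n_cells)) {
          prof <- exp(-(z_planes - z_cells[k])^2 / (2 * psf_sd_um^2))
          vox[, y_cells[k], x_cells[k]] <-
            vox[, y_cells[k], x_cells[k]] + prof
        }
      }
      volumetric_stack(vox, voxel_size_um = voxel_size_um,
                       time_min = times_min[i], chamber_id = chamber_id)
    })
  })
}

#' Simulate a CIMI table from a saturating-exponential truth
#'
#' Generates replicated CIMI responses from `A (1 - exp(-x/s))` (time or
#' distance axis) or `A (1 - exp(-k c))` (dose axis) with i.i.d. Gaussian
#' noise. The response at covariate 0 is exactly 0, as it is by construction
#' in the measured index (baseline compared with itself).
#'
#' @param model_kind `"time"`, `"distance"`, or `"dose"`.
#' @param amplitude plateau A.
#' @param scale_or_rate e-folding scale (time/distance axes) or rate k per nM
#'   (dose axis).
#' @param design_points non-negative covariate values.
#' @param noise_sd Gaussian noise SD on the response.
#' @param n_replicates number of replicates.
#' @param seed integer seed (optional).
#' @return Data frame with columns `replicate_id`, `axis_kind`, `axis_value`,
#'   `psi`.
#' @export
simulate_cimi_table <- function(model_kind = c("time", "distance", "dose"),
                                amplitude, scale_or_rate, design_points,
                                noise_sd = 0.02, n_replicates = 1,
                                seed = NULL) {
  model_kind <- match.arg(model_kind)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (any(design_points < 0)) stop("design points must be non-negative")
  axis_kind <- switch(model_kind, time = "time_min", distance = "distance_um",
                      dose = "concentration_nM")
  scale <- if (model_kind == "dose") 1 / scale_or_rate else scale_or_rate
  mu <- satexp_model(design_points, amplitude, scale)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      y <- mu + stats::rnorm(length(mu), 0, noise_sd)
      y[design_points == 0] <- 0
      data.frame(replicate_id = sprintf("r%d", r), axis_kind = axis_kind,
                 axis_value = design_points, psi = y,
                 stringsAsFactors = FALSE)
    }))
  })
}
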