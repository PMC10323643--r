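# Collagen-network topology from fluorescence images.
#
# Pore sizes are quantified by morphological opening of the pore phase with
# discrete disks of growing diameter: the opened set is exactly the union of
# all disk placements that fit inside the pores ("filling the pores with
# disks"), and the filled-area fraction versus disk diameter is a cumulative
# pore-size ladder. The mean pore diameter is read off where the filled
# fraction crosses 50%.

#' Binary fibril/pore mask
#'
#' @param pixels logical matrix, `TRUE` = fibril, `FALSE` = pore.
#' @param pixel_size_um physical pixel pitch, um/px.
#' @return Object of class `"network_mask"`.
#' @export
network_mask <- function(pixels, pixel_size_um = 1) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!is.logical(pixels)) pixels <- pixels > 0
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("Network mask %d x %d px (%.3g um/px), fibril fraction %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              mean(x$pixels)))
  invisible(x)
}

#' Discrete disk structuring element
#'
#' Pixel `(dx, dy)` belongs to the element of diameter `d` iff its centre lies
#' within Euclidean distance `d/2` of the element centre; diameter 1 is the
#' single-pixel element.
#'
#' @param d disk diameter in pixels, >= 1.
#' @return 0/1 matrix of odd side length.
#' @export
disk_kernel <- function(d) {
  if (d < 1) stop("disk diameter must be >= 1")
  r <- floor(d / 2)
  idx <- -r:r
  outer(idx, idx, function(dx, dy) as.numeric(sqrt(dx^2 + dy^2) <= d / 2))
}

#' Segment a fluorescence image into fibril and pore phases
#'
#' Applies an automatic global (between-class-variance) threshold, optionally
#' after subtracting a smooth background estimate (a wide Gaussian blur,
#' floored at zero). Fibrils are the bright phase unless `invert = TRUE`.
#'
#' @param image numeric matrix of intensities.
#' @param pixel_size_um physical pixel pitch, um/px.
#' @param invert set `TRUE` when fibrils are the dark phase.
#' @param bg_sigma_px standard deviation (px) of the Gaussian background
#'   estimate; 0 (default) disables background subtraction.
#' @return A [network_mask()].
#' @export
binarize <- function(image, pixel_size_um = 1, invert = FALSE,
                     bg_sigma_px = 0) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (diff(range(image)) == 0)
    stop("constant image cannot be segmented")
  img <- image
  if (bg_sigma_px > 0) {
    bg <- EBImage::gblur(EBImage::Image(img), sigma = bg_sigma_px)
    img <- pmax(img - as.matrix(EBImage::imageData(bg)), 0)
    if (diff(range(img)) == 0)
      stop("image is constant after background subtraction")
  }
  img01 <- (img - min(img)) / diff(range(img))
  thr <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
  fibril <- if (invert) img01 < thr else img01 > thr
  network_mask(fibril, pixel_size_um)
}

#' Filled pore-area fractions over a disk-diameter ladder
#'
#' For each diameter `d`, the pore phase is morphologically opened with the
#' disk of diameter `d` and the fraction of pore area covered by the opening
#' is reported. The opening is computed through exact Euclidean distance
#' transforms: a disk centred at pixel `p` fits iff no fibril pixel lies
#' within distance `d/2` of `p`, and the opened set is the union of all
#' fitting placements — every pore pixel within `d/2` of some fitting centre.
#' Unlike openings with sampled discrete kernels, this family of openings is
#' a proper granulometry, so fractions are in \[0, 1\], equal 1 at `d = 1`,
#' and are non-increasing in `d`; the opened set is always a subset of the
#' pore phase.
#'
#' @param mask a [network_mask()].
#' @param disk_diameters_px strictly increasing diameters, >= 1.
#' @return Numeric vector of filled fractions, named by diameter.
#' @export
eroded_pore_area <- function(mask, disk_diameters_px = c(1, 5, 10, 15)) {
  if (!inherits(mask, "network_mask")) stop("mask must be a network_mask")
  d <- disk_diameters_px
  if (any(d < 1)) stop("disk diameters must be >= 1")
  if (any(diff(d) <= 0)) stop("disk diameters must be strictly increasing")
  pore <- !mask$pixels
  if (!any(pore) || all(pore))
    stop("mask must contain both pore and fibril pixels")
  pore_area <- sum(pore)
  # distance from each pixel to the nearest fibril pixel
  dist_to_fibril <- as.matrix(EBImage::distmap(
    matrix(as.numeric(pore), nrow(pore), ncol(pore))))
  fractions <- vapply(d, function(di) {
    if (di > max(dim(pore))) {
      warning("disk diameter ", di, " exceeds image size; fraction set to 0")
      return(0)
    }
    r <- di / 2
    centres <- dist_to_fibril > r          # erosion: the disk fits here
    if (!any(centres)) return(0)
    dist_to_centres <- as.matrix(EBImage::distmap(
      matrix(as.numeric(!centres), nrow(pore), ncol(pore))))
    opened <- dist_to_centres <= r         # dilation back to the opening
    sum(opened & pore) / pore_area
  }, numeric(1))
  # Lattice openings with integer disk centres are not a perfect
  # granulometry: a wider disk can occasionally cover pixels a narrower one
  # misses, because the intermediate (continuous) centres do not exist on the
  # grid. The continuous-space coverable area at diameter d is bounded below
  # by every lattice opening at d' >= d, so the running maximum from the
  # right is the tightest lattice estimate and is non-increasing by
  # construction.
  fractions <- rev(cummax(rev(fractions)))
  stats::setNames(fractions, d)
}

#' Mean pore diameter by the 50% filled-area rule
#'
#' The mean pore diameter is the structuring-element diameter at which half
#' the pore area remains coverable, obtained by piecewise-linear interpolation
#' of the filled-fraction ladder at 0.5.
#'
#' @param disk_diameters_px ladder diameters, strictly increasing.
#' @param filled_fractions non-increasing filled-area fractions.
#' @return Interpolated diameter in pixels.
#' @examples
#' mean_pore_diameter(c(1, 5, 10, 15), c(0.9339, 0.6745, 0.3684, 0.2051))
#' @export
mean_pore_diameter <- function(disk_diameters_px, filled_fractions) {
  d <- disk_diameters_px; fr <- filled_fractions
  if (length(d) != length(fr)) stop("ladder vectors must have equal length")
  if (length(d) < 2) stop("need at least 2 ladder points")
  if (any(diff(fr) > 1e-9))
    stop("filled fractions must be non-increasing in diameter")
  if (min(fr) > 0.5 || max(fr) < 0.5)
    stop("the ladder does not bracket 50% filled area; ",
         "widen the diameter ladder")
  i <- which(fr <= 0.5)[1]
  if (fr[i] == 0.5) return(unname(d[i]))
  # interpolate between the bracketing pair (fr[i-1] > 0.5 >= fr[i])
  unname(d[i - 1] +
           (fr[i - 1] - 0.5) / (fr[i - 1] - fr[i]) * (d[i] - d[i - 1]))
}

#' Pore-size ladder analysis of a network mask
#'
#' Convenience wrapper running [eroded_pore_area()] over a (by default fine,
#' odd 1-31 px) diameter ladder and applying the 50% rule, with the result in
#' both pixel and physical units.
#'
#' @param mask a [network_mask()].
#' @param disk_diameters_px ladder; the coarse instrument ladder
#'   `c(1, 5, 10, 15)` can be passed for fidelity runs.
#' @return Object of class `"pore_ladder"`: `disk_diameters_px`,
#'   `filled_fractions`, `mean_pore_diameter_px`, `mean_pore_diameter_um`.
#' @export
pore_size_ladder <- function(mask, disk_diameters_px = seq(1, 31, 2)) {
  fr <- eroded_pore_area(mask, disk_diameters_px)
  mpd <- mean_pore_diameter(disk_diameters_px, fr)
  structure(list(disk_diameters_px = disk_diameters_px,
                 filled_fractions = unname(fr),
                 mean_pore_diameter_px = mpd,
                 mean_pore_diameter_um = mpd * mask$pixel_size_um),
            class = "pore_ladder")
}

#' @export
print.pore_ladder <- function(x, ...) {
  cat(sprintf("Pore-size ladder (%d diameters): mean pore diameter %.3g px = %.3g um\n",
              length(x$disk_diameters_px), x$mean_pore_diameter_px,
              x$mean_pore_diameter_um))
  invisible(x)
}

#' @export
plot.pore_ladder <- function(x, ...) {
  graphics::plot(x$disk_diameters_px, 100 * x$filled_fractions, type = "b",
                 xlab = "disk diameter (px)", ylab = "filled pore area (%)",
                 ...)
  graphics::abline(h = 50, lty = 2)
  graphics::abline(v = x$mean_pore_diameter_px, lty = 3, col = 2)
  invisible(x)
}

#' Fibril volume fraction
#'
#' Fraction of fibril pixels, averaged over the slices of a stack of masks.
#'
#' @param masks a [network_mask()] or a list of them.
#' @return Mean fibril fraction in \[0, 1\].
#' @export
fibril_content <- function(masks) {
  if (inherits(masks, "network_mask")) masks <- list(masks)
  if (length(masks) < 1) stop("need at least one mask")
  mean(vapply(masks, function(m) {
    if (!inherits(m, "network_mask")) stop("all elements must be network_mask")
    mean(m$pixels)
  }, numeric(1)))
}
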