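#' Equivalent-circuit parameter vector
#'
#' Constructs the nine-element parameter vector of the interdigitated-electrode
#' equivalent circuit: the electrode interface (a constant-phase element in
#' parallel with a charge-transfer resistance), the culture-medium resistance,
#' the collagen-matrix RC block, and the cell block (seal resistance, cell
#' resistance and cell capacitance in three-way parallel).
#'
#' @param R_ccm culture-medium resistance, Ohm.
#' @param R_ECM matrix (ECM) resistance, Ohm.
#' @param C_ECM matrix capacitance, F.
#' @param R_seal seal resistance of the cell layer over the electrodes, Ohm.
#' @param R_cell cell resistance, Ohm.
#' @param C_cell cell capacitance, F.
#' @param R_ct charge-transfer resistance of the electrode interface, Ohm.
#' @param Q constant-phase-element magnitude, S s^n.
#' @param n constant-phase-element exponent, dimensionless, in \[0, 1\];
#'   `n = 1` is an ideal capacitor, `n = 0` a resistor.
#' @return A named numeric vector of class `"circuit_params"`.
#' @seealso [circuit_impedance()], [fit_circuit()]
#' @examples
#' p <- circuit_params(R_ccm = 500, R_ECM = 2000, C_ECM = 1e-9,
#'                     R_seal = 3000, R_cell = 5000, C_cell = 1e-9,
#'                     R_ct = 1e5, Q = 1e-6, n = 0.8)
#' circuit_impedance(2 * pi * 1e4, p)
#' @export
circuit_params <- function(R_ccm, R_ECM, C_ECM, R_seal, R_cell, C_cell,
                           R_ct, Q, n) {
  p <- c(R_ccm = R_ccm, R_ECM = R_ECM, C_ECM = C_ECM, R_seal = R_seal,
         R_cell = R_cell, C_cell = C_cell, R_ct = R_ct, Q = Q, n = n)
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

#' @rdname circuit_params
#' @param p a named numeric vector with the nine parameter names.
#' @export
as_circuit_params <- function(p) {
  p <- p[circuit_param_names()]
  if (anyNA(p)) stop("missing circuit parameter(s): ",
                     paste(circuit_param_names()[is.na(p)], collapse = ", "))
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

circuit_param_names <- function() {
  c("R_ccm", "R_ECM", "C_ECM", "R_seal", "R_cell", "C_cell", "R_ct", "Q", "n")
}

validate_circuit_params <- function(p) {
  pos <- p[setdiff(circuit_param_names(), "n")]
  if (any(!is.finite(p))) stop("circuit parameters must be finite")
  if (any(pos <= 0))
    stop("all resistances, capacitances and Q must be strictly positive; ",
         "offending: ", paste(names(pos)[pos <= 0], collapse = ", "))
  if (p[["n"]] < 0 || p[["n"]] > 1)
    stop("CPA exponent n must satisfy 0 <= n <= 1, got ", p[["n"]])
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters:\n")
  print(format(unclass(x), digits = 4), quote = FALSE)
  invisible(x)
}

#' Constant-phase-element impedance
#'
#' Impedance of a constant-phase element, `1 / (Q (j w)^n)`. Its phase is
#' frequency-independent at `-n * 90` degrees; `n = 0` reduces to a resistor
#' of value `1/Q` and `n = 1` to an ideal capacitor of capacitance `Q`.
#'
#' @param omega angular frequency, rad/s (vectorised); must be positive.
#' @param Q element magnitude, S s^n; must be positive.
#' @param n element exponent in \[0, 1\].
#' @return Complex impedance in Ohm, one value per `omega`.
#' @examples
#' cpa_impedance(1e4, Q = 1e-6, n = 0.5)  # |Z| = 1e4, phase -45 deg
#' @export
cpa_impedance <- function(omega, Q, n) {
  if (any(omega <= 0)) stop("omega must be strictly positive")
  if (Q <= 0) stop("Q must be strictly positive")
  if (n < 0 || n > 1) stop("n must lie in [0, 1]")
  1 / (Q * (1i * omega)^n)
}

#' Forward equivalent-circuit impedance
#'
#' Evaluates the complex impedance of the chip's equivalent circuit as the
#' series sum of four blocks: the electrode interface (charge-transfer
#' resistance in parallel with the constant-phase element), the culture-medium
#' resistance, the matrix RC block, and the cell block (seal resistance, cell
#' resistance and cell capacitance in three-way parallel).
#'
#' @param omega angular frequency, rad/s (vectorised); must be positive.
#' @param params a [circuit_params()] vector.
#' @return Complex impedance in Ohm, one value per `omega`.
#' @export
circuit_impedance <- function(omega, params) {
  if (any(omega <= 0)) stop("omega must be strictly positive")
  p <- as_circuit_params(params)
  zcpa <- cpa_impedance(omega, p[["Q"]], p[["n"]])
  interface <- p[["R_ct"]] * zcpa / (p[["R_ct"]] + zcpa)
  ecm <- p[["R_ECM"]] / (1i * omega * p[["C_ECM"]] * p[["R_ECM"]] + 1)
  rs <- p[["R_seal"]]; rc <- p[["R_cell"]]
  cell <- rs * rc / (1i * omega * p[["C_cell"]] * rs * rc + rs + rc)
  interface + p[["R_ccm"]] + ecm + cell
}

#' Impedance spectrum container
#'
#' One frequency sweep of complex impedance for one chip chamber at one time
#' point. Frequencies are in Hz (the instrument's convention); the angular
#' frequency `w = 2 pi f` is used internally by the circuit model.
#'
#' @param frequencies_hz strictly increasing positive sweep grid, Hz.
#' @param z complex impedance per frequency, Ohm.
#' @param chamber_id chamber identifier.
#' @param time_min sampling time, minutes.
#' @return An object of class `"impedance_spectrum"`.
#' @export
impedance_spectrum <- function(frequencies_hz, z, chamber_id = "A1",
                               time_min = 0) {
  if (length(frequencies_hz) != length(z))
    stop("frequencies_hz and z must have equal length")
  if (length(frequencies_hz) < 2)
    stop("a spectrum needs at least 2 frequency points")
  if (any(frequencies_hz <= 0)) stop("frequencies must be positive")
  if (any(diff(frequencies_hz) <= 0))
    stop("frequencies must be strictly increasing")
  if (any(!is.finite(z)))
    stop("non-finite impedance values in spectrum")
  structure(list(chamber_id = as.character(chamber_id),
                 time_min = as.numeric(time_min),
                 frequencies_hz = as.numeric(frequencies_hz),
                 z = as.complex(z)),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: chamber %s, t = %g min, %d points (%g-%g Hz)\n",
              x$chamber_id, x$time_min, length(x$z),
              min(x$frequencies_hz), max(x$frequencies_hz)))
  invisible(x)
}

# Default instrument sweep: 50 log-spaced points over the 10-100 kHz band.
#' Default frequency sweep grid
#'
#' 50 log-spaced frequencies spanning 10-100 kHz, the band in which the chip's
#' impedance is most sensitive to 3D cell motion.
#'
#' @param n_points number of points.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_frequency_grid <- function(n_points = 50) {
  10^seq(log10(1e4), log10(1e5), length.out = n_points)
}

#' Default equivalent-circuit parameters
#'
#' Physically plausible magnitudes for a cell-covered interdigitated-electrode
#' chamber, used as the simulation baseline. No measured parameter table is
#' bundled; these are placeholders with realistic orders of magnitude.
#'
#' @return A [circuit_params()] vector.
#' @export
default_circuit_params <- function() {
  circuit_params(R_ccm = 500, R_ECM = 2000, C_ECM = 3e-9,
                 R_seal = 3000, R_cell = 5000, C_cell = 1e-9,
                 R_ct = 5e4, Q = 1e-8, n = 0.8)
}
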