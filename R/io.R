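# File dialects: long-format spectra CSV, CIMI tables, multi-page grayscale
# TIFF stacks, JSON fit records, YAML run configuration. All CSVs are comma
# separated, '.' decimal, UTF-8, header mandatory.

SPECTRA_COLUMNS <- c("chamber_id", "time_min", "frequency_hz",
                     "z_real_ohm", "z_imag_ohm")
CIMI_COLUMNS <- c("replicate_id", "axis_kind", "axis_value", "psi")
SCHEMA_VERSION <- "1"

#' Read an impedance-spectra CSV
#'
#' Long format with columns `chamber_id, time_min, frequency_hz, z_real_ohm,
#' z_imag_ohm`; rows are grouped by `(chamber_id, time_min)` and sorted by
#' frequency within each spectrum.
#'
#' @param path CSV file path.
#' @return List of [impedance_spectrum()], ordered by chamber then time.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(SPECTRA_COLUMNS, names(df))
  if (length(missing))
    stop("spectra CSV is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("time_min", "frequency_hz", "z_real_ohm", "z_imag_ohm")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric value in column '", col, "' at data row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  key <- paste(df$chamber_id, df$time_min, df$frequency_hz, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (chamber, time, frequency) row(s), first at data row ",
         which(duplicated(key))[1])
  groups <- split(df, list(df$chamber_id, df$time_min), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$frequency_hz), ]
    impedance_spectrum(g$frequency_hz,
                       complex(real = g$z_real_ohm, imaginary = g$z_imag_ohm),
                       chamber_id = g$chamber_id[1], time_min = g$time_min[1])
  })
  ord <- order(vapply(out, function(s) s$chamber_id, character(1)),
               vapply(out, function(s) s$time_min, numeric(1)))
  unname(out[ord])
}

#' Write impedance spectra to CSV
#'
#' @param spectra list of [impedance_spectrum()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "impedance_spectrum")) spectra <- list(spectra)
  rows <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(chamber_id = s$chamber_id, time_min = s$time_min,
               frequency_hz = s$frequencies_hz,
               z_real_ohm = Re(s$z), z_imag_ohm = Im(s$z),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write CIMI tables
#'
#' Columns: `replicate_id, axis_kind, axis_value, psi`.
#'
#' @param path CSV path.
#' @return `read_cimi_csv`: a data frame with the four columns.
#' @export
read_cimi_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(CIMI_COLUMNS, names(df))
  if (length(missing))
    stop("CIMI CSV is missing column(s): ", paste(missing, collapse = ", "))
  df[CIMI_COLUMNS]
}

#' @rdname read_cimi_csv
#' @param table data frame with the CIMI columns.
#' @export
write_cimi_csv <- function(table, path) {
  utils::write.csv(table[CIMI_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a grayscale TIFF stack
#'
#' Accepts single- or multi-page 8/16-bit grayscale TIFF; page order becomes
#' z order with page 1 as the electrode plane.
#'
#' @param path TIFF path.
#' @param voxel_size_um `(z, y, x)` pitches, um.
#' @param time_min acquisition time for the stack's metadata.
#' @param chamber_id chamber label.
#' @return A [volumetric_stack()].
#' @export
read_stack_tiff <- function(path, voxel_size_um = c(5, 1, 1), time_min = 0,
                            chamber_id = "A1") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("TIFF contains no pages")
  if (any(vapply(pages, function(p) length(dim(p)) != 2, logical(1))))
    stop("unsupported TIFF format: expected 2D grayscale pages")
  vox <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  volumetric_stack(vox, voxel_size_um = voxel_size_um, time_min = time_min,
                   chamber_id = chamber_id)
}

#' Write a stack (or a 2D image) as 16-bit grayscale TIFF
#'
#' Intensities are rounded and clipped to the 16-bit range, so round trips are
#' exact for integer-valued stacks up to 65535.
#'
#' @param stack a [volumetric_stack()] or a numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  vox <- if (inherits(stack, "volumetric_stack")) stack$voxels else
    array(stack, dim = c(1, nrow(stack), ncol(stack)))
  vox <- pmin(pmax(round(vox), 0), 65535)
  pages <- lapply(seq_len(dim(vox)[1]), function(i) vox[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Serialize circuit-fit results to JSON
#'
#' One record per (chamber, time) with all nine parameters, the cost, and the
#' convergence flag, under a `schema_version` field.
#'
#' @param fits a [fit_circuit()] result or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "circuit_fit")) fits <- list(fits)
  recs <- lapply(fits, function(f) {
    c(list(chamber_id = f$spectrum$chamber_id,
           time_min = f$spectrum$time_min),
      as.list(unclass(f$params)),
      list(cost = f$cost, converged = f$converged))
  })
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION, fits = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- run configuration ------------------------------------------------------

known_config_keys <- function() {
  c("seed", "weighting", "cimi_mode", "ladder", "pixel_size_um",
    "voxel_size_um", "fix_scale", "bin_min", "log_level", "out_dir")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected by name so that typos never silently change a
#' run.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), known_config_keys())
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Write a provenance record beside an output file
#'
#' Echoes the effective configuration together with the package version and a
#' timestamp, as `<out>.provenance.json`.
#'
#' @param out_path the output file the record describes.
#' @param config named list of effective settings.
#' @return Provenance path, invisibly.
#' @export
write_provenance <- function(out_path, config = list()) {
  prov <- list(schema_version = SCHEMA_VERSION,
               tool = "cima3d",
               version = as.character(utils::packageVersion("cima3d")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = config)
  p <- paste0(out_path, ".provenance.json")
  jsonlite::write_json(prov, p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
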