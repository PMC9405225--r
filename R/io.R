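#' Path to a packaged example / fixture file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return Full path (or character vector of file names).
#' @export
#' @examples
#' vwoxy_example()
vwoxy_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "vwoxy")))
  }
  path <- system.file("extdata", file, package = "vwoxy")
  if (path == "") stop("vwoxy_example(): no packaged file called ", file, call. = FALSE)
  path
}

#' Read a delimited numeric table with a declared schema
#'
#' Comma- or tab-delimited text with a header row; the delimiter is
#' auto-detected from the header. Columns listed in `required` must be
#' present; all `numeric_cols` (default: every required column) are strictly
#' type-checked, with the offending file, column and row reported on
#' failure.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers.
#' @return data.frame.
#' @export
read_table <- function(path, required = character(), numeric_cols = required) {
  if (!file.exists(path)) stop("read_table(): no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", fill = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("read_table(): %s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (cc in intersect(numeric_cols, names(df))) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        bad <- which(is.na(num))[1]
        stop(sprintf("read_table(): %s: column '%s', row %d: non-numeric value '%s'",
                     path, cc, bad, v[bad]), call. = FALSE)
      }
      df[[cc]] <- num
    }
  }
  df
}

#' Write a table as delimited text
#'
#' Comma-separated, header row, period decimal separator regardless of
#' locale, no row names. Inputs are never modified; the output is a new
#' file.
#'
#' @param x data.frame.
#' @param path Output path.
#' @param sep Field separator; default ",".
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, sep = ",") {
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the contact-area table
#'
#' Parses the packaged (or user) working-volume / contact-area table into a
#' tidy data.frame with SI helpers.
#'
#' @param path Path to a CSV with columns `volume_mL`, `area_cm2`,
#'   `specific_area_m1`; defaults to the packaged table.
#' @return data.frame with the three columns plus `V_m3` and `A_m2`.
#' @export
read_area_table <- function(path = vwoxy_example("table1_contact_areas.csv")) {
  df <- read_table(path, required = c("volume_mL", "area_cm2", "specific_area_m1"))
  df$V_m3 <- df$volume_mL * 1e-6
  df$A_m2 <- df$area_cm2 * 1e-4
  df
}

#' Read a Sherwood-constants table
#'
#' Parses a constants table laid out one row per constant (k, alpha, beta,
#' gamma) and one column per provenance, into a named list of
#' [sherwood_constants()].
#'
#' @param path CSV path; defaults to the packaged table with columns
#'   `constant`, `experimental`, `simulation`, `adjusted`.
#' @return Named list of [sherwood_constants()], one per non-`constant`
#'   column.
#' @export
#' @examples
#' read_sherwood_constants()$experimental
read_sherwood_constants <- function(path = vwoxy_example("table3_sherwood_constants.csv")) {
  df <- read_table(path, required = "constant", numeric_cols = character())
  sets <- setdiff(names(df), "constant")
  rows <- df$constant
  out <- lapply(sets, function(s) {
    v <- stats::setNames(as.numeric(df[[s]]), rows)
    sherwood_constants(v[["k"]], v[["alpha"]], beta = v[["beta"]],
                       gamma = v[["gamma"]], provenance = s)
  })
  stats::setNames(out, sets)
}

#' Read a pre-extracted intensity trace
#'
#' @param path CSV/TSV with columns `time_s`, `intensity`.
#' @param I_max,I_min Optional plateau intensities.
#' @return An [intensity_trace()].
#' @export
read_trace_table <- function(path, I_max = NULL, I_min = NULL) {
  df <- read_table(path, required = c("time_s", "intensity"))
  intensity_trace(df$time_s, df$intensity, I_max = I_max, I_min = I_min)
}

#' Read a long-format spectrum series
#'
#' @param path CSV/TSV with columns `time_s`, `wavelength_nm`, `counts`
#'   and optionally `dark` (per-wavelength dark spectrum, repeated per time
#'   point).
#' @return A [spectrum_series()].
#' @export
read_spectrum_table <- function(path) {
  df <- read_table(path, required = c("time_s", "wavelength_nm", "counts"))
  times <- sort(unique(df$time_s))
  wl <- sort(unique(df$wavelength_nm))
  m <- matrix(NA_real_, length(times), length(wl))
  ti <- match(df$time_s, times)
  wi <- match(df$wavelength_nm, wl)
  m[cbind(ti, wi)] <- df$counts
  if (anyNA(m)) {
    stop("read_spectrum_table(): ", path,
         ": the (time, wavelength) grid is ragged/incomplete", call. = FALSE)
  }
  dark <- rep(0, length(wl))
  if ("dark" %in% names(df)) {
    first <- df$time_s == times[1]
    dark <- df$dark[first][order(df$wavelength_nm[first])]
  }
  spectrum_series(times, wl, m, dark = dark)
}

#' Read a per-cell gradient-field table
#'
#' @param path CSV/TSV with columns `x`, `y`, `z`, `cell_volume`, the nine
#'   gradient components `dudx` ... `dwdz`, and optionally `k_sgs`, `nu_t`.
#' @param nu Molecular kinematic viscosity (m2/s).
#' @return A [gradient_field()].
#' @export
read_field_table <- function(path, nu) {
  df <- read_table(path, required = c("x", "y", "z", "cell_volume", grad_cols()))
  gradient_field(df, nu = nu)
}

#' Read a surface flux table
#'
#' @param path CSV/TSV with columns `area`, `dCdy` and optionally `D_ABt`.
#' @param C_sat,C_bulk_mean Interface and bulk concentrations (mol/m3).
#' @return A [surface_flux_field()].
#' @export
read_surface_table <- function(path, C_sat, C_bulk_mean) {
  df <- read_table(path, required = c("area", "dCdy"))
  surface_flux_field(df, C_sat = C_sat, C_bulk_mean = C_bulk_mean)
}

#' Default run configuration
#'
#' All pinned numerical choices of the pipeline in one serialisable list:
#' geometry (wheel diameter and the packaged area table), property-fit
#' coefficients, fit options, turbulence constants and the seed. Values
#' round-trip losslessly through [write_config()] / [read_config()].
#'
#' @param seed Integer seed recorded in the config.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    geometry = list(wheel_diameter_m = 0.0414,
                    area_table = "table1_contact_areas.csv"),
    properties = list(
      viscosity = list(model = "vogel",
                       coef = list(A = -3.7188, B = 578.919, C = -137.546)),
      density = list(model = "kell1975"),
      diffusivity = list(model = "linear", c0 = 1.155e-9, c1 = 4.5e-11),
      solubility = list(model = "benson_krause1984", pO2_atm = 0.2095)
    ),
    fit = list(beta = 1 / 3, objective = "linear",
               kla_bracket_s = c(1e-6, 1e-1), kla_tol = 1e-10,
               fix_endpoints = TRUE),
    turbulence = list(Cw = 0.325, C_eps = 1.034, Sc_t = 1.34,
                      ke_ratio_threshold = 0.8,
                      eps_threshold_m2s3 = 0.5e-3,
                      literal_shear = FALSE),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `read_config()` returns the `run_config`; `write_config()` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
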