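#' Time-resolved luminescence spectra
#'
#' Container for a series of emission spectra acquired during an aeration
#' run: one spectrum (counts vs wavelength) per time point, plus the dark
#' reference spectrum subtracted during treatment.
#'
#' @param times Strictly increasing acquisition times (s).
#' @param wavelengths Strictly increasing wavelength grid (nm).
#' @param counts Matrix of intensities (counts), one row per time point,
#'   one column per wavelength.
#' @param dark Dark reference spectrum (counts), one value per wavelength.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(times, wavelengths, counts, dark = numeric(length(wavelengths))) {
  counts <- as.matrix(counts)
  stopifnot(all(diff(times) > 0), all(diff(wavelengths) > 0),
            nrow(counts) == length(times), ncol(counts) == length(wavelengths),
            length(dark) == length(wavelengths))
  structure(list(times = as.numeric(times), wavelengths = as.numeric(wavelengths),
                 counts = counts, dark = as.numeric(dark)),
            class = "spectrum_series")
}

#' Peak-intensity aeration trace
#'
#' The treated experimental signal: peak luminescence intensities over time
#' together with the plateau intensities at full deaeration (`I_max`) and at
#' saturation (`I_min`). Because dissolved oxygen quenches the dye, the
#' intensity decreases as oxygen enters the medium.
#'
#' @param times Strictly increasing times (s).
#' @param I_recorded Peak intensities (counts), one per time point.
#' @param I_max Intensity at full deaeration (counts); if `NULL` it must be
#'   set later (e.g. by [fit_kla()] plateau handling).
#' @param I_min Intensity at oxygen saturation (counts).
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(times, I_recorded, I_max = NULL, I_min = NULL) {
  stopifnot(all(diff(times) > 0), length(I_recorded) == length(times))
  if (!is.null(I_max) && !is.null(I_min)) stopifnot(I_max > I_min, I_min >= 0)
  structure(list(times = as.numeric(times), I_recorded = as.numeric(I_recorded),
                 I_max = I_max, I_min = I_min),
            class = "intensity_trace")
}

# centred moving average, window w points (w >= 1); shrinks at the edges
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- floor(w / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Extract a drift-corrected peak-intensity trace from spectra
#'
#' For each time point the dark spectrum is subtracted, the baseline drift
#' (slow additive offset from equipment temperature variations) is removed
#' by anchoring on an emission-free wavelength band, the spectrum is
#' smoothed with a centred moving average, and the maximum count within
#' `center +/- halfwidth` is taken as the peak intensity.
#'
#' @param series A [spectrum_series()].
#' @param center Peak wavelength (nm); default 608 nm, the dye emission peak.
#' @param halfwidth Half-width of the search window (nm); default 10 nm.
#' @param baseline_band Length-2 emission-free band (nm) whose mean count
#'   estimates the additive baseline at each time point; default c(450, 500).
#' @param smooth_points Moving-average window (points); default 30, matching
#'   the acquisition-side smoothing.
#' @return An [intensity_trace()] with `I_recorded` filled (plateaus unset).
#' @export
extract_peak <- function(series, center = 608, halfwidth = 10,
                         baseline_band = c(450, 500), smooth_points = 30) {
  stopifnot(inherits(series, "spectrum_series"))
  wl <- series$wavelengths
  if (center < min(wl) || center > max(wl)) {
    stop("extract_peak(): center outside the wavelength range", call. = FALSE)
  }
  win <- which(wl >= center - halfwidth & wl <= center + halfwidth)
  if (length(win) < 3) {
    stop("extract_peak(): fewer than 3 wavelength samples in the peak window",
         call. = FALSE)
  }
  base <- which(wl >= baseline_band[1] & wl <= baseline_band[2])
  peaks <- vapply(seq_along(series$times), function(i) {
    sp <- series$counts[i, ] - series$dark
    if (length(base) > 0) sp <- sp - mean(sp[base])
    sp <- moving_average(sp, smooth_points)
    max(sp[win])
  }, numeric(1))
  intensity_trace(series$times, peaks)
}

#' Aeration concentration profile (fixed kLa)
#'
#' Closed-form solution of dC/dt = kLa (C_sat - C) with C(0) = C0:
#' C(t) = C_sat - (C_sat - C0) exp(-kLa t). With the default C0 = 0 (absolute
#' deaeration) this is C_sat (1 - exp(-kLa t)).
#'
#' @param t Time(s) in s, >= 0.
#' @param kLa Volumetric mass-transfer coefficient (1/s), >= 0.
#' @param C_sat Saturation concentration (mol/m3).
#' @param C0 Initial concentration (mol/m3); default 0.
#' @return Concentration(s) in mol/m3.
#' @export
#' @examples
#' concentration_profile(1 / 2e-4, 2e-4, 0.26)  # 63.2% of saturation
concentration_profile <- function(t, kLa, C_sat, C0 = 0) {
  stopifnot(all(t >= 0), kLa >= 0, C_sat > 0, C0 >= 0)
  C_sat - (C_sat - C0) * exp(-kLa * t)
}

#' Integrate the aeration ODE for a (possibly time-varying) kLa
#'
#' Numerically integrates dC/dt = kLa(t) (C_sat - C) on the supplied time
#' grid with `deSolve`. For constant kLa the result agrees with
#' [concentration_profile()] to better than 1e-8 relative.
#'
#' @param kLa_of_t Function of time returning kLa (1/s), or a single number.
#' @param C_sat Saturation concentration (mol/m3).
#' @param t_grid Strictly increasing time grid (s) starting at the initial
#'   time.
#' @param C0 Initial concentration (mol/m3).
#' @return Numeric vector of concentrations on `t_grid`.
#' @export
integrate_aeration <- function(kLa_of_t, C_sat, t_grid, C0 = 0) {
  if (any(diff(t_grid) <= 0)) {
    stop("integrate_aeration(): time grid must be strictly increasing", call. = FALSE)
  }
  f <- if (is.function(kLa_of_t)) kLa_of_t else function(t) rep(kLa_of_t, length(t))
  if (any(f(t_grid) < 0)) {
    stop("integrate_aeration(): kLa(t) must be non-negative on the grid", call. = FALSE)
  }
  rhs <- function(t, y, parms) list(f(t) * (C_sat - y))
  out <- deSolve::ode(y = c(C = C0), times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  as.numeric(out[, "C"])
}

#' Modelled treated-intensity curve
#'
#' I_calculated(t) = (I_max - I_min) (1 - exp(-kLa t)): the treated-signal
#' analogue of the concentration profile, rising from 0 at t = 0 to the
#' full span I_max - I_min at saturation.
#'
#' @param t Time(s) in s.
#' @param kLa Volumetric mass-transfer coefficient (1/s).
#' @param I_max Intensity at full deaeration (counts).
#' @param I_min Intensity at saturation (counts).
#' @return Modelled treated intensities (counts).
#' @export
model_intensity <- function(t, kLa, I_max, I_min) {
  stopifnot(I_max > I_min)
  (I_max - I_min) * (1 - exp(-kLa * t))
}

#' Fit kLa to a luminescence aeration trace
#'
#' The recorded peaks are treated as I_treated = I_max - I_recorded (the
#' quenching inversion) and kLa is found by minimising
#' sum((I_treated - I_calculated)^2) over kLa > 0, where I_calculated is
#' [model_intensity()]. The search is a deterministic bounded scalar
#' minimisation on log(kLa) over \[1e-6, 1e-1\] 1/s.
#'
#' By default the plateau intensities are fixed from the data (median of the
#' leading/trailing plateau fractions) when not already present on the
#' trace, mirroring the experimental protocol; `fix_endpoints = FALSE`
#' instead treats I_max and I_min as free parameters of a 3-parameter
#' Levenberg-Marquardt fit.
#'
#' @param trace An [intensity_trace()] with >= 5 points.
#' @param a Specific interfacial area A/V (1/m) used to report kL = kLa / a.
#' @param fix_endpoints Keep I_max, I_min fixed (default) or fit them.
#' @param plateau_frac Fraction of leading/trailing points used for the
#'   plateau medians when the trace does not carry I_max / I_min.
#' @param bracket Search bracket for kLa (1/s).
#' @param tol Relative tolerance of the scalar search.
#' @return An object of class `kl_fit`: `kLa` (1/s), `kLa_h` (1/h),
#'   `kL` (m/s), `a`, `sse`, `n`, `I_max`, `I_min`, `residuals`,
#'   `boundary` (TRUE if the optimum sits on the search bracket) and
#'   `options`.
#' @export
#' @examples
#' syn <- gen_luminescence(trace_spec(kLa_true = 2 / 3600, seed = 1))
#' fit_kla(syn$trace, a = 16.4)
fit_kla <- function(trace, a, fix_endpoints = TRUE, plateau_frac = 0.05,
                    bracket = c(1e-6, 1e-1), tol = 1e-10) {
  stopifnot(inherits(trace, "intensity_trace"), a > 0)
  t <- trace$times
  n <- length(t)
  if (n < 5) stop("fit_kla(): need at least 5 time points", call. = FALSE)
  if (diff(range(trace$I_recorded)) == 0) {
    stop("fit_kla(): trace is constant; kLa is not estimable", call. = FALSE)
  }
  I_max <- trace$I_max
  I_min <- trace$I_min
  if (is.null(I_max)) {
    I_max <- stats::median(trace$I_recorded[seq_len(max(2, ceiling(plateau_frac * n)))])
  }
  if (is.null(I_min)) {
    I_min <- stats::median(trace$I_recorded[seq(n - max(2, ceiling(plateau_frac * n)) + 1, n)])
  }
  if (I_max <= I_min) {
    stop("fit_kla(): I_max must exceed I_min; trace does not decay", call. = FALSE)
  }
  t0 <- t - t[1]
  treated <- I_max - trace$I_recorded

  if (fix_endpoints) {
    sse_of <- function(lk) {
      sum((treated - model_intensity(t0, exp(lk), I_max, I_min))^2)
    }
    opt <- stats::optimize(sse_of, interval = log(bracket), tol = tol)
    kLa <- exp(opt$minimum)
    sse <- opt$objective
    boundary <- min(abs(opt$minimum - log(bracket))) < 1e-6
  } else {
    span0 <- I_max - I_min
    fit <- minpack.lm::nlsLM(
      treated ~ span * (1 - exp(-kla * t0)),
      start = list(span = span0, kla = 1 / max(t0[t0 > 0])),
      lower = c(1e-12, bracket[1]), upper = c(Inf, bracket[2]),
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 500))
    cf <- stats::coef(fit)
    kLa <- unname(cf[["kla"]])
    I_min <- I_max - unname(cf[["span"]])
    sse <- sum(stats::resid(fit)^2)
    boundary <- min(abs(kLa - bracket)) / kLa < 1e-6
  }
  res <- treated - model_intensity(t0, kLa, I_max, I_min)
  structure(list(kLa = kLa, kLa_h = kLa * 3600, kL = kLa / a, a = a,
                 sse = sse, n = n, I_max = I_max, I_min = I_min,
                 residuals = res, boundary = boundary,
                 options = list(fix_endpoints = fix_endpoints,
                                plateau_frac = plateau_frac,
                                bracket = bracket, tol = tol)),
            class = "kl_fit")
}

#' @export
print.kl_fit <- function(x, ...) {
  cat("kLa fit on", x$n, "points\n")
  cat(sprintf("  kLa = %.4g 1/s (%.3f 1/h)\n", x$kLa, x$kLa_h))
  cat(sprintf("  kL  = %.4g m/s (a = %.3g 1/m)\n", x$kL, x$a))
  cat(sprintf("  sse = %.4g counts^2\n", x$sse))
  if (isTRUE(x$boundary)) cat("  WARNING: optimum on the search bracket\n")
  invisible(x)
}
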