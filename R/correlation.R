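#' Sherwood-correlation constant set
#'
#' The constants (k, alpha, beta, gamma) of the modified power-law
#' correlation Sh = k Re^alpha Sc^beta G^gamma. The Schmidt exponent beta is
#' fixed at 1/3 by default, the standard mass-transfer value, which also
#' makes the correlation usable across culture temperatures.
#'
#' @param k Linear constant (> 0).
#' @param alpha Reynolds exponent.
#' @param beta Schmidt exponent; default 1/3.
#' @param gamma Geometric-number exponent.
#' @param provenance One of "experimental", "simulation", "adjusted" (or any
#'   free label) recording where the constants come from.
#' @return An object of class `sherwood_constants`.
#' @export
#' @examples
#' sherwood_constants(1.68, 0.551, gamma = 1.18, provenance = "experimental")
sherwood_constants <- function(k, alpha, beta = 1 / 3, gamma,
                               provenance = "experimental") {
  stopifnot(k > 0, is.finite(alpha), is.finite(beta), is.finite(gamma))
  structure(list(k = k, alpha = alpha, beta = beta, gamma = gamma,
                 provenance = provenance),
            class = "sherwood_constants")
}

#' @export
print.sherwood_constants <- function(x, ...) {
  cat(sprintf("Sherwood constants [%s]: Sh = %.4g Re^%.4g Sc^%.4g G^%.4g\n",
              x$provenance, x$k, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Correlation dataset of (Re, Sc, G, Sh) records
#'
#' @param records data.frame with positive columns `Re`, `Sc`, `G`, `Sh` and
#'   optionally `weight` plus condition metadata (`rpm`, `volume_mL`,
#'   `temperature_C`).
#' @return data.frame of class `correlation_dataset`.
#' @export
correlation_dataset <- function(records) {
  records <- as.data.frame(records)
  need <- c("Re", "Sc", "G", "Sh")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("correlation_dataset(): missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(records[need]) <= 0)) {
    stop("correlation_dataset(): all Re, Sc, G, Sh must be positive", call. = FALSE)
  }
  class(records) <- c("correlation_dataset", "data.frame")
  records
}

#' Predict Sherwood numbers from a constant set
#'
#' @param groups A [dimensionless_groups()] or data.frame with columns
#'   `Re`, `Sc`, `G`.
#' @param constants A [sherwood_constants()].
#' @return Sherwood number(s).
#' @export
predict_sherwood <- function(groups, constants) {
  stopifnot(all(c("Re", "Sc", "G") %in% names(groups)))
  with(constants, k * groups$Re^alpha * groups$Sc^beta * groups$G^gamma)
}

#' Fit the modified Sherwood correlation
#'
#' Least-squares fit of Sh = k Re^alpha Sc^beta G^gamma to a
#' [correlation_dataset()]. The default objective is the plain squared error
#' on Sh; a log-space objective (ordinary least squares on log Sh, an exact
#' linear solve) is available for diagnostics. The Schmidt exponent is fixed
#' at `beta` (default 1/3) unless `fix_beta = FALSE`, in which case beta is
#' fitted too.
#'
#' The linear-space fit is a deterministic Levenberg-Marquardt refinement
#' started from the log-space solution, so noise-free data are recovered to
#' numerical precision.
#'
#' @param data A [correlation_dataset()] (>= 4 records; more when beta is
#'   free).
#' @param fix_beta Fix the Schmidt exponent (default TRUE).
#' @param beta Value of the fixed Schmidt exponent.
#' @param objective "linear" (squared error on Sh; default) or "log"
#'   (squared error on log Sh).
#' @return A list of class `sherwood_fit`: `constants`
#'   ([sherwood_constants()]), `fitted`, `residuals`, `ape` (per-record
#'   absolute percentage errors, |pred - obs| / obs * 100), `mae` (their
#'   mean), `max_ape`, `sse`, `n`.
#' @export
#' @examples
#' ds <- gen_sherwood_dataset(sh_dataset_spec(seed = 1, noise_cv = 0))
#' fit_sherwood(ds)
fit_sherwood <- function(data, fix_beta = TRUE, beta = 1 / 3,
                         objective = c("linear", "log")) {
  objective <- match.arg(objective)
  data <- correlation_dataset(data)
  n <- nrow(data)
  npar <- if (fix_beta) 3L else 4L
  if (n < npar + 1L) {
    stop(sprintf("fit_sherwood(): need at least %d records to fit %d constants",
                 npar + 1L, npar), call. = FALSE)
  }
  lRe <- log(data$Re); lSc <- log(data$Sc); lG <- log(data$G); lSh <- log(data$Sh)
  if (stats::sd(lRe) < 1e-12 || stats::sd(lG) < 1e-12 ||
      (!fix_beta && stats::sd(lSc) < 1e-12)) {
    stop("fit_sherwood(): no variation in Re, G (or Sc with free beta); constants are not identifiable",
         call. = FALSE)
  }
  w <- if ("weight" %in% names(data)) data$weight else rep(1, n)

  # exact log-space OLS; global optimum of the log objective and the
  # deterministic starting point for the linear-space refinement
  if (fix_beta) {
    ols <- stats::lm((lSh - beta * lSc) ~ lRe + lG, weights = w)
    start <- list(k = exp(stats::coef(ols)[[1]]), alpha = stats::coef(ols)[[2]],
                  gamma = stats::coef(ols)[[3]])
  } else {
    ols <- stats::lm(lSh ~ lRe + lSc + lG, weights = w)
    start <- list(k = exp(stats::coef(ols)[[1]]), alpha = stats::coef(ols)[[2]],
                  beta = stats::coef(ols)[[3]], gamma = stats::coef(ols)[[4]])
  }

  if (objective == "log") {
    cst <- sherwood_constants(start$k, start$alpha,
                              beta = if (fix_beta) beta else start$beta,
                              gamma = start$gamma, provenance = "fitted(log)")
  } else {
    Re <- data$Re; Sc <- data$Sc; G <- data$G; Sh <- data$Sh
    if (fix_beta) {
      fit <- minpack.lm::nlsLM(
        Sh ~ k * Re^alpha * Sc^beta * G^gamma,
        start = start, weights = w,
        control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                             maxiter = 1000))
    } else {
      fit <- minpack.lm::nlsLM(
        Sh ~ k * Re^alpha * Sc^beta2 * G^gamma,
        start = list(k = start$k, alpha = start$alpha, beta2 = start$beta,
                     gamma = start$gamma),
        weights = w,
        control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                             maxiter = 1000))
    }
    cf <- stats::coef(fit)
    cst <- sherwood_constants(cf[["k"]], cf[["alpha"]],
                              beta = if (fix_beta) beta else cf[["beta2"]],
                              gamma = cf[["gamma"]], provenance = "fitted")
  }
  pred <- predict_sherwood(data, cst)
  res <- data$Sh - pred
  ape <- abs(pred - data$Sh) / data$Sh * 100
  structure(list(constants = cst, fitted = pred, residuals = res, ape = ape,
                 mae = mean(ape), max_ape = max(ape),
                 sse = sum(w * res^2), n = n, objective = objective),
            class = "sherwood_fit")
}

#' @export
print.sherwood_fit <- function(x, ...) {
  print(x$constants)
  cat(sprintf("  n = %d, sse = %.4g, mean APE = %.3g%%, max APE = %.3g%%\n",
              x$n, x$sse, x$mae, x$max_ape))
  invisible(x)
}

#' Adjust the linear constant of a correlation against observations
#'
#' Keeps the exponents of `sim` untouched and rescales its linear constant k
#' by the single multiplicative factor that minimises the squared error
#' between the correlation predictions and the observations (closed-form
#' least squares through the origin). This corrects a correlation whose
#' shape is right but whose level over-predicts, e.g. one fitted to
#' rigid-lid simulation output.
#'
#' @param sim A [sherwood_constants()] set to be adjusted.
#' @param observations A [correlation_dataset()]; the observed values are
#'   the `Sh` column, or, with `scale = "kL"`, kL values obtained from Sh
#'   via columns `D` (m) and `D_AB` (m2/s) when present. The factor is
#'   invariant to that choice when D and D_AB are common to all records.
#' @param scale Compare on the "kL" scale (default) or the "Sh" scale.
#' @return list with `constants` (adjusted set, provenance "adjusted") and
#'   `correction_factor` = k_adjusted / k_sim.
#' @export
#' @examples
#' tab <- read_sherwood_constants(vwoxy_example("table3_sherwood_constants.csv"))
#' ds <- gen_sherwood_dataset(sh_dataset_spec(constants_true = tab$adjusted,
#'                                            noise_cv = 0, seed = 1))
#' adjust_linear_constant(tab$simulation, ds)$correction_factor  # 0.473
adjust_linear_constant <- function(sim, observations, scale = c("kL", "Sh")) {
  scale <- match.arg(scale)
  stopifnot(inherits(sim, "sherwood_constants"))
  observations <- correlation_dataset(observations)
  pred <- predict_sherwood(observations, sim)
  obs <- observations$Sh
  if (scale == "kL" && all(c("D", "D_AB") %in% names(observations))) {
    conv <- observations$D_AB / observations$D
    pred <- pred * conv
    obs <- obs * conv
  }
  factor <- sum(pred * obs) / sum(pred^2)
  adj <- sherwood_constants(sim$k * factor, sim$alpha, beta = sim$beta,
                            gamma = sim$gamma, provenance = "adjusted")
  list(constants = adj, correction_factor = factor)
}

#' Predict kLa and kL for an operating condition
#'
#' Composes the pipeline: dimensionless groups -> Sherwood number ->
#' kL = Sh D_AB / D -> kLa = kL A / V.
#'
#' @param op An [operating_point()].
#' @param props A [medium_properties()]; defaults to water at the operating
#'   temperature.
#' @param constants A [sherwood_constants()].
#' @return list of class `kla_prediction` with `Sh`, `kL` (m/s), `kLa`
#'   (1/s), `kLa_h` (1/h), `groups`.
#' @export
#' @examples
#' op <- operating_point(rpm = 60, volume_mL = 100, specific_area = 16.4)
#' cexp <- sherwood_constants(1.68, 0.551, gamma = 1.18)
#' predict_kla(op, constants = cexp)
predict_kla <- function(op, props = medium_properties(op$T), constants) {
  g <- dimensionless_groups(op, props)
  Sh <- predict_sherwood(g, constants)
  kL <- kl_from_sherwood(Sh, op$D, props$D_AB)
  kLa <- kL * op$A / op$V
  structure(list(Sh = Sh, kL = kL, kLa = kLa, kLa_h = kLa * 3600, groups = g),
            class = "kla_prediction")
}

#' @export
print.kla_prediction <- function(x, ...) {
  cat(sprintf("Predicted Sh = %.4g, kL = %.4g m/s, kLa = %.4g 1/s (%.3f 1/h)\n",
              x$Sh, x$kL, x$kLa, x$kLa_h))
  cat(sprintf("  at Re = %.4g, Sc = %.4g, G = %.4g\n",
              x$groups$Re, x$groups$Sc, x$groups$G))
  invisible(x)
}

#' Oxygen-limited maximum cell density
#'
#' Equates the oxygen transfer rate OTR = kLa C_sat to the uptake rate
#' OUR = X qO2 of a homogeneous culture that consumes all transferred oxygen
#' (bulk concentration ~ 0), giving X = kLa C_sat / qO2.
#'
#' @param kLa Volumetric mass-transfer coefficient (1/s).
#' @param C_sat Saturation concentration (mol/m3).
#' @param qO2 Specific oxygen consumption per cell (mol/cell/s), > 0.
#' @return list with `X_per_m3` (cells/m3) and `X_per_mL` (cells/mL).
#' @export
#' @examples
#' max_cell_density(1e-3, 0.2, 1e-16)  # 2e6 cells/mL
max_cell_density <- function(kLa, C_sat, qO2) {
  stopifnot(kLa > 0, C_sat > 0)
  if (any(qO2 <= 0)) stop("max_cell_density(): qO2 must be positive", call. = FALSE)
  X <- kLa * C_sat / qO2
  list(X_per_m3 = X, X_per_mL = X * 1e-6)
}
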