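#' Specification of a synthetic luminescence aeration trace
#'
#' Defines the conditions under which [gen_luminescence()] emulates an
#' aeration run: the ground-truth kLa, the plateau intensities, additive
#' Gaussian detector noise, a linear baseline drift and the sampling grid.
#' Defaults mirror a bench acquisition: a kLa of 2 1/h (mid experimental
#' range), a few-thousand-count dynamic range, noise at 1% of the span and
#' a run long enough (~5 time constants) to reach the saturation plateau.
#'
#' @param kLa_true Ground-truth kLa (1/s), or a function of time (s).
#' @param I_max,I_min Plateau intensities (counts).
#' @param noise_sigma Additive Gaussian noise sd (counts).
#' @param drift_slope Linear baseline drift (counts/s).
#' @param duration Run duration (s); default 5 / kLa (constant kLa) so the
#'   trace saturates.
#' @param dt Sampling interval (s).
#' @param seed Integer RNG seed; generation is bit-reproducible per seed.
#' @return list of class `trace_spec`.
#' @export
trace_spec <- function(kLa_true = 2 / 3600, I_max = 5000, I_min = 1000,
                       noise_sigma = 0.01 * (I_max - I_min), drift_slope = 0,
                       duration = NULL, dt = NULL, seed = 1) {
  if (is.null(duration)) {
    duration <- if (is.function(kLa_true)) 9000 else 5 / kLa_true
  }
  if (is.null(dt)) dt <- duration / 150
  stopifnot(I_max > I_min, I_min >= 0, dt > 0, duration >= dt)
  structure(list(kLa_true = kLa_true, I_max = I_max, I_min = I_min,
                 noise_sigma = noise_sigma, drift_slope = drift_slope,
                 duration = duration, dt = dt, seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a synthetic luminescence aeration run
#'
#' Builds the recorded-intensity trace
#' I(t) = I_max - (I_max - I_min)(1 - exp(-kLa t)) + drift * t + N(0, sigma)
#' and, optionally, wraps every time point in a synthetic emission spectrum
#' (Gaussian peak at 608 nm, sd 15 nm, over a flat dark floor, with the
#' drift applied across all wavelengths so that band-anchored detrending can
#' remove it). A time-varying kLa(t) is honoured by integrating the aeration
#' ODE.
#'
#' @param spec A [trace_spec()].
#' @param spectra Also generate a [spectrum_series()] (default FALSE).
#' @param wavelengths Wavelength grid (nm) for the spectra.
#' @param dark_floor Dark-spectrum level (counts).
#' @return list with `trace` (an [intensity_trace()] with plateaus set),
#'   `kLa_true`, `spec`, and when `spectra = TRUE` a `series`
#'   ([spectrum_series()]).
#' @export
#' @examples
#' syn <- gen_luminescence(trace_spec(kLa_true = 2 / 3600, noise_sigma = 0, seed = 7))
#' fit_kla(syn$trace, a = 16.4)$kLa_h  # ~2
gen_luminescence <- function(spec, spectra = FALSE,
                             wavelengths = seq(420, 750, by = 1),
                             dark_floor = 120) {
  stopifnot(inherits(spec, "trace_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  span <- spec$I_max - spec$I_min
  sat_frac <- if (is.function(spec$kLa_true)) {
    integrate_aeration(spec$kLa_true, C_sat = 1, t_grid = t)
  } else {
    1 - exp(-spec$kLa_true * t)
  }
  clean <- spec$I_max - span * sat_frac
  set.seed(spec$seed)
  noise <- stats::rnorm(length(t), 0, spec$noise_sigma)
  recorded <- clean + spec$drift_slope * t + noise
  out <- list(trace = intensity_trace(t, recorded, I_max = spec$I_max,
                                      I_min = spec$I_min),
              kLa_true = spec$kLa_true, spec = spec)
  if (spectra) {
    emission <- exp(-(wavelengths - 608)^2 / (2 * 15^2))
    counts <- outer(clean + noise, emission) + spec$drift_slope * t +
      matrix(dark_floor, length(t), length(wavelengths))
    out$series <- spectrum_series(t, wavelengths, counts,
                                  dark = rep(dark_floor, length(wavelengths)))
  }
  out
}

#' Specification of an analytic flow field
#'
#' Closed-form velocity fields whose gradients (and hence dissipation and
#' WALE diagnostics) are known exactly, used as oracles for the
#' post-processing operators. Kinds:
#' * `taylor_green`: u = A cos(kx) sin(ky), v = -A sin(kx) cos(ky), w = 0 on
#'   one periodic box of side 2 pi / kappa; volume-mean resolved dissipation
#'   is nu A^2 kappa^2.
#' * `solid_rotation`: rigid rotation at rate omega about z; zero strain,
#'   WALE nu_t = (Cw Delta)^2 (2/3)^(1/4) omega.
#' * `pure_shear`: du/dy = gamma_dot only; WALE nu_t = 0 identically.
#' * `random_smooth`: seeded superposition of a few Fourier modes.
#'
#' @param kind Flow kind (see above).
#' @param A Velocity amplitude (m/s).
#' @param kappa Wavenumber (1/m) for taylor_green / random_smooth.
#' @param omega Rotation rate (1/s) for solid_rotation.
#' @param gamma_dot Shear rate (1/s) for pure_shear.
#' @param grid_n Cells per axis (>= 8).
#' @param domain_L Domain side (m); defaults to one Taylor-Green period.
#' @param nu Molecular kinematic viscosity (m2/s).
#' @param seed RNG seed (random_smooth only).
#' @return list of class `flow_spec`.
#' @export
flow_spec <- function(kind = c("taylor_green", "solid_rotation", "pure_shear",
                               "random_smooth"),
                      A = 0.1, kappa = 100, omega = 10, gamma_dot = 10,
                      grid_n = 16, domain_L = NULL, nu = 1e-6, seed = 1) {
  kind <- match.arg(kind)
  if (grid_n < 8) stop("flow_spec(): grid_n must be >= 8", call. = FALSE)
  if (is.null(domain_L)) {
    domain_L <- if (kind %in% c("taylor_green", "random_smooth")) 2 * pi / kappa else 0.01
  }
  structure(list(kind = kind, A = A, kappa = kappa, omega = omega,
                 gamma_dot = gamma_dot, grid_n = as.integer(grid_n),
                 domain_L = domain_L, nu = nu, seed = as.integer(seed)),
            class = "flow_spec")
}

#' Generate an analytic gradient field with closed-form diagnostics
#'
#' Samples the analytic velocity gradients of the flow in [flow_spec()] at
#' the cell centres of a uniform `grid_n`^3 mesh and returns a
#' [gradient_field()] together with its ground truth.
#'
#' @param spec A [flow_spec()].
#' @return list with `field` (a [gradient_field()]) and `truth`, a list
#'   holding closed-form values: per-cell `eps_res` and, depending on kind,
#'   `mean_eps_res` (taylor_green), `nu_t` (pure_shear: 0;
#'   solid_rotation: the WALE closed form as a function of Cw).
#' @export
#' @examples
#' gf <- gen_flow(flow_spec("taylor_green", grid_n = 16))
#' mean(eps_total(gf$field)$eps_res)  # ~ nu A^2 kappa^2
gen_flow <- function(spec) {
  stopifnot(inherits(spec, "flow_spec"))
  n <- spec$grid_n
  L <- spec$domain_L
  h <- L / n
  ctr <- (seq_len(n) - 0.5) * h
  g <- expand.grid(x = ctr, y = ctr, z = ctr)
  ncell <- nrow(g)
  zero <- numeric(ncell)
  cells <- data.frame(g, cell_volume = rep(h^3, ncell))
  truth <- list()

  if (spec$kind == "taylor_green") {
    A <- spec$A; k <- spec$kappa
    sx <- sin(k * g$x); cx <- cos(k * g$x)
    sy <- sin(k * g$y); cy <- cos(k * g$y)
    cells$dudx <- -A * k * sx * sy
    cells$dudy <- A * k * cx * cy
    cells$dudz <- zero
    cells$dvdx <- -A * k * cx * cy
    cells$dvdy <- A * k * sx * sy
    cells$dvdz <- zero
    cells$dwdx <- zero; cells$dwdy <- zero; cells$dwdz <- zero
    truth$eps_res <- 4 * spec$nu * A^2 * k^2 * sx^2 * sy^2
    truth$mean_eps_res <- spec$nu * A^2 * k^2
  } else if (spec$kind == "solid_rotation") {
    w <- spec$omega
    cells$dudx <- zero; cells$dudy <- rep(-w, ncell); cells$dudz <- zero
    cells$dvdx <- rep(w, ncell); cells$dvdy <- zero; cells$dvdz <- zero
    cells$dwdx <- zero; cells$dwdy <- zero; cells$dwdz <- zero
    truth$eps_res <- zero
    truth$nu_t <- function(Cw = 0.325, delta = h) (Cw * delta)^2 * (2 / 3)^(1 / 4) * w
  } else if (spec$kind == "pure_shear") {
    gd <- spec$gamma_dot
    cells$dudx <- zero; cells$dudy <- rep(gd, ncell); cells$dudz <- zero
    cells$dvdx <- zero; cells$dvdy <- zero; cells$dvdz <- zero
    cells$dwdx <- zero; cells$dwdy <- zero; cells$dwdz <- zero
    truth$eps_res <- rep(spec$nu * gd^2, ncell)
    truth$nu_t <- 0
  } else { # random_smooth: seeded sum of solenoidal Fourier modes
    set.seed(spec$seed)
    nmodes <- 4
    amp <- spec$A * stats::runif(nmodes, 0.2, 1)
    kx <- spec$kappa * sample(1:3, nmodes, replace = TRUE)
    ky <- spec$kappa * sample(1:3, nmodes, replace = TRUE)
    ph <- stats::runif(nmodes, 0, 2 * pi)
    dudx <- dudy <- dvdx <- dvdy <- zero
    for (m in seq_len(nmodes)) {
      # streamfunction psi = amp sin(kx x + ky y + ph): u = dpsi/dy, v = -dpsi/dx
      arg <- kx[m] * g$x + ky[m] * g$y + ph[m]
      dudx <- dudx - amp[m] * kx[m] * ky[m] * sin(arg)
      dudy <- dudy - amp[m] * ky[m]^2 * sin(arg)
      dvdx <- dvdx + amp[m] * kx[m]^2 * sin(arg)
      dvdy <- dvdy + amp[m] * kx[m] * ky[m] * sin(arg)
    }
    cells$dudx <- dudx; cells$dudy <- dudy; cells$dudz <- zero
    cells$dvdx <- dvdx; cells$dvdy <- dvdy; cells$dvdz <- zero
    cells$dwdx <- zero; cells$dwdy <- zero; cells$dwdz <- zero
    SS <- gradient_contractions(as.matrix(cells[grad_cols()]))$SS
    truth$eps_res <- 2 * spec$nu * SS
  }
  list(field = gradient_field(cells, nu = spec$nu), truth = truth, spec = spec)
}

#' Specification of a synthetic Sherwood-correlation dataset
#'
#' Defaults reproduce the experimental study conditions: dimensionless
#' groups sampled log-uniformly over Re in \[624, 3172\], Sc in \[366, 395\]
#' and G in \[0.651, 1.08\] (the stated fit ranges), the experimental
#' constant set as ground truth, and multiplicative Gaussian scatter on Sh.
#'
#' @param constants_true A [sherwood_constants()] generating the data.
#' @param Re_range,Sc_range,G_range Sampling intervals.
#' @param n_records Number of records.
#' @param noise_cv Relative (multiplicative) noise sd on Sh.
#' @param seed Integer RNG seed.
#' @return list of class `sh_dataset_spec`.
#' @export
sh_dataset_spec <- function(constants_true = sherwood_constants(1.68, 0.551,
                                                                gamma = 1.18),
                            Re_range = c(624, 3172), Sc_range = c(366, 395),
                            G_range = c(0.651, 1.08), n_records = 50,
                            noise_cv = 0.02, seed = 1) {
  stopifnot(all(c(Re_range, Sc_range, G_range) > 0), n_records >= 1,
            noise_cv >= 0)
  structure(list(constants_true = constants_true, Re_range = Re_range,
                 Sc_range = Sc_range, G_range = G_range,
                 n_records = as.integer(n_records), noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "sh_dataset_spec")
}

#' Generate a synthetic (Re, Sc, G, Sh) dataset
#'
#' Log-uniform samples of the groups over the spec ranges and
#' Sh = k Re^alpha Sc^beta G^gamma (1 + eps) with eps ~ N(0, noise_cv).
#' Deterministic per seed.
#'
#' @param spec A [sh_dataset_spec()].
#' @return A [correlation_dataset()] with attribute `constants_true`.
#' @export
#' @examples
#' ds <- gen_sherwood_dataset(sh_dataset_spec(noise_cv = 0, seed = 3))
#' fit_sherwood(ds)$constants
gen_sherwood_dataset <- function(spec) {
  stopifnot(inherits(spec, "sh_dataset_spec"))
  set.seed(spec$seed)
  lu <- function(r, n) exp(stats::runif(n, log(r[1]), log(r[2])))
  n <- spec$n_records
  Re <- lu(spec$Re_range, n)
  Sc <- lu(spec$Sc_range, n)
  G <- lu(spec$G_range, n)
  Sh0 <- predict_sherwood(list(Re = Re, Sc = Sc, G = G), spec$constants_true)
  Sh <- Sh0 * (1 + stats::rnorm(n, 0, spec$noise_cv))
  if (any(Sh <= 0)) Sh <- pmax(Sh, 1e-6 * Sh0)  # guard absurd noise draws
  ds <- correlation_dataset(data.frame(Re = Re, Sc = Sc, G = G, Sh = Sh))
  attr(ds, "constants_true") <- spec$constants_true
  ds
}

#' Generate a surface flux field with known kL
#'
#' Film-theory construction: every face gets the wall-normal gradient
#' dC/dy = kL_true (C_sat - C_bulk) / D_AB so that [surface_kl()] returns
#' `kL_true` exactly. Optional face-to-face perturbations have zero
#' area-weighted mean, leaving the area-mean flux (and hence kL) unchanged.
#'
#' @param kL_true Target mass-transfer coefficient (m/s).
#' @param C_sat Interface concentration (mol/m3).
#' @param C_bulk Bulk concentration (mol/m3), below `C_sat`.
#' @param D_AB Molecular diffusivity (m2/s).
#' @param n_faces Number of faces.
#' @param perturb Relative amplitude of the zero-mean face perturbation.
#' @param seed RNG seed (used only when `perturb > 0`).
#' @return A [surface_flux_field()] with attribute `kL_true`.
#' @export
#' @examples
#' sf <- gen_surface_profile(2.68e-5, C_sat = 0.26, C_bulk = 0.05, D_AB = 2.1e-9)
#' surface_kl(sf, D_AB = 2.1e-9)$kL  # 2.68e-5
gen_surface_profile <- function(kL_true, C_sat, C_bulk, D_AB,
                                n_faces = 64, perturb = 0, seed = 1) {
  stopifnot(kL_true > 0, C_sat > C_bulk, D_AB > 0, n_faces >= 1, perturb >= 0)
  area <- rep(1 / n_faces, n_faces)
  base <- kL_true * (C_sat - C_bulk) / D_AB
  p <- numeric(n_faces)
  if (perturb > 0 && n_faces > 1) {
    set.seed(seed)
    p <- stats::runif(n_faces, -perturb, perturb)
    p <- p - sum(area * p) / sum(area)  # zero area-weighted mean
  }
  sf <- surface_flux_field(data.frame(area = area, dCdy = base * (1 + p), D_ABt = 0),
                           C_sat = C_sat, C_bulk_mean = C_bulk)
  attr(sf, "kL_true") <- kL_true
  sf
}
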