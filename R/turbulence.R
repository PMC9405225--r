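#' Per-cell velocity-gradient field
#'
#' Flat-table representation of a CFD export: one row per cell with
#' position, cell volume, the nine velocity-gradient components (row-major:
#' dudx dudy dudz dvdx ... dwdz, i.e. component (i, j) = d u_i / d x_j) and
#' optionally the sub-grid-scale kinetic energy and eddy viscosity.
#'
#' @param cells data.frame with columns `x`, `y`, `z`, `cell_volume`,
#'   `dudx`, `dudy`, `dudz`, `dvdx`, `dvdy`, `dvdz`, `dwdx`, `dwdy`, `dwdz`
#'   and optionally `k_sgs`, `nu_t`.
#' @param nu Molecular kinematic viscosity (m2/s).
#' @param delta_rule Filter-width convention; only "cube_root"
#'   (Delta = cell_volume^(1/3), the cell's average length) is implemented.
#' @return Object of class `gradient_field` (a data.frame with attributes
#'   `nu` and `delta_rule`; a `delta` column is added).
#' @export
gradient_field <- function(cells, nu, delta_rule = "cube_root") {
  cells <- as.data.frame(cells)
  need <- c("x", "y", "z", "cell_volume", grad_cols())
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("gradient_field(): missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(cells$cell_volume > 0), nu > 0,
            all(is.finite(as.matrix(cells[grad_cols()]))))
  delta_rule <- match.arg(delta_rule, "cube_root")
  cells$delta <- cells$cell_volume^(1 / 3)
  attr(cells, "nu") <- nu
  attr(cells, "delta_rule") <- delta_rule
  class(cells) <- c("gradient_field", "data.frame")
  cells
}

grad_cols <- function() {
  c("dudx", "dudy", "dudz", "dvdx", "dvdy", "dvdz", "dwdx", "dwdy", "dwdz")
}

# n x 9 matrix of gradients, row-major (i, j) -> column 3*(i-1)+j
grad_matrix <- function(field) as.matrix(field[grad_cols()])

#' Resolved strain-rate tensor
#'
#' S = (gradU + gradU^T) / 2, the symmetric part of the velocity gradient.
#' Vanishes identically for solid-body rotation.
#'
#' @param gradU 3x3 velocity-gradient matrix with gradU\[i, j\] = d u_i / d x_j.
#' @return Symmetric 3x3 strain-rate tensor (1/s).
#' @export
strain_rate <- function(gradU) {
  gradU <- as.matrix(gradU)
  stopifnot(all(dim(gradU) == c(3, 3)), all(is.finite(gradU)))
  (gradU + t(gradU)) / 2
}

# Vectorised double contractions for an n x 9 gradient matrix.
# Returns list(SS = S:S, SdSd = S^d:S^d) per row.
gradient_contractions <- function(gm) {
  g <- function(i, j) gm[, 3 * (i - 1) + j]
  SS <- 0
  for (i in 1:3) for (j in 1:3) SS <- SS + ((g(i, j) + g(j, i)) / 2)^2
  # squared gradient tensor g2[i,j] = sum_k g[i,k] g[k,j]
  g2 <- vector("list", 9)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:3) s <- s + g(i, k) * g(k, j)
    g2[[3 * (i - 1) + j]] <- s
  }
  tr <- g2[[1]] + g2[[5]] + g2[[9]]
  SdSd <- 0
  for (i in 1:3) for (j in 1:3) {
    sd <- (g2[[3 * (i - 1) + j]] + g2[[3 * (j - 1) + i]]) / 2 -
      (if (i == j) tr / 3 else 0)
    SdSd <- SdSd + sd^2
  }
  list(SS = SS, SdSd = SdSd)
}

#' WALE sub-grid eddy viscosity
#'
#' Wall-adapting local eddy-viscosity closure:
#' nu_t = (Cw Delta)^2 (Sd:Sd)^(3/2) / ((S:S)^(5/2) + (Sd:Sd)^(5/4)),
#' where Sd is the traceless symmetric part of the squared velocity-gradient
#' tensor. Returns 0 when both contractions vanish (quiescent cell), and --
#' by design of the closure -- exactly 0 for pure shear, where the squared
#' gradient is nilpotent.
#'
#' @param gradU 3x3 velocity-gradient matrix, or an n x 9 row-major matrix.
#' @param delta Filter width Delta (m), scalar or per-row.
#' @param Cw WALE constant; default 0.325.
#' @return Eddy viscosity nu_t (m2/s), one value per input row.
#' @export
#' @examples
#' omega <- 10
#' rot <- matrix(c(0, -omega, 0, omega, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
#' wale_nut(rot, delta = 1e-3)  # (Cw Delta)^2 (2/3)^(1/4) omega
wale_nut <- function(gradU, delta, Cw = 0.325) {
  stopifnot(all(delta > 0), Cw > 0)
  gm <- if (is.matrix(gradU) && all(dim(gradU) == c(3, 3))) {
    matrix(t(gradU), nrow = 1)  # row-major flatten
  } else {
    as.matrix(gradU)
  }
  stopifnot(ncol(gm) == 9)
  con <- gradient_contractions(gm)
  num <- con$SdSd^(3 / 2)
  den <- con$SS^(5 / 2) + con$SdSd^(5 / 4)
  out <- ifelse(den > 0, (Cw * delta)^2 * num / den, 0)
  as.numeric(out)
}

#' Energy dissipation rate per cell
#'
#' Resolved part eps_res = 2 nu S:S plus, when requested and available, the
#' sub-grid part eps_sgs = C_eps k_sgs^(3/2) / Delta.
#'
#' @param field A [gradient_field()].
#' @param nu_t_source "none" uses only the resolved part; "k_sgs" adds the
#'   SGS contribution from the `k_sgs` column (error if absent). Default
#'   adds SGS when the column is present.
#' @param C_eps SGS dissipation constant; default 1.034.
#' @return data.frame with per-cell `S_dd` (S:S, 1/s2), `eps_res`,
#'   `eps_sgs`, `eps` (m2/s3).
#' @export
eps_total <- function(field, nu_t_source = c("auto", "k_sgs", "none"),
                      C_eps = 1.034) {
  stopifnot(inherits(field, "gradient_field"))
  nu_t_source <- match.arg(nu_t_source)
  nu <- attr(field, "nu")
  con <- gradient_contractions(grad_matrix(field))
  eps_res <- 2 * nu * con$SS
  want_sgs <- switch(nu_t_source,
                     auto = "k_sgs" %in% names(field),
                     k_sgs = TRUE,
                     none = FALSE)
  if (want_sgs && !("k_sgs" %in% names(field))) {
    stop("eps_total(): SGS dissipation requested but field has no k_sgs column",
         call. = FALSE)
  }
  eps_sgs <- if (want_sgs) C_eps * field$k_sgs^(3 / 2) / field$delta else 0 * eps_res
  data.frame(S_dd = con$SS, eps_res = eps_res, eps_sgs = eps_sgs,
             eps = eps_res + eps_sgs)
}

#' Kolmogorov length scale
#'
#' eta = (nu^3 / eps)^(1/4): the smallest eddy size, used as a hydrodynamic
#' proxy for the attainable cell-aggregate size. Cells with eps = 0 map to
#' +Inf (quiescent; no finite Kolmogorov scale) with a warning.
#'
#' @param nu Kinematic viscosity (m2/s).
#' @param eps Energy dissipation rate(s) (m2/s3), >= 0.
#' @return Kolmogorov length(s) (m).
#' @export
#' @examples
#' kolmogorov(9.78e-7, 1e-3)  # ~1.75e-4 m
kolmogorov <- function(nu, eps) {
  stopifnot(nu > 0, all(eps >= 0))
  if (any(eps == 0)) {
    warning("kolmogorov(): eps = 0 in ", sum(eps == 0),
            " cell(s); eta reported as Inf", call. = FALSE)
  }
  (nu^3 / eps)^(1 / 4)
}

#' Shear-stress estimate per cell
#'
#' Default form tau = (mu + mu_t) sqrt(2 S:S), the magnitude of the
#' (laminar + eddy) viscous stress built from the strain-rate norm, which is
#' dimensionally a stress. `literal = TRUE` instead computes
#' (mu + mu_t) * (S:S), the product form some post-processing scripts use;
#' note its units are Pa/s, so it is exposed for comparison only.
#'
#' @param gradU 3x3 gradient matrix or n x 9 row-major matrix.
#' @param mu Dynamic viscosity (Pa s).
#' @param mu_t Eddy (dynamic) viscosity (Pa s), scalar or per-row.
#' @param literal Use the product form (see above).
#' @return Shear stress tau (Pa; or Pa/s for the literal form).
#' @export
shear_stress <- function(gradU, mu, mu_t = 0, literal = FALSE) {
  stopifnot(all(mu >= 0), all(mu_t >= 0))
  gm <- if (is.matrix(gradU) && all(dim(gradU) == c(3, 3))) {
    matrix(t(gradU), nrow = 1)
  } else {
    as.matrix(gradU)
  }
  SS <- gradient_contractions(gm)$SS
  if (literal) as.numeric((mu + mu_t) * SS) else as.numeric((mu + mu_t) * sqrt(2 * SS))
}

#' Turbulent (eddy) mass diffusivity
#'
#' D_ABt = nu_t / Sc_t with the turbulent Schmidt number Sc_t, taken
#' constant (default 1.34, appropriate for transitional flow at high
#' molecular Schmidt number).
#'
#' @param nu_t Eddy viscosity (m2/s), >= 0.
#' @param Sc_t Turbulent Schmidt number; default 1.34.
#' @return Turbulent diffusivity (m2/s).
#' @export
turb_diffusivity <- function(nu_t, Sc_t = 1.34) {
  stopifnot(all(nu_t >= 0), Sc_t > 0)
  nu_t / Sc_t
}

#' Velocity-fluctuation sample series per probe
#'
#' Time samples of the resolved velocity fluctuations (mean-removed) and
#' paired SGS kinetic-energy samples at each probe. The set of samples
#' supplied per probe IS the time-averaging window of the resolved kinetic
#' energy.
#'
#' @param samples data.frame with columns `probe`, `ux`, `uy`, `uz` (m/s)
#'   and `k_sgs` (m2/s2).
#' @param demean Remove the per-probe mean of each component (default TRUE)
#'   so the series are fluctuations by construction.
#' @return data.frame of class `fluctuation_series`.
#' @export
fluctuation_series <- function(samples, demean = TRUE) {
  samples <- as.data.frame(samples)
  need <- c("probe", "ux", "uy", "uz", "k_sgs")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("fluctuation_series(): missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(table(samples$probe) < 2)) {
    stop("fluctuation_series(): every probe needs >= 2 samples", call. = FALSE)
  }
  if (demean) {
    for (cc in c("ux", "uy", "uz")) {
      samples[[cc]] <- samples[[cc]] - stats::ave(samples[[cc]], samples$probe)
    }
  }
  class(samples) <- c("fluctuation_series", "data.frame")
  samples
}

#' Resolved kinetic-energy ratio per probe
#'
#' k_resolved = (mean(ux'^2) + mean(uy'^2) + mean(uz'^2)) / 2 and
#' k_ratio = k_resolved / (k_resolved + mean(k_sgs)). A ratio of at least
#' 0.8 (80% of the kinetic energy resolved) is the usual LES mesh-quality
#' rule of thumb; probes below the threshold are flagged.
#'
#' @param fluct A [fluctuation_series()].
#' @param threshold Mesh-quality flag threshold; default 0.8.
#' @return data.frame with one row per probe: `probe`, `k_resolved`,
#'   `k_sgs_mean`, `k_ratio`, `adequate` (k_ratio >= threshold). Probes with
#'   zero total energy get `k_ratio = NA` and a warning.
#' @export
#' @examples
#' s <- data.frame(probe = 1, ux = c(-0.02, 0.02), uy = 0, uz = 0, k_sgs = 1e-4)
#' ke_ratio(fluctuation_series(s))
ke_ratio <- function(fluct, threshold = 0.8) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  probes <- split(fluct, fluct$probe)
  out <- do.call(rbind, lapply(probes, function(p) {
    k_res <- 0.5 * (mean(p$ux^2) + mean(p$uy^2) + mean(p$uz^2))
    k_sgs <- mean(p$k_sgs)
    total <- k_res + k_sgs
    data.frame(probe = p$probe[1],
               k_resolved = k_res, k_sgs_mean = k_sgs,
               k_ratio = if (total > 0) k_res / total else NA_real_)
  }))
  rownames(out) <- NULL
  if (anyNA(out$k_ratio)) {
    warning("ke_ratio(): zero total kinetic energy at ",
            sum(is.na(out$k_ratio)), " probe(s); ratio undefined", call. = FALSE)
  }
  out$adequate <- !is.na(out$k_ratio) & out$k_ratio >= threshold
  out
}

#' Surface flux field at the gas-liquid interface
#'
#' @param faces data.frame with columns `area` (m2), `dCdy` (wall-normal
#'   concentration gradient at the surface, mol/m4; y points into the bulk)
#'   and optionally `D_ABt` (m2/s, default 0).
#' @param C_sat Interface (saturation) concentration (mol/m3).
#' @param C_bulk_mean Volume-average bulk concentration (mol/m3), below
#'   `C_sat` for an absorbing run.
#' @return Object of class `surface_flux_field`.
#' @export
surface_flux_field <- function(faces, C_sat, C_bulk_mean) {
  faces <- as.data.frame(faces)
  miss <- setdiff(c("area", "dCdy"), names(faces))
  if (length(miss)) {
    stop("surface_flux_field(): missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!("D_ABt" %in% names(faces))) faces$D_ABt <- 0
  stopifnot(all(faces$area > 0), all(faces$D_ABt >= 0), C_sat > C_bulk_mean)
  structure(list(faces = faces, C_sat = C_sat, C_bulk_mean = C_bulk_mean),
            class = "surface_flux_field")
}

#' Surface-flux mass-transfer coefficient
#'
#' Per-face flux magnitude N = (D_AB + D_ABt) |dC/dy| (Fick's law augmented
#' with the eddy diffusivity), area-weighted mean flux <N>, and
#' kL = <N> / (C_sat - <C_bulk>).
#'
#' @param surface A [surface_flux_field()].
#' @param D_AB Molecular diffusivity (m2/s).
#' @return list with `kL` (m/s), `N_mean` (mol/m2/s) and per-face fluxes
#'   `N` (mol/m2/s).
#' @export
surface_kl <- function(surface, D_AB) {
  stopifnot(inherits(surface, "surface_flux_field"), D_AB > 0)
  drive <- surface$C_sat - surface$C_bulk_mean
  if (drive < 1e-9 * surface$C_sat) {
    stop("surface_kl(): driving force C_sat - <C> has vanished (saturated run)",
         call. = FALSE)
  }
  f <- surface$faces
  N <- (D_AB + f$D_ABt) * abs(f$dCdy)
  N_mean <- sum(f$area * N) / sum(f$area)
  list(kL = N_mean / drive, N_mean = N_mean, N = N)
}

#' Full per-cell turbulence diagnostics
#'
#' One-call post-processing of a [gradient_field()]: strain contraction,
#' WALE eddy viscosity (or the solver-supplied `nu_t` column), resolved /
#' SGS / total dissipation, Kolmogorov scale, shear stress and turbulent
#' diffusivity.
#'
#' @param field A [gradient_field()].
#' @param Cw WALE constant (default 0.325).
#' @param C_eps SGS dissipation constant (default 1.034).
#' @param Sc_t Turbulent Schmidt number (default 1.34).
#' @param rho Density (kg/m3) used to build dynamic viscosities for the
#'   shear stress; default 998 (water near room temperature).
#' @param use_field_nut Use the field's `nu_t` column when present instead
#'   of recomputing WALE (default FALSE).
#' @param literal_shear Use the literal product form of the shear stress.
#' @return data.frame of class `turbulence_diagnostics`: per-cell
#'   `S_dd`, `nu_t`, `eps_res`, `eps_sgs`, `eps`, `eta`, `tau`, `D_ABt`,
#'   plus `cell_volume` carried through for weighting.
#' @export
turbulence_diagnostics <- function(field, Cw = 0.325, C_eps = 1.034,
                                   Sc_t = 1.34, rho = 998,
                                   use_field_nut = FALSE,
                                   literal_shear = FALSE) {
  stopifnot(inherits(field, "gradient_field"))
  nu <- attr(field, "nu")
  gm <- grad_matrix(field)
  ep <- eps_total(field, C_eps = C_eps)
  nu_t <- if (use_field_nut && "nu_t" %in% names(field)) {
    field$nu_t
  } else {
    wale_nut(gm, delta = field$delta, Cw = Cw)
  }
  eta <- suppressWarnings(kolmogorov(nu, ep$eps))
  tau <- shear_stress(gm, mu = rho * nu, mu_t = rho * nu_t,
                      literal = literal_shear)
  out <- data.frame(S_dd = ep$S_dd, nu_t = nu_t,
                    eps_res = ep$eps_res, eps_sgs = ep$eps_sgs, eps = ep$eps,
                    eta = eta, tau = tau,
                    D_ABt = turb_diffusivity(nu_t, Sc_t),
                    cell_volume = field$cell_volume)
  class(out) <- c("turbulence_diagnostics", "data.frame")
  out
}

# weighted quantiles, inverse-CDF convention on the weighted ECDF
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Volume-weighted distribution summaries of the diagnostics
#'
#' Histograms and quantiles of the Kolmogorov scale, dissipation rate and
#' shear stress, weighted by cell volume (so the tables describe the
#' fraction of reactor volume, not the fraction of mesh cells). Also
#' reports the volume fraction with eps above a culture-relevant threshold
#' (default 0.5e-3 m2/s3).
#'
#' @param diag A [turbulence_diagnostics()].
#' @param weights Cell volumes (m3); defaults to the `cell_volume` column.
#' @param breaks Number of histogram bins (passed to [graphics::hist()]
#'   break computation via [base::pretty()]).
#' @param probs Quantile probabilities.
#' @param eps_threshold Dissipation threshold (m2/s3) for the high-shear
#'   volume-fraction flag.
#' @return list with `histograms` (named list of data.frames `bin_lo`,
#'   `bin_hi`, `volume_fraction`), `quantiles` (data.frame), and
#'   `frac_eps_above` (scalar).
#' @export
summarize_distributions <- function(diag, weights = diag$cell_volume,
                                    breaks = 30,
                                    probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                    eps_threshold = 0.5e-3) {
  stopifnot(nrow(diag) > 0, length(weights) == nrow(diag), all(weights > 0))
  vars <- c("eta", "eps", "tau")
  w <- weights / sum(weights)
  hists <- lapply(vars, function(v) {
    x <- diag[[v]]
    finite <- is.finite(x)
    x <- x[finite]; wf <- w[finite] / sum(w[finite])
    if (diff(range(x)) == 0) {
      return(data.frame(bin_lo = x[1], bin_hi = x[1], volume_fraction = 1))
    }
    br <- pretty(range(x), n = breaks)
    idx <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
    vf <- vapply(seq_len(length(br) - 1), function(b) sum(wf[idx == b]), numeric(1))
    data.frame(bin_lo = br[-length(br)], bin_hi = br[-1], volume_fraction = vf)
  })
  names(hists) <- vars
  qt <- do.call(rbind, lapply(vars, function(v) {
    x <- diag[[v]]
    finite <- is.finite(x)
    data.frame(variable = v,
               prob = probs,
               value = weighted_quantile(x[finite], w[finite], probs))
  }))
  list(histograms = hists, quantiles = qt,
       frac_eps_above = sum(w[diag$eps > eps_threshold]))
}
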