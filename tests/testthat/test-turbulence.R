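test_that("strain_rate is the symmetric part of the gradient", {
  # antisymmetric (rigid rotation) -> zero strain
  expect_equal(strain_rate(rotation_gradU(c(1, -2, 3))), matrix(0, 3, 3))
  # pure shear du/dy = gd -> S12 = S21 = gd/2
  gd <- 7
  shear <- matrix(c(0, gd, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  S <- strain_rate(shear)
  expect_equal(S[1, 2], gd / 2)
  expect_equal(S[2, 1], gd / 2)
  expect_equal(sum(abs(S)) - abs(S[1, 2]) - abs(S[2, 1]), 0)
  # random tensor matches (g + g^T)/2 elementwise
  g <- random_gradU(31)
  expect_equal(strain_rate(g), (g + t(g)) / 2)
})

test_that("WALE eddy viscosity honours its design properties", {
  # pure shear: squared gradient is nilpotent, Sd = 0, nu_t = 0 exactly
  for (pos in list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))) {
    g <- matrix(0, 3, 3); g[pos[1], pos[2]] <- 13.7
    expect_identical(wale_nut(g, delta = 1e-3), 0)
  }
  # quiescent cell -> 0 (0/0 guard)
  expect_identical(wale_nut(matrix(0, 3, 3), delta = 1e-3), 0)
  # solid-body rotation closed form: (Cw Delta)^2 (2/3)^(1/4) omega
  omega <- 10; Cw <- 0.325; delta <- 1e-3
  rot <- rotation_gradU(c(0, 0, omega))
  expect_equal(wale_nut(rot, delta = delta, Cw = Cw),
               (Cw * delta)^2 * (2 / 3)^(1 / 4) * omega, tolerance = 1e-10)
  expect_equal(wale_nut(rot, delta = delta, Cw = Cw), 9.54e-7, tolerance = 1e-3)
})

test_that("dissipation, Kolmogorov scale and shear stress match hand arithmetic", {
  # SGS dissipation: C_eps k^(3/2) / Delta
  cells <- data.frame(x = 0, y = 0, z = 0, cell_volume = 1e-9,
                      dudx = 0, dudy = 0, dudz = 0, dvdx = 0, dvdy = 0,
                      dvdz = 0, dwdx = 0, dwdy = 0, dwdz = 0, k_sgs = 1e-4)
  fld <- gradient_field(cells, nu = 1e-6)
  ep <- eps_total(fld)
  expect_equal(ep$eps_sgs, 1.034 * (1e-4)^1.5 / 1e-3, tolerance = 1e-12)
  expect_equal(ep$eps_sgs, 1.034e-3, tolerance = 1e-12)
  expect_equal(ep$eps_res, 0)
  expect_equal(ep$eps, ep$eps_res + ep$eps_sgs)  # conservation, per cell
  # requesting SGS without the column errors
  fld2 <- gradient_field(cells[setdiff(names(cells), "k_sgs")], nu = 1e-6)
  expect_error(eps_total(fld2, nu_t_source = "k_sgs"), "k_sgs")
  expect_equal(eps_total(fld2)$eps, 0)  # quiescent

  # Kolmogorov scale
  expect_equal(kolmogorov(9.78e-7, 1e-3), 1.75e-4, tolerance = 1e-3)
  expect_equal(kolmogorov(9.78e-7, 16e-3), kolmogorov(9.78e-7, 1e-3) / 2,
               tolerance = 1e-12)
  expect_warning(eta0 <- kolmogorov(1e-6, c(0, 1e-3)), "Inf")
  expect_true(is.infinite(eta0[1]))

  # shear stress: default magnitude form on pure shear gives mu * gd
  gd <- 10
  shear <- matrix(c(0, gd, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(shear_stress(shear, mu = 1e-3), 0.01, tolerance = 1e-12)
  expect_equal(shear_stress(matrix(0, 3, 3), mu = 1e-3), 0)
  expect_equal(shear_stress(shear, mu = 1e-3, mu_t = 1e-3),
               2 * shear_stress(shear, mu = 1e-3), tolerance = 1e-12)
  # literal (printed) product form: (mu + mu_t) * S:S
  expect_equal(shear_stress(shear, mu = 1e-3, literal = TRUE),
               1e-3 * gd^2 / 2, tolerance = 1e-12)

  # turbulent diffusivity
  expect_equal(turb_diffusivity(1.34e-6), 1.0e-6)
  expect_equal(turb_diffusivity(0), 0)
  expect_equal(turb_diffusivity(9.54e-7), 7.12e-7, tolerance = 1e-3)
})

test_that("diagnostics are objective under superposed rigid rotation", {
  nu <- 1e-6; rho <- 998
  field_from <- function(gm) {
    cells <- data.frame(x = 0, y = 0, z = 0, cell_volume = 1e-9)
    cols <- c("dudx", "dudy", "dudz", "dvdx", "dvdy", "dvdz",
              "dwdx", "dwdy", "dwdz")
    cells[cols] <- as.list(as.numeric(t(gm)))
    gradient_field(cells, nu = nu)
  }
  for (seed in c(17, 18, 19)) {
    g <- random_gradU(seed)
    grot <- g + rotation_gradU(c(3, -5, 2))
    expect_equal(strain_rate(grot), strain_rate(g), tolerance = 1e-12)
    expect_equal(eps_total(field_from(grot))$eps_res,
                 eps_total(field_from(g))$eps_res, tolerance = 1e-12)
    expect_equal(shear_stress(grot, mu = rho * nu),
                 shear_stress(g, mu = rho * nu), tolerance = 1e-12)
  }
})

test_that("Taylor-Green volume-mean dissipation matches the closed form", {
  for (n in c(8, 16)) {
    gf <- gen_flow(flow_spec("taylor_green", A = 0.1, kappa = 100, nu = 1e-6,
                             grid_n = n))
    ep <- eps_total(gf$field)
    expect_equal(ep$eps_res, gf$truth$eps_res, tolerance = 1e-10)
    vol_mean <- sum(ep$eps_res * gf$field$cell_volume) / sum(gf$field$cell_volume)
    expect_equal(vol_mean, gf$truth$mean_eps_res, tolerance = 0.01)
    expect_equal(gf$truth$mean_eps_res, 1e-4)  # nu A^2 kappa^2
  }
})

test_that("ke_ratio computes the resolved-energy fraction with flags", {
  # constructed probe exactly at the 80% mesh-quality threshold
  s <- data.frame(probe = "p1", ux = c(-0.04, 0.04), uy = 0, uz = 0,
                  k_sgs = 2e-4)
  r <- ke_ratio(fluctuation_series(s))
  expect_equal(r$k_resolved, 8e-4)
  expect_equal(r$k_ratio, 0.8)
  expect_true(r$adequate)

  # no SGS energy -> ratio 1; zero total energy -> NA with warning
  s2 <- data.frame(probe = rep(c("a", "b"), each = 2),
                   ux = c(-0.01, 0.01, 0, 0), uy = 0, uz = 0,
                   k_sgs = c(0, 0, 0, 0))
  expect_warning(r2 <- ke_ratio(fluctuation_series(s2)), "zero total")
  expect_equal(r2$k_ratio[r2$probe == "a"], 1)
  expect_true(is.na(r2$k_ratio[r2$probe == "b"]))

  # ratio lies in [0, 1] and decreases with k_sgs at fixed resolved energy
  ratios <- vapply(c(0, 1e-4, 5e-4, 2e-3), function(ks) {
    s <- data.frame(probe = 1, ux = c(-0.04, 0.04), uy = 0, uz = 0, k_sgs = ks)
    ke_ratio(fluctuation_series(s))$k_ratio
  }, numeric(1))
  expect_true(all(ratios >= 0 & ratios <= 1))
  expect_true(all(diff(ratios) < 0))

  # isotropic fluctuations: k_resolved -> 1.5 sigma^2 for many samples
  set.seed(99)
  sigma <- 0.02
  iso <- data.frame(probe = 1, ux = rnorm(20000, 0, sigma),
                    uy = rnorm(20000, 0, sigma), uz = rnorm(20000, 0, sigma),
                    k_sgs = 0)
  expect_equal(ke_ratio(fluctuation_series(iso))$k_resolved, 1.5 * sigma^2,
               tolerance = 0.05)

  expect_error(fluctuation_series(data.frame(probe = 1, ux = 1, uy = 1,
                                             uz = 1, k_sgs = 0)), ">= 2")
})

test_that("surface_kl implements the area-mean augmented Fick flux", {
  # single-face hand arithmetic
  sf <- surface_flux_field(data.frame(area = 1e-3, dCdy = 1e5, D_ABt = 0),
                           C_sat = 0.26, C_bulk_mean = 0.06)
  out <- surface_kl(sf, D_AB = 2.1e-9)
  expect_equal(out$N_mean, 2.1e-4, tolerance = 1e-12)
  expect_equal(out$kL, 1.05e-3, tolerance = 1e-12)
  # no gradient, no transfer
  sf0 <- surface_flux_field(data.frame(area = c(1, 2), dCdy = 0),
                            C_sat = 0.26, C_bulk_mean = 0)
  expect_equal(surface_kl(sf0, D_AB = 2.1e-9)$kL, 0)
  # saturated run trips the driving-force guard
  sfs <- surface_flux_field(data.frame(area = 1, dCdy = 1), C_sat = 0.26,
                            C_bulk_mean = 0.26 * (1 - 1e-12))
  expect_error(surface_kl(sfs, D_AB = 2.1e-9), "driving force")
  # film-theory generator round trip, with zero-mean face perturbations
  sfp <- gen_surface_profile(2.68e-5, C_sat = 0.26, C_bulk = 0.05,
                             D_AB = 2.1e-9, n_faces = 128, perturb = 0.2,
                             seed = 3)
  expect_equal(surface_kl(sfp, D_AB = 2.1e-9)$kL, 2.68e-5, tolerance = 1e-12)
})

test_that("distribution summaries are volume-weighted", {
  # two-valued field with volumes 1:3 -> weighted quantiles split at 25/75
  diag <- structure(data.frame(eta = c(1e-4, 4e-4), eps = c(1e-3, 2e-5),
                               tau = c(0.5, 0.1), cell_volume = c(1, 3)),
                    class = c("turbulence_diagnostics", "data.frame"))
  s <- summarize_distributions(diag, breaks = 4)
  q <- s$quantiles
  expect_equal(q$value[q$variable == "eta" & q$prob == 0.25], 1e-4)
  expect_equal(q$value[q$variable == "eta" & q$prob == 0.75], 4e-4)
  # 25% of the volume is above the dissipation threshold
  expect_equal(s$frac_eps_above, 0.25)
  # uniform field -> a single occupied bin
  diag2 <- structure(data.frame(eta = rep(2e-4, 5), eps = rep(1e-4, 5),
                                tau = rep(0.2, 5), cell_volume = rep(1, 5)),
                     class = c("turbulence_diagnostics", "data.frame"))
  s2 <- summarize_distributions(diag2)
  expect_equal(nrow(s2$histograms$eta), 1)
  expect_equal(s2$histograms$eta$volume_fraction, 1)
  # equal weights reproduce the unweighted histogram fractions
  set.seed(4)
  x <- runif(200, 1e-4, 5e-4)
  diag3 <- structure(data.frame(eta = x, eps = x, tau = x,
                                cell_volume = rep(2, 200)),
                     class = c("turbulence_diagnostics", "data.frame"))
  s3 <- summarize_distributions(diag3, breaks = 10)
  h <- s3$histograms$eta
  counts <- table(cut(x, breaks = c(h$bin_lo[1], h$bin_hi),
                      include.lowest = TRUE))
  expect_equal(h$volume_fraction, as.numeric(counts) / 200)
})

test_that("turbulence_diagnostics composes the per-cell operators", {
  gf <- gen_flow(flow_spec("taylor_green", grid_n = 8))
  diag <- turbulence_diagnostics(gf$field)
  expect_equal(diag$eps, diag$eps_res + diag$eps_sgs)
  expect_equal(diag$D_ABt, diag$nu_t / 1.34, tolerance = 1e-12)
  finite <- is.finite(diag$eta)
  expect_equal(diag$eta[finite],
               (attr(gf$field, "nu")^3 / diag$eps[finite])^0.25)
  expect_true(all(diag$tau >= 0))
})
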