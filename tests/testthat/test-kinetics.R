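test_that("extract_peak recovers peak intensities from synthetic spectra", {
  wl <- seq(420, 750, by = 1)
  times <- 0:9
  # flat spectra equal to the dark spectrum -> zero everywhere
  dark <- rep(100, length(wl))
  flat <- spectrum_series(times, wl, matrix(100, 10, length(wl)), dark = dark)
  expect_equal(extract_peak(flat, smooth_points = 1)$I_recorded, rep(0, 10))

  # Gaussian peak of amplitude 500 at 608 nm on zero dark -> 500 (unsmoothed)
  gauss <- outer(rep(500, 10), exp(-(wl - 608)^2 / (2 * 15^2)))
  ser <- spectrum_series(times, wl, gauss)
  expect_equal(extract_peak(ser, smooth_points = 1)$I_recorded, rep(500, 10),
               tolerance = 1e-12)

  # linear drift applied across wavelengths is removed by band anchoring
  spec <- trace_spec(kLa_true = 2 / 3600, noise_sigma = 0, seed = 5)
  clean <- gen_luminescence(spec, spectra = TRUE)
  drift <- gen_luminescence(trace_spec(kLa_true = 2 / 3600, noise_sigma = 0,
                                       drift_slope = 1, seed = 5),
                            spectra = TRUE)
  p_clean <- extract_peak(clean$series)$I_recorded
  p_drift <- extract_peak(drift$series)$I_recorded
  expect_equal(p_drift, p_clean, tolerance = 1e-9)

  # errors: peak centre outside range, too-narrow window
  expect_error(extract_peak(ser, center = 900), "outside")
  expect_error(extract_peak(ser, halfwidth = 0.5), "fewer than 3")
})

test_that("concentration profile matches the closed form and the ODE", {
  expect_equal(concentration_profile(0, 2e-4, 0.26), 0)
  expect_equal(concentration_profile(1 / 2e-4, 2e-4, 0.26),
               0.26 * (1 - exp(-1)), tolerance = 1e-12)
  # numeric integration of the aeration ODE agrees to 1e-8 relative
  tg <- seq(0, 2e4, length.out = 100)
  expect_equal(integrate_aeration(2e-4, 0.26, tg),
               concentration_profile(tg, 2e-4, 0.26),
               tolerance = 1e-8)
})

test_that("integrate_aeration handles degenerate and time-varying kLa", {
  tg <- seq(0, 400, by = 4)
  expect_equal(integrate_aeration(0, 0.26, tg), rep(0, length(tg)))
  # piecewise-constant kLa -> product-of-exponentials closed form
  kla <- function(t) ifelse(t < 100, 1e-3, 2e-3)
  exact <- 0.26 * (1 - exp(-ifelse(tg < 100, 1e-3 * tg,
                                   1e-3 * 100 + 2e-3 * (tg - 100))))
  expect_equal(integrate_aeration(kla, 0.26, tg), exact, tolerance = 1e-6)
  expect_error(integrate_aeration(1e-3, 0.26, c(0, 10, 5)), "increasing")
  expect_error(integrate_aeration(function(t) -1e-3, 0.26, tg), "non-negative")
})

test_that("model_intensity follows the treated-signal closed form", {
  expect_equal(model_intensity(0, 1e-3, 1000, 200), 0)
  expect_equal(model_intensity(1e9, 1e-3, 1000, 200), 800)
  expect_equal(model_intensity(log(2) / 1e-3, 1e-3, 1000, 200), 400,
               tolerance = 1e-12)
  expect_error(model_intensity(1, 1e-3, 200, 1000))
})

test_that("fit_kla recovers generator truth and validates its inputs", {
  spec <- trace_spec(kLa_true = 2 / 3600, noise_sigma = 0, seed = 11)
  syn <- gen_luminescence(spec)
  fit <- fit_kla(syn$trace, a = 16.4)
  expect_equal(fit$kLa_h, 2, tolerance = 1e-3)    # 0.1%
  expect_equal(fit$kL, fit$kLa / 16.4, tolerance = 1e-12)
  expect_false(fit$boundary)
  # free-endpoint variant recovers the same truth
  fit_free <- fit_kla(syn$trace, a = 16.4, fix_endpoints = FALSE)
  expect_equal(fit_free$kLa_h, 2, tolerance = 1e-3)

  # degenerate traces
  flat <- intensity_trace(0:9, rep(500, 10), I_max = 1000, I_min = 0)
  expect_error(fit_kla(flat, a = 16.4), "constant")
  short <- intensity_trace(0:3, c(5, 4, 3, 2), I_max = 5, I_min = 1)
  expect_error(fit_kla(short, a = 16.4), "at least 5")
})

test_that("fit is invariant to affine intensity rescaling and time units", {
  syn <- gen_luminescence(trace_spec(kLa_true = 1.5 / 3600, noise_sigma = 30,
                                     seed = 21))
  f0 <- fit_kla(syn$trace, a = 16.4)
  g <- 3.7; off <- 250
  scaled <- intensity_trace(syn$trace$times, g * syn$trace$I_recorded + off,
                            I_max = g * syn$trace$I_max + off,
                            I_min = g * syn$trace$I_min + off)
  f1 <- fit_kla(scaled, a = 16.4)
  expect_equal(f1$kLa, f0$kLa, tolerance = 1e-8)
  expect_equal(f1$sse, g^2 * f0$sse, tolerance = 1e-6)

  # minutes instead of seconds: kLa in 1/min is 60x the 1/s value
  mins <- intensity_trace(syn$trace$times / 60, syn$trace$I_recorded,
                          I_max = syn$trace$I_max, I_min = syn$trace$I_min)
  f2 <- fit_kla(mins, a = 16.4)
  expect_equal(f2$kLa, 60 * f0$kLa, tolerance = 1e-6)
})

test_that("plateau fallback estimates endpoints when the trace lacks them", {
  syn <- gen_luminescence(trace_spec(kLa_true = 2 / 3600, noise_sigma = 0,
                                     duration = 10 * 1800, dt = 30))
  bare <- intensity_trace(syn$trace$times, syn$trace$I_recorded)
  fit <- fit_kla(bare, a = 16.4)
  # approximate: leading-plateau median underestimates I_max on a trace
  # that starts decaying immediately
  expect_equal(fit$kLa_h, 2, tolerance = 0.25)
})

test_that("a single-kLa fit on a time-varying-kLa trace shows the early/late bias", {
  k0 <- 2 / 3600
  ramp <- function(t) k0 * (0.5 + t / 9000)  # kLa increasing through the run
  syn <- gen_luminescence(trace_spec(kLa_true = ramp, noise_sigma = 0,
                                     duration = 9000))
  fit <- fit_kla(syn$trace, a = 16.4)
  n <- fit$n; q <- floor(n / 4)
  early <- mean(fit$residuals[1:q])
  late <- mean(fit$residuals[(n - q + 1):n])
  # model over-predicts the early points and under-predicts the late ones
  expect_lt(early, 0)
  expect_gt(late, 0)
})
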