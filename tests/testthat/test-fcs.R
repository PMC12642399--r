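test_that("the single-component model has the expected analytic behavior", {
  geom <- test_geometry()  # structure ratio 0.04
  expect_equal(model_autocorrelation(0, 5, 1e-4, geom), 1 + 1 / 5)
  expect_equal(model_autocorrelation(1e4, 5, 1e-4, geom), 1,
               tolerance = 1e-6)
  expect_equal(model_autocorrelation(1e-4, 1, 1e-4, geom),
               1 + 0.5 / sqrt(1.04), tolerance = 1e-12)
  # strictly decreasing in lag; amplitude scales exactly as 1/N
  lags <- 10^seq(-6, 0, length.out = 40)
  g <- model_autocorrelation(lags, 3, 1e-4, geom)
  expect_true(all(diff(g) < 0))
  g2 <- model_autocorrelation(lags, 6, 1e-4, geom)
  expect_equal((g - 1) / (g2 - 1), rep(2, 40))
  expect_error(model_autocorrelation(1e-4, 0, 1e-4, geom), "n_particles")
  expect_error(model_autocorrelation(1e-4, 1, -1, geom), "taud")
  expect_error(instrument_geometry(1e-6, 2e-7), "structure ratio")
})

test_that("fits round-trip noiseless model data across a parameter grid", {
  for (kappa_geom in list(instrument_geometry(2e-7, 1e-6),
                          instrument_geometry(3e-7, 1.5e-6))) {
    for (N in c(0.5, 5, 50)) {
      for (taud in c(1e-5, 1e-4, 1e-2)) {
        lags <- exp(seq(log(1e-6), log(1), length.out = 50))
        tr <- autocorrelation_trace(
          lags, model_autocorrelation(lags, N, taud, kappa_geom))
        fit <- fit_autocorrelation(tr, kappa_geom)
        expect_true(fit$converged)
        expect_equal(fit$n_particles, N, tolerance = 1e-3)
        expect_equal(fit$taud, taud, tolerance = 1e-3)
      }
    }
  }
})

test_that("noisy traces recover parameters to a few percent", {
  geom <- test_geometry()
  cal <- test_calibration()
  res <- t(vapply(1:30, function(s) {
    tr <- generate_fcs_trace(radius_for_taud(1e-4), geometry = geom,
                             cal = cal, n_particles = 5, noise_sd = 0.001,
                             seed = s)
    f <- fit_autocorrelation(tr, geom)
    c(f$n_particles, f$taud)
  }, numeric(2)))
  expect_equal(median(res[, 1]), 5, tolerance = 0.05)
  expect_equal(median(res[, 2]), 1e-4, tolerance = 0.05)
})

test_that("flat traces return a non-converged fit, not an error", {
  lags <- exp(seq(log(1e-6), log(1), length.out = 50))
  f <- fit_autocorrelation(autocorrelation_trace(lags, rep(1, 50)),
                           test_geometry())
  expect_false(f$converged)
  expect_match(f$message, "flat|noise")
  set.seed(3)
  f2 <- fit_autocorrelation(
    autocorrelation_trace(lags, 1 + rnorm(50, sd = 1e-4)), test_geometry())
  expect_false(f2$converged)
})

test_that("radius conversion is the calibration-scaled Stokes-Einstein law", {
  cal <- fcs_calibration(d_ref = 4.14e-10, taud_ref = 30e-6,
                         temperature = 298)
  # calibration identity
  expect_equal(diffusion_time_to_radius(30e-6, cal),
               1.380649e-23 * 298 / (6 * pi * 1e-3 * 4.14e-10))
  # linearity
  expect_equal(diffusion_time_to_radius(60e-6, cal),
               2 * diffusion_time_to_radius(30e-6, cal))
  # worked value: 300 us diffusion time -> 5.3 nm
  expect_equal(signif(diffusion_time_to_radius(300e-6, cal) * 1e9, 2), 5.3)
  # algebraic identity: Rh = kB T / (6 pi eta D_sample)
  taud <- 7e-5
  d_sample <- cal$d_ref * cal$taud_ref / taud
  expect_equal(diffusion_time_to_radius(taud, cal),
               1.380649e-23 * 298 / (6 * pi * 1e-3 * d_sample),
               tolerance = 1e-12)
})

test_that("radius_series fits batches and reflects polydispersity", {
  geom <- test_geometry()
  cal <- test_calibration()
  r_true <- 5e-9
  traces <- lapply(1:50, function(s)
    generate_fcs_trace(r_true, geometry = geom, cal = cal,
                       n_particles = 5, noise_sd = 0.001, seed = 100 + s))
  series <- radius_series(traces, geom, cal)
  expect_equal(nrow(series), 50)
  expect_true(all(series$converged))
  expect_equal(median(series$radius_m), r_true, tolerance = 0.05)
  s1 <- summarize_radius_series(series)
  expect_equal(s1$n_converged, 50)
  # a two-population mixture spreads the fitted radii
  mix <- lapply(1:50, function(s)
    generate_fcs_trace(c(2e-9, 20e-9),
                       weights = if (s %% 2) c(0.9, 0.1) else c(0.3, 0.7),
                       geometry = geom, cal = cal, n_particles = 5,
                       noise_sd = 0.001, seed = 200 + s))
  series_mix <- radius_series(mix, geom, cal)
  expect_gt(IQR(series_mix$radius_m, na.rm = TRUE),
            IQR(series$radius_m))
  # single trace in, length-1 series out
  expect_equal(nrow(radius_series(traces[[1]], geom, cal)), 1)
})

test_that("traces read back from delimited text", {
  geom <- test_geometry()
  tr <- generate_fcs_trace(5e-9, geometry = geom, cal = test_calibration(),
                           n_particles = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(lag_s = tr$lags, g = tr$g_values), path,
            row.names = FALSE)
  back <- read_fcs_trace(path)
  expect_equal(back$lags, tr$lags)
  expect_equal(back$g_values, tr$g_values)
})
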