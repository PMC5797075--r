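test_that("modified Beer-Lambert evaluation matches direct substitution", {
  # eps c B = 1 cm^-1 over a 3 mm liquid path plus wall loss 0.5
  p <- mbll_params(1, eps_c = 1 / 1.2, path_factor = 1.2, wall_loss = 0.5,
                   d0_mm = 4, d1_mm = 0.5)
  expect_equal(mbll_log_intensity(p), -0.8, tolerance = 1e-12)
  # transparent sample: output equals input at every wavelength
  p0 <- mbll_params(c(10, 20, 30), eps_c = rep(0, 3), wall_loss = 0,
                    d0_mm = 4, d1_mm = 0.5)
  expect_equal(mbll_log_intensity(p0), log(c(10, 20, 30)))
  # attenuation is linear in the liquid thickness d0 - 2 d1
  a1 <- mbll_log_intensity(mbll_params(1, 2, 1.3, 0, d0_mm = 4, d1_mm = 0.5))
  a2 <- mbll_log_intensity(mbll_params(1, 2, 1.3, 0, d0_mm = 7, d1_mm = 0.5))
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
  expect_error(mbll_params(1, 1, d0_mm = 1, d1_mm = 0.5), "geometry")
})

test_that("extinction surrogate is anchored, positive and reproducible", {
  wl <- seq(620, 1772, length.out = 860)
  eps <- make_extinction_profile(wl, seed = 1)
  at800 <- eps[which.min(abs(wl - 800))]
  # 70 g/L lands in the configured absorption window at 800 nm
  expect_gt(at800 * 70, 0.33)
  expect_lt(at800 * 70, 0.40)
  # and 70-240 g/L spans within the simulated 0.35-1.55 cm^-1 grid range
  expect_true(all(eps * 70 > 0))
  expect_lt(max(at800 * 240), 1.55)
  expect_true(all(eps > 0))
  expect_identical(eps, make_extinction_profile(wl, seed = 1))
  expect_false(identical(eps, make_extinction_profile(wl, seed = 2)))
})

test_that("noiseless samples invert exactly to -eps c slopes", {
  cfg <- synthetic_config(wavelength_nm = seq(620, 1772, length.out = 50),
                          noise_sd = 0, path_factor = 1)
  set.seed(1)
  sp <- generate_sample(cfg, conc = 120, measurement = 1,
                        d1_mm = 0.6, g_loss = 0.8)
  ss <- compute_slope_spectrum(sp)
  # d ln I / d l = -eps * c (per cm) -> /10 per mm
  expect_equal(ss$slope_per_mm, -cfg$extinction * 120 / 10,
               tolerance = 1e-10)
  expect_true(all(sp$intensity > 0))
  expect_error(generate_sample(cfg, conc = 500), "range")
})

test_that("wall loss moves intercepts but never the slope spectrum", {
  cfg <- synthetic_config(wavelength_nm = seq(620, 1772, length.out = 30),
                          noise_sd = 0)
  sp1 <- generate_sample(cfg, 100, 1, d1_mm = 0.55, g_loss = 0.5)
  sp2 <- generate_sample(cfg, 100, 1, d1_mm = 0.55, g_loss = 1.1)
  s1 <- compute_slope_spectrum(sp1)
  s2 <- compute_slope_spectrum(sp2)
  expect_equal(s1$slope_per_mm, s2$slope_per_mm, tolerance = 1e-12)
  expect_equal(s2$intercept, s1$intercept - 0.6, tolerance = 1e-10)
})

test_that("the film protocol thins the liquid at unchanged plate grid", {
  cfg <- synthetic_config(wavelength_nm = c(700, 900, 1100), noise_sd = 0)
  m1 <- generate_sample(cfg, 140, 1, d1_mm = 0.6, g_loss = 0.7)
  m2 <- generate_sample(cfg, 140, 2, d1_mm = 0.6, g_loss = 0.7)
  expect_identical(m1$pathlength_mm, m2$pathlength_mm)
  # identical wall loss: the intensity ratio is exactly the Beer factor of
  # the 0.3 mm of displaced liquid, constant across plate separations
  ratio <- log(m2$intensity) - log(m1$intensity)
  expect_equal(ratio[1, ], cfg$extinction * 140 * 0.03 * cfg$path_factor,
               tolerance = 1e-10)
  expect_equal(ratio[1, ], ratio[4, ], tolerance = 1e-12)
})

test_that("datasets honour the range, split and seed contracts", {
  cfg <- synthetic_config(wavelength_nm = seq(700, 1700, length.out = 20))
  ds <- generate_dataset(cfg, n_samples = 60, seed = 4)
  expect_equal(table(ds$samples$split),
               table(factor(rep(c("calibration", "prediction"), c(40, 20)))))
  expect_true(all(ds$samples$hb_g_per_l >= 72 &
                    ds$samples$hb_g_per_l <= 161))
  expect_length(ds$spectra_m1, 60)
  expect_length(ds$spectra_m2, 60)
  ds2 <- generate_dataset(cfg, n_samples = 60, seed = 4)
  expect_identical(ds, ds2)
  ds3 <- generate_dataset(cfg, n_samples = 60, seed = 5)
  expect_false(identical(ds$samples$hb_g_per_l, ds3$samples$hb_g_per_l))
})

test_that("recovered slopes are affine in concentration", {
  cfg <- synthetic_config(wavelength_nm = seq(650, 1650, length.out = 10),
                          noise_sd = 0)
  conc <- seq(75, 155, length.out = 9)
  slope_at_1 <- vapply(conc, function(cc) {
    sp <- generate_sample(cfg, cc, 1, d1_mm = 0.6, g_loss = 0.7)
    compute_slope_spectrum(sp)$slope_per_mm[1]
  }, numeric(1))
  r2 <- summary(stats::lm(slope_at_1 ~ conc))$r.squared
  expect_gt(r2, 0.999)
})
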