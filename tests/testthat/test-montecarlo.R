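test_that("fresnel_reflectance matches closed forms", {
  # matched media reflect nothing at any angle
  for (ci in c(1, 0.7, 0.3, 0.05))
    expect_identical(fresnel_reflectance(1.4, 1.4, ci), 0)
  # normal incidence closed form ((n1-n2)/(n1+n2))^2
  expect_equal(fresnel_reflectance(1.0, 1.5, 1), 0.04)
  expect_equal(fresnel_reflectance(1.5, 1.0, 1), 0.04)
  # beyond the critical angle: total internal reflection
  expect_identical(fresnel_reflectance(1.5, 1.0, 0.1), 1)
  # limits and input validation
  expect_true(all(fresnel_reflectance(1.0, 1.33, seq(0, 1, 0.1)) >= 0))
  expect_true(all(fresnel_reflectance(1.0, 1.33, seq(0, 1, 0.1)) <= 1))
  expect_error(fresnel_reflectance(1.0, 1.5, -0.1), "cos_incidence")
  expect_error(fresnel_reflectance(1.0, 1.5, 1.1), "cos_incidence")
})

test_that("Henyey-Greenstein sampling matches its inverse CDF and mean", {
  # closed form at u = 0.5, g = 0.8:
  # (1/2g) [1 + g^2 - ((1 - g^2)/(1 - g + 2 g u))^2]
  expect_equal(sample_scattering_cosine(0.8, 0.5),
               (1 / 1.6) * (1.64 - (0.36 / 1.0)^2), tolerance = 1e-12)
  # isotropic special case maps u linearly onto [-1, 1]
  expect_equal(sample_scattering_cosine(0, c(0, 0.25, 0.5, 0.75)),
               c(-1, -0.5, 0, 0.5))
  # E[cos theta] = g, checked within 3 standard errors
  set.seed(31)
  for (g in c(0, 0.8)) {
    draws <- sample_scattering_cosine(g, stats::runif(2e5))
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - g), 3 * se)
  }
  expect_true(all(abs(sample_scattering_cosine(0.75, stats::runif(1e3))) <= 1))
  expect_error(sample_scattering_cosine(1, 0.5), "g")
})

test_that("clear matched-index stacks obey Beer-Lambert exactly", {
  # continuous absorption weighting makes the ballistic case exact
  r <- run_mc(beer_stack(1, 1), settings = quick_mc(2e3, 7))
  expect_equal(r$total_transmittance, exp(-1), tolerance = 1e-12)
  expect_equal(r$detected_weight_fraction, exp(-1), tolerance = 1e-12)
  # multi-layer stack: exp(-sum mu_a d)
  st <- layer_stack(list(optical_layer(1, 0.5, 0, 0, 1),
                         optical_layer(1, 2.0, 0, 0, 0.25)))
  r2 <- run_mc(st, settings = quick_mc(2e3, 8))
  expect_equal(r2$total_transmittance, exp(-1), tolerance = 1e-12)
  # vacuum: everything is detected
  r3 <- run_mc(layer_stack(list(optical_layer(1, 0, 0, 0, 1))),
               settings = quick_mc(500, 9))
  expect_identical(r3$detected_weight_fraction, 1)
})

test_that("lossless slab reflectance matches the multiple-reflection series", {
  # R_total = 2R/(1+R) with R = 0.04 for n = 1.5 in air
  n <- 2e5
  r <- run_mc(glass_stack(), settings = quick_mc(n, 3))
  expected <- 2 * 0.04 / 1.04
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(r$total_reflectance - expected), 3 * se)
  expect_equal(r$total_reflectance + r$total_transmittance, 1,
               tolerance = 1e-9) # nothing absorbs
})

test_that("energy is conserved and detection bounded by transmission", {
  st <- bag_stack(d1_mm = 0.5, mus1 = 75, mua2 = 0.35, d2_mm = 3.0)
  r <- run_mc(st, settings = quick_mc(1e5, 4))
  expect_lt(abs(r$total_reflectance + r$total_transmittance +
                  r$total_absorbance - 1), 2e-3)
  expect_lte(r$detected_weight_fraction, r$total_transmittance)
  expect_gt(r$detected_weight_fraction, 0)
})

test_that("identical settings reproduce bit-identical results", {
  st <- bag_stack(d1_mm = 0.5, mus1 = 75, mua2 = 0.35, d2_mm = 3.0)
  r1 <- run_mc(st, settings = quick_mc(2e4, 123))
  r2 <- run_mc(st, settings = quick_mc(2e4, 123))
  expect_identical(r1, r2)
  r3 <- run_mc(st, settings = quick_mc(2e4, 124))
  expect_false(identical(r1$detected_weight_fraction,
                         r3$detected_weight_fraction))
})

test_that("straight rays land on the entry axis when nothing scatters", {
  # matched indices, mu_s = 0: exit point equals the launch radius, so a
  # detector as small as the beam still catches the full Beer weight
  st <- beer_stack(0.3, 1)
  r <- run_mc(st, detector = detector_spec(1.0, 0.22),
              settings = quick_mc(2e3, 5))
  expect_equal(r$detected_weight_fraction, r$total_transmittance,
               tolerance = 1e-12)
  expect_equal(r$total_transmittance, exp(-0.3), tolerance = 1e-12)
})

test_that("trace_photon partitions a single photon's weight", {
  out <- trace_photon(layer_stack(list(optical_layer(1, 0, 0, 0, 1))),
                      seed = 2)
  expect_identical(out$detected, 1)
  expect_identical(out$reflected, 0)
  out2 <- trace_photon(beer_stack(1, 1), seed = 3)
  expect_equal(out2$detected + out2$transmitted + out2$reflected +
                 out2$absorbed, 1, tolerance = 1e-12)
})

test_that("absorption sweeps are exact for clear stacks and monotone", {
  grid <- seq(0.35, 1.55, by = 0.05)
  # mu_s = 0, matched indices: ln I = -mu_a2 * d2 exactly, slope -d2 (cm)
  clear <- layer_stack(list(optical_layer(1, 0.5, 0, 0, 0.4)))
  sw <- sweep_absorption(clear, grid, d2_mm = 4.0, settings = quick_mc(1e3, 6))
  expect_equal(nrow(sw), 25)
  fit <- fit_line(sw$mu_a2_cm1, sw$ln_detected_intensity)
  expect_equal(fit$slope, -0.4, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  # scattering sandwich: shared photon paths make the curve exactly monotone
  st <- bag_stack(d1_mm = 0.5, mus1 = 75)
  sw2 <- sweep_absorption(st, grid, d2_mm = 4.0, settings = quick_mc(2e4, 6))
  expect_true(all(diff(sw2$ln_detected_intensity) < 0))
  expect_error(sweep_absorption(st, numeric(0)), "nonempty")
  expect_error(sweep_absorption(st, c(0.5, -1)), "positive")
})

test_that("thickness sweeps reproduce Beer slopes and duplicate grid points", {
  d2g <- seq(3.0, 4.0, by = 0.1)
  clear <- layer_stack(list(optical_layer(1, 0, 0, 0, 0.4)))
  sw <- sweep_thickness(clear, mu_a2 = 1.0, d2_grid_mm = d2g,
                        settings = quick_mc(1e3, 6))
  expect_equal(nrow(sw), 11)
  # ln I = -mu_a2 * d2(cm): slope per mm is -mu_a2/10
  fit <- fit_line(sw$d2_mm, sw$ln_detected_intensity)
  expect_equal(fit$slope, -0.1, tolerance = 1e-9)
  st <- bag_stack(d1_mm = 0.5, mus1 = 75)
  dup <- sweep_thickness(st, 0.35, c(3.0, 3.0, 3.5), settings = quick_mc(5e3, 6))
  expect_identical(dup$ln_detected_intensity[1], dup$ln_detected_intensity[2])
})
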