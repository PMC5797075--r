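test_that("fit_line is exact on lines and matches a normal-equations oracle", {
  f <- fit_line(c(0, 1, 2), c(1, 3, 5))
  expect_equal(unlist(f), c(slope = 2, intercept = 1, rss = 0),
               tolerance = 1e-12)
  f2 <- fit_line(c(0, 1), c(0, 3))
  expect_equal(f2$slope, 3)
  expect_equal(f2$intercept, 0)
  # exact exponential on the plate-separation grid
  x <- c(4.2, 3.8, 3.4, 3.0)
  f3 <- fit_line(x, log(10 * exp(-0.5 * x)))
  expect_equal(f3$slope, -0.5, tolerance = 1e-12)
  expect_equal(f3$intercept, log(10), tolerance = 1e-12)
  expect_lt(f3$rss, 1e-20)
  # brute-force normal equations on random well-conditioned designs
  set.seed(17)
  for (i in 1:20) {
    x <- stats::runif(10, 1, 5)
    y <- stats::rnorm(10)
    f <- fit_line(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(f$intercept, beta[1], tolerance = 1e-10)
    expect_equal(f$slope, beta[2], tolerance = 1e-10)
    expect_equal(f$rss, sum((y - X %*% beta)^2), tolerance = 1e-10)
  }
  expect_error(fit_line(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_line(1:3, 1:4), "length")
})

test_that("slope spectra recover exponential decays and ignore gain", {
  sp <- exp_spectra(k = 0.5)
  ss <- compute_slope_spectrum(sp)
  # per-wavelength decay rates were j * k / 2 for channel j
  expect_equal(ss$slope_per_mm, -0.5 * seq_along(sp$wavelength_nm) / 2,
               tolerance = 1e-12)
  expect_lt(max(ss$rss), 1e-20)
  # constant intensity: all slopes zero
  flat <- multipath_spectra(1:5, c(3, 3.4, 3.8, 4.2),
                            matrix(7, 4, 5))
  expect_equal(compute_slope_spectrum(flat)$slope_per_mm, rep(0, 5))
  # multiplying all intensities by gamma leaves slopes untouched and
  # shifts intercepts by ln(gamma) -- the wall-loss cancellation at the
  # heart of the method
  g <- 3.7
  sp2 <- multipath_spectra(sp$wavelength_nm, sp$pathlength_mm,
                           g * sp$intensity)
  ss2 <- compute_slope_spectrum(sp2)
  expect_equal(ss2$slope_per_mm, ss$slope_per_mm, tolerance = 1e-10)
  expect_equal(ss2$intercept, ss$intercept + log(g), tolerance = 1e-10)
})

test_that("nonpositive intensities are refused with cell context", {
  I <- matrix(1, 4, 3)
  I[2, 3] <- 0
  sp <- multipath_spectra(c(700, 800, 900), c(4.2, 3.8, 3.4, 3.0), I)
  expect_error(compute_slope_spectrum(sp), "900 nm.*3\\.8 mm")
  expect_error(multipath_spectra(1:3, c(3, 3), matrix(1, 2, 3)),
               "strictly increasing or decreasing")
  expect_error(multipath_spectra(1:3, c(3, 4), matrix(1, 3, 2)), "2 x 3")
})

test_that("difference coefficient matches hand evaluation and its identities", {
  expect_equal(difference_coefficient(c(1, 2, 3), c(2, 3, 4)), 1.5)
  p <- c(1.2, -0.4, 2.2, 0.9)
  expect_identical(difference_coefficient(p, p), 0)
  set.seed(23)
  for (i in 1:20) {
    a <- stats::rnorm(25)
    b <- stats::rnorm(25)
    # symmetry
    expect_equal(difference_coefficient(a, b), difference_coefficient(b, a))
    expect_gte(difference_coefficient(a, b), 0)
    # constant-shift identity: DC(P, P + c) = n c^2 / sum((p - pbar)^2)
    cshift <- stats::runif(1, -2, 2)
    expect_equal(difference_coefficient(a, a + cshift),
                 25 * cshift^2 / sum((a - mean(a))^2), tolerance = 1e-10)
    # invariance under common rescaling of both curves
    expect_equal(difference_coefficient(3 * a, 3 * b),
                 difference_coefficient(a, b), tolerance = 1e-12)
  }
  expect_error(difference_coefficient(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(difference_coefficient(1:3, 1:4), "length")
})
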