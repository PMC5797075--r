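#' Unpolarized Fresnel reflectance at a planar interface
#'
#' Average of the s- and p-polarized reflectances; returns 1 at and beyond
#' the critical angle of total internal reflection.
#'
#' @param n_incident,n_transmitted Refractive indices (>= 1).
#' @param cos_incidence Cosine of the incidence angle, in [0, 1].
#' @return Reflectance fraction in [0, 1] (vectorized over `cos_incidence`).
#' @examples
#' fresnel_reflectance(1.0, 1.5, 1)   # 0.04
#' fresnel_reflectance(1.5, 1.0, 0.1) # 1, beyond the critical angle
#' @export
fresnel_reflectance <- function(n_incident, n_transmitted, cos_incidence) {
  if (any(cos_incidence < 0) || any(cos_incidence > 1))
    stop("cos_incidence must lie in [0, 1]")
  if (n_incident < 1 || n_transmitted < 1)
    stop("refractive indices must be >= 1")
  vapply(cos_incidence, function(ci)
    fresnel_cpp(n_incident, n_transmitted, ci), numeric(1))
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function; over many
#' uniform draws the sample mean of the cosine converges to `g`.
#'
#' @param g Anisotropy factor, |g| < 1; `g = 0` is isotropic.
#' @param u Uniform random number(s) in [0, 1).
#' @return Deflection cosine(s) in [-1, 1].
#' @examples
#' sample_scattering_cosine(0.8, 0.5) # 0.944...
#' @export
sample_scattering_cosine <- function(g, u) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  if (any(u < 0) || any(u >= 1 + 1e-12)) stop("u must lie in [0, 1)")
  vapply(u, function(ui) hg_cosine_cpp(g, ui), numeric(1))
}

.run_kernel <- function(stack, beam, detector, settings, mua_grid = numeric(0)) {
  sm <- .stack_matrix(stack)
  mc_transport_cpp(sm$m, stack$n_above, stack$n_below,
                   beam$radius_cm, detector$radius_cm,
                   detector$numerical_aperture,
                   settings$n_photons, settings$seed, sm$liquid_index,
                   mua_grid, settings$roulette_threshold,
                   settings$roulette_survival)
}

#' Run the Monte Carlo transport simulation
#'
#' Launches `settings$n_photons` photons uniformly over the beam disc at
#' normal incidence and propagates them through the stack with
#' Henyey-Greenstein scattering, probabilistic Fresnel boundaries and
#' Russian roulette. Specular reflection at the entry face is deducted
#' before propagation. Identical settings give bit-identical results.
#'
#' @param stack A [layer_stack()].
#' @param beam A [beam_spec()].
#' @param detector A [detector_spec()].
#' @param settings An [mc_settings()].
#' @return An object of class `mc_result` with fields
#'   `detected_weight_fraction`, `detected_se`, `total_transmittance`,
#'   `total_reflectance` (including specular), `total_absorbance`,
#'   `n_photons` and `seed`.
#' @examples
#' st <- bag_stack(mua2 = 0.35, d2_mm = 3.0)
#' run_mc(st, settings = mc_settings(n_photons = 1e4, seed = 7))
#' @export
run_mc <- function(stack, beam = beam_spec(), detector = detector_spec(),
                   settings = mc_settings()) {
  stopifnot(inherits(stack, "layer_stack"), inherits(beam, "beam_spec"),
            inherits(detector, "detector_spec"),
            inherits(settings, "mc_settings"))
  out <- .run_kernel(stack, beam, detector, settings)
  structure(list(detected_weight_fraction = out$detected[1],
                 detected_se = out$detected_se[1],
                 total_transmittance = out$transmitted[1],
                 total_reflectance = out$reflected[1],
                 total_absorbance = out$absorbed[1],
                 specular_reflectance = out$specular,
                 n_photons = out$n_photons, seed = settings$seed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(paste0("<mc_result> n = %g photons\n",
                     "  detected  %.6g (se %.2g)\n  transmit  %.6g\n",
                     "  reflect   %.6g\n  absorb    %.6g\n"),
              x$n_photons, x$detected_weight_fraction, x$detected_se,
              x$total_transmittance, x$total_reflectance,
              x$total_absorbance))
  invisible(x)
}

#' Trace a single photon
#'
#' Runs the transport kernel for one photon and reports how its terminal
#' weight was partitioned. Mainly useful for testing and teaching; results
#' for ensembles come from [run_mc()].
#'
#' @inheritParams run_mc
#' @param seed Substream seed for this photon.
#' @return List with `detected`, `transmitted`, `reflected` and `absorbed`
#'   weights (summing to 1 up to Russian-roulette variance).
#' @export
trace_photon <- function(stack, beam = beam_spec(), detector = detector_spec(),
                         seed = 1L) {
  s <- mc_settings(n_photons = 1, seed = seed)
  out <- .run_kernel(stack, beam, detector, s)
  list(detected = out$detected[1],
       transmitted = out$transmitted[1] - out$detected[1],
       reflected = out$reflected[1],
       absorbed = out$absorbed[1])
}

.substream <- function(seed, offset) {
  (seed * 69069 + offset) %% 2147483629
}

#' Sweep the liquid absorption coefficient
#'
#' Computes the log detected intensity as a function of the liquid-layer
#' absorption coefficient, at fixed liquid thickness. A single photon
#' ensemble is propagated through the pure-scattering process and
#' re-weighted exactly by the Beer factor for every grid value (correlated
#' sampling), so the whole curve shares one set of photon paths.
#'
#' @param stack_template A `layer_stack`; its liquid layer's `mu_a` and
#'   thickness are overridden by `mu_a2_grid` and `d2_mm`.
#' @param mu_a2_grid Absorption grid, cm^-1 (positive, nonempty).
#' @param d2_mm Liquid thickness in mm (default: the template's).
#' @inheritParams run_mc
#' @return Data frame with columns `mu_a2_cm1`, `ln_detected_intensity`,
#'   `stderr` (standard error of the log intensity, delta method) and
#'   `detected_fraction`. Grid points with zero detected weight get `NA`
#'   log intensity and a warning.
#' @export
sweep_absorption <- function(stack_template, mu_a2_grid, d2_mm = NULL,
                             beam = beam_spec(), detector = detector_spec(),
                             settings = mc_settings()) {
  if (length(mu_a2_grid) < 1 || any(mu_a2_grid <= 0))
    stop("mu_a2_grid must be nonempty and positive")
  stack <- stack_template
  if (!is.null(d2_mm))
    stack$layers[[stack$liquid_index]]$thickness_cm <- d2_mm / 10
  out <- .run_kernel(stack, beam, detector, settings, as.numeric(mu_a2_grid))
  f <- out$detected
  if (any(f <= 0))
    warning("zero detected weight at some grid points; ln undefined there")
  ln <- ifelse(f > 0, log(f), NA_real_)
  data.frame(mu_a2_cm1 = as.numeric(mu_a2_grid),
             ln_detected_intensity = ln,
             stderr = ifelse(f > 0, out$detected_se / f, NA_real_),
             detected_fraction = f)
}

#' Sweep the liquid thickness
#'
#' Computes the log detected intensity over a grid of liquid thicknesses at
#' fixed absorption. All thicknesses share the per-photon seed substreams of
#' the master seed (common random numbers), which correlates the Monte
#' Carlo noise along the curve and sharply reduces the variance of fitted
#' slopes; duplicated grid values reproduce identical intensities.
#'
#' @param stack_template A `layer_stack`.
#' @param mu_a2 Liquid absorption coefficient, cm^-1.
#' @param d2_grid_mm Increasing grid of liquid thicknesses, mm.
#' @inheritParams run_mc
#' @return Data frame with columns `d2_mm`, `ln_detected_intensity`,
#'   `stderr`, `detected_fraction`.
#' @export
sweep_thickness <- function(stack_template, mu_a2, d2_grid_mm,
                            beam = beam_spec(), detector = detector_spec(),
                            settings = mc_settings()) {
  if (length(d2_grid_mm) < 1) stop("d2_grid_mm must be nonempty")
  if (is.unsorted(d2_grid_mm)) stop("d2_grid_mm must be non-decreasing")
  rows <- lapply(d2_grid_mm, function(d2) {
    stack <- stack_template
    stack$layers[[stack$liquid_index]]$mu_a <- mu_a2
    stack$layers[[stack$liquid_index]]$thickness_cm <- d2 / 10
    out <- .run_kernel(stack, beam, detector, settings)
    f <- out$detected[1]
    data.frame(d2_mm = d2,
               ln_detected_intensity = if (f > 0) log(f) else NA_real_,
               stderr = if (f > 0) out$detected_se[1] / f else NA_real_,
               detected_fraction = f)
  })
  res <- do.call(rbind, rows)
  if (any(res$detected_fraction <= 0))
    warning("zero detected weight at some grid points; ln undefined there")
  res
}

# Full (mu_a2 x d2) log-intensity surface for one package configuration:
# one kernel run per thickness re-weighted over the whole absorption grid,
# all runs sharing the per-photon substreams of the master seed (common
# random numbers). Returns list(ln = matrix [d2 x mua2], se = matrix).
.sweep_grid <- function(stack_template, mu_a2_grid, d2_grid_mm,
                        beam, detector, settings) {
  L <- length(d2_grid_mm)
  ln <- se <- matrix(NA_real_, L, length(mu_a2_grid))
  for (i in seq_len(L)) {
    stack <- stack_template
    stack$layers[[stack$liquid_index]]$thickness_cm <- d2_grid_mm[i] / 10
    out <- .run_kernel(stack, beam, detector, settings,
                       as.numeric(mu_a2_grid))
    f <- out$detected
    ln[i, ] <- ifelse(f > 0, log(f), NA_real_)
    se[i, ] <- ifelse(f > 0, out$detected_se / f, NA_real_)
  }
  list(ln = ln, se = se, d2_mm = d2_grid_mm, mu_a2 = mu_a2_grid)
}
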