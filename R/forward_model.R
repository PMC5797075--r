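#' Modified Beer-Lambert parameters
#'
#' Parameters of the attenuation model for a liquid sample inside a
#' flexible package squeezed to total thickness `d0`:
#' \deqn{\ln I_o = \ln I_i - \epsilon c\,(d_0 - 2 d_1)\,B - G}
#' where `eps_c` is the extinction-concentration product (cm^-1), `B >= 1`
#' the path factor describing scattering-induced path lengthening, and
#' `G >= 0` the unknown ln-domain intensity loss caused by the package
#' wall.
#'
#' @param incident_intensity Incident intensity counts per wavelength (> 0;
#'   scalar or vector).
#' @param eps_c Extinction-concentration product per wavelength, cm^-1.
#' @param path_factor Path factor B per wavelength (>= 1; scalar or vector).
#' @param wall_loss Wall loss G, ln-units (>= 0).
#' @param d0_mm Total thickness (wall + liquid + wall), mm.
#' @param d1_mm Wall thickness, mm; requires `d0_mm > 2 * d1_mm`.
#' @return An object of class `mbll_params`.
#' @export
mbll_params <- function(incident_intensity, eps_c, path_factor = 1.2,
                        wall_loss = 0, d0_mm, d1_mm) {
  if (any(incident_intensity <= 0)) stop("incident_intensity must be > 0")
  if (any(path_factor < 1)) stop("path_factor must be >= 1")
  if (wall_loss < 0) stop("wall_loss must be >= 0")
  if (d0_mm <= 2 * d1_mm)
    stop("geometry error: need d0_mm > 2 * d1_mm")
  structure(list(incident_intensity = incident_intensity, eps_c = eps_c,
                 path_factor = path_factor, wall_loss = wall_loss,
                 d0_mm = d0_mm, d1_mm = d1_mm),
            class = "mbll_params")
}

#' Log transmitted intensity under the modified Beer-Lambert law
#'
#' Evaluates the attenuation model of [mbll_params()] per wavelength. The
#' result is linear in the liquid thickness `d0 - 2 d1`, which is what the
#' slope spectrum exploits: the slope with respect to total thickness is
#' `-eps_c * B` (per cm) regardless of the wall loss `G`.
#'
#' @param params An `mbll_params` object.
#' @return Vector of ln(transmitted intensity), one per wavelength.
#' @examples
#' p <- mbll_params(1, eps_c = 1 / 1.2, path_factor = 1.2, wall_loss = 0.5,
#'                  d0_mm = 4, d1_mm = 0.5)
#' mbll_log_intensity(p) # -0.8
#' @export
mbll_log_intensity <- function(params) {
  stopifnot(inherits(params, "mbll_params"))
  liquid_cm <- (params$d0_mm - 2 * params$d1_mm) / 10
  log(params$incident_intensity) -
    params$eps_c * liquid_cm * params$path_factor - params$wall_loss
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Surrogate extinction profile
#'
#' A smooth, strictly positive extinction curve (sum of Gaussian bands with
#' seed-jittered amplitudes) standing in for the hemoglobin spectrum. It is
#' anchored at 800 nm so that the extinction-concentration product for
#' concentrations of 70-240 g/L spans about 0.35-1.55 cm^-1, the absorption
#' range used in the transport simulations. Deterministic per seed.
#'
#' @param wavelength_nm Wavelength grid, nm.
#' @param seed Integer seed for the band-amplitude jitter.
#' @return Vector of extinction values, cm^-1 per (g/L).
#' @export
make_extinction_profile <- function(wavelength_nm, seed = 1L) {
  if (length(wavelength_nm) < 1) stop("empty wavelength grid")
  bands <- cbind(center = c(620, 760, 910, 1200, 1450, 1690),
                 width  = c(90, 45, 70, 90, 60, 80),
                 amp    = c(1.0, 0.35, 0.55, 0.25, 0.9, 0.4))
  jit <- .with_seed(seed, stats::runif(nrow(bands), -0.1, 0.1))
  shape <- rep(0.25, length(wavelength_nm))
  for (b in seq_len(nrow(bands))) {
    shape <- shape + bands[b, "amp"] * (1 + jit[b]) *
      exp(-((wavelength_nm - bands[b, "center"]) / bands[b, "width"])^2)
  }
  at800 <- 0.25
  for (b in seq_len(nrow(bands))) {
    at800 <- at800 + bands[b, "amp"] * (1 + jit[b]) *
      exp(-((800 - bands[b, "center"]) / bands[b, "width"])^2)
  }
  shape * (0.0055 / at800)
}

#' Synthetic-data generator configuration
#'
#' Declares the generative conditions for multi-pathlength transmission
#' spectra of red-cell suspensions in flexible bags: the wavelength grid,
#' the concentration range, the plate-separation grid, the per-sample wall
#' thickness and wall-loss distributions, the path factor, a multiplicative
#' log-normal noise level, and the extra PVC film (protocol 2) that thickens
#' the wall by 0.3 mm and enlarges the wall loss.
#'
#' @param wavelength_nm Wavelength grid (default 860 channels, 620-1772 nm).
#' @param conc_range_g_l Hb concentration range, g/L (default 72-161).
#' @param pathlengths_mm Plate separations, mm (default 4.2, 3.8, 3.4, 3.0).
#' @param d1_range_mm Per-sample wall thickness range, mm (default 0.5-0.7).
#' @param g_loss_range Per-sample wall-loss range, ln-units; the default
#'   ln(1/0.6)-ln(1/0.4) reproduces empty-bag transmission attenuated by
#'   40-60 percent.
#' @param film_g_increment Range of the additional wall loss from the
#'   attached film, ln-units.
#' @param path_factor Path factor B (scalar or per-wavelength vector, >= 1).
#' @param noise_sd Standard deviation of the multiplicative log-normal
#'   intensity noise (>= 0).
#' @param film_mm Film thickness, mm (default 0.3).
#' @param extinction_seed Seed of the surrogate extinction profile.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(wavelength_nm = seq(620, 1772, length.out = 860),
                             conc_range_g_l = c(72, 161),
                             pathlengths_mm = c(4.2, 3.8, 3.4, 3.0),
                             d1_range_mm = c(0.5, 0.7),
                             g_loss_range = c(log(1 / 0.6), log(1 / 0.4)),
                             film_g_increment = c(0.1, 0.3),
                             path_factor = 1.2,
                             noise_sd = 0.01,
                             film_mm = 0.3,
                             extinction_seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(path_factor < 1)) stop("path_factor must be >= 1")
  if (diff(conc_range_g_l) < 0 || any(conc_range_g_l <= 0))
    stop("invalid concentration range")
  if (length(pathlengths_mm) < 2) stop("need at least two pathlengths")
  cfg <- list(wavelength_nm = as.numeric(wavelength_nm),
              conc_range_g_l = conc_range_g_l,
              pathlengths_mm = as.numeric(pathlengths_mm),
              d1_range_mm = d1_range_mm,
              g_loss_range = g_loss_range,
              film_g_increment = film_g_increment,
              path_factor = path_factor,
              noise_sd = noise_sd, film_mm = film_mm,
              extinction_seed = as.integer(extinction_seed))
  cfg$extinction <- make_extinction_profile(cfg$wavelength_nm,
                                            cfg$extinction_seed)
  # halogen-like smooth source envelope, counts
  cfg$incident_intensity <-
    3e4 * exp(-((cfg$wavelength_nm - 1100) / 500)^2) + 5e3
  structure(cfg, class = "synthetic_config")
}

#' Generate one synthetic multi-pathlength sample
#'
#' Evaluates the modified Beer-Lambert model at every plate separation for
#' one sample, drawing the wall thickness and the wall loss from the
#' configured per-sample distributions (unless given explicitly) and adding
#' multiplicative log-normal noise. Under protocol 2 an extra film thickens
#' the wall: the plate grid is unchanged, the liquid gets thinner, and the
#' wall loss is re-drawn with an extra increment.
#'
#' Uses the current R random number generator state; seed control belongs
#' to the caller (see [generate_dataset()]).
#'
#' @param config A [synthetic_config()].
#' @param conc Hb concentration, g/L, within the configured range.
#' @param measurement 1 (bare bag) or 2 (bag with attached film).
#' @param d1_mm,g_loss Optional explicit wall thickness / wall loss,
#'   overriding the per-sample draws.
#' @param sample_id Optional sample label.
#' @return A [multipath_spectra()] object.
#' @export
generate_sample <- function(config, conc, measurement = 1, d1_mm = NULL,
                            g_loss = NULL, sample_id = NA_character_) {
  stopifnot(inherits(config, "synthetic_config"))
  if (conc < config$conc_range_g_l[1] || conc > config$conc_range_g_l[2])
    stop("concentration outside the configured range")
  if (!measurement %in% c(1, 2)) stop("measurement must be 1 or 2")
  if (is.null(d1_mm))
    d1_mm <- stats::runif(1, config$d1_range_mm[1], config$d1_range_mm[2])
  if (is.null(g_loss)) {
    g_loss <- stats::runif(1, config$g_loss_range[1], config$g_loss_range[2])
    if (measurement == 2)
      g_loss <- g_loss + stats::runif(1, config$film_g_increment[1],
                                      config$film_g_increment[2])
  }
  film <- if (measurement == 2) config$film_mm else 0
  W <- length(config$wavelength_nm)
  L <- length(config$pathlengths_mm)
  I <- matrix(0, L, W)
  for (i in seq_len(L)) {
    liquid_cm <- (config$pathlengths_mm[i] - 2 * d1_mm - film) / 10
    if (liquid_cm <= 0) stop("geometry error: no liquid left between walls")
    ln <- log(config$incident_intensity) -
      config$extinction * conc * liquid_cm * config$path_factor - g_loss
    if (config$noise_sd > 0)
      ln <- ln + stats::rnorm(W, sd = config$noise_sd)
    I[i, ] <- exp(ln)
  }
  multipath_spectra(config$wavelength_nm, config$pathlengths_mm, I,
                    sample_id = sample_id,
                    label = paste0("measurement", measurement))
}

#' Generate a synthetic calibration/prediction dataset
#'
#' Draws `n_samples` concentrations uniformly from the configured range,
#' splits them deterministically into calibration and prediction sets
#' (2:1, i.e. 40/20 at the default n = 60), and produces the protocol-1 and
#' protocol-2 spectra for every sample (same bag wall, independent wall
#' losses). Fully reproducible from the seed.
#'
#' @param config A [synthetic_config()].
#' @param n_samples Number of samples (>= 3; default 60).
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: list with `samples`
#'   (data frame: sample_id, hb_g_per_l, split), `spectra_m1`,
#'   `spectra_m2` (lists of [multipath_spectra()]), `config`, `seed`.
#' @export
generate_dataset <- function(config = synthetic_config(), n_samples = 60,
                             seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_samples < 3) stop("n_samples must be >= 3")
  n_cal <- round(n_samples * 2 / 3)
  .with_seed(seed, {
    conc <- stats::runif(n_samples, config$conc_range_g_l[1],
                         config$conc_range_g_l[2])
    spectra_m1 <- vector("list", n_samples)
    spectra_m2 <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      id <- sprintf("S%03d", i)
      d1 <- stats::runif(1, config$d1_range_mm[1], config$d1_range_mm[2])
      spectra_m1[[i]] <- generate_sample(config, conc[i], measurement = 1,
                                         d1_mm = d1, sample_id = id)
      spectra_m2[[i]] <- generate_sample(config, conc[i], measurement = 2,
                                         d1_mm = d1, sample_id = id)
    }
    samples <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n_samples)),
      hb_g_per_l = conc,
      split = rep(c("calibration", "prediction"),
                  c(n_cal, n_samples - n_cal)))
    structure(list(samples = samples, spectra_m1 = spectra_m1,
                   spectra_m2 = spectra_m2, config = config, seed = seed),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d samples ",
                     "(%d calibration / %d prediction), seed %d\n"),
              nrow(x$samples), sum(x$samples$split == "calibration"),
              sum(x$samples$split == "prediction"), x$seed))
  invisible(x)
}

#' Packaged reference Hb concentrations
#'
#' The 60 hemoglobin concentrations (g/L, hematology-analyzer reference
#' values) of the red-cell-suspension samples, with the standard 40/20
#' calibration/prediction split labels.
#'
#' @return Data frame with columns `sample_id`, `hb_g_per_l`, `split`.
#' @examples
#' range(reference_concentrations()$hb_g_per_l) # 72 161
#' @export
reference_concentrations <- function() {
  path <- system.file("extdata", "hb_concentrations.csv",
                      package = "slopespec", mustWork = TRUE)
  df <- utils::read.csv(path)
  df$split <- rep(c("calibration", "prediction"), c(40, 20))
  df
}
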