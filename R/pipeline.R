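# ---- small utilities ------------------------------------------------------

# djb2 32-bit hash of a JSON-serialized object, for run manifests
.config_hash <- function(x) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                   digits = NA)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# atomic write: writer(path) to a temp file in the target directory, then
# rename over the destination
.write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

# ---- multi-pathlength CSV dialect ----------------------------------------

#' Write multi-pathlength spectra to CSV
#'
#' Dialect: first column `wavelength_nm`, then one intensity column per
#' pathlength, named by its value in mm. Written atomically with full
#' double precision so that write-then-read is an identity up to 1e-9
#' relative.
#'
#' @param spectra A [multipath_spectra()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_multipath_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "multipath_spectra"))
  df <- data.frame(wavelength_nm = spectra$wavelength_nm,
                   t(spectra$intensity), check.names = FALSE)
  names(df)[-1] <- format(spectra$pathlength_mm, trim = TRUE, digits = 15)
  .write_atomic(path, function(p)
    utils::write.csv(format(df, digits = 15, trim = TRUE), p,
                     row.names = FALSE, quote = FALSE))
}

#' Read multi-pathlength spectra from CSV
#'
#' Inverse of [write_multipath_csv()]. Malformed headers and nonpositive
#' intensities raise errors naming the offending cell.
#'
#' @param path CSV file path.
#' @param sample_id,label Optional metadata to attach.
#' @return A [multipath_spectra()] object.
#' @export
read_multipath_csv <- function(path, sample_id = NA_character_,
                               label = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "wavelength_nm")
    stop("malformed header: expected wavelength_nm plus >= 2 pathlength ",
         "columns in ", path)
  pl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(pl))
    stop("malformed header: pathlength columns must be named by their mm ",
         "value in ", path)
  I <- t(as.matrix(df[, -1, drop = FALSE]))
  bad <- which(I <= 0 | is.na(I), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "nonpositive intensity in %s at wavelength %g nm, pathlength %g mm",
      path, df$wavelength_nm[bad[1, 2]], pl[bad[1, 1]]))
  multipath_spectra(df$wavelength_nm, pl, I, sample_id = sample_id,
                    label = label)
}

#' Write a slope spectrum to CSV
#' @param slopes A `slope_spectrum` (see [compute_slope_spectrum()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_slope_csv <- function(slopes, path) {
  .write_atomic(path, function(p)
    utils::write.csv(format(as.data.frame(slopes), digits = 15,
                            trim = TRUE),
                     p, row.names = FALSE, quote = FALSE))
}

# ---- synthetic dataset on disk -------------------------------------------

#' Write a synthetic dataset to a directory
#'
#' Layout: `samples.csv` (sample_id, hb_g_per_l, split), one spectra CSV
#' per sample and measurement under `m1/` and `m2/`, and `manifest.json`
#' recording the seed and a hash of the generator configuration.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset_dir <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(file.path(dir, "m1"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "m2"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  for (i in seq_len(nrow(dataset$samples))) {
    id <- dataset$samples$sample_id[i]
    write_multipath_csv(dataset$spectra_m1[[i]],
                        file.path(dir, "m1", paste0(id, ".csv")))
    write_multipath_csv(dataset$spectra_m2[[i]],
                        file.path(dir, "m2", paste0(id, ".csv")))
  }
  cfg <- unclass(dataset$config)
  manifest <- list(seed = dataset$seed, n_samples = nrow(dataset$samples),
                   config_hash = .config_hash(cfg),
                   wavelengths = length(dataset$config$wavelength_nm),
                   pathlengths_mm = dataset$config$pathlengths_mm,
                   noise_sd = dataset$config$noise_sd)
  .write_atomic(file.path(dir, "manifest.json"), function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}

#' Read a synthetic dataset from a directory
#' @param dir Directory written by [write_dataset_dir()].
#' @return List with `samples`, `spectra_m1`, `spectra_m2`.
#' @export
read_dataset_dir <- function(dir) {
  samples <- utils::read.csv(file.path(dir, "samples.csv"))
  m1 <- lapply(samples$sample_id, function(id)
    read_multipath_csv(file.path(dir, "m1", paste0(id, ".csv")),
                       sample_id = id, label = "measurement1"))
  m2 <- lapply(samples$sample_id, function(id)
    read_multipath_csv(file.path(dir, "m2", paste0(id, ".csv")),
                       sample_id = id, label = "measurement2"))
  list(samples = samples, spectra_m1 = m1, spectra_m2 = m2)
}

# ---- simulation study -----------------------------------------------------

#' Simulation-study configuration
#'
#' Declares the package/liquid configurations and sweep grids of the
#' transport simulation study. The three package configurations contrast
#' wall scattering (75 vs 175 cm^-1 at 0.5 mm) and wall thickness (0.5 vs
#' 0.7 mm at 75 cm^-1); slope curves are fitted over a 3.0-4.0 mm liquid
#' window, plus a 4.0-5.0 mm window for the first configuration. The
#' `"fast"` preset (1e5 photons per thickness run) suits interactive
#' checks; the `"paper"` preset (4e5) brings the Monte Carlo noise floor of
#' the slope-curve difference coefficients to roughly 0.005-0.01 while one
#' full study stays in the ten-minute range on a single core. Every photon
#' of a run contributes to all 25 absorption grid points through exact
#' Beer re-weighting, so the per-grid-point ensemble equals the run size.
#'
#' @param preset `"fast"` or `"paper"` photon budget.
#' @param n_photons Photons per (configuration, thickness) run; overrides
#'   the preset. Each run serves the whole absorption grid by correlated
#'   re-weighting.
#' @param mu_a2_grid Liquid absorption grid, cm^-1.
#' @param d2_fig4_mm Liquid thickness of the intensity-vs-absorption
#'   curves, mm.
#' @param slope_window_mm,alt_window_mm Thickness fit windows, mm.
#' @param d2_step_mm Thickness grid step, mm.
#' @param configs Named list of package configurations
#'   (`list(d1_mm =, mus1 =)`).
#' @return An object of class `sim_study_config`.
#' @export
sim_study_config <- function(preset = c("fast", "paper"), n_photons = NULL,
                             mu_a2_grid = seq(0.35, 1.55, by = 0.05),
                             d2_fig4_mm = 4.0,
                             slope_window_mm = c(3.0, 4.0),
                             alt_window_mm = c(4.0, 5.0),
                             d2_step_mm = 0.1,
                             configs = list(
                               c1 = list(d1_mm = 0.5, mus1 = 75),
                               c2 = list(d1_mm = 0.5, mus1 = 175),
                               c3 = list(d1_mm = 0.7, mus1 = 75))) {
  preset <- match.arg(preset)
  if (is.null(n_photons))
    n_photons <- if (preset == "paper") 4e5 else 1e5
  structure(list(preset = preset, n_photons = n_photons,
                 mu_a2_grid = mu_a2_grid, d2_fig4_mm = d2_fig4_mm,
                 slope_window_mm = slope_window_mm,
                 alt_window_mm = alt_window_mm, d2_step_mm = d2_step_mm,
                 configs = configs),
            class = "sim_study_config")
}

#' Run the Monte Carlo simulation study
#'
#' For every package configuration, computes the log detected intensity
#' over the (absorption, thickness) grid, extracts (a) the intensity
#' curves at the reference thickness and (b) the slope curves from linear
#' fits of log intensity against thickness over the configured windows,
#' and evaluates the difference coefficient for the configured curve
#' pairs. Curve 4 is the first configuration refitted over the alternative
#' thickness window. Bit-identical given (config, seed).
#'
#' @param config A [sim_study_config()].
#' @param seed Master seed; per-run substreams are derived from it.
#' @return An object of class `simulation_study_report`: list with
#'   `intensity_curves`, `slope_curves` (data frames), `dc` (data frame
#'   of curve pairs and their difference coefficients) and `manifest`.
#' @export
run_simulation_study <- function(config = sim_study_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_study_config"))
  wlo <- config$slope_window_mm; whi <- config$alt_window_mm
  ic <- list(); sc <- list()
  for (i in seq_along(config$configs)) {
    cf <- config$configs[[i]]
    nm <- names(config$configs)[i]
    d2max <- if (i == 1L) max(whi, config$d2_fig4_mm) else
      max(wlo, config$d2_fig4_mm)
    d2_grid <- seq(min(wlo), d2max, by = config$d2_step_mm)
    st <- bag_stack(d1_mm = cf$d1_mm, mus1 = cf$mus1)
    settings <- mc_settings(n_photons = config$n_photons, seed = seed)
    surf <- .sweep_grid(st, config$mu_a2_grid, d2_grid,
                        beam_spec(), detector_spec(), settings)
    i4 <- which.min(abs(d2_grid - config$d2_fig4_mm))
    ic[[nm]] <- data.frame(config = nm, mu_a2_cm1 = config$mu_a2_grid,
                           ln_detected_intensity = surf$ln[i4, ],
                           stderr = surf$se[i4, ])
    in_lo <- d2_grid >= min(wlo) - 1e-9 & d2_grid <= max(wlo) + 1e-9
    slopes_lo <- apply(surf$ln[in_lo, , drop = FALSE], 2, function(yy)
      fit_line(d2_grid[in_lo], yy)$slope)
    sc[[nm]] <- data.frame(config = nm, window = "lo",
                           mu_a2_cm1 = config$mu_a2_grid,
                           slope_per_mm = slopes_lo)
    if (i == 1L) {
      in_hi <- d2_grid >= min(whi) - 1e-9 & d2_grid <= max(whi) + 1e-9
      slopes_hi <- apply(surf$ln[in_hi, , drop = FALSE], 2, function(yy)
        fit_line(d2_grid[in_hi], yy)$slope)
      sc[["c4"]] <- data.frame(config = nm, window = "hi",
                               mu_a2_cm1 = config$mu_a2_grid,
                               slope_per_mm = slopes_hi)
    }
  }
  nms <- names(config$configs)
  dc <- rbind(
    data.frame(pair = paste0(nms[1], "-", nms[2]), type = "intensity",
               dc = difference_coefficient(
                 ic[[1]]$ln_detected_intensity,
                 ic[[2]]$ln_detected_intensity)),
    data.frame(pair = paste0(nms[1], "-", nms[3]), type = "intensity",
               dc = difference_coefficient(
                 ic[[1]]$ln_detected_intensity,
                 ic[[3]]$ln_detected_intensity)),
    data.frame(pair = paste0(nms[1], "-", nms[2]), type = "slope",
               dc = difference_coefficient(sc[[nms[1]]]$slope_per_mm,
                                           sc[[nms[2]]]$slope_per_mm)),
    data.frame(pair = paste0(nms[1], "-", nms[3]), type = "slope",
               dc = difference_coefficient(sc[[nms[1]]]$slope_per_mm,
                                           sc[[nms[3]]]$slope_per_mm)),
    data.frame(pair = paste0(nms[1], "-c4"), type = "slope",
               dc = difference_coefficient(sc[[nms[1]]]$slope_per_mm,
                                           sc[["c4"]]$slope_per_mm)))
  manifest <- list(seed = seed, n_photons = config$n_photons,
                   preset = config$preset,
                   config_hash = .config_hash(unclass(config)))
  structure(list(intensity_curves = do.call(rbind, ic),
                 slope_curves = do.call(rbind, sc),
                 dc = dc, manifest = manifest),
            class = "simulation_study_report")
}

#' @export
print.simulation_study_report <- function(x, ...) {
  cat("<simulation_study_report>\n")
  print(x$dc, row.names = FALSE)
  invisible(x)
}

#' Persist a simulation-study report
#' @param report A [run_simulation_study()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$intensity_curves,
                   file.path(dir, "intensity_curves.csv"), row.names = FALSE)
  utils::write.csv(report$slope_curves,
                   file.path(dir, "slope_curves.csv"), row.names = FALSE)
  utils::write.csv(report$dc, file.path(dir, "difference_coefficients.csv"),
                   row.names = FALSE)
  .write_atomic(file.path(dir, "manifest.json"), function(p)
    jsonlite::write_json(report$manifest, p, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}

# ---- model comparison -----------------------------------------------------

# design matrices: slope spectra (model "slope") or single-thickness log
# spectra (model "single") at the given plate separation
.build_design <- function(spectra_list, model = c("slope", "single"),
                          single_thickness_mm = 3.0) {
  model <- match.arg(model)
  if (model == "slope") {
    t(vapply(spectra_list, function(sp)
      compute_slope_spectrum(sp)$slope_per_mm,
      numeric(length(spectra_list[[1]]$wavelength_nm))))
  } else {
    t(vapply(spectra_list, function(sp) {
      i <- which.min(abs(sp$pathlength_mm - single_thickness_mm))
      log(sp$intensity[i, ])
    }, numeric(length(spectra_list[[1]]$wavelength_nm))))
  }
}

#' Compare slope-spectrum and single-thickness calibrations
#'
#' Generates a synthetic dataset and builds two PLSR calibrations from the
#' protocol-1 data: Model 1 on the slope spectra and Model 2 on the
#' log-transmission spectra at a single 3.0 mm plate separation. Both are
#' evaluated on the matched prediction set (protocol 1) and on the
#' perturbed prediction set (protocol 2: thicker wall, larger wall loss).
#' Component counts are chosen by 5-fold cross-validation on the
#' calibration set unless given.
#'
#' @param config A [synthetic_config()].
#' @param n_samples Number of samples (default 60).
#' @param seed Master seed.
#' @param n_components Optional fixed component count for both models.
#' @param single_thickness_mm Plate separation of the Model 2 spectra.
#' @return An object of class `comparison_report`: a data frame with one
#'   row per (model, dataset) combination and columns `model`, `dataset`,
#'   `role`, `r2`, `rmse`, `n_components`, plus the dataset as an
#'   attribute-free `manifest` entry.
#' @export
run_model_comparison <- function(config = synthetic_config(),
                                 n_samples = 60, seed = 1L,
                                 n_components = NULL,
                                 single_thickness_mm = 3.0) {
  ds <- generate_dataset(config, n_samples = n_samples, seed = seed)
  cal <- ds$samples$split == "calibration"
  y <- ds$samples$hb_g_per_l
  rows <- list()
  for (model in c("slope", "single")) {
    X1 <- .build_design(ds$spectra_m1, model, single_thickness_mm)
    X2 <- .build_design(ds$spectra_m2, model, single_thickness_mm)
    k <- n_components
    if (is.null(k))
      k <- select_components(X1[cal, , drop = FALSE], y[cal],
                             seed = .substream(seed, 17L))$k
    fit <- plsr_fit(X1[cal, , drop = FALSE], y[cal], k)
    mlab <- if (model == "slope") "model1_slope" else "model2_single"
    dlab <- if (model == "slope") c("S1", "S2") else c("A1", "A2")
    mc <- compute_metrics(y[cal], plsr_predict(fit, X1[cal, , drop = FALSE]),
                          "calibration")
    mm <- compute_metrics(y[!cal], plsr_predict(fit, X1[!cal, , drop = FALSE]),
                          "prediction_matched")
    mp <- compute_metrics(y[!cal], plsr_predict(fit, X2[!cal, , drop = FALSE]),
                          "prediction_perturbed")
    rows[[model]] <- data.frame(
      model = mlab,
      dataset = c(dlab[1], dlab[1], dlab[2]),
      role = c("calibration", "prediction_matched", "prediction_perturbed"),
      r2 = c(mc$r2, mm$r2, mp$r2),
      rmse = c(mc$rmse, mm$rmse, mp$rmse),
      n_components = k)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "manifest") <- list(seed = seed, n_samples = n_samples,
                                noise_sd = config$noise_sd,
                                config_hash = .config_hash(unclass(config)))
  class(out) <- c("comparison_report", "data.frame")
  out
}

#' Read a simulation-study configuration from YAML
#'
#' Keys mirror the arguments of [sim_study_config()]; grids may be given
#' either as explicit vectors or as `{from, to, by}` maps, and package
#' configurations as a named map of `{d1_mm, mus1}` entries. A top-level
#' `seed` is returned alongside the config so a study file is fully
#' self-describing.
#'
#' @param path YAML file path.
#' @return List with elements `config` (a `sim_study_config`) and `seed`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_grid <- function(x) {
    if (is.list(x)) seq(x$from, x$to, by = x$by) else as.numeric(x)
  }
  args <- list()
  if (!is.null(y$preset)) args$preset <- y$preset
  if (!is.null(y$n_photons)) args$n_photons <- as.numeric(y$n_photons)
  if (!is.null(y$mu_a2_grid)) args$mu_a2_grid <- as_grid(y$mu_a2_grid)
  for (k in c("d2_fig4_mm", "slope_window_mm", "alt_window_mm",
              "d2_step_mm"))
    if (!is.null(y[[k]])) args[[k]] <- as.numeric(unlist(y[[k]]))
  if (!is.null(y$configs))
    args$configs <- lapply(y$configs, function(cf)
      list(d1_mm = as.numeric(cf$d1_mm), mus1 = as.numeric(cf$mus1)))
  list(config = do.call(sim_study_config, args),
       seed = as.integer(y$seed %||% 1L))
}
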