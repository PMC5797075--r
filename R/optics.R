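#' Optical layer
#'
#' A homogeneous plane-parallel layer described by its refractive index,
#' absorption coefficient, scattering coefficient, Henyey-Greenstein
#' anisotropy and thickness. Internal units are cm and cm^-1; thickness may
#' be given in mm via `unit = "mm"`.
#'
#' @param refractive_index Refractive index (>= 1, dimensionless).
#' @param mu_a Absorption coefficient, cm^-1 (>= 0).
#' @param mu_s Scattering coefficient, cm^-1 (>= 0).
#' @param g Scattering anisotropy, mean cosine of the deflection angle
#'   (-1 <= g <= 1).
#' @param thickness Layer thickness (> 0), in `unit`.
#' @param unit Unit of `thickness`: `"cm"` (default) or `"mm"`.
#' @return An object of class `optical_layer`.
#' @examples
#' optical_layer(1.3, mu_a = 0.005, mu_s = 75, g = 0.8,
#'               thickness = 0.5, unit = "mm")
#' @export
optical_layer <- function(refractive_index, mu_a, mu_s, g, thickness,
                          unit = c("cm", "mm")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(refractive_index), length(refractive_index) == 1L,
            is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s), length(mu_s) == 1L,
            is.numeric(g), length(g) == 1L,
            is.numeric(thickness), length(thickness) == 1L)
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (g < -1 || g > 1) stop("g must lie in [-1, 1]")
  if (thickness <= 0) stop("thickness must be > 0")
  d_cm <- if (unit == "mm") thickness / 10 else thickness
  structure(list(refractive_index = refractive_index, mu_a = mu_a,
                 mu_s = mu_s, g = g, thickness_cm = d_cm),
            class = "optical_layer")
}

#' Layer stack
#'
#' An ordered stack of [optical_layer()] objects with the ambient refractive
#' index above and below (air by default). `liquid_index` marks the layer
#' holding the analyte, used by the absorption sweeps.
#'
#' @param layers List of `optical_layer` objects, top to bottom.
#' @param n_above,n_below Ambient refractive indices (default 1, air).
#' @param liquid_index Index of the sample layer (default the middle layer).
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(layers, n_above = 1.0, n_below = 1.0,
                        liquid_index = NULL) {
  if (inherits(layers, "optical_layer")) layers <- list(layers)
  if (length(layers) < 1L) stop("a stack needs at least one layer")
  ok <- vapply(layers, inherits, logical(1), what = "optical_layer")
  if (!all(ok)) stop("all elements of `layers` must be optical_layer objects")
  if (n_above < 1 || n_below < 1) stop("ambient indices must be >= 1")
  if (is.null(liquid_index)) liquid_index <- ceiling(length(layers) / 2)
  liquid_index <- as.integer(liquid_index)
  if (liquid_index < 1L || liquid_index > length(layers))
    stop("liquid_index out of range")
  structure(list(layers = layers, n_above = n_above, n_below = n_below,
                 liquid_index = liquid_index),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers, ambient n = %.3g / %.3g\n",
              length(x$layers), x$n_above, x$n_below))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d]%s n=%.3g mu_a=%.4g mu_s=%.4g g=%.3g d=%.3g mm\n",
                i, if (i == x$liquid_index) "*" else " ", l$refractive_index,
                l$mu_a, l$mu_s, l$g, l$thickness_cm * 10))
  }
  invisible(x)
}

#' Bag/liquid/bag sandwich stack
#'
#' Convenience constructor for the three-layer geometry of a flexible
#' package squeezed around a liquid sample: identical walls above and below
#' the liquid. Defaults are the red-cell-suspension scenario (wall n 1.3,
#' mu_a 0.005 cm^-1, g 0.8; liquid n 1.4, mu_s 100 cm^-1, g 0.75).
#'
#' @param d1_mm Wall thickness, mm.
#' @param mus1 Wall scattering coefficient, cm^-1.
#' @param mua2 Liquid absorption coefficient, cm^-1.
#' @param d2_mm Liquid thickness, mm.
#' @param mua1 Wall absorption coefficient, cm^-1.
#' @param mus2 Liquid scattering coefficient, cm^-1.
#' @param n1,n2 Wall and liquid refractive indices.
#' @param g1,g2 Wall and liquid anisotropies.
#' @return A `layer_stack` with `liquid_index = 2`.
#' @examples
#' bag_stack(d1_mm = 0.5, mus1 = 75, mua2 = 0.35, d2_mm = 3.0)
#' @export
bag_stack <- function(d1_mm = 0.5, mus1 = 75, mua2 = 0.35, d2_mm = 4.0,
                      mua1 = 0.005, mus2 = 100, n1 = 1.3, n2 = 1.4,
                      g1 = 0.8, g2 = 0.75) {
  wall <- optical_layer(n1, mua1, mus1, g1, d1_mm, unit = "mm")
  liquid <- optical_layer(n2, mua2, mus2, g2, d2_mm, unit = "mm")
  layer_stack(list(wall, liquid, wall), liquid_index = 2L)
}

#' Beam specification
#'
#' Flat-top collimated beam at normal incidence, centered on the stack axis.
#'
#' @param diameter_mm Beam diameter in mm (default 1).
#' @export
beam_spec <- function(diameter_mm = 1.0) {
  stopifnot(is.numeric(diameter_mm), length(diameter_mm) == 1L)
  if (diameter_mm <= 0) stop("beam diameter must be > 0")
  structure(list(diameter_mm = diameter_mm, radius_cm = diameter_mm / 20),
            class = "beam_spec")
}

#' Detector specification
#'
#' Coaxial fiber-probe detector on the exit surface: a photon is detected if
#' it leaves the bottom face inside the detector disc with an exit angle (in
#' the ambient medium) within the fiber acceptance cone, sin(theta) <= NA.
#'
#' @param diameter_mm Detector diameter in mm (default 10).
#' @param numerical_aperture Fiber numerical aperture in (0, 1), default 0.22.
#' @export
detector_spec <- function(diameter_mm = 10.0, numerical_aperture = 0.22) {
  stopifnot(is.numeric(diameter_mm), is.numeric(numerical_aperture))
  if (diameter_mm <= 0) stop("detector diameter must be > 0")
  if (numerical_aperture <= 0 || numerical_aperture >= 1)
    stop("numerical_aperture must lie in (0, 1)")
  structure(list(diameter_mm = diameter_mm, radius_cm = diameter_mm / 20,
                 numerical_aperture = numerical_aperture),
            class = "detector_spec")
}

#' Monte Carlo settings
#'
#' @param n_photons Number of photons to launch (>= 1).
#' @param seed Integer seed; identical settings give bit-identical results.
#' @param roulette_threshold Weight below which Russian roulette triggers.
#' @param roulette_survival Survival probability of the roulette.
#' @export
mc_settings <- function(n_photons = 1e5, seed = 1L,
                        roulette_threshold = 1e-4, roulette_survival = 0.1) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (roulette_threshold <= 0 || roulette_threshold >= 1)
    stop("roulette_threshold must lie in (0, 1)")
  if (roulette_survival <= 0 || roulette_survival > 1)
    stop("roulette_survival must lie in (0, 1]")
  structure(list(n_photons = as.numeric(n_photons), seed = as.numeric(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "mc_settings")
}

# drop degenerate zero-thickness layers and flatten to the kernel matrix
.stack_matrix <- function(stack) {
  keep <- vapply(stack$layers, function(l) l$thickness_cm > 0, logical(1))
  layers <- stack$layers[keep]
  m <- t(vapply(layers, function(l)
    c(l$refractive_index, l$mu_a, l$mu_s, l$g, l$thickness_cm), numeric(5)))
  li <- cumsum(keep)[stack$liquid_index]
  list(m = m, liquid_index = as.integer(li))
}
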