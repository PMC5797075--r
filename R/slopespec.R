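#' Multi-pathlength spectra container
#'
#' Transmission intensity counts measured on a common wavelength grid at
#' several optical pathlengths (plate separations), the raw material for a
#' slope spectrum. Intensities must be strictly positive so the log
#' transform is defined.
#'
#' @param wavelength_nm Wavelength grid, nm (length W).
#' @param pathlength_mm Pathlength grid, mm (length L >= 2, strictly
#'   monotone).
#' @param intensity L x W matrix of intensity counts (> 0).
#' @param sample_id,label Optional metadata.
#' @return An object of class `multipath_spectra`.
#' @export
multipath_spectra <- function(wavelength_nm, pathlength_mm, intensity,
                              sample_id = NA_character_,
                              label = NA_character_) {
  intensity <- as.matrix(intensity)
  W <- length(wavelength_nm); L <- length(pathlength_mm)
  if (L < 2) stop("need at least two pathlengths")
  d <- diff(pathlength_mm)
  if (!(all(d > 0) || all(d < 0)))
    stop("pathlength_mm must be strictly increasing or decreasing")
  if (nrow(intensity) != L || ncol(intensity) != W)
    stop(sprintf("intensity must be %d x %d (pathlengths x wavelengths)",
                 L, W))
  if (anyNA(intensity)) stop("intensity contains missing values")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 pathlength_mm = as.numeric(pathlength_mm),
                 intensity = unname(intensity),
                 sample_id = sample_id, label = label),
            class = "multipath_spectra")
}

#' @export
print.multipath_spectra <- function(x, ...) {
  cat(sprintf(paste0("<multipath_spectra> %s %d wavelengths ",
                     "(%.4g-%.4g nm) x %d pathlengths (%s mm)\n"),
              if (is.na(x$sample_id)) "" else paste0("[", x$sample_id, "] "),
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), length(x$pathlength_mm),
              paste(x$pathlength_mm, collapse = ", ")))
  invisible(x)
}

#' Least-squares line fit
#'
#' Ordinary least-squares fit of `y = a x + b`, exact for collinear input.
#'
#' @param x Predictor values (>= 2 distinct values).
#' @param y Response values, same length as `x`.
#' @return List with `slope`, `intercept` and `rss` (residual sum of
#'   squares).
#' @examples
#' fit_line(c(0, 1, 2), c(1, 3, 5)) # slope 2, intercept 1, rss 0
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2) stop("need at least two points")
  if (diff(range(x)) == 0) stop("degenerate design: all x values identical")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  fit <- stats::lm.fit(cbind(intercept = 1, x = x), y)
  list(slope = unname(fit$coefficients["x"]),
       intercept = unname(fit$coefficients["intercept"]),
       rss = sum(fit$residuals^2))
}

#' Slope spectrum from multi-pathlength spectra
#'
#' For every wavelength, fits the natural log of intensity against the
#' pathlength by ordinary least squares and collects the per-wavelength
#' slopes (ln-counts per mm), intercepts and residual sums of squares.
#' Because an additive loss in the log domain (e.g. attenuation by the
#' package wall) shifts every intensity by a common factor, it moves the
#' intercepts but leaves the slopes untouched -- the robustness property
#' the slope spectrum is built on.
#'
#' @param spectra A [multipath_spectra()] object.
#' @return An object of class `slope_spectrum`: a data frame with columns
#'   `wavelength_nm`, `slope_per_mm`, `intercept`, `rss`.
#' @export
compute_slope_spectrum <- function(spectra) {
  stopifnot(inherits(spectra, "multipath_spectra"))
  I <- spectra$intensity
  bad <- which(I <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "nonpositive intensity at wavelength %g nm, pathlength %g mm",
      spectra$wavelength_nm[bad[1, 2]], spectra$pathlength_mm[bad[1, 1]]))
  x <- spectra$pathlength_mm
  fit <- stats::lm.fit(cbind(1, x), log(I))
  co <- fit$coefficients
  res <- if (is.matrix(fit$residuals)) fit$residuals else
    matrix(fit$residuals, ncol = 1)
  out <- data.frame(wavelength_nm = spectra$wavelength_nm,
                    slope_per_mm = unname(co[2, ]),
                    intercept = unname(co[1, ]),
                    rss = unname(colSums(res^2)))
  class(out) <- c("slope_spectrum", "data.frame")
  out
}

#' Difference coefficient between two curves
#'
#' Normalized squared-difference statistic
#' \deqn{DC(P, Q) = \frac{\sum_i (p_i - q_i)^2}
#'   {\sqrt{\sum_i (p_i - \bar p)^2 \sum_i (q_i - \bar q)^2}}}
#' It is 0 for identical curves, grows with their discrepancy, is symmetric
#' in its arguments, and is invariant to a common rescaling of both curves.
#'
#' @param p,q Numeric vectors of equal length (>= 2), neither constant.
#' @return Non-negative scalar.
#' @examples
#' difference_coefficient(c(1, 2, 3), c(2, 3, 4)) # 1.5
#' @export
difference_coefficient <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (length(p) < 2) stop("need at least two points")
  if (anyNA(p) || anyNA(q)) stop("missing values in input")
  sp <- sum((p - mean(p))^2)
  sq <- sum((q - mean(q))^2)
  if (sp == 0 || sq == 0)
    stop("constant vector: difference coefficient undefined")
  sum((p - q)^2) / sqrt(sp * sq)
}
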