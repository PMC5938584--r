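#' A1 visual-pigment absorbance template
#'
#' Standard vitamin-A1 rhodopsin nomogram (Govardovskii-type alpha band
#' plus beta band) parameterised only by the wavelength of peak
#' sensitivity. Used for all receptor classes here because the measured
#' spectral sensitivity curves of the receptors are characterised by their
#' peak wavelengths; the template is normalised to unit peak on the
#' evaluation grid.
#'
#' @param lambda_max peak wavelength in nm, within 300-650.
#' @param grid wavelength grid in nm (default 300:700).
#' @return Numeric sensitivity curve on `grid`, unit peak, positive
#'   everywhere.
#' @export
pigment_sensitivity <- function(lambda_max, grid = 300:700) {
  if (!is.finite(lambda_max) || lambda_max < 300 || lambda_max > 650)
    stop("lambda_max must be within 300-650 nm")
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambda_max          # beta-band peak
  b <- -40.5 + 0.195 * lambda_max          # beta-band width
  beta <- 0.26 * exp(-((grid - lmb) / b)^2)
  s <- alpha + beta
  s / max(s)
}

# CIE standard illuminant D65, relative spectral power at 10 nm steps,
# 300-700 nm (normalised to 100 at 560 nm)
d65_10nm <- c(
  0.03, 3.29, 20.24, 37.05, 39.95, 44.91, 46.64, 52.09, 49.98, 54.65,
  82.75, 91.49, 93.43, 86.68, 104.86, 117.01, 117.81, 114.86, 115.92,
  108.81, 109.35, 107.80, 104.79, 107.69, 104.41, 104.05, 100.00, 96.33,
  95.79, 88.69, 90.01, 89.60, 87.70, 83.29, 83.70, 80.03, 80.21, 82.28,
  78.28, 69.72, 71.61)

#' Built-in and custom illuminants
#'
#' `illuminant("D65")` is the CIE standard daylight illuminant (relative
#' spectral power, tabulated at 10 nm and interpolated to the working
#' grid). `illuminant("forestshade")` is a canopy-filtered daylight:
#' D65 multiplied by a smooth synthetic leaf-canopy transmission that is
#' poor in UV and peaks in the green (the construction is documented in
#' the methods vignette). A custom illuminant supplies its own irradiance
#' curve.
#'
#' @param name `"D65"`, `"forestshade"`, or `"custom"`.
#' @param grid wavelength grid in nm (default 300:700).
#' @param irradiance for `name = "custom"`, non-negative irradiance on
#'   `grid` (arbitrary units).
#' @return An object of class `illuminant`: list with `name`, `grid`,
#'   `irradiance`.
#' @export
illuminant <- function(name = c("D65", "forestshade", "custom"),
                       grid = 300:700, irradiance = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(irradiance) || length(irradiance) != length(grid))
      stop("custom illuminant needs an irradiance curve on the grid")
    if (any(irradiance < 0)) stop("irradiance must be non-negative")
    irr <- as.numeric(irradiance)
  } else {
    base <- stats::approx(seq(300, 700, by = 10), d65_10nm,
                          xout = grid, rule = 2)$y
    irr <- switch(name,
      D65 = base,
      forestshade = {
        canopy <- (0.15 + 0.85 * exp(-((grid - 555) / 80)^2)) /
          (1 + exp((400 - grid) / 30))
        base * canopy
      })
  }
  structure(list(name = name, grid = as.numeric(grid), irradiance = irr),
            class = "illuminant")
}

#' @export
print.illuminant <- function(x, ...) {
  cat(sprintf("<illuminant> %s on %g-%g nm\n", x$name, min(x$grid),
              max(x$grid)))
  invisible(x)
}

# smooth short-wavelength cut-on approximating passerine ocular media
# transmission (unit transmission in the long-wavelength limit)
ocular_media_curve <- function(grid = 300:700) {
  1 / (1 + exp(-(grid - 340) / 15))
}
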