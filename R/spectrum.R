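#' Reflectance spectrum of a wing patch
#'
#' The basic currency of the pipeline: reflectance (% of a diffuse white
#' standard) sampled on a strictly increasing wavelength grid, with
#' acquisition metadata (taxon, wing, incidence angle, individual).
#'
#' @param wavelength_nm numeric, strictly increasing wavelengths in nm
#'   (at least 2 points).
#' @param reflectance_pct numeric, reflectance in percent of the white
#'   standard; same length as `wavelength_nm`, all finite.
#' @param taxon,wing,individual character metadata; `wing` is `"fore"` or
#'   `"hind"`.
#' @param angle_deg signed incidence angle in degrees (rotation away from
#'   normal along the scale rows).
#' @return An object of class `wing_spectrum`: a list with elements
#'   `wavelength_nm`, `reflectance_pct` and `meta`.
#' @examples
#' s <- wing_spectrum(300:700, rep(5, 401), taxon = "H. sara", angle_deg = 0)
#' peak_and_fwhm(normalize_min_zero(s))
#' @export
wing_spectrum <- function(wavelength_nm, reflectance_pct,
                          taxon = NA_character_, wing = NA_character_,
                          angle_deg = NA_real_, individual = NA_character_) {
  wavelength_nm <- as.numeric(wavelength_nm)
  reflectance_pct <- as.numeric(reflectance_pct)
  if (length(wavelength_nm) < 2L)
    stop("a spectrum needs at least 2 wavelength points")
  if (length(reflectance_pct) != length(wavelength_nm))
    stop("wavelength and reflectance lengths differ")
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be finite and strictly increasing")
  if (any(!is.finite(reflectance_pct)))
    stop("reflectance values must be finite")
  structure(
    list(wavelength_nm = wavelength_nm,
         reflectance_pct = reflectance_pct,
         meta = list(taxon = taxon, wing = wing,
                     angle_deg = as.numeric(angle_deg),
                     individual = individual)),
    class = "wing_spectrum")
}

#' @export
print.wing_spectrum <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<wing_spectrum> %s %s ind=%s angle=%s deg\n",
              m$taxon, m$wing, m$individual,
              format(m$angle_deg)))
  cat(sprintf("  %d points, %g-%g nm, reflectance %.3g-%.3g %%\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$reflectance_pct),
              max(x$reflectance_pct)))
  invisible(x)
}

#' @export
as.data.frame.wing_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength_nm,
             reflectance_pct = x$reflectance_pct)
}

#' @export
plot.wing_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$reflectance_pct, type = "l",
                 xlab = "wavelength (nm)", ylab = "reflectance (%)", ...)
  invisible(x)
}

# carry metadata onto new reflectance values
spectrum_like <- function(template, wavelength_nm, reflectance_pct) {
  m <- template$meta
  wing_spectrum(wavelength_nm, reflectance_pct, taxon = m$taxon,
                wing = m$wing, angle_deg = m$angle_deg,
                individual = m$individual)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the target grid must lie inside the measured range
#' (no extrapolation). Metadata is preserved. Spectra must share a grid
#' before they can be averaged or compared pointwise.
#'
#' @param spec a [wing_spectrum()].
#' @param grid numeric, strictly increasing target wavelengths in nm.
#' @return A `wing_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spec, grid) {
  stopifnot(inherits(spec, "wing_spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  rng <- range(spec$wavelength_nm)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop(sprintf("target grid [%g, %g] outside measured range [%g, %g]",
                 min(grid), max(grid), rng[1], rng[2]))
  y <- stats::approx(spec$wavelength_nm, spec$reflectance_pct,
                     xout = grid, method = "linear")$y
  spectrum_like(spec, grid, y)
}

#' Smooth a spectrum by local quadratic regression
#'
#' Degree-2 local regression (tricube weights) with `span` interpreted as
#' the fraction of points in the local window, followed by clamping any
#' negative smoothed value to zero. This mirrors the usual spectrometry
#' processing chain for reflectance data (smooth, then fix negatives to
#' zero); the default span of 0.3 is the value used throughout the
#' pipeline.
#'
#' @param spec a [wing_spectrum()].
#' @param span fraction of points in the local regression window, in (0, 1].
#' @return The smoothed `wing_spectrum` (no negative values).
#' @export
smooth_spectrum <- function(spec, span = 0.3) {
  stopifnot(inherits(spec, "wing_spectrum"))
  if (!is.finite(span) || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  n <- length(spec$wavelength_nm)
  if (floor(span * n) < 3L)
    stop("span too small: local window holds fewer than 3 points")
  fit <- stats::loess(r ~ w,
                      data = data.frame(w = spec$wavelength_nm,
                                        r = spec$reflectance_pct),
                      span = span, degree = 2, family = "gaussian",
                      surface = "direct")
  y <- as.numeric(stats::predict(fit, newdata =
                                   data.frame(w = spec$wavelength_nm)))
  y[y < 0] <- 0
  spectrum_like(spec, spec$wavelength_nm, y)
}

#' Normalise a spectrum so its minimum is zero
#'
#' Subtracts the minimum reflectance over the working window from every
#' wavelength, so the minimum of the output is exactly 0. Idempotent.
#'
#' @param spec a [wing_spectrum()].
#' @param window wavelength range (nm) over which the minimum is taken;
#'   defaults to the bird/butterfly visible range 300-700 nm intersected
#'   with the measured range.
#' @return The normalised `wing_spectrum`.
#' @export
normalize_min_zero <- function(spec, window = c(300, 700)) {
  stopifnot(inherits(spec, "wing_spectrum"))
  inw <- spec$wavelength_nm >= window[1] & spec$wavelength_nm <= window[2]
  if (!any(inw)) inw <- rep(TRUE, length(spec$wavelength_nm))
  spectrum_like(spec, spec$wavelength_nm,
                spec$reflectance_pct - min(spec$reflectance_pct[inw]))
}

#' Average spectra measured on a common grid
#'
#' Pointwise arithmetic mean of repeated measurements (e.g. several spots
#' on one wing). All spectra must already share an identical wavelength
#' grid; resample first if they do not.
#'
#' @param specs a list of [wing_spectrum()] objects on one common grid.
#' @return A `wing_spectrum` carrying the metadata of the first input.
#' @export
average_spectra <- function(specs) {
  if (length(specs) == 0L) stop("no spectra to average")
  stopifnot(all(vapply(specs, inherits, logical(1), "wing_spectrum")))
  grid <- specs[[1]]$wavelength_nm
  for (s in specs)
    if (length(s$wavelength_nm) != length(grid) ||
        any(s$wavelength_nm != grid))
      stop("spectra are on different wavelength grids; resample first")
  ymat <- vapply(specs, function(s) s$reflectance_pct, numeric(length(grid)))
  spectrum_like(specs[[1]], grid, rowMeans(as.matrix(ymat)))
}

#' Peak wavelength, FWHM and maximum reflectance of a spectrum
#'
#' The peak is the argmax of reflectance inside the working window; the
#' full width at half maximum is found by linearly interpolating the two
#' half-maximum crossings flanking the peak. If the peak sits on a window
#' boundary (monotone spectrum -- the behaviour of non-iridescent wings
#' whose reflectance keeps rising to 700 nm) the result is flagged
#' `peak_at_boundary` and the FWHM is reported missing. A half-maximum
#' crossing falling outside the window likewise leaves the FWHM missing
#' with `fwhm_truncated = TRUE`.
#'
#' @param spec a [wing_spectrum()] covering the window.
#' @param window wavelength range (nm) searched, default `c(300, 700)`.
#' @return A list with `peak_nm`, `fwhm_nm` (NA when truncated),
#'   `max_pct`, and logical flags `peak_at_boundary`, `fwhm_truncated`.
#' @export
peak_and_fwhm <- function(spec, window = c(300, 700)) {
  stopifnot(inherits(spec, "wing_spectrum"))
  inw <- which(spec$wavelength_nm >= window[1] &
                 spec$wavelength_nm <= window[2])
  if (length(inw) < 3L) stop("spectrum does not cover the window")
  wl <- spec$wavelength_nm[inw]
  y <- spec$reflectance_pct[inw]
  i <- which.max(y)
  peak <- wl[i]
  maxv <- y[i]
  at_boundary <- (i == 1L || i == length(y))
  half <- maxv / 2
  cross <- function(idx_seq) {
    # first half-maximum crossing walking away from the peak
    for (k in idx_seq) {
      if (y[k] <= half) {
        # interpolate between k and the neighbour closer to the peak
        k2 <- k + sign(i - k)
        if (y[k2] == y[k]) return(wl[k])
        return(wl[k] + (half - y[k]) * (wl[k2] - wl[k]) / (y[k2] - y[k]))
      }
    }
    NA_real_
  }
  lo <- if (i > 1L) cross(seq(i - 1L, 1L)) else NA_real_
  hi <- if (i < length(y)) cross(seq(i + 1L, length(y))) else NA_real_
  truncated <- is.na(lo) || is.na(hi)
  list(peak_nm = peak,
       fwhm_nm = if (truncated) NA_real_ else hi - lo,
       max_pct = maxv,
       peak_at_boundary = at_boundary,
       fwhm_truncated = truncated)
}

#' Angle-resolved series of spectra
#'
#' An ordered set of spectra from one taxon/wing/individual, one per
#' incidence angle. Angles must be unique and all spectra must share a
#' common wavelength grid.
#'
#' @param specs list of [wing_spectrum()] objects with distinct
#'   `angle_deg` metadata and identical grids.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(specs) {
  if (length(specs) < 1L) stop("empty angle series")
  stopifnot(all(vapply(specs, inherits, logical(1), "wing_spectrum")))
  angles <- vapply(specs, function(s) s$meta$angle_deg, numeric(1))
  if (anyNA(angles)) stop("every spectrum needs an angle_deg")
  if (anyDuplicated(angles)) stop("angles must be unique")
  grid <- specs[[1]]$wavelength_nm
  for (s in specs)
    if (length(s$wavelength_nm) != length(grid) ||
        any(s$wavelength_nm != grid))
      stop("spectra in a series must share one wavelength grid")
  o <- order(angles)
  structure(list(spectra = specs[o], angles = angles[o]),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d angles: %s deg\n", length(x$angles),
              paste(format(x$angles), collapse = ", ")))
  invisible(x)
}

#' Angle of maximum reflectance in an angle series
#'
#' Returns the incidence angle whose spectrum attains the global maximum
#' reflectance within the working window. Ties are broken toward the
#' smaller absolute angle (a reproducibility convention, no physical
#' claim). Optional quadratic refinement fits a parabola through the
#' maximum and its two bracketing angles.
#'
#' @param series an [angle_series()] with at least 2 angles.
#' @param window wavelength range (nm) searched, default `c(300, 700)`.
#' @param refine logical; quadratic refinement of the angle (default off).
#' @return A list with `angle_deg` and `max_pct`.
#' @export
angle_of_max <- function(series, window = c(300, 700), refine = FALSE) {
  stopifnot(inherits(series, "angle_series"))
  if (length(series$angles) < 2L) stop("need at least 2 angles")
  maxima <- vapply(series$spectra, function(s) {
    inw <- s$wavelength_nm >= window[1] & s$wavelength_nm <= window[2]
    max(s$reflectance_pct[inw])
  }, numeric(1))
  best <- max(maxima)
  tied <- which(maxima == best)
  i <- tied[which.min(abs(series$angles[tied]))]
  ang <- series$angles[i]
  if (refine && i > 1L && i < length(maxima)) {
    a <- series$angles[(i - 1):(i + 1)]
    v <- maxima[(i - 1):(i + 1)]
    den <- (a[1] - a[2]) * (a[1] - a[3]) * (a[2] - a[3])
    # vertex of the interpolating parabola
    A <- (a[3] * (v[2] - v[1]) + a[2] * (v[1] - v[3]) +
            a[1] * (v[3] - v[2])) / den
    B <- (a[3]^2 * (v[1] - v[2]) + a[2]^2 * (v[3] - v[1]) +
            a[1]^2 * (v[2] - v[3])) / den
    if (A < 0) ang <- -B / (2 * A)
  }
  list(angle_deg = ang, max_pct = best)
}
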