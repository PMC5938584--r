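#' A corrected 2-D SAXS detector image
#'
#' Holds the (already dark/flat/flux-corrected) detector counts with the
#' beam geometry needed to map pixels to momentum transfer q. Pixels are
#' addressed (row, col), 0-based, with the beam centre allowed at
#' fractional pixel positions. The synchrotron geometry of the ridge
#' measurements was a 30.98 m sample-detector distance with 0.1 nm X-rays.
#'
#' @param intensity numeric matrix of non-negative counts.
#' @param beam_center numeric length-2, (row, col) of the direct beam in
#'   0-based fractional pixels.
#' @param pixel_size_mm detector pixel pitch in mm.
#' @param distance_mm sample-to-detector distance in mm.
#' @param wavelength_nm X-ray wavelength in nm.
#' @param mask logical matrix, TRUE = pixel excluded (beam stop, edges);
#'   defaults to no masking.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(intensity, beam_center, pixel_size_mm,
                           distance_mm = 30980, wavelength_nm = 0.1,
                           mask = NULL) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  if (distance_mm <= 0 || wavelength_nm <= 0 || pixel_size_mm <= 0)
    stop("geometry values must be positive")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(intensity), ncol(intensity))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(intensity)))
    stop("mask shape must match intensity")
  structure(list(intensity = intensity,
                 beam_center = as.numeric(beam_center),
                 pixel_size_mm = pixel_size_mm,
                 distance_mm = distance_mm,
                 wavelength_nm = wavelength_nm,
                 mask = mask),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %dx%d px, pixel %g mm, D = %g mm, lambda = %g nm\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size_mm,
              x$distance_mm, x$wavelength_nm))
  invisible(x)
}

#' Momentum transfer of a detector pixel
#'
#' Maps a pixel to q = (4 pi / lambda) sin(theta), where the scattering
#' angle 2 theta = atan(r / D) and r is the in-plane distance of the pixel
#' from the beam centre.
#'
#' @param img a [detector_image()].
#' @param pixel numeric length-2 (row, col), 0-based; may be a 2-column
#'   matrix of pixels.
#' @return q in 1/nm (vector if `pixel` is a matrix).
#' @export
q_of_pixel <- function(img, pixel) {
  stopifnot(inherits(img, "detector_image"))
  p <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2)
  r_mm <- sqrt((p[, 1] - img$beam_center[1])^2 +
                 (p[, 2] - img$beam_center[2])^2) * img$pixel_size_mm
  two_theta <- atan(r_mm / img$distance_mm)
  (4 * pi / img$wavelength_nm) * sin(two_theta / 2)
}

# q for every pixel of the image (matrix)
q_map <- function(img) {
  nr <- nrow(img$intensity); nc <- ncol(img$intensity)
  dr <- (seq_len(nr) - 1) - img$beam_center[1]
  dc <- (seq_len(nc) - 1) - img$beam_center[2]
  r_mm <- sqrt(outer(dr^2, dc^2, `+`)) * img$pixel_size_mm
  (4 * pi / img$wavelength_nm) * sin(atan(r_mm / img$distance_mm) / 2)
}

#' Radially integrate a detector image
#'
#' Azimuthally averages the masked detector counts into q bins (mean
#' intensity of the unmasked pixels per bin); bins containing no pixels
#' are dropped. This is the standard reduction from the 2-D pattern to the
#' 1-D scattering curve I(q).
#'
#' @param img a [detector_image()].
#' @param q_bins number of equal-width q bins spanning the image
#'   (default 300).
#' @return An object of class `scattering_profile`: list with strictly
#'   increasing `q_nm_inv` (bin centres) and `intensity`.
#' @export
radial_integrate <- function(img, q_bins = 300L) {
  stopifnot(inherits(img, "detector_image"))
  q <- q_map(img)
  keep <- !img$mask
  if (!any(keep)) stop("fully masked image: nothing to integrate")
  qv <- q[keep]; iv <- img$intensity[keep]
  edges <- seq(0, max(qv) * (1 + 1e-12), length.out = q_bins + 1L)
  bin <- findInterval(qv, edges, rightmost.closed = TRUE)
  means <- tapply(iv, bin, mean)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- as.integer(names(means))
  structure(list(q_nm_inv = centers[idx], intensity = as.numeric(means)),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %d bins, q %.4g-%.4g 1/nm\n",
              length(x$q_nm_inv), min(x$q_nm_inv), max(x$q_nm_inv)))
  invisible(x)
}

#' @export
plot.scattering_profile <- function(x, ...) {
  graphics::plot(x$q_nm_inv, x$intensity, type = "l", log = "xy",
                 xlab = "q (1/nm)", ylab = "I (a.u.)", ...)
  invisible(x)
}

#' Ridge spacing from a 1-D scattering profile
#'
#' Fits a power-law background I = A q^-m to the profile on the flanks
#' outside the search window, subtracts it, locates the maximum of the
#' residual inside the window, refines the peak position with a 3-point
#' parabolic fit, and returns the real-space spacing d = 2 pi / q_peak.
#' The default window 2 pi / 1500 ... 2 pi / 500 1/nm brackets all
#' observed ridge spacings.
#'
#' @param profile a `scattering_profile`.
#' @param q_window numeric length-2 (q_lo, q_hi) in 1/nm.
#' @return Spacing in nm.
#' @export
ridge_spacing_from_profile <- function(profile,
                                       q_window = 2 * pi / c(1500, 500)) {
  stopifnot(inherits(profile, "scattering_profile"))
  q <- profile$q_nm_inv; I <- profile$intensity
  inw <- q >= q_window[1] & q <= q_window[2]
  if (sum(inw) < 3L) stop("q window not covered by the profile")
  flank <- !inw & I > 0 & q > 0
  resid <- I
  if (sum(flank) >= 2L) {
    fit <- stats::lm(ly ~ lq, data = data.frame(ly = log(I[flank]),
                                                lq = log(q[flank])))
    co <- stats::coef(fit)
    bg <- exp(co[1] + co[2] * log(q))
    resid <- I - bg
  }
  iw <- which(inw)
  k <- iw[which.max(resid[iw])]
  # interior local maximum required: flat/monotone residuals mean no peak
  if (k <= min(iw) || k >= max(iw) ||
      !(resid[k] > resid[k - 1] && resid[k] > resid[k + 1]))
    stop("no local maximum inside the q window (no-peak)")
  # and it must stand clearly above the background-fit residual scatter
  noise <- stats::sd(resid[flank])
  if (!is.finite(noise) || resid[k] <= 5 * noise ||
      resid[k] <= 1e-9 * max(I))
    stop("no significant peak above the background (no-peak)")
  qp <- parabolic_vertex(q[(k - 1):(k + 1)], resid[(k - 1):(k + 1)])
  2 * pi / qp
}

# vertex of the parabola through three (x, y) points; falls back to the
# middle x when the points are degenerate
parabolic_vertex <- function(x, y) {
  den <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  A <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
          x[1] * (y[3] - y[2])) / den
  B <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / den
  if (!is.finite(A) || A >= 0) return(x[2])
  v <- -B / (2 * A)
  if (v < x[1] || v > x[3]) x[2] else v
}

#' An AFM height map
#'
#' A 2-D grid of surface heights in nm with a square pixel pitch; the
#' scans behind the ridge-spacing estimates were 10 um square images.
#'
#' @param height_nm numeric matrix of heights (finite).
#' @param pixel_pitch_nm physical size of one pixel in nm, > 0.
#' @return An object of class `height_map`.
#' @export
height_map <- function(height_nm, pixel_pitch_nm) {
  height_nm <- as.matrix(height_nm)
  if (any(!is.finite(height_nm))) stop("heights must be finite")
  if (!is.finite(pixel_pitch_nm) || pixel_pitch_nm <= 0)
    stop("pixel pitch must be positive")
  structure(list(height_nm = height_nm, pixel_pitch_nm = pixel_pitch_nm),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %dx%d px, pitch %g nm (%g um side)\n",
              nrow(x$height_nm), ncol(x$height_nm), x$pixel_pitch_nm,
              nrow(x$height_nm) * x$pixel_pitch_nm / 1000))
  invisible(x)
}

#' Image-averaged ridge spacing from an AFM height map
#'
#' De-trends the map (best-fit plane), applies a 2-D Hann window, computes
#' the 2-D FFT power spectrum, azimuthally integrates it to 1-D power vs
#' spatial frequency, locates the dominant non-DC peak and returns
#' 1 / frequency. Azimuthal integration makes the estimate independent of
#' the in-plane ridge orientation.
#'
#' @param map a [height_map()] spanning at least ~4 expected periods.
#' @param f_bins number of spatial-frequency bins (default: half the
#'   smaller image dimension).
#' @return Image-averaged spacing in nm.
#' @export
afm_ridge_spacing <- function(map, f_bins = NULL) {
  stopifnot(inherits(map, "height_map"))
  h <- map$height_nm
  nr <- nrow(h); nc <- ncol(h)
  # plane de-trend
  rr <- row(h); cc <- col(h)
  fit <- stats::lm.fit(cbind(1, as.vector(rr), as.vector(cc)), as.vector(h))
  h <- matrix(fit$residuals, nr, nc)
  # 2-D Hann window
  wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
  wc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  hw <- h * outer(wr, wc)
  P <- Mod(stats::fft(hw))^2
  # spatial frequency (cycles/nm) of each FFT pixel
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / (nr * map$pixel_pitch_nm)
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / (nc * map$pixel_pitch_nm)
  fmag <- sqrt(outer(fr^2, fc^2, `+`))
  if (is.null(f_bins)) f_bins <- min(nr, nc) %/% 2
  fmax <- min(max(abs(fr)), max(abs(fc)))   # stay inside the inscribed circle
  edges <- seq(0, fmax, length.out = f_bins + 1L)
  keep <- fmag <= fmax
  bin <- findInterval(fmag[keep], edges, rightmost.closed = TRUE)
  pow <- tapply(P[keep], bin, mean)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- as.integer(names(pow))
  f1 <- centers[idx]; p1 <- as.numeric(pow)
  nonDC <- f1 > edges[2]          # drop the DC/lowest bin
  if (!any(nonDC)) stop("no non-DC power: featureless map (no-peak)")
  f1 <- f1[nonDC]; p1 <- p1[nonDC]
  k <- which.max(p1)
  # demand a genuine peak: dominant bin must stand clearly above the median
  if (!is.finite(p1[k]) || p1[k] <= 10 * stats::median(p1) ||
      p1[k] == 0)
    stop("no dominant periodicity peak in the power spectrum (no-peak)")
  # sub-bin refinement: power-weighted centroid of the spatial frequency
  # over the annulus around the dominant bin (the windowed ridge line is
  # spread symmetrically about its true frequency)
  bw <- edges[2] - edges[1]
  near <- keep & abs(fmag - f1[k]) <= 2.5 * bw & fmag > bw
  fp <- sum(P[near] * fmag[near]) / sum(P[near])
  1 / fp
}
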