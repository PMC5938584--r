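# run expr with a local, restored RNG state so generators are pure
# functions of (parameters, seed)
with_seed <- function(seed, expr) {
  if (!is.finite(seed)) stop("a seed is required for stochastic output")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthetic Gaussian reflectance spectrum
#'
#' A Gaussian reflectance peak on the working grid with optional seeded
#' Gaussian noise -- the simplest emulation of a measured iridescent wing
#' spectrum, parameterised directly by the descriptors the pipeline
#' extracts (peak wavelength, FWHM, amplitude).
#'
#' @param peak_nm peak wavelength in nm.
#' @param fwhm_nm full width at half maximum in nm.
#' @param amplitude_pct peak reflectance in %.
#' @param noise_sd_pct Gaussian noise s.d. in % (default 0 = noiseless).
#' @param seed RNG seed, required when `noise_sd_pct > 0`.
#' @param grid wavelength grid (default 300:700).
#' @param taxon,wing,individual,angle_deg metadata passed to
#'   [wing_spectrum()].
#' @return A [wing_spectrum()]. Noise is added then clipped at 0.
#' @export
gen_gaussian_spectrum <- function(peak_nm, fwhm_nm, amplitude_pct,
                                  noise_sd_pct = 0, seed = NULL,
                                  grid = 300:700, taxon = NA_character_,
                                  wing = NA_character_,
                                  individual = NA_character_,
                                  angle_deg = NA_real_) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  y <- amplitude_pct * exp(-((grid - peak_nm)^2) / (2 * sigma^2))
  if (noise_sd_pct > 0) {
    if (is.null(seed)) stop("noisy generation requires a seed")
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd_pct))
    y[y < 0] <- 0
  }
  wing_spectrum(grid, y, taxon = taxon, wing = wing,
                individual = individual, angle_deg = angle_deg)
}

#' Parameters for a synthetic angle-resolved measurement
#'
#' Bundles the physical and instrumental parameters from which
#' [gen_angle_series()] builds a measurement: the ridge multilayer, the
#' ridge spacing, a Gaussian angular envelope for the brightest viewing
#' geometry, the overall amplitude, and the instrument noise level.
#'
#' @param taxon taxon label.
#' @param stack a [multilayer_stack()] (default [sara_ridge_stack()]).
#' @param ridge_spacing_nm ridge spacing in nm (used by the SAXS/AFM
#'   generators for the same synthetic specimen).
#' @param envelope_centre_deg,envelope_width_deg centre and s.d. (deg) of
#'   the Gaussian angular envelope.
#' @param amplitude_pct maximum reflectance in % at the envelope centre.
#' @param noise_sd_pct spectrometer noise s.d. in %.
#' @param seed RNG seed (mandatory for any stochastic output).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(taxon = "synthetic", stack = sara_ridge_stack(),
                           ridge_spacing_nm = 812,
                           envelope_centre_deg = 10,
                           envelope_width_deg = 15,
                           amplitude_pct = 30.6, noise_sd_pct = 0.5,
                           seed = 1L) {
  stopifnot(inherits(stack, "multilayer_stack"),
            ridge_spacing_nm > 0, envelope_width_deg > 0,
            amplitude_pct > 0, noise_sd_pct >= 0)
  structure(list(taxon = taxon, stack = stack,
                 ridge_spacing_nm = ridge_spacing_nm,
                 envelope_centre_deg = envelope_centre_deg,
                 envelope_width_deg = envelope_width_deg,
                 amplitude_pct = amplitude_pct,
                 noise_sd_pct = noise_sd_pct, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic angle-resolved reflectance series
#'
#' Per angle, the spectrum is the stack's transfer-matrix reflectance at
#' that angle, scaled so the envelope-centre maximum equals
#' `amplitude_pct`, multiplied by a Gaussian angular envelope, plus seeded
#' Gaussian noise clipped at 0. The spectral peak therefore blue-shifts
#' with angle away from the envelope centre, as in the measurements the
#' generator emulates.
#'
#' @param spec a [synthetic_spec()].
#' @param angles incidence angles in degrees.
#' @param grid wavelength grid (default 300:700).
#' @param individual individual id carried in the metadata.
#' @return An [angle_series()].
#' @export
gen_angle_series <- function(spec, angles = seq(0, 40, by = 4),
                             grid = 300:700, individual = "i1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  ref <- tmm_reflectance(spec$stack, grid,
                         theta_deg = max(0, spec$envelope_centre_deg))
  scale <- spec$amplitude_pct / max(100 * ref)
  with_seed(spec$seed, {
    specs <- lapply(angles, function(th) {
      base <- 100 * tmm_reflectance(spec$stack, grid, theta_deg = abs(th))
      env <- exp(-((th - spec$envelope_centre_deg)^2) /
                   (2 * spec$envelope_width_deg^2))
      y <- scale * base * env
      if (spec$noise_sd_pct > 0)
        y <- y + stats::rnorm(length(y), 0, spec$noise_sd_pct)
      y[y < 0] <- 0
      wing_spectrum(grid, y, taxon = spec$taxon, wing = "fore",
                    angle_deg = th, individual = individual)
    })
    angle_series(specs)
  })
}

#' Generate a synthetic SAXS detector image
#'
#' An isotropic Debye-Scherrer-type ring centred at q = 2 pi / spacing
#' with Gaussian radial width, on a power-law background, Poisson-sampled
#' (photon counting) at the given seed, with a central beam-stop mask.
#' The default geometry matches the synchrotron setup of the ridge
#' measurements (0.1 nm X-rays, 30.98 m distance).
#'
#' @param spacing_nm real-space ridge spacing in nm.
#' @param seed RNG seed for the Poisson sampling.
#' @param size_px detector side length in pixels (square detector).
#' @param pixel_size_mm pixel pitch in mm.
#' @param distance_mm sample-detector distance in mm.
#' @param wavelength_nm X-ray wavelength in nm.
#' @param ring_width_frac Gaussian ring s.d. as a fraction of the ring q.
#' @param ring_intensity expected counts at the ring maximum.
#' @param background_intensity power-law background amplitude at the ring
#'   position.
#' @param background_slope power-law exponent m of the q^-m background.
#' @param beamstop_px beam-stop mask radius in pixels.
#' @return A [detector_image()].
#' @export
gen_saxs_image <- function(spacing_nm, seed = 1L, size_px = 256L,
                           pixel_size_mm = 0.05, distance_mm = 30980,
                           wavelength_nm = 0.1, ring_width_frac = 0.04,
                           ring_intensity = 200,
                           background_intensity = 50,
                           background_slope = 3, beamstop_px = 12) {
  if (spacing_nm <= 0) stop("spacing must be positive")
  q0 <- 2 * pi / spacing_nm
  centre <- (size_px - 1) / 2
  img0 <- detector_image(matrix(0, size_px, size_px),
                         beam_center = c(centre, centre),
                         pixel_size_mm = pixel_size_mm,
                         distance_mm = distance_mm,
                         wavelength_nm = wavelength_nm)
  q <- q_map(img0)
  if (q0 >= max(q) * 0.95)
    stop("ring falls outside the detector for this geometry")
  sigma_q <- ring_width_frac * q0
  # background: A q^-m referenced to the ring position, capped near the beam
  qsafe <- pmax(q, q0 / 10)
  expected <- background_intensity * (qsafe / q0)^(-background_slope) +
    ring_intensity * exp(-((q - q0)^2) / (2 * sigma_q^2))
  counts <- with_seed(seed,
                      matrix(stats::rpois(length(expected), expected),
                             nrow(expected), ncol(expected)))
  rr <- row(counts) - 1 - centre
  cc <- col(counts) - 1 - centre
  mask <- sqrt(rr^2 + cc^2) <= beamstop_px
  detector_image(counts, beam_center = c(centre, centre),
                 pixel_size_mm = pixel_size_mm, distance_mm = distance_mm,
                 wavelength_nm = wavelength_nm, mask = mask)
}

#' Generate a synthetic AFM height map of parallel ridges
#'
#' Parallel sinusoidal ridges at the set spacing across a square scan,
#' optionally rotated in-plane. `profile = "curved"` superimposes a slow
#' cross-ridge height modulation (the curved-lamellae phenotype);
#' `lamellae_sawtooth` adds along-ridge sawtooth discontinuities. Seeded
#' Gaussian roughness emulates instrument noise.
#'
#' @param spacing_nm ridge spacing in nm (at least ~4 periods must fit).
#' @param seed RNG seed for the roughness.
#' @param size_px image side in pixels.
#' @param pitch_nm pixel pitch in nm (default: 10 um / `size_px`).
#' @param ridge_height_nm peak-to-trough ridge amplitude / 2.
#' @param profile `"flat"` or `"curved"` ridge profile.
#' @param lamellae_sawtooth add along-ridge sawtooth discontinuities.
#' @param rotation_deg in-plane ridge rotation.
#' @param noise_sd_nm roughness s.d. in nm.
#' @return A [height_map()].
#' @export
gen_height_map <- function(spacing_nm, seed = 1L, size_px = 512L,
                           pitch_nm = 10000 / size_px,
                           ridge_height_nm = 60,
                           profile = c("flat", "curved"),
                           lamellae_sawtooth = FALSE, rotation_deg = 0,
                           noise_sd_nm = 5) {
  profile <- match.arg(profile)
  extent <- size_px * pitch_nm
  if (extent < 4 * spacing_nm)
    stop("map spans fewer than 4 ridge periods")
  x <- (seq_len(size_px) - 1) * pitch_nm
  X <- matrix(x, size_px, size_px, byrow = TRUE)   # column coordinate
  Y <- matrix(x, size_px, size_px)                 # row coordinate
  th <- rotation_deg * pi / 180
  u <- X * cos(th) + Y * sin(th)    # across-ridge coordinate
  v <- -X * sin(th) + Y * cos(th)   # along-ridge coordinate
  h <- ridge_height_nm * cos(2 * pi * u / spacing_nm)
  if (profile == "curved")
    h <- h * (0.75 + 0.25 * cos(2 * pi * u / (6 * spacing_nm)))
  if (lamellae_sawtooth) {
    saw_period <- 4 * spacing_nm
    h <- h + 0.3 * ridge_height_nm * ((v %% saw_period) / saw_period - 0.5)
  }
  if (noise_sd_nm > 0)
    h <- h + with_seed(seed, matrix(stats::rnorm(length(h), 0,
                                                 noise_sd_nm),
                                    size_px, size_px))
  height_map(h, pixel_pitch_nm = pitch_nm)
}

#' The per-taxon study summary table
#'
#' The transcribed per-taxon structural and optical descriptors of the
#' eight study taxa: ridge spacing from AFM and from SAXS (mean +/- s.d.),
#' peak reflectance wavelength, FWHM, angle of maximum reflectance and
#' maximum reflectance (means of four individuals +/- s.d.; one taxon has
#' a single individual and no SAXS/AFM values). Non-iridescent taxa whose
#' reflectance rises to the 700 nm window edge have `peak_at_boundary =
#' TRUE` (peak reported as ~700 nm) and no FWHM or angle entry.
#'
#' @return A `data.frame` with one row per taxon.
#' @export
table1_fixture <- function() {
  data.frame(
    taxon = c("H. erato cyrbia", "H. erato demophoon", "H. sara (Ecuador)",
              "H. sara (Panama)", "H. eleuchia", "H. cydno",
              "H. melpomene cythera", "H. melpomene rosina"),
    ridge_spacing_afm_nm = c(887, 1149, 723, NA, 1159, 1143, 1242, 1253),
    ridge_spacing_saxs_nm = c(812, 1063, 742, NA, 889, 929, 823, 1025),
    ridge_spacing_saxs_sd = c(28, 39, 28, NA, 73, 58, 22, 82),
    peak_wavelength_nm = c(369, 700, 497, 443, 455, 390, 362, 700),
    peak_wavelength_sd = c(8, NA, 7, 3, 12, 2, 10, NA),
    peak_at_boundary = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                         TRUE),
    fwhm_nm = c(177, NA, 191, 274, 172, 192, 180, NA),
    fwhm_sd = c(12, NA, 5, 2, 1, 20, 9, NA),
    angle_of_max_deg = c(11.8, NA, 10.0, 3.5, 6.0, 6.7, 16.7, NA),
    angle_of_max_sd = c(4.9, NA, 7.2, 0.7, 3.5, 3.0, 4.6, NA),
    max_reflectance_pct = c(19.4, 2.4, 30.6, 15.9, 14.4, 3.4, 6.4, 1.9),
    max_reflectance_sd = c(9.3, 1.4, 10.1, 2.1, 5.3, 1.1, 2.4, 0.7),
    stringsAsFactors = FALSE)
}
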