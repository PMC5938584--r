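test_that("pixel-to-q mapping follows the scattering geometry", {
  img <- detector_image(matrix(1, 8, 8), beam_center = c(3, 3),
                        pixel_size_mm = 0.05, distance_mm = 30980,
                        wavelength_nm = 0.1)
  expect_equal(q_of_pixel(img, c(3, 3)), 0)

  # r chosen so the full scattering angle is 0.002 rad
  r_mm <- 1000 * tan(0.002)
  img2 <- detector_image(matrix(1, 4, 4), beam_center = c(0, 0),
                         pixel_size_mm = r_mm, distance_mm = 1000,
                         wavelength_nm = 0.1)
  expect_equal(q_of_pixel(img2, c(0, 1)), 4 * pi * sin(0.001) / 0.1,
               tolerance = 1e-12)

  # doubling the distance halves q to first order at small angles
  img3 <- detector_image(matrix(1, 4, 4), beam_center = c(0, 0),
                         pixel_size_mm = r_mm, distance_mm = 2000,
                         wavelength_nm = 0.1)
  expect_equal(q_of_pixel(img3, c(0, 1)) / q_of_pixel(img2, c(0, 1)),
               0.5, tolerance = 1e-4)

  # radial symmetry about the beam centre
  imgc <- detector_image(matrix(1, 9, 9), beam_center = c(4, 4),
                         pixel_size_mm = 0.1)
  expect_equal(q_of_pixel(imgc, c(4, 7)), q_of_pixel(imgc, c(1, 4)))
})

test_that("radial integration averages azimuthally and respects the mask", {
  uniform <- gen_saxs_image(812, seed = 1, ring_intensity = 0,
                            background_intensity = 0)
  # zero-intensity image integrates to an all-zero flat profile
  prof0 <- radial_integrate(uniform)
  expect_true(all(prof0$intensity == 0))
  expect_true(all(diff(prof0$q_nm_inv) > 0))

  img <- gen_saxs_image(812, seed = 2, background_intensity = 0,
                        ring_intensity = 500)
  prof <- radial_integrate(img)
  q0 <- 2 * pi / 812
  expect_lt(abs(prof$q_nm_inv[which.max(prof$intensity)] - q0),
            diff(prof$q_nm_inv[1:2]) * 1.5)

  # masking half the detector leaves the azimuthal average's peak put
  masked <- img
  half_mask <- img$mask
  half_mask[, seq_len(ncol(half_mask) %/% 2)] <- TRUE
  masked <- detector_image(img$intensity, img$beam_center,
                           img$pixel_size_mm, img$distance_mm,
                           img$wavelength_nm, mask = half_mask)
  prof_m <- radial_integrate(masked)
  expect_lt(abs(prof_m$q_nm_inv[which.max(prof_m$intensity)] - q0),
            diff(prof_m$q_nm_inv[1:2]) * 1.5)

  all_masked <- detector_image(img$intensity, img$beam_center,
                               img$pixel_size_mm, img$distance_mm,
                               img$wavelength_nm,
                               mask = matrix(TRUE, 256, 256))
  expect_error(radial_integrate(all_masked), "masked")
})

test_that("ridge spacing is read off the background-subtracted profile peak", {
  # ideal synthetic profile with a peak exactly at q = 2 pi / 742
  q <- seq(0.002, 0.015, length.out = 400)
  q0 <- 2 * pi / 742
  I <- 5 * (q / q0)^-3 + 100 * exp(-((q - q0)^2) / (2 * (0.03 * q0)^2))
  prof <- structure(list(q_nm_inv = q, intensity = I),
                    class = "scattering_profile")
  expect_equal(ridge_spacing_from_profile(prof), 742, tolerance = 1e-3)

  img <- gen_saxs_image(812, seed = 7)
  est <- ridge_spacing_from_profile(radial_integrate(img))
  expect_lt(abs(est - 812) / 812, 0.01)

  decay <- structure(list(q_nm_inv = q, intensity = 5 * q^-3),
                     class = "scattering_profile")
  expect_error(ridge_spacing_from_profile(decay), "no-peak|no local")
})

test_that("spacing estimates are invariant to intensity scale", {
  img <- gen_saxs_image(887, seed = 5)
  bright <- detector_image(img$intensity * 2, img$beam_center,
                           img$pixel_size_mm, img$distance_mm,
                           img$wavelength_nm, mask = img$mask)
  e1 <- ridge_spacing_from_profile(radial_integrate(img))
  e2 <- ridge_spacing_from_profile(radial_integrate(bright))
  expect_equal(e1, e2, tolerance = 1e-12)

  hm <- gen_height_map(887, seed = 5)
  tall <- height_map(hm$height_nm * 3, hm$pixel_pitch_nm)
  expect_equal(afm_ridge_spacing(hm), afm_ridge_spacing(tall),
               tolerance = 1e-9)
})

test_that("AFM spacing estimation is accurate and rotation-invariant", {
  hm <- gen_height_map(887, seed = 4)
  est <- afm_ridge_spacing(hm)
  f_bin <- 1 / (512 * hm$pixel_pitch_nm)
  f_true <- 1 / 887
  expect_lt(abs(1 / est - f_true), f_bin)        # within one FFT bin
  expect_lt(abs(est - 887) / 887, 0.01)

  rot <- gen_height_map(887, seed = 4, rotation_deg = 30)
  expect_lt(abs(afm_ridge_spacing(rot) - est) / est, 0.01)

  flat <- height_map(matrix(5, 128, 128), pixel_pitch_nm = 20)
  expect_error(afm_ridge_spacing(flat), "no-peak|featureless|no dominant")

  # curved and sawtooth phenotypes keep the same dominant spacing
  curved <- gen_height_map(887, seed = 4, profile = "curved",
                           lamellae_sawtooth = TRUE)
  expect_lt(abs(afm_ridge_spacing(curved) - 887) / 887, 0.02)
})

test_that("paired SAXS and AFM estimates agree on one synthetic spacing", {
  for (s in c(742, 1025)) {
    sx <- ridge_spacing_from_profile(radial_integrate(
      gen_saxs_image(s, seed = 11)))
    af <- afm_ridge_spacing(gen_height_map(s, seed = 12))
    expect_lt(abs(sx - af) / s, 0.02)
  }
})

test_that("detector images and height maps round-trip through text grids", {
  dir <- withr::local_tempdir()
  img <- gen_saxs_image(812, seed = 3, size_px = 64L,
                        pixel_size_mm = 0.2)
  f <- file.path(dir, "t1.saxs.txt")
  write_detector_image(img, f)
  img2 <- read_detector_image(f)
  expect_equal(img2$intensity, unname(img$intensity))
  expect_equal(img2$mask, unname(img$mask))
  expect_equal(img2$distance_mm, img$distance_mm)
  expect_equal(q_of_pixel(img2, c(0, 0)), q_of_pixel(img, c(0, 0)))

  hm <- gen_height_map(900, seed = 3, size_px = 64L)
  g <- file.path(dir, "t1.afm.txt")
  write_height_map(hm, g)
  hm2 <- read_height_map(g)
  expect_equal(hm2$height_nm, unname(hm$height_nm))
  expect_equal(hm2$pixel_pitch_nm, hm$pixel_pitch_nm)
})
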