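#' Construct a visual system
#'
#' A named receptor set for receptor-noise-limited modelling: ordered
#' receptors (short to long wavelength) with peak wavelengths and
#' sensitivity curves, a Weber fraction for the reference (long
#' wavelength, L) receptor, relative receptor abundances with the L
#' receptor fixed at 1, and optional ocular-media transmission. The L
#' receptor is always the achromatic channel.
#'
#' @param name system label.
#' @param labels character receptor labels, 3 or 4 receptors, last = L.
#' @param lambda_max peak wavelengths in nm, one per receptor.
#' @param weber_fraction Weber fraction w of the reference (L) receptor.
#' @param abundances relative receptor abundances, same order; the last
#'   (L) entry must be 1 and all must be positive.
#' @param grid wavelength grid (default 300:700).
#' @param ocular_media optional transmission curve on `grid`, or TRUE for
#'   the bundled passerine-like curve.
#' @return An object of class `visual_system`.
#' @export
visual_system <- function(name, labels, lambda_max, weber_fraction,
                          abundances, grid = 300:700,
                          ocular_media = NULL) {
  k <- length(labels)
  if (k < 3L || k > 4L) stop("3 or 4 receptors supported")
  stopifnot(length(lambda_max) == k, length(abundances) == k)
  if (any(abundances <= 0)) stop("abundances must be positive")
  if (abs(abundances[k] - 1) > 1e-12)
    stop("the long-wavelength (last) receptor abundance must be 1")
  if (!is.finite(weber_fraction) || weber_fraction <= 0)
    stop("Weber fraction must be positive")
  tocular <- if (isTRUE(ocular_media)) ocular_media_curve(grid)
  else if (is.numeric(ocular_media)) {
    stopifnot(length(ocular_media) == length(grid))
    ocular_media
  } else rep(1, length(grid))
  sens <- vapply(lambda_max, pigment_sensitivity, numeric(length(grid)),
                 grid = grid)
  colnames(sens) <- labels
  structure(list(name = name, labels = labels,
                 lambda_max = as.numeric(lambda_max),
                 weber_fraction = weber_fraction,
                 abundances = as.numeric(abundances),
                 grid = as.numeric(grid),
                 sensitivities = sens,
                 ocular_media = tocular,
                 achromatic_receptor = labels[k]),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system> %s: %d receptors, w = %g\n", x$name,
              length(x$labels), x$weber_fraction))
  cat(sprintf("  %s: lambda_max %s nm, abundance %s\n",
              paste(x$labels, collapse = "/"),
              paste(x$lambda_max, collapse = "/"),
              paste(x$abundances, collapse = "/")))
  invisible(x)
}

#' The five built-in visual systems
#'
#' Returns the receiver models used throughout the pipeline, with
#' parameters from published intracellular and ommatidial measurements:
#'
#' * `avian_vs` -- average violet-sensitive bird (the typical predator
#'   visual class): peaks 416, 478, 542, 607 nm; Weber fraction 0.06;
#'   relative cone abundances VS = 0.25, S = 0.5, M = 1, L = 1; bundled
#'   ocular-media transmission applied.
#' * `heli_I` -- *Heliconius* type I (tetrachromatic, *H. erato* female):
#'   peaks 355 (UV1), 390 (UV2), 470 (B), 555 (L) nm; Weber fraction
#'   0.05; abundances 0.09, 0.07, 0.17, 1.
#' * `heli_II` -- type II (trichromatic, *H. erato*/*H. sara* male):
#'   390, 470, 555 nm; abundances 0.13, 0.2, 1.
#' * `heli_III` -- type III (tetrachromatic, *H. sara* female):
#'   355, 390, 470, 555 nm; abundances 0.09, 0.13, 0.2, 1.
#' * `heli_IV` -- type IV (trichromatic, *H. melpomene*):
#'   355, 470, 555 nm; abundances 0.07, 0.26, 1.
#'
#' @param grid wavelength grid (default 300:700).
#' @return Named list of five [visual_system()] objects.
#' @export
builtin_visual_systems <- function(grid = 300:700) {
  list(
    avian_vs = visual_system(
      "avian_vs", c("VS", "S", "M", "L"), c(416, 478, 542, 607),
      weber_fraction = 0.06, abundances = c(0.25, 0.5, 1, 1),
      grid = grid, ocular_media = TRUE),
    heli_I = visual_system(
      "heli_I", c("UV1", "UV2", "B", "L"), c(355, 390, 470, 555),
      weber_fraction = 0.05, abundances = c(0.09, 0.07, 0.17, 1),
      grid = grid),
    heli_II = visual_system(
      "heli_II", c("UV2", "B", "L"), c(390, 470, 555),
      weber_fraction = 0.05, abundances = c(0.13, 0.2, 1),
      grid = grid),
    heli_III = visual_system(
      "heli_III", c("UV1", "UV2", "B", "L"), c(355, 390, 470, 555),
      weber_fraction = 0.05, abundances = c(0.09, 0.13, 0.2, 1),
      grid = grid),
    heli_IV = visual_system(
      "heli_IV", c("UV1", "B", "L"), c(355, 470, 555),
      weber_fraction = 0.05, abundances = c(0.07, 0.26, 1),
      grid = grid))
}

#' Relative receptor abundances from ommatidial composition
#'
#' Whole-eye relative receptor abundances are the ommatidial-type
#' fractions multiplied by the proportion of each receptor class within
#' each ommatidial type, summed over types and normalised so the
#' long-wavelength (L) receptor equals 1.
#'
#' @param ommatidial_fractions numeric fractions of each ommatidial type,
#'   summing to 1.
#' @param receptor_composition list (one element per ommatidial type) of
#'   named numeric vectors giving receptor proportions within the type,
#'   each summing to 1.
#' @param reference label of the reference receptor (default `"L"`).
#' @return Named numeric vector of relative abundances with
#'   `reference` = 1.
#' @export
derive_abundances <- function(ommatidial_fractions, receptor_composition,
                              reference = "L") {
  stopifnot(length(ommatidial_fractions) == length(receptor_composition))
  if (abs(sum(ommatidial_fractions) - 1) > 1e-8)
    stop("ommatidial fractions must sum to 1")
  for (comp in receptor_composition)
    if (abs(sum(comp) - 1) > 1e-8)
      stop("receptor proportions within each type must sum to 1")
  labels <- unique(unlist(lapply(receptor_composition, names)))
  eta <- stats::setNames(numeric(length(labels)), labels)
  for (i in seq_along(ommatidial_fractions))
    for (r in names(receptor_composition[[i]]))
      eta[r] <- eta[r] +
        ommatidial_fractions[i] * receptor_composition[[i]][[r]]
  if (!reference %in% labels || eta[reference] == 0)
    stop("reference receptor absent or has zero abundance")
  eta / eta[[reference]]
}
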