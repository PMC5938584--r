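#' Receptor quantum catches of a stimulus
#'
#' Integrates reflectance x receptor sensitivity x illuminant x
#' ocular-media transmission over wavelength (trapezoid rule on a 1 nm
#' grid) for every receptor of a visual system. With `von_kries = TRUE`
#' each catch is divided by the catch of the adapting background -- a
#' perfect white reflector under the same illuminant -- so the catches of
#' that white are exactly 1 in every receptor.
#'
#' @param spec a [wing_spectrum()] covering the system's grid.
#' @param system a [visual_system()].
#' @param illum an [illuminant()] (default D65).
#' @param von_kries logical, apply the von Kries transform (default TRUE).
#' @return An object of class `catch_vector`: named numeric catches with
#'   attributes `system`, `illuminant`, `von_kries`.
#' @export
quantum_catches <- function(spec, system, illum = illuminant("D65"),
                            von_kries = TRUE) {
  stopifnot(inherits(spec, "wing_spectrum"),
            inherits(system, "visual_system"),
            inherits(illum, "illuminant"))
  grid <- system$grid
  refl <- stats::approx(spec$wavelength_nm, spec$reflectance_pct,
                        xout = grid, rule = 2)$y / 100
  irr <- stats::approx(illum$grid, illum$irradiance, xout = grid,
                       rule = 2)$y
  Q <- numeric(length(system$labels))
  for (i in seq_along(Q)) {
    w <- system$sensitivities[, i] * irr * system$ocular_media
    Q[i] <- trapz(grid, refl * w)
    if (von_kries) {
      Qwhite <- trapz(grid, w)   # perfect white reflector
      if (Qwhite <= 0) stop("degenerate stimulus: zero white catch for ",
                            system$labels[i])
      Q[i] <- Q[i] / Qwhite
    }
  }
  if (any(Q <= 0))
    stop("degenerate stimulus: non-positive quantum catch")
  structure(stats::setNames(Q, system$labels), class = "catch_vector",
            system = system$name, illuminant = illum$name,
            von_kries = von_kries)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Colour-space coordinates of a catch vector
#'
#' Normalises catches to relative catches (sum 1) and embeds them in the
#' receptor simplex: tetrachromats in the standard tetrahedral colour
#' space whose achromatic centre is the origin and whose vertices lie at
#' distance 0.75 from it; trichromats in a Maxwell triangle (unit edge,
#' centroid at the origin). Equal catches map to the origin in both.
#'
#' @param catches a `catch_vector` (or positive named numeric vector) with
#'   3 or 4 receptors, ordered short to long wavelength.
#' @return A list with `relative` (catches summing to 1) and `coords`
#'   (`x`, `y`, and for tetrachromats `z`).
#' @export
colour_point <- function(catches) {
  q <- as.numeric(catches)
  if (any(q <= 0)) stop("catches must be positive")
  k <- length(q)
  rel <- q / sum(q)
  if (k == 4L) {
    u <- rel[1]; s <- rel[2]; m <- rel[3]
    coords <- c(x = ((1 - 2 * s - m - u) / 2) * sqrt(3 / 2),
                y = (-1 + 3 * m + u) / (2 * sqrt(2)),
                z = u - 0.25)
  } else if (k == 3L) {
    v <- rbind(c(-0.5, -sqrt(3) / 6),
               c(0.5, -sqrt(3) / 6),
               c(0, sqrt(3) / 3))
    xy <- colSums(v * rel)
    coords <- c(x = xy[[1]], y = xy[[2]])
  } else stop("3 or 4 receptors supported")
  list(relative = rel, coords = coords)
}

# receptor noise per channel: e_i = w * sqrt(eta_ref / eta_i), reference
# receptor is L with abundance 1
receptor_noise <- function(system) {
  system$weber_fraction * sqrt(1 / system$abundances)
}

check_catch_pair <- function(a, b, system) {
  k <- length(system$labels)
  if (length(a) != k || length(b) != k)
    stop("catch vectors do not match the system's receptor count")
  if (any(as.numeric(a) <= 0) || any(as.numeric(b) <= 0))
    stop("catches must be positive")
}

#' Chromatic discriminability (receptor-noise-limited JND)
#'
#' Receptor-noise-limited colour distance between two stimuli with
#' log-coded receptor signals df_i = ln(Qa_i / Qb_i) and channel noise
#' e_i = w * sqrt(eta_L / eta_i). Uses the closed-form trichromat and
#' tetrachromat expressions of the receptor-noise model (the dichromat
#' form |df1 - df2| / sqrt(e1^2 + e2^2) is also available for reduced
#' systems). A value of 1 marks the discrimination threshold; the
#' distance is 0 exactly when the two catch vectors are proportional.
#'
#' @param a,b `catch_vector`s (or positive numeric vectors) under one
#'   system; use raw (non von Kries) catches or consistently transformed
#'   ones -- the distance only depends on catch ratios.
#' @param system the [visual_system()].
#' @return Chromatic distance in just-noticeable differences (JND).
#' @export
chromatic_jnd <- function(a, b, system) {
  stopifnot(inherits(system, "visual_system"))
  check_catch_pair(a, b, system)
  df <- log(as.numeric(a) / as.numeric(b))
  e <- receptor_noise(system)
  rnl_distance(df, e)
}

#' Receptor-noise-limited distance from log signals and channel noise
#'
#' The low-level closed forms of the receptor-noise model for 2, 3 or 4
#' channels, taking log-coded signal differences `df` and per-channel
#' noise `e` directly. [chromatic_jnd()] wraps this for catch vectors; the
#' dichromat form is exposed here for reduced systems and for
#' cross-checking the closed forms against the noise-weighted projection
#' form of the model.
#'
#' @param df numeric log signal differences, one per channel.
#' @param e positive per-channel noise values, same length.
#' @return The chromatic distance in JND.
#' @export
rnl_distance <- function(df, e) {
  stopifnot(length(df) == length(e), all(e > 0))
  k <- length(df)
  if (k == 2L) {
    sqrt((df[1] - df[2])^2 / (e[1]^2 + e[2]^2))
  } else if (k == 3L) {
    num <- e[1]^2 * (df[3] - df[2])^2 + e[2]^2 * (df[3] - df[1])^2 +
      e[3]^2 * (df[1] - df[2])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    sqrt(num / den)
  } else if (k == 4L) {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
      (e[1] * e[3])^2 * (df[4] - df[2])^2 +
      (e[1] * e[4])^2 * (df[3] - df[2])^2 +
      (e[2] * e[3])^2 * (df[4] - df[1])^2 +
      (e[2] * e[4])^2 * (df[3] - df[1])^2 +
      (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
      (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    sqrt(num / den)
  } else stop("2-4 receptor channels supported")
}

#' Achromatic discriminability (JND)
#'
#' Brightness discriminability based on the long-wavelength (L)
#' photoreceptor alone: |ln(Qa_L / Qb_L)| / w. One Weber step of the L
#' signal is one JND.
#'
#' @inheritParams chromatic_jnd
#' @return Achromatic distance in JND.
#' @export
achromatic_jnd <- function(a, b, system) {
  stopifnot(inherits(system, "visual_system"))
  check_catch_pair(a, b, system)
  k <- length(system$labels)
  abs(log(as.numeric(a)[k] / as.numeric(b)[k])) / system$weber_fraction
}

#' Pairwise discriminability between two groups of spectra
#'
#' Computes chromatic and achromatic JNDs for every cross-pair between
#' two groups of spectra (|A| x |B| comparisons; 4 individuals per group
#' gives the 16 pairwise comparisons of a co-mimic design) under one
#' visual system and illuminant, using raw quantum catches.
#'
#' @param groupA,groupB non-empty lists of [wing_spectrum()] objects.
#' @param system a [visual_system()].
#' @param illum an [illuminant()].
#' @return A `data.frame` with one row per pair (`a`, `b`,
#'   `chromatic_jnd`, `achromatic_jnd`, `system`, `illuminant`) and a
#'   `summary` attribute holding quartiles of both JND distributions.
#' @export
pairwise_discriminability <- function(groupA, groupB, system,
                                      illum = illuminant("D65")) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  qa <- lapply(groupA, quantum_catches, system = system, illum = illum,
               von_kries = FALSE)
  qb <- lapply(groupB, quantum_catches, system = system, illum = illum,
               von_kries = FALSE)
  res <- expand.grid(a = seq_along(qa), b = seq_along(qb))
  res$chromatic_jnd <- mapply(function(i, j)
    chromatic_jnd(qa[[i]], qb[[j]], system), res$a, res$b)
  res$achromatic_jnd <- mapply(function(i, j)
    achromatic_jnd(qa[[i]], qb[[j]], system), res$a, res$b)
  res$system <- system$name
  res$illuminant <- illum$name
  attr(res, "summary") <- list(
    chromatic = stats::quantile(res$chromatic_jnd),
    achromatic = stats::quantile(res$achromatic_jnd))
  res
}

#' Write a JND table as long-format TSV
#'
#' @param jnd a `data.frame` from [pairwise_discriminability()] (rows from
#'   several runs may be bound together).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_jnd_tsv <- function(jnd, path) {
  utils::write.table(jnd, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
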