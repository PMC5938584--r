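#' A homogeneous optical layer
#'
#' One non-absorbing layer of the ridge-lamellae multilayer: a real
#' refractive index (chitin n = 1.56, air n = 1.0) and a thickness in nm.
#'
#' @param n refractive index, dimensionless, >= 1.
#' @param d_nm thickness in nm, > 0 and finite.
#' @return An object of class `optical_layer`.
#' @export
layer <- function(n, d_nm) {
  if (!is.finite(n) || n < 1) stop("refractive index must be finite and >= 1")
  if (!is.finite(d_nm) || d_nm <= 0) stop("thickness must be positive, finite")
  structure(list(n = n, d_nm = d_nm), class = "optical_layer")
}

#' A periodic multilayer stack
#'
#' The optical model of the lamellae stacked within a wing-scale ridge: an
#' ordered unit cell of layers repeated `repeats` times between an ambient
#' medium (air above the scale) and a substrate (the chitin ridge body).
#' The observed ridges carry approximately two regular periodic chitin
#' protrusions, hence the default of 2 repeats.
#'
#' @param unit_cell list of [layer()] objects, in order from the ambient
#'   side.
#' @param repeats integer >= 1, number of unit-cell repeats.
#' @param ambient refractive index above the stack (default air, 1.0).
#' @param substrate refractive index below the stack (default chitin,
#'   1.56).
#' @return An object of class `multilayer_stack`.
#' @examples
#' st <- multilayer_stack(list(layer(1.0, 119), layer(1.56, 85)))
#' stack_period(st)            # 204 nm
#' bragg_peak_wavelength(st, 0)  # ~503 nm
#' @export
multilayer_stack <- function(unit_cell, repeats = 2L, ambient = 1.0,
                             substrate = 1.56) {
  stopifnot(length(unit_cell) >= 0,
            all(vapply(unit_cell, inherits, logical(1), "optical_layer")))
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L) stop("repeats must be >= 1")
  if (ambient < 1 || substrate < 1)
    stop("ambient/substrate indices must be >= 1")
  structure(list(unit_cell = unit_cell, repeats = repeats,
                 ambient = ambient, substrate = substrate),
            class = "multilayer_stack")
}

#' @export
print.multilayer_stack <- function(x, ...) {
  cat(sprintf("<multilayer_stack> %d-layer unit cell x %d, ambient n=%g, substrate n=%g\n",
              length(x$unit_cell), x$repeats, x$ambient, x$substrate))
  for (l in x$unit_cell)
    cat(sprintf("  n = %-5g d = %g nm\n", l$n, l$d_nm))
  cat(sprintf("  period %g nm\n", stack_period(x)))
  invisible(x)
}

unit_cell_n <- function(stack) vapply(stack$unit_cell, `[[`, numeric(1), "n")
unit_cell_d <- function(stack) vapply(stack$unit_cell, `[[`, numeric(1), "d_nm")

#' Period of the multilayer unit cell
#'
#' Sum of the unit-cell layer thicknesses, in nm.
#'
#' @param stack a [multilayer_stack()].
#' @return Period in nm.
#' @export
stack_period <- function(stack) {
  stopifnot(inherits(stack, "multilayer_stack"))
  sum(unit_cell_d(stack))
}

#' Effective (average) refractive index of the unit cell
#'
#' Thickness-weighted arithmetic mean of the layer indices,
#' n_eff = sum(n_i d_i) / sum(d_i). For the measured ridge unit cell
#' (119 nm air + 85 nm chitin) this gives 1.233.
#'
#' @param stack a [multilayer_stack()].
#' @return Dimensionless effective index.
#' @export
effective_index <- function(stack) {
  stopifnot(inherits(stack, "multilayer_stack"))
  n <- unit_cell_n(stack); d <- unit_cell_d(stack)
  sum(n * d) / sum(d)
}

#' First-order constructive-interference wavelength of the stack
#'
#' The classical multilayer reflector condition: the first-order reflected
#' wavelength at incidence angle theta (measured in the ambient medium) is
#' lambda_1 = 2 * sum_i d_i * sqrt(n_i^2 - sin^2 theta) over the unit
#' cell, which at normal incidence reduces to 2 * sum(n_i d_i).
#'
#' @param stack a [multilayer_stack()].
#' @param theta_deg incidence angle in degrees, 0 <= theta < 90.
#' @return Predicted peak wavelength in nm.
#' @export
bragg_peak_wavelength <- function(stack, theta_deg = 0) {
  stopifnot(inherits(stack, "multilayer_stack"))
  if (theta_deg < 0 || theta_deg >= 90) stop("theta must be in [0, 90)")
  s2 <- sin(theta_deg * pi / 180)^2
  n <- unit_cell_n(stack); d <- unit_cell_d(stack)
  2 * sum(d * sqrt(n^2 - s2))
}

# characteristic-matrix reflectance for one polarization at one wavelength
tmm_reflectance_one <- function(n_layers, d_layers, n0, ns, lambda_nm,
                                theta_deg, pol) {
  s0 <- n0 * sin(theta_deg * pi / 180)        # Snell invariant n sin(theta)
  cos_in <- function(n) sqrt(as.complex(1 - (s0 / n)^2))
  eta <- function(n, ct) if (pol == "s") n * ct else n / ct
  ct0 <- cos_in(n0); cts <- cos_in(ns)
  M <- diag(2) + 0i
  if (length(n_layers)) {
    for (j in seq_along(n_layers)) {
      ctj <- cos_in(n_layers[j])
      delta <- 2 * pi * n_layers[j] * d_layers[j] * ctj / lambda_nm
      ej <- eta(n_layers[j], ctj)
      # column-major fill: [[cos d, i sin d / eta], [i eta sin d, cos d]]
      Mj <- matrix(c(cos(delta), 1i * ej * sin(delta),
                     1i * sin(delta) / ej, cos(delta)), 2, 2)
      M <- M %*% Mj
    }
  }
  e0 <- eta(n0, ct0); es <- eta(ns, cts)
  BC <- M %*% c(1, es)
  r <- (e0 * BC[1] - BC[2]) / (e0 * BC[1] + BC[2])
  Mod(r)^2
}

#' Transfer-matrix reflectance of the finite stack
#'
#' Exact plane-wave (characteristic-matrix) reflectance of the finite
#' lossless multilayer between ambient and substrate, for s or p
#' polarization or their unpolarized mean. Vectorized over wavelength.
#'
#' @param stack a [multilayer_stack()].
#' @param wavelength_nm wavelength(s) in nm, > 0.
#' @param theta_deg incidence angle in degrees in the ambient medium,
#'   0 <= theta < 90.
#' @param polarization one of `"s"`, `"p"`, `"unpolarized"`.
#' @return Reflectance fraction(s) in `[0, 1]`, same length as
#'   `wavelength_nm`.
#' @export
tmm_reflectance <- function(stack, wavelength_nm, theta_deg = 0,
                            polarization = c("unpolarized", "s", "p")) {
  stopifnot(inherits(stack, "multilayer_stack"))
  polarization <- match.arg(polarization)
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  if (theta_deg < 0 || theta_deg >= 90) stop("theta must be in [0, 90)")
  n_seq <- rep(unit_cell_n(stack), times = stack$repeats)
  d_seq <- rep(unit_cell_d(stack), times = stack$repeats)
  one <- function(lam, pol)
    tmm_reflectance_one(n_seq, d_seq, stack$ambient, stack$substrate,
                        lam, theta_deg, pol)
  vapply(wavelength_nm, function(lam) {
    switch(polarization,
           s = one(lam, "s"),
           p = one(lam, "p"),
           unpolarized = (one(lam, "s") + one(lam, "p")) / 2)
  }, numeric(1))
}

#' Model reflectance spectrum of a stack
#'
#' Vectorized [tmm_reflectance()] over a wavelength grid, returned as a
#' [wing_spectrum()] in percent (reflectance fraction x 100).
#'
#' @inheritParams tmm_reflectance
#' @param grid wavelength grid in nm.
#' @param taxon optional taxon label carried in the metadata.
#' @return A `wing_spectrum`.
#' @export
reflectance_spectrum <- function(stack, grid = 300:700, theta_deg = 0,
                                 polarization = "unpolarized",
                                 taxon = NA_character_) {
  R <- tmm_reflectance(stack, grid, theta_deg, polarization)
  wing_spectrum(grid, 100 * R, taxon = taxon, angle_deg = theta_deg)
}

#' Read or write a multilayer stack as JSON
#'
#' The JSON layout is
#' `{"ambient": 1.0, "substrate": 1.56,
#'   "unit_cell": [{"n": 1.0, "d_nm": 119}, {"n": 1.56, "d_nm": 85}],
#'   "repeats": 2}`.
#'
#' @param path JSON file path.
#' @return `read_stack_json` returns a [multilayer_stack()];
#'   `write_stack_json` returns `path` invisibly.
#' @export
read_stack_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  multilayer_stack(lapply(j$unit_cell, function(l) layer(l$n, l$d_nm)),
                   repeats = j$repeats %||% 2L,
                   ambient = j$ambient %||% 1.0,
                   substrate = j$substrate %||% 1.56)
}

#' @rdname read_stack_json
#' @param stack a [multilayer_stack()].
#' @export
write_stack_json <- function(stack, path) {
  stopifnot(inherits(stack, "multilayer_stack"))
  jsonlite::write_json(
    list(ambient = stack$ambient, substrate = stack$substrate,
         unit_cell = lapply(stack$unit_cell, function(l)
           list(n = l$n, d_nm = l$d_nm)),
         repeats = stack$repeats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The measured iridescent-ridge multilayer
#'
#' Convenience constructor for the unit cell measured by FIB-SEM on
#' iridescent *H. sara* ridges: 119 nm air + 85 nm chitin (n = 1.56),
#' repeated twice over a chitin substrate.
#'
#' @param repeats number of unit-cell repeats (default 2).
#' @return A [multilayer_stack()].
#' @export
sara_ridge_stack <- function(repeats = 2L) {
  multilayer_stack(list(layer(1.0, 119), layer(1.56, 85)),
                   repeats = repeats, ambient = 1.0, substrate = 1.56)
}
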