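#' Read a reflectance spectrum from a two-column CSV file
#'
#' Files hold one spectrum per incidence angle with header
#' `wavelength_nm,reflectance_pct`. Metadata is taken from the file name,
#' which by convention is `taxon_wing_individual_angle.csv`
#' (e.g. `sara-ecuador_fore_i1_+10.csv`); a JSON sidecar named
#' `<file>.json` with any of the fields `taxon`, `wing`, `individual`,
#' `angle_deg` overrides the file-name parse.
#'
#' @param path path to the CSV file.
#' @return A [wing_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("wavelength_nm", "reflectance_pct") %in% names(d)))
    stop("expected columns wavelength_nm,reflectance_pct in ", path)
  meta <- parse_spectrum_filename(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    ov <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (f in intersect(names(ov), c("taxon", "wing", "individual",
                                     "angle_deg")))
      meta[[f]] <- ov[[f]]
  }
  wing_spectrum(d$wavelength_nm, d$reflectance_pct,
                taxon = meta$taxon, wing = meta$wing,
                angle_deg = meta$angle_deg, individual = meta$individual)
}

parse_spectrum_filename <- function(path) {
  stem <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  meta <- list(taxon = NA_character_, wing = NA_character_,
               individual = NA_character_, angle_deg = NA_real_)
  if (length(parts) >= 4L) {
    meta$taxon <- parts[1]
    meta$wing <- parts[2]
    meta$individual <- parts[3]
    ang <- suppressWarnings(as.numeric(sub("^\\+", "", parts[4])))
    meta$angle_deg <- ang
  }
  meta
}

#' Write a spectrum to a two-column CSV file
#'
#' Writes the `wavelength_nm,reflectance_pct` table and, when `sidecar` is
#' TRUE, a JSON sidecar carrying the metadata so the file round-trips
#' independently of its name.
#'
#' @param spec a [wing_spectrum()].
#' @param path output path.
#' @param sidecar write `<path>.json` metadata (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path, sidecar = TRUE) {
  stopifnot(inherits(spec, "wing_spectrum"))
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE,
                   quote = FALSE)
  if (sidecar)
    jsonlite::write_json(spec$meta[!vapply(spec$meta, function(v)
      all(is.na(v)), logical(1))], paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Summarise one processed spectrum or angle series
#'
#' Convenience wrapper producing the per-measurement descriptor row used
#' by the per-taxon summary table: peak wavelength, FWHM, maximum
#' reflectance, and (for an angle series) the angle of maximum
#' reflectance.
#'
#' @param x a [wing_spectrum()] or [angle_series()].
#' @param window working wavelength range (nm).
#' @return A one-row `data.frame`.
#' @export
summarize_spectrum <- function(x, window = c(300, 700)) {
  if (inherits(x, "angle_series")) {
    am <- angle_of_max(x, window = window)
    best <- which(vapply(x$spectra, function(s) {
      inw <- s$wavelength_nm >= window[1] & s$wavelength_nm <= window[2]
      max(s$reflectance_pct[inw])
    }, numeric(1)) == am$max_pct)[1]
    pf <- peak_and_fwhm(x$spectra[[best]], window = window)
    meta <- x$spectra[[best]]$meta
    angle <- am$angle_deg
  } else {
    stopifnot(inherits(x, "wing_spectrum"))
    pf <- peak_and_fwhm(x, window = window)
    meta <- x$meta
    angle <- meta$angle_deg
  }
  data.frame(taxon = meta$taxon, wing = meta$wing,
             individual = meta$individual,
             peak_wavelength_nm = pf$peak_nm,
             fwhm_nm = pf$fwhm_nm,
             angle_of_max_deg = angle,
             max_reflectance_pct = pf$max_pct,
             peak_at_boundary = pf$peak_at_boundary,
             stringsAsFactors = FALSE)
}
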