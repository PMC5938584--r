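#' Per-taxon summary of structural and optical descriptors
#'
#' Aggregates per-individual descriptors (peak wavelength, FWHM, angle of
#' maximum reflectance, maximum reflectance, ridge-spacing estimates) to
#' per-taxon mean and sample standard deviation (n - 1). Taxa with a
#' single individual get an NA standard deviation.
#'
#' @param data a `data.frame` with a `taxon` column and numeric descriptor
#'   columns (e.g. the rows produced by [summarize_spectrum()] merged with
#'   spacing estimates).
#' @param columns descriptor columns to aggregate; defaults to every
#'   numeric column except `taxon`.
#' @return A `data.frame`, one row per taxon, with `<col>_mean`,
#'   `<col>_sd` and `n` columns.
#' @export
build_summary <- function(data, columns = NULL) {
  stopifnot(is.data.frame(data), "taxon" %in% names(data))
  if (is.null(columns))
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  columns <- setdiff(columns, "taxon")
  taxa <- unique(data$taxon)
  rows <- lapply(taxa, function(tx) {
    d <- data[data$taxon == tx, , drop = FALSE]
    out <- list(taxon = tx, n = nrow(d))
    for (cl in columns) {
      v <- d[[cl]][is.finite(d[[cl]])]
      out[[paste0(cl, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(cl, "_sd")]] <- if (length(v) > 1L) stats::sd(v)
      else NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' Sample Pearson correlation r with the two-sided p-value from
#' t = r sqrt((n - 2) / (1 - r^2)) against Student's t with n - 2 degrees
#' of freedom -- the single planned test relating mean ridge spacing to
#' mean maximum reflectance across taxa.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with a missing
#'   value are dropped.
#' @return A list with `r`, `p`, `n`, `t`, `df`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p, n = n, t = t, df = n - 2)
}

#' Ridge-spacing versus brightness analysis
#'
#' The taxon-level association between mean ridge spacing (SAXS) and mean
#' maximum reflectance: global Pearson r and p over all taxa with both
#' values, plus ordinary-least-squares slopes of reflectance on spacing
#' fitted separately within each clade grouping. Taxa missing a spacing
#' or reflectance value are excluded from the correlation.
#'
#' @param rows a `data.frame` with columns `taxon`,
#'   `ridge_spacing_saxs_nm`, `max_reflectance_pct` (mean values).
#' @param clades named character vector mapping taxon to clade label;
#'   defaults to the *H. erato* / *H. melpomene* clade grouping of the
#'   study taxa.
#' @return A list with `r`, `p`, `n` and `slopes` (named per-clade OLS
#'   slope, % reflectance per nm of spacing).
#' @export
spacing_reflectance_analysis <- function(rows, clades = default_clades()) {
  stopifnot(is.data.frame(rows),
            all(c("taxon", "ridge_spacing_saxs_nm",
                  "max_reflectance_pct") %in% names(rows)))
  ok <- is.finite(rows$ridge_spacing_saxs_nm) &
    is.finite(rows$max_reflectance_pct)
  d <- rows[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 taxa with both values")
  ct <- pearson_with_p(d$ridge_spacing_saxs_nm, d$max_reflectance_pct)
  d$clade <- unname(clades[d$taxon])
  slopes <- vapply(split(d, d$clade), function(g) {
    if (nrow(g) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(max_reflectance_pct ~
                                   ridge_spacing_saxs_nm, data = g))[2])
  }, numeric(1))
  list(r = ct$r, p = ct$p, n = ct$n, slopes = slopes)
}

#' Default clade grouping of the study taxa
#'
#' @return Named character vector taxon -> clade (`"erato"` or
#'   `"melpomene"`).
#' @export
default_clades <- function() {
  c("H. erato cyrbia" = "erato",
    "H. erato demophoon" = "erato",
    "H. sara (Ecuador)" = "erato",
    "H. sara (Panama)" = "erato",
    "H. eleuchia" = "erato",
    "H. cydno" = "melpomene",
    "H. melpomene cythera" = "melpomene",
    "H. melpomene rosina" = "melpomene")
}

#' Write a per-taxon summary table as TSV
#'
#' @param rows a `data.frame` of summary rows.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
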