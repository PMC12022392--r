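#' Tabulated chromophore spectrum
#'
#' Container for a tabulated wavelength-dependent absorption spectrum of a
#' single chromophore, either as a molar extinction coefficient
#' (L mol^-1 cm^-1) or directly as an absorption coefficient (cm^-1).
#' Queries interpolate linearly and error outside the tabulated range.
#'
#' @param wavelength_nm Strictly increasing wavelengths in nm. Must cover at
#'   least the 400--1000 nm analysis band.
#' @param value Non-negative values, same length as `wavelength_nm`.
#' @param name Chromophore label.
#' @param kind `"epsilon"` for molar extinction (L mol^-1 cm^-1) or `"mua"`
#'   for an absorption coefficient (cm^-1).
#' @return An object of class `extinction_table`.
#' @export
extinction_table <- function(wavelength_nm, value, name, kind = c("epsilon", "mua")) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value))
    stop("wavelength and value must have the same length")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(value < 0) || anyNA(value))
    stop("values must be non-negative and finite")
  structure(list(name = name, wavelength_nm = wavelength_nm,
                 value = value, kind = kind),
            class = "extinction_table")
}

#' @export
print.extinction_table <- function(x, ...) {
  unit <- if (x$kind == "epsilon") "L mol^-1 cm^-1" else "cm^-1"
  cat(sprintf("<extinction_table> %s: %d points, %g-%g nm [%s]\n",
              x$name, length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm), unit))
  invisible(x)
}

#' Read a two-column chromophore table
#'
#' Reads a plain-text TSV with columns `wavelength_nm` and `value`
#' (`#` comment header lines allowed).
#'
#' @param path File path.
#' @param name Chromophore label (defaults to the file name).
#' @inheritParams extinction_table
#' @return An [extinction_table()].
#' @export
read_extinction_table <- function(path, name = NULL, kind = c("epsilon", "mua")) {
  kind <- match.arg(kind)
  d <- utils::read.delim(path, comment.char = "#", header = TRUE)
  if (is.null(name))
    name <- sub("\\.(tsv|txt)$", "", basename(path))
  extinction_table(d$wavelength_nm, d$value, name = name, kind = kind)
}

#' Query a tabulated spectrum
#'
#' Linear interpolation; wavelengths outside the tabulated range are an error.
#'
#' @param table An [extinction_table()].
#' @param lambda_nm Wavelengths in nm.
#' @return Interpolated values.
#' @export
ext_value <- function(table, lambda_nm) {
  stopifnot(inherits(table, "extinction_table"))
  rng <- range(table$wavelength_nm)
  if (any(lambda_nm < rng[1] | lambda_nm > rng[2]))
    stop(sprintf("wavelength outside tabulated range [%g, %g] nm for %s",
                 rng[1], rng[2], table$name))
  stats::approx(table$wavelength_nm, table$value, xout = lambda_nm)$y
}

#' Bundled chromophore tables
#'
#' Loads the chromophore spectra shipped with the package: molar extinction
#' of oxy-, deoxy- and methemoglobin (per 64500 g/mol) and bilirubin, and
#' absorption coefficients of water, beta-carotene and fat. The bundled
#' tables are synthetic approximations of the published compilations (see
#' the file headers under `extdata/`); user-supplied directories with the
#' same file names may be substituted.
#'
#' @param dir Directory holding the TSV files; defaults to the package data.
#' @return Named list of [extinction_table()] objects with elements
#'   `oxy`, `deoxy`, `met`, `water`, `bilirubin`, `betacarotene`, `fat`.
#' @export
chromophore_tables <- function(dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", package = "drsmethb")
  spec <- list(
    oxy          = c("eps_oxyhb_synthetic.tsv", "epsilon"),
    deoxy        = c("eps_deoxyhb_synthetic.tsv", "epsilon"),
    met          = c("eps_methb_synthetic.tsv", "epsilon"),
    water        = c("mua_water_synthetic.tsv", "mua"),
    bilirubin    = c("eps_bilirubin_synthetic.tsv", "epsilon"),
    betacarotene = c("mua_betacarotene_synthetic.tsv", "mua"),
    fat          = c("mua_fat_synthetic.tsv", "mua")
  )
  out <- lapply(names(spec), function(nm) {
    read_extinction_table(file.path(dir, spec[[nm]][1]),
                          name = nm, kind = spec[[nm]][2])
  })
  names(out) <- names(spec)
  out
}
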