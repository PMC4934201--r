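#' Read a spectrum from a two-column text file
#'
#' The format is comma-delimited UTF-8 text with a `wavelength_nm,value`
#' header and optional `#`-prefixed comment lines. Wavelengths must parse,
#' be finite and strictly increasing.
#'
#' @param path File path.
#' @param unit Unit tag to attach (the file format itself is unit-agnostic).
#' @return A [sif_spectrum()].
#' @export
read_spectrum <- function(path, unit = "radiance") {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(df))) {
    rlang::abort(sprintf("%s: expected columns wavelength_nm,value.", path))
  }
  if (anyNA(df$wavelength_nm) || anyNA(df$value)) {
    bad <- which(is.na(df$wavelength_nm) | is.na(df$value))[1]
    rlang::abort(sprintf("%s: unparseable value at data row %d.", path, bad))
  }
  if (nrow(df) > 1 && any(diff(df$wavelength_nm) <= 0)) {
    bad <- which(diff(df$wavelength_nm) <= 0)[1] + 1L
    rlang::abort(sprintf("%s: wavelengths not strictly increasing at data row %d.", path, bad))
  }
  sif_spectrum(df$wavelength_nm, df$value, unit)
}

#' Write a spectrum to a two-column text file
#'
#' Deterministic formatting: `#` provenance comments (package version, unit,
#' optional seed), the `wavelength_nm,value` header, then one row per sample
#' with six decimal places on wavelengths and full precision on values.
#'
#' @param spectrum A non-empty [sif_spectrum()].
#' @param path Output path.
#' @param seed Optional seed to record in the provenance comments.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path, seed = NULL) {
  if (nrow(spectrum) == 0) rlang::abort("Refusing to write an empty spectrum.")
  header <- c(
    sprintf("# canopysif %s", as.character(utils::packageVersion("canopysif"))),
    sprintf("# unit: %s", sif_unit(spectrum)),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
  body <- sprintf("%.6f,%.15g", spectrum$wavelength_nm, spectrum$value)
  writeLines(c(header, "wavelength_nm,value", body), path)
  invisible(path)
}

#' Load retrieval windows from a parameter file
#'
#' Reads a comma-delimited window table (columns: `algorithm`, `band`, `set`,
#' `candidate`, `lambda_in`, `lambda_left`, `lambda_right`, `degree_r`,
#' `degree_f`; wavelength lists separated by `;`) and validates each row into
#' a [retrieval_window()]. The bundled default file carries, for each band,
#' the three candidate parameter sets per algorithm and the selected set used
#' by the evaluation experiments.
#'
#' @param path Path to a window file; default is the bundled table.
#' @return A tibble with the parsed columns plus a `window` list-column of
#'   validated [retrieval_window()] objects.
#' @export
load_windows <- function(path = system.file("extdata", "retrieval_windows.csv",
                                            package = "canopysif")) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          algorithm = "c", band = "c", set = "c", candidate = "i",
                          lambda_in = "d", lambda_left = "c", lambda_right = "c",
                          degree_r = "i", degree_f = "i"
                        ))
  parse_list <- function(x) {
    if (is.na(x) || !nzchar(x)) numeric() else as.numeric(strsplit(x, ";")[[1]])
  }
  df$window <- purrr::pmap(df, function(algorithm, band, set, candidate,
                                        lambda_in, lambda_left, lambda_right,
                                        degree_r, degree_f, ...) {
    tryCatch(
      retrieval_window(algorithm, band, lambda_in,
                       parse_list(lambda_left), parse_list(lambda_right),
                       degree_r, degree_f),
      error = function(e) {
        rlang::abort(sprintf("Invalid window row (%s %s %s #%s): %s",
                             algorithm, band, set, candidate, conditionMessage(e)))
      }
    )
  })
  df
}

#' @rdname load_windows
#' @param set `"selected"` (the evaluation defaults) or `"candidate"`.
#' @param band Optionally restrict to `"O2A"` or `"O2B"`.
#' @export
default_windows <- function(set = c("selected", "candidate"), band = NULL) {
  set <- match.arg(set)
  df <- load_windows()
  df <- df[df$set == set, , drop = FALSE]
  if (!is.null(band)) df <- df[df$band == band, , drop = FALSE]
  df
}
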