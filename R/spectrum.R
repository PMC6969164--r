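#' Sampled spectrum container
#'
#' A `spectrum` holds one sampled intensity curve on a strictly increasing
#' abscissa: wavelength in nm for circular-dichroism (CD) and fluorescence
#' data, wavenumber in cm^-1 for FTIR. It is the common currency of the
#' spectroscopic modules: the two-state CD decomposition, Amide I band
#' fitting, and fluorescent-probe analyses all consume and produce it.
#'
#' @param grid numeric abscissa, strictly increasing, length >= 8
#'   (nm or cm^-1 depending on `kind`).
#' @param values numeric signal per grid point (mdeg for CD, absorbance for
#'   FTIR, counts for fluorescence); same length as `grid`.
#' @param kind one of `"cd"`, `"ftir"`, `"fluorescence"`.
#' @return An object of class `spectrum`: a list with elements `grid`,
#'   `values` and `kind`.
#' @examples
#' s <- spectrum(185:260, rep(0, 76), kind = "cd")
#' length(s$grid)
#' @export
spectrum <- function(grid, values, kind = c("cd", "ftir", "fluorescence")) {
  kind <- match.arg(kind)
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) != length(values))
    stop_input("grid and values must have equal length")
  if (length(grid) < 8L)
    stop_input("a spectrum needs at least 8 points")
  if (any(!is.finite(grid)) || any(diff(grid) <= 0))
    stop_input("grid must be finite and strictly increasing")
  if (any(!is.finite(values)))
    stop_input("values must be finite")
  structure(list(grid = grid, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$kind == "ftir") "cm^-1" else "nm"
  cat(sprintf("<spectrum [%s]> %d points, %g-%g %s\n",
              x$kind, length(x$grid), min(x$grid), max(x$grid), unit))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

# Shared grid check used by operations combining several spectra.
check_same_grid <- function(...) {
  specs <- list(...)
  g <- specs[[1]]$grid
  for (s in specs[-1]) {
    if (length(s$grid) != length(g) || any(abs(s$grid - g) > 1e-9))
      stop_input("spectra must share an identical grid")
  }
  invisible(g)
}

#' Write / read a spectrum as commented-header CSV
#'
#' The on-disk format is two columns `grid,value` preceded by a `# kind=...`
#' comment line, so fixtures stay inspectable plain text.
#'
#' @param x a [spectrum()].
#' @param path file path.
#' @return `write_spectrum_csv` returns `path` invisibly;
#'   `read_spectrum_csv` returns a [spectrum()].
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(is_spectrum(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", x$kind), con)
  writeLines("grid,value", con)
  writeLines(sprintf("%.12g,%.12g", x$grid, x$values), con)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  kind <- sub("^# kind=", "", grep("^# kind=", meta, value = TRUE)[1])
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  spectrum(body$grid, body$value, kind = kind)
}
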