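#' Standard measurement grid
#'
#' Wavelength grid used throughout the vision pipeline: 300 to 650 nm at
#' 10 nm steps, matching the resolution of a benchtop UV-visible
#' spectrophotometer with a diffuse-reflectance attachment.
#'
#' @return Numeric vector of 36 wavelengths (nm).
#' @export
standard_grid <- function() seq(300, 650, by = 10)

#' Construct a spectrum
#'
#' A spectrum is a wavelength-indexed curve: a flower reflectance
#' (fraction relative to a white standard), an illuminant (relative photon
#' flux), or a photoreceptor sensitivity (peak-normalized).
#'
#' @param wavelength Numeric vector of wavelengths (nm), strictly increasing.
#' @param value Numeric vector of the same length. Reflectance values must be
#'   non-negative; values above 1 are retained (a surface can exceed the
#'   white standard).
#' @param kind One of `"reflectance"`, `"illuminant"`, `"sensitivity"`.
#' @param label Optional sample identifier.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength, value,
                     kind = c("reflectance", "illuminant", "sensitivity"),
                     label = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(wavelength) || !is.numeric(value))
    stop("wavelength and value must be numeric")
  if (length(wavelength) != length(value))
    stop("wavelength and value differ in length")
  if (anyNA(wavelength) || anyNA(value))
    stop("spectrum contains missing values")
  if (length(wavelength) < 1L)
    stop("a spectrum needs at least one point")
  dw <- diff(wavelength)
  if (any(dw == 0))
    stop("duplicate wavelengths at rows: ",
         paste(which(dw == 0) + 1L, collapse = ", "))
  if (any(dw < 0))
    stop("wavelength grid not strictly increasing at rows: ",
         paste(which(dw < 0) + 1L, collapse = ", "))
  if (kind == "reflectance" && any(value < 0))
    stop("negative reflectance values; clean the input first")
  structure(list(wavelength = as.numeric(wavelength),
                 value = as.numeric(value),
                 kind = kind, label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s%s, %d points, %g-%g nm>\n", x$kind,
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$value)
}

covers_standard_grid <- function(s) {
  min(s$wavelength) <= 300 && max(s$wavelength) >= 650
}

#' Read spectra from delimited text
#'
#' Reads a comma- or tab-delimited file (autodetected) whose first column is
#' the wavelength in nm and whose remaining columns are one sample each.
#' Negative readings (instrument noise below the dark reference) are clipped
#' to zero with a warning giving the number of clipped cells.
#'
#' @param path Path to the file. The header row names the samples.
#' @param kind Spectrum kind passed to [spectrum()].
#' @return Named list of `spectrum` objects, one per sample column.
#' @export
read_spectra <- function(path, kind = "reflectance") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("need a wavelength column plus at least one sample")
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric cell in column '", names(df)[j], "', row ",
           bad[1L] + 1L)
    }
  }
  wl <- df[[1L]]
  n_clipped <- 0L
  out <- lapply(names(df)[-1L], function(nm) {
    v <- df[[nm]]
    if (kind == "reflectance" && any(v < 0)) {
      n_clipped <<- n_clipped + sum(v < 0)
      v[v < 0] <- 0
    }
    spectrum(wl, v, kind = kind, label = nm)
  })
  if (n_clipped > 0L)
    warning(sprintf("clipped %d negative reflectance value(s) to 0", n_clipped))
  names(out) <- names(df)[-1L]
  out
}

#' Write spectra to delimited text
#'
#' Inverse of [read_spectra()]: all spectra must share one wavelength grid.
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_spectra <- function(spectra, path, sep = ",") {
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1L]]$wavelength
  for (s in spectra)
    if (!identical(s$wavelength, wl)) stop("spectra are on different grids")
  labels <- vapply(seq_along(spectra), function(i) {
    if (!is.null(spectra[[i]]$label)) spectra[[i]]$label
    else if (!is.null(names(spectra)[i]) && nzchar(names(spectra)[i]))
      names(spectra)[i]
    else paste0("sample_", i)
  }, character(1))
  df <- cbind(data.frame(wavelength_nm = wl),
              as.data.frame(lapply(spectra, `[[`, "value"),
                            col.names = labels, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; exact at source nodes, so resampling onto a finer
#' grid and back is lossless. Extrapolation beyond the source range is
#' refused.
#'
#' @param s A `spectrum`.
#' @param grid Target wavelength grid (nm), within the source range.
#' @return A `spectrum` on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  if (min(grid) < min(s$wavelength) || max(grid) > max(s$wavelength))
    stop("target grid [", min(grid), ", ", max(grid),
         "] extends beyond source range [", min(s$wavelength), ", ",
         max(s$wavelength), "]; extrapolation refused")
  v <- stats::approx(s$wavelength, s$value, xout = grid, method = "linear")$y
  spectrum(grid, v, kind = s$kind, label = s$label)
}

#' CIE D65 daylight illuminant as photon flux
#'
#' The tabulated CIE standard illuminant D65 relative spectral power
#' distribution on 300-650 nm, converted from energy to relative photon flux
#' by multiplying each value by its wavelength (the remaining physical
#' constants cancel under von Kries normalization), then normalized to 1 at
#' 550 nm.
#'
#' @return An illuminant `spectrum` on the standard grid.
#' @export
illuminant_d65 <- function() {
  path <- system.file("extdata", "cie_d65_300_650.csv", package = "polmorph",
                      mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  flux <- df$relative_power * df$wavelength_nm
  flux <- flux / flux[df$wavelength_nm == 550]
  spectrum(df$wavelength_nm, flux, kind = "illuminant", label = "D65")
}

# A1 visual-pigment alpha-band absorbance nomogram (Govardovskii-type),
# parameterized only by the peak wavelength. Returns absorbance relative to
# the value at lambda_max (exactly 1 there).
pigment_template <- function(wavelength, lambda_max) {
  x <- lambda_max / wavelength
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  band <- function(x) 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                             exp(-14.9 * (1.104 - x)) + 0.674)
  band(x) / band(1)
}

#' Trichromatic photoreceptor sensitivity set
#'
#' Builds the three hymenopteran photoreceptor spectral-sensitivity curves
#' (UV, blue, green) from a standard visual-pigment absorbance template
#' parameterized by the peak wavelength of each class. Defaults are honeybee
#' (*Apis mellifera*) peak positions. Curves are normalized to 1 at their
#' peak and tabulated on the standard grid augmented with the exact peak
#' node, so linear resampling recovers the peak exactly.
#'
#' @param lambda_max Named numeric vector `c(UV=, B=, G=)` of peak
#'   wavelengths in nm, each within 300-650.
#' @return Object of class `receptor_set`: a list of three sensitivity
#'   spectra plus the `lambda_max` used.
#' @export
receptor_set <- function(lambda_max = c(UV = 344, B = 436, G = 544)) {
  need <- c("UV", "B", "G")
  if (!all(need %in% names(lambda_max)))
    stop("lambda_max must name UV, B and G")
  lambda_max <- lambda_max[need]
  if (any(lambda_max < 300 | lambda_max > 650))
    stop("lambda_max outside the 300-650 nm grid")
  curves <- lapply(need, function(cl) {
    lm <- lambda_max[[cl]]
    grid <- sort(unique(c(standard_grid(), lm)))
    spectrum(grid, pigment_template(grid, lm), kind = "sensitivity",
             label = paste0("S_", cl))
  })
  names(curves) <- need
  structure(list(curves = curves, lambda_max = lambda_max),
            class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  cat(sprintf("<receptor_set: UV %g nm, B %g nm, G %g nm>\n",
              x$lambda_max[["UV"]], x$lambda_max[["B"]], x$lambda_max[["G"]]))
  invisible(x)
}

#' Flat achromatic adaptation background
#'
#' Constant-reflectance background the visual system is assumed adapted to;
#' 10% reflectance is the conventional choice for vegetation-like scenes.
#'
#' @param level Reflectance fraction in (0, 1].
#' @return A reflectance `spectrum` on the standard grid.
#' @export
flat_background <- function(level = 0.10) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1)
    stop("background level must be in (0, 1]")
  grid <- standard_grid()
  spectrum(grid, rep(level, length(grid)), kind = "reflectance",
           label = sprintf("flat_%g", level))
}
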