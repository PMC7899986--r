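#' Photoreceptor quantum catches with von Kries adaptation
#'
#' For each receptor class the raw catch is the trapezoidal integral of
#' illuminant x sensitivity x reflectance over the standard grid; the
#' adapted catch divides by the same integral taken over the adaptation
#' background, so a stimulus identical to the background yields a catch of
#' exactly 1 in every class.
#'
#' @param reflectance Reflectance `spectrum` covering 300-650 nm.
#' @param receptors A [receptor_set()].
#' @param illuminant Illuminant `spectrum`; default [illuminant_d65()].
#' @param background Adaptation background; default [flat_background()].
#' @return Named numeric vector `c(UV=, B=, G=)` of class `quantum_catch`.
#' @export
quantum_catch <- function(reflectance, receptors,
                          illuminant = illuminant_d65(),
                          background = flat_background()) {
  stopifnot(inherits(reflectance, "spectrum"),
            inherits(receptors, "receptor_set"),
            inherits(illuminant, "spectrum"),
            inherits(background, "spectrum"))
  for (s in list(reflectance, illuminant, background))
    if (!covers_standard_grid(s))
      stop("spectrum '", s$label, "' does not cover 300-650 nm")
  grid <- standard_grid()
  R <- resample_spectrum(reflectance, grid)$value
  I <- resample_spectrum(illuminant, grid)$value
  Rb <- resample_spectrum(background, grid)$value
  P <- vapply(receptors$curves, function(sens) {
    S <- resample_spectrum(sens, grid)$value
    denom <- pracma::trapz(grid, I * S * Rb)
    if (denom <= 0) stop("degenerate adaptation: zero background catch")
    pracma::trapz(grid, I * S * R) / denom
  }, numeric(1))
  structure(P, class = "quantum_catch")
}

#' Receptor excitation from quantum catch
#'
#' The phototransduction nonlinearity E = P/(P+1): the background (P = 1)
#' maps to half-maximal excitation, and excitations stay in `[0, 1)`.
#'
#' @param P Named non-negative numeric vector of catches (UV, B, G).
#' @return Named numeric vector of excitations.
#' @export
excitation <- function(P) {
  P <- unclass(P)
  if (any(P < 0)) stop("negative quantum catch")
  E <- P / (P + 1)
  names(E) <- names(P)
  E
}

#' Hexagon colour-space locus
#'
#' Projects the three excitations into the colour hexagon:
#' x = (sqrt(3)/2) (E_G - E_UV), y = E_B - (E_UV + E_G)/2, with UV at the
#' lower left, green at the lower right and blue at the top. The adapted
#' background sits at the origin.
#'
#' @param E Named numeric vector `c(UV=, B=, G=)` of excitations in `[0, 1)`.
#' @param label Sample identifier.
#' @param part Flower part: `"sepal"`, `"labellum"` or `"other"`.
#' @param category Colour-category code (1-5) or `NA`.
#' @return Object of class `hex_locus` with fields `E_UV`, `E_B`, `E_G`,
#'   `x`, `y`, `label`, `part`, `category`.
#' @export
hexagon_locus <- function(E, label = NULL, part = "other", category = NA) {
  need <- c("UV", "B", "G")
  if (!all(need %in% names(E))) stop("E must name UV, B and G")
  if (any(E[need] < 0 | E[need] >= 1)) stop("excitations must be in [0, 1)")
  structure(list(E_UV = unname(E[["UV"]]), E_B = unname(E[["B"]]),
                 E_G = unname(E[["G"]]),
                 x = sqrt(3) / 2 * (E[["G"]] - E[["UV"]]),
                 y = E[["B"]] - (E[["UV"]] + E[["G"]]) / 2,
                 label = label, part = part, category = category),
            class = "hex_locus")
}

#' @export
print.hex_locus <- function(x, ...) {
  cat(sprintf("<hex_locus%s: x = %.4f, y = %.4f>\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$x, x$y))
  invisible(x)
}

#' Colour contrast of a locus
#'
#' Euclidean distance of the hexagon locus from the origin (the adapted
#' background): the chromatic signal strength of the stimulus.
#'
#' @param locus A `hex_locus`.
#' @return Non-negative scalar in hexagon units.
#' @export
color_contrast <- function(locus) {
  stopifnot(inherits(locus, "hex_locus"))
  sqrt(locus$x^2 + locus$y^2)
}

#' Green (achromatic) contrast
#'
#' The long-wavelength receptor's deviation from its adapted level,
#' |E_G - 0.5|; hymenopterans use this channel to detect small targets.
#'
#' @param x A `hex_locus` or a named excitation vector containing `G`.
#' @return Non-negative scalar.
#' @export
green_contrast <- function(x) {
  eg <- if (inherits(x, "hex_locus")) x$E_G else x[["G"]]
  abs(eg - 0.5)
}

#' Spectra to hexagon loci
#'
#' Convenience wrapper running each reflectance spectrum through
#' [quantum_catch()], [excitation()] and [hexagon_locus()].
#'
#' @param spectra List of reflectance spectra (as from [read_spectra()]).
#' @param receptors A [receptor_set()].
#' @param illuminant,background Passed to [quantum_catch()].
#' @param parts Optional character vector of flower parts per sample; by
#'   default parsed from labels of the form `<flower>_<part>`.
#' @return A data frame with one row per sample: label, part, E values,
#'   hexagon coordinates and both contrasts.
#' @export
hexagon_loci <- function(spectra, receptors = receptor_set(),
                         illuminant = illuminant_d65(),
                         background = flat_background(),
                         parts = NULL) {
  if (is.null(parts)) {
    parts <- vapply(spectra, function(s) {
      m <- regmatches(s$label, regexpr("(sepal|labellum)$", s$label))
      if (length(m)) m else "other"
    }, character(1))
  }
  rows <- lapply(seq_along(spectra), function(i) {
    P <- quantum_catch(spectra[[i]], receptors, illuminant, background)
    loc <- hexagon_locus(excitation(P), label = spectra[[i]]$label,
                         part = parts[i])
    data.frame(label = loc$label, part = loc$part,
               E_UV = loc$E_UV, E_B = loc$E_B, E_G = loc$E_G,
               x = loc$x, y = loc$y,
               color_contrast = color_contrast(loc),
               green_contrast = green_contrast(loc))
  })
  do.call(rbind, rows)
}

#' Pairwise colour distances between loci
#'
#' Euclidean distances between hexagon loci; the perceptual predictor fed to
#' the discrimination function.
#'
#' @param loci Either a list of `hex_locus` objects or a data frame with
#'   columns `label`, `x`, `y` (as from [hexagon_loci()]).
#' @return Labelled symmetric matrix with zero diagonal.
#' @export
pairwise_distances <- function(loci) {
  if (is.data.frame(loci)) {
    labs <- loci$label; x <- loci$x; y <- loci$y
  } else {
    labs <- vapply(loci, `[[`, character(1), "label")
    x <- vapply(loci, `[[`, numeric(1), "x")
    y <- vapply(loci, `[[`, numeric(1), "y")
  }
  if (length(labs) < 2L) stop("need at least two loci")
  if (anyDuplicated(labs))
    stop("duplicate locus labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  d <- as.matrix(stats::dist(cbind(x, y)))
  dimnames(d) <- list(labs, labs)
  d
}
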