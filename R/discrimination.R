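#' Fit the colour-discrimination psychometric function
#'
#' Calibrates the distance-to-probability curve used to decide whether a
#' hymenopteran observer can tell two colours apart. The model is a
#' three-parameter logistic with the lower asymptote pinned at chance level
#' (0.5, absolute conditioning):
#' \deqn{P(d) = 0.5 + (A - 0.5) / (1 + \exp(-(d - d_0)/s))}
#' with upper asymptote `A`, midpoint `d0` and slope scale `s` (hexagon
#' units). Fitting is least squares over multiple jittered restarts of a
#' Nelder-Mead search in an unconstrained reparameterization, keeping the
#' best root-mean-square error.
#'
#' @param distance Non-negative hexagon distances (>= 4 values, not all
#'   equal).
#' @param probability Observed discrimination probabilities in `[0.5, 1]`.
#' @param n_starts Number of jittered restarts.
#' @param seed Seed for the restart jitter.
#' @return Object of class `psychometric`: `A`, `d0`, `s`, `rmse`,
#'   `degenerate` (TRUE when the fitted asymptote collapses to chance).
#' @export
fit_psychometric <- function(distance, probability, n_starts = 5, seed = 1) {
  if (length(distance) != length(probability))
    stop("distance and probability differ in length")
  if (length(distance) < 4L) stop("need at least 4 calibration pairs")
  if (any(distance < 0)) stop("negative distances")
  if (any(probability < 0.5 - 1e-9 | probability > 1 + 1e-9))
    stop("probabilities must be in [0.5, 1]")
  if (diff(range(distance)) == 0) stop("all calibration distances are equal")

  # unconstrained parameterization: A in (0.5, 1], d0 > 0, s > 0
  predict_par <- function(par, d) {
    A <- 0.5 + 0.5 * stats::plogis(par[1])
    0.5 + (A - 0.5) / (1 + exp(-(d - exp(par[2])) / exp(par[3])))
  }
  obj <- function(par) sqrt(mean((predict_par(par, distance) - probability)^2))

  start0 <- c(stats::qlogis(min(max(2 * (max(probability) - 0.5), 1e-3),
                                1 - 1e-9)),
              log(max(stats::median(distance), 1e-6)),
              log(diff(range(distance)) / 10))
  best <- NULL
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(max(1L, n_starts))) {
    st <- start0 + if (i == 1L) 0 else stats::rnorm(3, 0, 0.4)
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  A <- 0.5 + 0.5 * stats::plogis(best$par[1])
  structure(list(A = A, d0 = exp(best$par[2]), s = exp(best$par[3]),
                 rmse = best$value, n = length(distance),
                 degenerate = (A - 0.5) < 1e-3),
            class = "psychometric")
}

#' @export
print.psychometric <- function(x, ...) {
  cat(sprintf(
    "<psychometric: A = %.4f, d0 = %.4f, s = %.4f, RMSE = %.4f (n = %d)%s>\n",
    x$A, x$d0, x$s, x$rmse, x$n,
    if (x$degenerate) ", DEGENERATE (asymptote at chance)" else ""))
  invisible(x)
}

#' Predicted discrimination probability
#'
#' @param model A fitted [fit_psychometric()] model.
#' @param d Non-negative hexagon distance(s).
#' @return Probabilities in `[0.5, A]`, non-decreasing in `d`.
#' @export
discrim_prob <- function(model, d) {
  stopifnot(inherits(model, "psychometric"))
  if (any(d < 0)) stop("negative distance")
  0.5 + (model$A - 0.5) / (1 + exp(-(d - model$d0) / model$s))
}

#' Above-threshold classification
#'
#' A colour pair counts as discriminable only when the predicted probability
#' strictly exceeds the threshold (the conventional criterion is 70%).
#'
#' @param probability Probabilities in `[0, 1]`.
#' @param theta Threshold, default 0.70.
#' @return Logical vector.
#' @export
above_threshold <- function(probability, theta = 0.70) {
  if (any(probability < 0 | probability > 1)) stop("probability outside [0, 1]")
  probability > theta
}

#' Summarize discriminability by comparison class
#'
#' Classifies every pair of samples into one of four comparison classes --
#' sepal vs sepal on different flowers, labellum vs labellum on different
#' flowers, sepal vs labellum within a flower, and sepal vs labellum across
#' flowers -- and reports how many pairs exceed the discrimination
#' threshold in each.
#'
#' @param distance_matrix Labelled symmetric distance matrix (hexagon units).
#' @param part Character vector (per row of the matrix): `"sepal"` or
#'   `"labellum"`.
#' @param flower Character vector of flower/plant identifiers per row.
#' @param model A fitted [fit_psychometric()] model.
#' @param theta Discrimination threshold.
#' @return Data frame with columns `comparison`, `n_pairs`, `n_above`,
#'   `fraction_above` (whole-percent).
#' @export
summarize_comparisons <- function(distance_matrix, part, flower, model,
                                  theta = 0.70) {
  n <- nrow(distance_matrix)
  if (length(part) != n || length(flower) != n)
    stop("part and flower labels must match the distance matrix rows")
  if (anyNA(part) || anyNA(flower)) stop("missing part or flower labels")
  if (!all(part %in% c("sepal", "labellum")))
    stop("part labels must be 'sepal' or 'labellum'")
  classes <- c("sepal-sepal", "labellum-labellum", "within-flower",
               "cross-flower")
  counts <- stats::setNames(rep(0L, 4L), classes)
  above <- counts
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      cls <- if (part[i] == "sepal" && part[j] == "sepal") "sepal-sepal"
      else if (part[i] == "labellum" && part[j] == "labellum")
        "labellum-labellum"
      else if (flower[i] == flower[j]) "within-flower"
      else "cross-flower"
      counts[cls] <- counts[cls] + 1L
      if (above_threshold(discrim_prob(model, distance_matrix[i, j]), theta))
        above[cls] <- above[cls] + 1L
    }
  }
  data.frame(comparison = classes,
             n_pairs = as.integer(counts),
             n_above = as.integer(above),
             fraction_above = ifelse(counts > 0,
                                     round(100 * above / counts), NA),
             row.names = NULL)
}
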