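read_fixture <- function(name) {
  utils::read.csv(system.file("extdata", name, package = "polmorph",
                              mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}

#' Bundled flowering census counts
#'
#' Multi-year counts of flowering tagged plants in the study population,
#' cross-classified by colour category (levels 1-5) and, separately, by
#' patch (levels 1-5). Long format: `stratum`, `level`, `year`, `flowers`.
#'
#' @return Data frame.
#' @export
flowering_counts <- function() read_fixture("flowering_counts.csv")

#' Bundled natural-pollination outcome counts
#'
#' Flowers monitored and fruits set per colour category and per patch in the
#' two fruiting census years. Long format: `stratum`, `level`, `year`,
#' `flowers`, `fruits`.
#'
#' @return Data frame.
#' @export
fruiting_counts <- function() read_fixture("fruiting_counts.csv")

#' Bundled artificial-cross outcomes
#'
#' Capsule formation percentages and evaluable cross counts per unordered
#' category combination, with seed-viability summaries where assayed.
#'
#' @return Data frame.
#' @export
capsule_crosses <- function() read_fixture("capsule_crosses.csv")

#' Bundled hexagon contrast values
#'
#' Green and colour contrast of the measured sepals and labella, with flower
#' id, part, and colour category. Consumed as recorded values; the raw
#' spectra behind them are not distributed.
#'
#' @return Data frame.
#' @export
hexagon_contrasts <- function() read_fixture("hexagon_contrasts.csv")

#' Bundled psychometric calibration pairs
#'
#' The 21 pairwise hexagon distances between measured flower parts with the
#' observed probability of discrimination by a hymenopteran trichromat under
#' absolute conditioning. These calibrate [fit_psychometric()].
#'
#' @return Data frame with sample/flower/part labels, `distance` and
#'   `probability`.
#' @export
discrimination_pairs <- function() read_fixture("discrimination_pairs.csv")

#' Distance matrix from the bundled calibration pairs
#'
#' Reassembles the 7 x 7 symmetric hexagon distance matrix (zero diagonal)
#' from [discrimination_pairs()], together with the part and flower label of
#' each sample.
#'
#' @return List with `distance` (matrix), `part`, `flower`, `sample`.
#' @export
discrimination_matrix <- function() {
  pr <- discrimination_pairs()
  samples <- unique(c(pr$sample_a, pr$sample_b))
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (k in seq_len(nrow(pr))) {
    i <- pr$sample_a[k]; j <- pr$sample_b[k]
    d[i, j] <- d[j, i] <- pr$distance[k]
  }
  info <- unique(rbind(
    data.frame(sample = pr$sample_a, flower = pr$flower_a, part = pr$part_a),
    data.frame(sample = pr$sample_b, flower = pr$flower_b, part = pr$part_b)))
  info <- info[match(samples, info$sample), ]
  list(distance = d, part = info$part, flower = info$flower, sample = samples)
}
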