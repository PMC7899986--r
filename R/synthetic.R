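# Seeded generators for every input the analysis modules consume. Each
# generator draws all randomness from its own seed and restores the caller's
# RNG state, so identical seeds give bit-identical output.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a flower-like reflectance spectrum
#'
#' Builds a reflectance curve on the standard grid from a small set of shape
#' components that emulate the measured flowers: a baseline, a sigmoid
#' long-pass edge (the step-up near 400 nm typical of yellow-green tepals),
#' a Gaussian red bump (crimson labellum pigment), an optional UV bump, and
#' Gaussian measurement noise. The result is clipped to `[0, 1.2]`
#' (slight exceedance of the white standard is physical; negatives are not).
#'
#' @param baseline Baseline reflectance fraction.
#' @param edge_pos,edge_steepness,edge_amp Long-pass edge position (nm),
#'   steepness (nm) and amplitude.
#' @param red_center,red_width,red_amp Red bump center (nm), width (nm) and
#'   amplitude.
#' @param uv_center,uv_amp UV bump center (nm) and amplitude (width fixed at
#'   25 nm).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Seed for the noise.
#' @param label Sample label.
#' @return A reflectance `spectrum` on the standard grid.
#' @export
gen_spectrum <- function(baseline = 0.05, edge_pos = 400, edge_steepness = 15,
                         edge_amp = 0.45, red_center = 640, red_width = 40,
                         red_amp = 0, uv_center = 350, uv_amp = 0,
                         noise_sd = 0, seed = 1, label = NULL) {
  stopifnot(edge_pos >= 300, edge_pos <= 650,
            red_center >= 300, red_center <= 650,
            uv_center >= 300, uv_center <= 650)
  wl <- standard_grid()
  v <- baseline +
    edge_amp / (1 + exp(-(wl - edge_pos) / edge_steepness)) +
    red_amp * exp(-((wl - red_center) / red_width)^2) +
    uv_amp * exp(-((wl - uv_center) / 25)^2)
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(wl), 0, noise_sd))
  v <- pmin(pmax(v, 0), 1.2)
  spectrum(wl, v, kind = "reflectance", label = label)
}

#' Generate tagged-plant records
#'
#' Simulates a multi-year census of a colour-polymorphic population:
#' each plant-year draws a colour category and a patch independently from
#' the supplied probability vectors and fruits with a patch-specific
#' probability. Defaults are the observed study-population conditions:
#' two census years of 70 and 64 plants, category mix 21/26/30/15/8%,
#' patch mix and per-patch fruit set from the fruiting census (patch drives
#' success; category does not), which together give an expected overall
#' fruit set of 15.7%.
#'
#' @param years Census years.
#' @param n_per_year Plants tagged per year.
#' @param category_probs Probability of each colour category (sums to 1).
#' @param patch_probs Probability of each patch (sums to 1).
#' @param fruit_prob_patch Fruiting probability per patch.
#' @param seed Seed.
#' @return Data frame of plant records (`plant_id`, `year`, `category`,
#'   `patch`, `treatment`, `fruited`).
#' @export
gen_plant_records <- function(years = c(2003, 2004),
                              n_per_year = c(70, 64),
                              category_probs = c(0.21, 0.26, 0.30, 0.15, 0.08),
                              patch_probs = c(0.261, 0.179, 0.075, 0.119,
                                              0.366),
                              fruit_prob_patch = c(0.314, 0.250, 0.100,
                                                   0.063, 0.041),
                              seed = 1) {
  stopifnot(length(years) == length(n_per_year),
            abs(sum(category_probs) - 1) < 1e-9,
            abs(sum(patch_probs) - 1) < 1e-9,
            all(category_probs >= 0), all(patch_probs >= 0),
            all(fruit_prob_patch >= 0 & fruit_prob_patch <= 1))
  with_seed(seed, {
    n <- sum(n_per_year)
    category <- sample.int(length(category_probs), n, replace = TRUE,
                           prob = category_probs)
    patch <- sample.int(length(patch_probs), n, replace = TRUE,
                        prob = patch_probs)
    data.frame(plant_id = sprintf("S%04d", seq_len(n)),
               year = rep(years, n_per_year),
               category = category, patch = patch,
               treatment = "natural",
               fruited = stats::rbinom(n, 1, fruit_prob_patch[patch]))
  })
}

#' Generate a dominant-marker matrix with controlled differentiation
#'
#' Per locus, a shared mean band frequency is drawn uniformly on
#' `[0.2, 0.8]` and population-specific band frequencies around it from a
#' beta distribution with variance F p(1-p) (the Balding-Nichols model with
#' F = `differentiation`); individual bands are then Bernoulli draws. For a
#' 0/1 band indicator the among-population variance is F p(1-p) and the
#' expected within-population variance (1-F) p(1-p), so the expected AMOVA
#' phi-PT equals the requested differentiation level directly, with no
#' further calibration.
#'
#' @param n_pops Number of populations.
#' @param n_per_pop Individuals per population.
#' @param n_loci Number of binary loci.
#' @param differentiation Target phi-PT in `[0, 1)`.
#' @param seed Seed.
#' @return A [marker_matrix()].
#' @export
gen_marker_matrix <- function(n_pops = 5, n_per_pop = 6, n_loci = 60,
                              differentiation = 0.085, seed = 1) {
  stopifnot(differentiation >= 0, differentiation < 1,
            n_pops >= 2, n_per_pop >= 2, n_loci >= 1)
  with_seed(seed, {
    N <- n_pops * n_per_pop
    pop <- rep(seq_len(n_pops), each = n_per_pop)
    X <- matrix(0L, N, n_loci)
    for (l in seq_len(n_loci)) {
      pbar <- stats::runif(1, 0.2, 0.8)
      pk <- if (differentiation > 0) {
        stats::rbeta(n_pops,
                     pbar * (1 - differentiation) / differentiation,
                     (1 - pbar) * (1 - differentiation) / differentiation)
      } else rep(pbar, n_pops)
      X[, l] <- stats::rbinom(N, 1, pk[pop])
    }
    rownames(X) <- sprintf("ind_%03d", seq_len(N))
    marker_matrix(X, paste0("pop", pop))
  })
}

jc_mutate <- function(seq, branch_length) {
  # substitution probability over an expected branch_length subs/site
  p_change <- 0.75 * (1 - exp(-4 * branch_length / 3))
  hit <- stats::runif(length(seq)) < p_change
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    seq[hit] <- vapply(seq[hit],
                       function(b) sample(setdiff(bases, b), 1L),
                       character(1))
  }
  seq
}

#' Generate a Jukes-Cantor star-topology alignment
#'
#' Evolves an ancestral random sequence under the Jukes-Cantor model along a
#' star topology: a group-ancestor branch of length
#' `(d_between - d_within)/2` per group, then a tip branch of `d_within/2`
#' per sequence, so the expected pairwise distance is `d_within` within a
#' group and `d_between` between groups.
#'
#' @param n_groups Number of groups.
#' @param n_per_group Sequences per group.
#' @param length Alignment length (sites).
#' @param d_within Target expected within-group distance
#'   (substitutions/site).
#' @param d_between Target expected between-group distance; must be
#'   `>= d_within` and below saturation.
#' @param seed Seed.
#' @return An [alignment()] with groups `grp1..grpK`.
#' @export
gen_alignment <- function(n_groups = 5, n_per_group = 7, length = 500,
                          d_within = 0.001, d_between = 0.002, seed = 1) {
  stopifnot(d_within >= 0, d_between >= d_within, d_between < 0.75,
            n_groups >= 1, n_per_group >= 1, length >= 1)
  with_seed(seed, {
    root <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    t_group <- (d_between - d_within) / 2
    t_tip <- d_within / 2
    seqs <- vector("list", n_groups * n_per_group)
    group <- character(n_groups * n_per_group)
    id <- character(n_groups * n_per_group)
    k <- 0L
    for (g in seq_len(n_groups)) {
      anc <- jc_mutate(root, t_group)
      for (i in seq_len(n_per_group)) {
        k <- k + 1L
        seqs[[k]] <- jc_mutate(anc, t_tip)
        group[k] <- paste0("grp", g)
        id[k] <- sprintf("grp%d_seq%d", g, i)
      }
    }
    alignment(do.call(rbind, seqs), id = id, group = group)
  })
}
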