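#' Construct a dominant binary marker matrix
#'
#' Band-presence matrix for dominant markers (e.g. ISSR fingerprints): rows
#' are individuals, columns are loci, entries are 0/1, with a population
#' label per individual.
#'
#' @param x Matrix (or data frame) of 0/1 band presences.
#' @param population Character or factor vector, one label per row.
#' @return Object of class `marker_matrix`.
#' @export
marker_matrix <- function(x, population) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("entries must be 0/1")
  if (nrow(x) < 2L) stop("need at least 2 individuals")
  if (length(population) != nrow(x))
    stop("one population label per individual required")
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) colnames(x) <- paste0("locus_", seq_len(ncol(x)))
  structure(list(bands = x, population = as.character(population)),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix: %d individuals x %d loci, %d population(s)>\n",
              nrow(x$bands), ncol(x$bands), length(unique(x$population))))
  invisible(x)
}

#' Read a marker matrix from delimited text
#'
#' Expected columns: `individual`, `population`, then one 0/1 column per
#' locus.
#'
#' @param path File path (comma or tab separated, autodetected).
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need individual, population and >= 1 locus column")
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df[[1L]]
  marker_matrix(x, df[[2L]])
}

#' Write a marker matrix to delimited text
#'
#' @param m A [marker_matrix()].
#' @param path Output path.
#' @export
write_marker_matrix <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  ind <- rownames(m$bands)
  if (is.null(ind)) ind <- sprintf("ind_%03d", seq_len(nrow(m$bands)))
  df <- cbind(data.frame(individual = ind, population = m$population),
              as.data.frame(m$bands))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Allele frequencies for dominant markers
#'
#' A dominant marker shows a band for both the heterozygote and the dominant
#' homozygote, so allele frequencies must be inferred: under Hardy-Weinberg
#' the null-allele frequency is q = sqrt(1 - band frequency) and
#' p = 1 - q.
#'
#' @param m A [marker_matrix()].
#' @return Data frame per locus: `band_freq`, `p`, `q`, `monomorphic`.
#' @export
dominant_allele_freqs <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  bf <- unname(colMeans(m$bands))
  q <- sqrt(1 - bf)
  data.frame(locus = colnames(m$bands), band_freq = bf,
             p = 1 - q, q = q,
             monomorphic = bf %in% c(0, 1), row.names = NULL)
}

#' Dominant-marker diversity statistics
#'
#' Per locus, from the inferred allele frequencies (p, q): expected
#' heterozygosity He = 2pq, effective number of alleles Ne = 1/(p^2 + q^2),
#' Shannon information index I = -(p ln p + q ln q), and unbiased
#' heterozygosity uHe = He * 2N / (2N - 1). Means and standard errors are
#' taken over loci.
#'
#' @param m A [marker_matrix()].
#' @return List: `per_locus` data frame and `summary` (mean and SE of each
#'   statistic over loci).
#' @export
diversity_stats <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (ncol(m$bands) < 1L) stop("empty marker matrix")
  fr <- dominant_allele_freqs(m)
  N <- nrow(m$bands)
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  per <- data.frame(locus = fr$locus,
                    He = 2 * fr$p * fr$q,
                    Ne = 1 / (fr$p^2 + fr$q^2),
                    I = -(xlogx(fr$p) + xlogx(fr$q)))
  per$uHe <- per$He * 2 * N / (2 * N - 1)
  sm <- vapply(c("Ne", "I", "He", "uHe"), function(st) {
    c(mean = mean(per[[st]]),
      se = stats::sd(per[[st]]) / sqrt(nrow(per)))
  }, numeric(2))
  list(per_locus = per, summary = t(sm))
}

# Within-group and total sums of squares of band vectors; the squared
# Euclidean distance form and the group-centroid form are identical, which
# the tests exploit as an independent oracle.
amova_ss <- function(X, pop) {
  pops <- unique(pop)
  sst <- sum(scale(X, scale = FALSE)^2)
  ssw <- sum(vapply(pops, function(g) {
    sum(scale(X[pop == g, , drop = FALSE], scale = FALSE)^2)
  }, numeric(1)))
  c(total = sst, within = ssw, among = sst - ssw)
}

#' AMOVA phi-PT for dominant binary markers
#'
#' Two-level analysis of molecular variance on squared-Euclidean
#' (band-difference count) distances: partitions marker variance within and
#' among populations, estimates the variance components by the standard
#' moment equations with the mean-population-size correction
#' n0 = (N - sum(n_g^2)/N)/(k - 1), and reports
#' phi_PT = sigma2_among / (sigma2_among + sigma2_within), the dominant-data
#' analogue of Fst. Significance is by permutation of population labels,
#' with the add-one correction p = (#{phi_perm >= phi_obs} + 1)/(n + 1).
#'
#' @param m A [marker_matrix()] with >= 2 populations of >= 2 individuals.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Permutation seed.
#' @return List: `phi_pt`, `p_value`, `ss` (total/within/among), `df`,
#'   `sigma2_among`, `sigma2_within`, `pct_among`, `pct_within`,
#'   `n_permutations`, `seed`.
#' @export
amova_phipt <- function(m, n_permutations = 999, seed = 1) {
  stopifnot(inherits(m, "marker_matrix"))
  pop <- m$population
  sizes <- table(pop)
  if (length(sizes) < 2L) stop("need at least 2 populations")
  if (any(sizes < 2L)) stop("every population needs at least 2 individuals")
  X <- m$bands
  N <- nrow(X); k <- length(sizes)
  phi_of <- function(labels) {
    ss <- amova_ss(X, labels)
    msw <- ss[["within"]] / (N - k)
    msa <- ss[["among"]] / (k - 1)
    n0 <- (N - sum(sizes^2) / N) / (k - 1)
    va <- (msa - msw) / n0
    c(phi = va / (va + msw), va = va, vw = msw)
  }
  obs <- phi_of(pop)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(i) phi_of(sample(pop))[["phi"]], numeric(1))
  va <- max(obs[["va"]], 0)  # percentages from non-negative components
  vw <- obs[["vw"]]
  ss <- amova_ss(X, pop)
  list(phi_pt = obs[["phi"]],
       p_value = (sum(perm >= obs[["phi"]]) + 1) / (n_permutations + 1),
       ss = ss,
       df = c(among = k - 1L, within = N - k),
       sigma2_among = obs[["va"]], sigma2_within = vw,
       pct_among = 100 * va / (va + vw),
       pct_within = 100 * vw / (va + vw),
       n_permutations = n_permutations, seed = seed)
}

#' Read an aligned FASTA with group labels
#'
#' Sequence names of the form `id|group` carry the group (e.g. colour
#' category) of each sequence; a name without `|` gets group `"ungrouped"`.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return Object of class `alignment`: character matrix `seqs`
#'   (individuals x sites, uppercase A/C/G/T/-/N) plus `id` and `group`.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 2L) stop("need at least 2 sequences")
  chars <- lapply(as.character(dna), function(s) toupper(s))
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  seqs <- do.call(rbind, chars)
  nm <- names(dna)
  id <- sub("\\|.*$", "", nm)
  group <- ifelse(grepl("\\|", nm), sub("^[^|]*\\|", "", nm), "ungrouped")
  alignment(seqs, id = id, group = group)
}

#' Construct an alignment object
#'
#' @param seqs Character matrix of aligned bases (rows = sequences), in
#'   `A/C/G/T/-/N` (case-insensitive).
#' @param id Sequence identifiers.
#' @param group Group label per sequence.
#' @return Object of class `alignment`.
#' @export
alignment <- function(seqs, id = rownames(seqs),
                      group = rep("ungrouped", nrow(seqs))) {
  seqs <- toupper(as.matrix(seqs))
  if (nrow(seqs) < 2L) stop("need at least 2 sequences")
  if (!all(seqs %in% c("A", "C", "G", "T", "-", "N")))
    stop("alignment contains characters outside A/C/G/T/-/N")
  if (is.null(id)) id <- paste0("seq_", seq_len(nrow(seqs)))
  if (length(group) != nrow(seqs)) stop("one group label per sequence")
  rownames(seqs) <- id
  structure(list(seqs = seqs, id = id, group = as.character(group)),
            class = "alignment")
}

#' Write an alignment to FASTA
#'
#' Names are emitted as `id|group`, the format [read_alignment()] expects.
#'
#' @param aln An [alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$seqs))) {
    writeLines(paste0(">", aln$id[i], "|", aln$group[i]), con)
    writeLines(paste(aln$seqs[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Jukes-Cantor pairwise distances
#'
#' For each pair, the proportion of differing sites p is taken over sites
#' where both sequences have an unambiguous base (pairwise deletion;
#' `deletion = "complete"` first drops every site with any gap or N), then
#' corrected for multiple substitutions: d = -(3/4) ln(1 - (4/3) p).
#' Saturated pairs (p >= 3/4) and pairs with no comparable sites are
#' returned as `NA`.
#'
#' @param aln An [alignment()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return List of class `jc_dist`: `d` (symmetric matrix, `NA` where
#'   undefined), `p_raw` (observed proportions), `n_sites` (sites compared),
#'   `undefined` (character matrix of reasons, `""` where defined).
#' @export
jc_distance <- function(aln, deletion = c("pairwise", "complete")) {
  stopifnot(inherits(aln, "alignment"))
  deletion <- match.arg(deletion)
  seqs <- aln$seqs
  valid <- seqs %in% c("A", "C", "G", "T")
  dim(valid) <- dim(seqs)
  if (deletion == "complete") {
    keep <- colSums(!valid) == 0
    seqs <- seqs[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(seqs)
  d <- p_raw <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  n_sites <- matrix(ncol(seqs), n, n, dimnames = list(aln$id, aln$id))
  reason <- matrix("", n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ok <- valid[i, ] & valid[j, ]
      ns <- sum(ok)
      n_sites[i, j] <- n_sites[j, i] <- ns
      if (ns == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        p_raw[i, j] <- p_raw[j, i] <- NA_real_
        reason[i, j] <- reason[j, i] <- "no comparable sites"
        next
      }
      p <- sum(seqs[i, ok] != seqs[j, ok]) / ns
      p_raw[i, j] <- p_raw[j, i] <- p
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- NA_real_
        reason[i, j] <- reason[j, i] <- "saturated (p >= 3/4)"
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  structure(list(d = d, p_raw = p_raw, n_sites = n_sites, undefined = reason),
            class = "jc_dist")
}

group_diversity_components <- function(dmat, groups) {
  ut <- upper.tri(dmat)
  total <- mean(dmat[ut], na.rm = TRUE)
  gl <- unique(groups)
  within <- vapply(gl, function(g) {
    sub <- dmat[groups == g, groups == g, drop = FALSE]
    v <- sub[upper.tri(sub)]
    if (!length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  among <- if (length(gl) > 1) {
    pairs <- utils::combn(gl, 2)
    mean(apply(pairs, 2, function(pr) {
      mean(dmat[groups == pr[1], groups == pr[2]], na.rm = TRUE)
    }), na.rm = TRUE)
  } else NA_real_
  d_s <- mean(within, na.rm = TRUE)
  list(within = stats::setNames(within, gl), among = among,
       total = total, d_s = d_s,
       coefficient = if (isTRUE(total > 0)) (total - d_s) / total
       else NA_real_)
}

#' Sequence diversity within and among groups
#'
#' From Jukes-Cantor distances: mean diversity within each group, mean
#' diversity among groups (average over group pairs of the mean cross-group
#' distance), total mean diversity over all pairs, and the coefficient of
#' differentiation (d_T - d_S)/d_T where d_S is the unweighted average
#' within-group diversity. The coefficient's standard error comes from a
#' seeded bootstrap over alignment sites.
#'
#' @param aln An [alignment()] with group labels.
#' @param deletion Passed to [jc_distance()].
#' @param n_boot Bootstrap replicates over sites (default 500).
#' @param seed Bootstrap seed.
#' @return List: `within` (per group), `among`, `total`, `d_s`,
#'   `coefficient`, `coefficient_se` (`NA` when the total diversity is 0 and
#'   the coefficient undefined).
#' @export
group_diversities <- function(aln, deletion = "pairwise", n_boot = 500,
                              seed = 1) {
  stopifnot(inherits(aln, "alignment"))
  if (length(unique(aln$group)) < 2L) stop("need at least 2 groups")
  base <- group_diversity_components(jc_distance(aln, deletion)$d, aln$group)
  se <- NA_real_
  if (!is.na(base$coefficient)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    L <- ncol(aln$seqs)
    reps <- vapply(seq_len(n_boot), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      a2 <- alignment(aln$seqs[, cols, drop = FALSE], id = aln$id,
                      group = aln$group)
      group_diversity_components(jc_distance(a2, deletion)$d,
                                 a2$group)$coefficient
    }, numeric(1))
    se <- stats::sd(reps, na.rm = TRUE)
  }
  c(base, list(coefficient_se = se))
}
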