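# Independent first-principles oracles used to cross-check the package's
# statistics, implemented deliberately without stats:: helpers.

oracle_chisq <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

oracle_midranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

oracle_spearman <- function(x, y)
  oracle_pearson(oracle_midranks(x), oracle_midranks(y))

oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- Tx <- Ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
      if (a == 0 && b == 0) next
      if (a == 0) Tx <- Tx + 1
      else if (b == 0) Ty <- Ty + 1
      else if (a == b) C <- C + 1
      else D <- D + 1
    }
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

# Goodman-Kruskal tau via expected misclassification counts (a different
# algebraic route from the implementation's probability form).
oracle_gk_tau <- function(x, y) {
  tab <- table(x, y)
  N <- sum(tab)
  e1 <- sum(colSums(tab) * (N - colSums(tab))) / N
  e2 <- sum(apply(tab, 1, function(row) {
    ni <- sum(row)
    if (ni == 0) 0 else sum(row * (ni - row)) / ni
  }))
  (e1 - e2) / e1
}

# AMOVA sums of squares from pairwise squared-Euclidean distances (the
# implementation works from group centroids; the identity of the two routes
# is what makes this an independent check).
oracle_amova_phipt <- function(bands, pop) {
  N <- nrow(bands)
  d2 <- as.matrix(dist(bands))^2
  ss_from <- function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }
  sst <- ss_from(seq_len(N))
  pops <- unique(pop)
  ssw <- sum(vapply(pops, function(g) ss_from(which(pop == g)), numeric(1)))
  k <- length(pops)
  sizes <- table(pop)[as.character(pops)]
  msw <- ssw / (N - k)
  msa <- (sst - ssw) / (k - 1)
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  va <- (msa - msw) / n0
  va / (va + msw)
}

# Expand a contingency table (codes x binary outcome) into individual pairs.
expand_table <- function(tab) {
  codes <- as.integer(rep(seq_len(nrow(tab)), rowSums(tab)))
  outcome <- integer(0)
  for (i in seq_len(nrow(tab)))
    outcome <- c(outcome, rep(c(0L, 1L), tab[i, ]))
  list(code = codes, outcome = outcome)
}

make_flat_spectrum <- function(level, label = NULL)
  spectrum(standard_grid(), rep(level, 36), kind = "reflectance",
           label = label)
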