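test_that("dominant allele frequencies follow the square-root estimator", {
  X <- rbind(matrix(1, 3, 2), matrix(0, 1, 2))  # band frequency 0.75
  m <- marker_matrix(X, rep("a", 4))
  fr <- dominant_allele_freqs(m)
  expect_equal(fr$q, c(0.5, 0.5))
  expect_equal(fr$p, c(0.5, 0.5))
  m0 <- marker_matrix(matrix(0, 4, 1), rep("a", 4))
  expect_equal(dominant_allele_freqs(m0)$p, 0)
  m1 <- marker_matrix(matrix(1, 4, 1), rep("a", 4))
  f1 <- dominant_allele_freqs(m1)
  expect_equal(f1$q, 0)
  expect_true(f1$monomorphic)
  set.seed(5)
  rand <- marker_matrix(matrix(rbinom(200, 1, 0.4), 20), rep("a", 20))
  fr2 <- dominant_allele_freqs(rand)
  expect_true(all(fr2$p >= 0 & fr2$p <= 1))
  expect_equal(fr2$p + fr2$q, rep(1, 10))
})

test_that("diversity statistics match their closed forms", {
  # band frequency 0.75 gives p = q = 0.5: maximal-diversity locus
  X <- rbind(matrix(1, 3, 3), matrix(0, 1, 3))
  st <- diversity_stats(marker_matrix(X, rep("a", 4)))
  expect_equal(st$per_locus$He, rep(0.5, 3))
  expect_equal(st$per_locus$Ne, rep(2, 3))
  expect_equal(st$per_locus$I, rep(log(2), 3))
  expect_equal(st$per_locus$uHe, rep(0.5 * 8 / 7, 3))
  mono <- diversity_stats(marker_matrix(matrix(1, 4, 1), rep("a", 4)))
  expect_equal(mono$per_locus$He, 0)
  expect_equal(mono$per_locus$Ne, 1)
  expect_equal(mono$per_locus$I, 0)
  # arbitrary known band frequencies against the formulas
  set.seed(8)
  m <- gen_marker_matrix(n_pops = 2, n_per_pop = 10, n_loci = 15,
                         differentiation = 0, seed = 3)
  st2 <- diversity_stats(m)
  q <- unname(sqrt(1 - colMeans(m$bands))); p <- 1 - q
  expect_equal(st2$per_locus$He, 2 * p * q, tolerance = 1e-12)
  expect_equal(st2$per_locus$Ne, 1 / (p^2 + q^2), tolerance = 1e-12)
})

test_that("diversity statistics are invariant to row permutation", {
  m <- gen_marker_matrix(seed = 12)
  set.seed(1)
  ord <- sample(nrow(m$bands))
  mp <- marker_matrix(m$bands[ord, ], m$population[ord])
  expect_equal(diversity_stats(mp)$summary, diversity_stats(m)$summary)
})

test_that("phi-PT matches the distance-based oracle and its boundary cases", {
  m <- gen_marker_matrix(n_pops = 3, n_per_pop = 5, n_loci = 25, seed = 21)
  res <- amova_phipt(m, n_permutations = 99, seed = 1)
  expect_equal(res$phi_pt, oracle_amova_phipt(m$bands, m$population),
               tolerance = 1e-9)
  expect_equal(res$pct_among + res$pct_within, 100, tolerance = 1e-9)
  expect_equal(res$phi_pt, res$pct_among / 100, tolerance = 1e-9)
  expect_gte(res$phi_pt, -1); expect_lte(res$phi_pt, 1)
  expect_gt(res$p_value, 0); expect_lte(res$p_value, 1)
  # disjoint fixed differences: all variance among populations
  fixed <- marker_matrix(rbind(matrix(rep(c(1, 0), 4), 3, 8, byrow = TRUE),
                               matrix(rep(c(0, 1), 4), 3, 8, byrow = TRUE)),
                         rep(c("a", "b"), each = 3))
  expect_equal(amova_phipt(fixed, n_permutations = 49)$phi_pt, 1)
  expect_error(amova_phipt(marker_matrix(diag(3), c("a", "a", "b"))),
               "at least 2 individuals")
})

test_that("phi-PT is centered on zero for undifferentiated populations", {
  est <- vapply(1:10, function(i) {
    m <- gen_marker_matrix(n_pops = 2, n_per_pop = 30, n_loci = 100,
                           differentiation = 0, seed = 100 + i)
    amova_phipt(m, n_permutations = 0, seed = 1)$phi_pt
  }, numeric(1))
  expect_lt(mean(abs(est)), 0.05)
})

test_that("permutation p-values are seed-reproducible", {
  m <- gen_marker_matrix(seed = 33)
  a <- amova_phipt(m, n_permutations = 199, seed = 7)
  b <- amova_phipt(m, n_permutations = 199, seed = 7)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$phi_pt, b$phi_pt)
})

test_that("marker matrix round-trips through delimited text", {
  f <- withr::local_tempfile(fileext = ".csv")
  m <- gen_marker_matrix(n_pops = 2, n_per_pop = 3, n_loci = 5, seed = 2)
  write_marker_matrix(m, f)
  back <- read_marker_matrix(f)
  expect_equal(unname(back$bands), unname(m$bands))
  expect_equal(back$population, m$population)
})

test_that("Jukes-Cantor distances correct observed differences", {
  a <- strsplit("ACGTACGTAC", "")[[1]]
  aln <- alignment(rbind(a, a), id = c("s1", "s2"))
  expect_equal(jc_distance(aln)$d["s1", "s2"], 0)
  # p = 0.1 over 100 sites
  s1 <- rep(c("A", "C", "G", "T"), 25)
  s2 <- s1; s2[1:10] <- c("C", "A", "T", "G", "C", "A", "T", "G", "C", "A")
  jc <- jc_distance(alignment(rbind(s1, s2), id = c("x", "y")))
  expect_equal(jc$p_raw["x", "y"], 0.1)
  expect_equal(round(jc$d["x", "y"], 4), 0.1073)
  # all-gap overlap pair is undefined with a reason
  g1 <- c("A", "C", "-", "-"); g2 <- c("-", "-", "G", "T")
  jg <- jc_distance(alignment(rbind(g1, g2), id = c("u", "v")))
  expect_true(is.na(jg$d["u", "v"]))
  expect_match(jg$undefined["u", "v"], "no comparable sites")
  # saturation
  s3 <- rep("A", 20); s4 <- rep("C", 20)
  js <- jc_distance(alignment(rbind(s3, s4), id = c("p", "q")))
  expect_true(is.na(js$d["p", "q"]))
  expect_match(js$undefined["p", "q"], "saturated")
})

test_that("Jukes-Cantor agrees with an established implementation", {
  aln <- gen_alignment(n_groups = 2, n_per_group = 4, length = 800,
                       d_within = 0.02, d_between = 0.08, seed = 14)
  ours <- jc_distance(aln)$d
  bin <- ape::as.DNAbin(tolower(aln$seqs))
  ref <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-9)
})

test_that("pairwise and complete deletion differ only via gapped sites", {
  s1 <- c("A", "C", "G", "T", "A", "C")
  s2 <- c("A", "-", "G", "T", "A", "G")
  s3 <- c("A", "C", "G", "T", "T", "G")
  aln <- alignment(rbind(s1, s2, s3), id = c("a", "b", "c"))
  pw <- jc_distance(aln, deletion = "pairwise")
  cp <- jc_distance(aln, deletion = "complete")
  expect_equal(pw$n_sites["a", "c"], 6)
  expect_equal(cp$n_sites["a", "c"], 5)
  expect_equal(pw$n_sites["a", "b"], 5)
})

test_that("group diversities and differentiation behave at the extremes", {
  same <- alignment(matrix("A", 4, 10),
                    id = paste0("s", 1:4), group = c("g1", "g1", "g2", "g2"))
  gd <- group_diversities(same, n_boot = 10)
  expect_equal(gd$total, 0)
  expect_true(is.na(gd$coefficient))
  # homogeneous groups, all diversity among them
  g1 <- matrix(rep(strsplit("ACGTACGTACGTACGTACGT", "")[[1]], 3), 3,
               byrow = TRUE)
  g2seq <- strsplit("ACGTACGTACGTACGTACGT", "")[[1]]
  g2seq[c(2, 7, 12)] <- c("G", "A", "C")
  g2 <- matrix(rep(g2seq, 3), 3, byrow = TRUE)
  aln2 <- alignment(rbind(g1, g2), id = paste0("t", 1:6),
                    group = rep(c("g1", "g2"), each = 3))
  gd2 <- group_diversities(aln2, n_boot = 20, seed = 2)
  expect_equal(gd2$d_s, 0)
  expect_equal(gd2$coefficient, 1)
})

test_that("simulated alignments recover the differentiation coefficient", {
  hits <- 0L
  for (i in 1:10) {
    aln <- gen_alignment(n_groups = 3, n_per_group = 4, length = 1500,
                         d_within = 0.01, d_between = 0.05, seed = 40 + i)
    gd <- group_diversities(aln, n_boot = 100, seed = 1)
    # expected coefficient from the star topology targets
    d_s <- 0.01
    d_t_expected <- gd$total
    expected <- (d_t_expected - d_s) / d_t_expected
    ci <- gd$coefficient + c(-2, 2) * gd$coefficient_se
    if (expected >= ci[1] && expected <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("alignment FASTA round-trip preserves sequences and groups", {
  f <- withr::local_tempfile(fileext = ".fasta")
  aln <- gen_alignment(n_groups = 2, n_per_group = 3, length = 60,
                       d_within = 0.05, d_between = 0.2, seed = 6)
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(unname(back$seqs), unname(aln$seqs))
  expect_equal(back$group, aln$group)
  expect_equal(back$id, aln$id)
})
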