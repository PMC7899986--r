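test_that("expanded count fixtures reproduce every printed margin", {
  rec <- records_from_counts(fruiting_counts(), "category")
  flowers <- tabulate_records(rec, "category", "year", "flowers")
  fruits <- tabulate_records(rec, "category", "year", "fruits")
  expect_equal(unname(rowSums(flowers)), c(30, 30, 50, 12, 12))
  expect_equal(unname(rowSums(fruits)), c(4, 6, 9, 1, 1))
  expect_equal(sum(flowers), 134)
  expect_equal(sum(fruits), 21)

  recp <- records_from_counts(fruiting_counts(), "patch")
  expect_equal(unname(rowSums(tabulate_records(recp, "patch", "year",
                                               "flowers"))),
               c(35, 24, 10, 16, 49))

  fl <- records_from_counts(flowering_counts(), "category")
  tab2 <- tabulate_records(fl, "category", "year", "flowers")
  expect_equal(unname(rowSums(tab2)), c(45, 56, 64, 31, 16))
  expect_equal(sum(tab2), 212)

  expect_error(tabulate_records(rec[0, ], "category"), "no records")
  bad <- rec; bad$category[1] <- 6L
  expect_error(tabulate_records(bad, "category"), "unknown category")
})

test_that("r x c chi-square matches the textbook formula on random tables", {
  set.seed(11)
  for (i in 1:200) {
    r <- sample(2:4, 1); k <- sample(2:4, 1)
    tab <- matrix(rpois(r * k, 6) + 1, r, k)
    res <- suppressWarnings(chisq_rxc(tab))
    expect_equal(res$chi2, oracle_chisq(tab), tolerance = 1e-9)
    expect_equal(res$df, (r - 1) * (k - 1))
  }
  prop <- outer(c(2, 4), c(3, 5, 2))  # proportional rows: independence
  expect_equal(suppressWarnings(chisq_rxc(prop))$chi2, 0, tolerance = 1e-12)
  expect_error(chisq_rxc(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(chisq_rxc(matrix(1:3, 1)), "2 x 2")
})

test_that("goodness of fit handles uniform and weighted expectations", {
  gof <- suppressWarnings(chisq_gof(c(11, 6, 1, 1, 2)))
  expect_equal(round(gof$chi2, 1), 17.8)
  expect_equal(gof$df, 4)
  expect_equal(suppressWarnings(chisq_gof(c(5, 5, 5))$chi2), 0)
  w <- suppressWarnings(chisq_gof(c(4, 6, 9), expected = c(30, 30, 50)))
  expect_equal(round(w$chi2, 2), 0.41)
  expect_error(chisq_gof(c(3, 4), expected = c(1, 0)), "expected")
  expect_error(chisq_gof(5), "2 cells")
})

test_that("the value-heterogeneity statistic reproduces its construction and warns", {
  expect_warning(res <- chisq_on_values(c(13.3, 20.0, 18.0, 8.3, 8.3)),
                 "not a standard")
  expect_equal(round(res$chi2, 1), 8.6)
  expect_equal(suppressWarnings(chisq_on_values(c(7, 7, 7))$chi2), 0)
  expect_equal(round(suppressWarnings(chisq_on_values(c(10, 20))$chi2), 2),
               3.33)
  expect_error(suppressWarnings(chisq_on_values(c(0, 0))), "zero mean")
})

test_that("regression wrapper returns slope, intercept and R-squared", {
  exact <- suppressWarnings(linreg(1:5, 2 * (1:5) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
  expect_error(linreg(rep(3, 5), 1:5), "constant")
  expect_error(linreg(1:2, 1:2), "3 points")
})

test_that("association measures match brute-force oracles on random data", {
  set.seed(23)
  for (i in 1:50) {
    code <- sample(1:4, 40, replace = TRUE)
    outcome <- rbinom(40, 1, 0.2 + 0.1 * code / 4)
    if (length(unique(code)) < 2 || length(unique(outcome)) < 2) next
    m <- association_measures(code, outcome)
    expect_equal(m$pearson_r, oracle_pearson(code, outcome),
                 tolerance = 1e-12)
    expect_equal(m$spearman_rho, oracle_spearman(code, outcome),
                 tolerance = 1e-12)
    expect_equal(m$kendall_tau_b, oracle_kendall_tau_b(code, outcome),
                 tolerance = 1e-12)
    expect_equal(m$goodman_kruskal_tau, oracle_gk_tau(code, outcome),
                 tolerance = 1e-12)
    tab <- table(code, outcome)
    expect_equal(m$cramers_v2,
                 oracle_chisq(tab) / (sum(tab) * (min(dim(tab)) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("association measures hit their boundary and degenerate cases", {
  perfect <- expand_table(matrix(c(4, 0, 0, 4), 2, byrow = TRUE))
  m <- association_measures(perfect$code, perfect$outcome)
  expect_equal(m$cramers_v2, 1)
  expect_equal(abs(m$kendall_tau_b), 1)
  indep <- expand_table(matrix(c(2, 4, 1, 2), 2, byrow = TRUE))
  mi <- association_measures(indep$code, indep$outcome)
  for (v in unlist(mi)) expect_lt(abs(v), 1e-12)
  degen <- association_measures(rep(1L, 10), rbinom(10, 1, 0.5))
  expect_true(all(is.na(unlist(degen))))
})

test_that("success rates report pooled and mean-of-years conventions", {
  rec <- records_from_counts(fruiting_counts(), "category")
  overall <- success_rates(rec, "overall")
  expect_equal(round(overall$pooled_pct, 1), 15.7)
  cat_rates <- success_rates(rec, "category")
  expect_equal(round(cat_rates$pooled_pct[1], 1), 13.3)

  recp <- records_from_counts(fruiting_counts(), "patch")
  patch_rates <- success_rates(recp, "patch")
  expect_equal(round(patch_rates$pct_2003[1], 1), 33.3)
  expect_equal(round(patch_rates$pct_2004[1], 1), 30.0)
  expect_equal(round(patch_rates$mean_pct[1], 1), 31.7)

  one_year <- rec[rec$year == 2003, ]
  r1 <- success_rates(one_year, "overall")
  expect_equal(r1$mean_pct, r1$pooled_pct)
  expect_true(is.na(r1$se_pct))
})

test_that("Kruskal-Wallis handles ties, rank oracle and identical data", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$H, 0)
  # a 30-point viability shift at n = 20/group is detectable
  set.seed(31)
  g1 <- pmin(pmax(rnorm(20, 40, 15), 0), 100)
  g2 <- pmin(pmax(rnorm(20, 70, 15), 0), 100)
  expect_lt(kruskal_wallis(list(g1, g2))$p, 0.05)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("capsule summaries exclude grazed and moldy crosses", {
  crosses <- data.frame(
    pollen_category = c(3, 3, 3, 3, 1, 1),
    ovule_category  = c(5, 5, 5, 5, 2, 2),
    capsule_fate    = c("capsule", "none", "none", "grazed",
                        "capsule", "moldy"))
  cs <- capsule_summary(crosses)
  cell35 <- cs$cells[cs$cells$category_a == 3 & cs$cells$category_b == 5, ]
  expect_equal(cell35$n_evaluable, 3)
  expect_equal(cell35$capsule_pct, 33)
  all_grazed <- capsule_summary(data.frame(
    pollen_category = 2, ovule_category = 4, capsule_fate = "grazed"))
  expect_true(is.na(all_grazed$cells$capsule_pct))
  # overall rate counts capsules over all crosses, evaluable or not
  many <- data.frame(pollen_category = rep(1, 91), ovule_category = 1,
                     capsule_fate = rep(c("capsule", "none", "grazed",
                                          "moldy", "lost"),
                                        c(70, 7, 8, 5, 1)))
  expect_equal(capsule_summary(many)$overall_pct, 77)
})

test_that("record validation reports all issues without stopping", {
  rec <- data.frame(plant_id = c("a", "b", "b"), year = c(2003, 2003, 2004),
                    category = c(6, 2, 3), patch = c(1, 9, 2),
                    treatment = "natural", fruited = c(1, 0, 2))
  iss <- validate_records(rec)
  expect_gte(nrow(iss), 4)
  expect_true(any(grepl("category", iss$issue)))
  expect_true(any(grepl("patch", iss$issue)))
  expect_true(any(grepl("reused", iss$issue)))
  expect_true(any(grepl("fruited", iss$issue)))
  clean <- records_from_counts(fruiting_counts(), "category")
  expect_equal(nrow(validate_records(clean)), 0)
})
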