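#' Read tagged-plant records
#'
#' Delimited text with header
#' `plant_id,year,category,patch,treatment,fruited,pollen_category,ovule_category,capsule_fate,viability_pct`.
#' Comma or tab separated (autodetected).
#'
#' @param path File path.
#' @return Data frame of records, validated with [validate_records()].
#' @export
read_plant_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  issues <- validate_records(rec)
  if (nrow(issues))
    stop("invalid records:\n", paste(issues$issue, collapse = "\n"))
  rec
}

#' Validate plant records
#'
#' Checks the schema contract without stopping at the first violation:
#' category and patch codes in 1-5, years numeric, fruited flag 0/1, each
#' plant used in one year only, and viability present only for crosses that
#' formed a capsule.
#'
#' @param records Data frame of plant records.
#' @return Data frame of issues (zero rows when clean).
#' @export
validate_records <- function(records) {
  issues <- character()
  chk <- function(cond, rows, what) {
    if (any(cond, na.rm = TRUE))
      issues <<- c(issues, sprintf("%s (rows: %s)", what,
                                   paste(rows[which(cond)], collapse = ", ")))
  }
  rows <- seq_len(nrow(records))
  if (!nrow(records)) return(data.frame(issue = character()))
  if ("category" %in% names(records))
    chk(!is.na(records$category) & !(records$category %in% 1:5), rows,
        "category code outside 1-5")
  if ("patch" %in% names(records))
    chk(!is.na(records$patch) & !(records$patch %in% 1:5), rows,
        "patch code outside 1-5")
  if ("fruited" %in% names(records))
    chk(!is.na(records$fruited) & !(records$fruited %in% 0:1), rows,
        "fruited flag not 0/1")
  if (all(c("plant_id", "year") %in% names(records))) {
    dup <- records$plant_id %in%
      unique(records$plant_id[duplicated(records[c("plant_id")])])
    multi <- stats::ave(records$year, records$plant_id,
                        FUN = function(y) length(unique(y))) > 1
    chk(dup & multi, rows, "plant_id reused across years")
  }
  if (all(c("viability_pct", "capsule_fate") %in% names(records)))
    chk(!is.na(records$viability_pct) &
          (is.na(records$capsule_fate) | records$capsule_fate != "capsule"),
        rows, "viability recorded without a capsule")
  data.frame(issue = issues)
}

#' Expand printed count tables into per-plant records
#'
#' Turns a long-format count table (as from [fruiting_counts()] or
#' [flowering_counts()]) into one row per flowering plant, with the fruited
#' flag set for the counted fruits. Only the requested stratum is carried;
#' the other classifier is unknown (`NA`) because the source tables report
#' the two margins separately.
#'
#' @param counts Data frame with columns `stratum`, `level`, `year`,
#'   `flowers` and optionally `fruits`.
#' @param stratum `"category"` or `"patch"`.
#' @return Data frame of plant records.
#' @export
records_from_counts <- function(counts, stratum = c("category", "patch")) {
  stratum <- match.arg(stratum)
  tab <- counts[counts$stratum == stratum, ]
  if (!nrow(tab)) stop("no rows for stratum '", stratum, "'")
  if (is.null(tab$fruits)) tab$fruits <- 0L
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    n <- tab$flowers[i]
    if (n == 0) return(NULL)
    k <- tab$fruits[i]
    data.frame(year = tab$year[i],
               level = tab$level[i],
               fruited = rep(c(1L, 0L), c(k, n - k)))
  })
  rec <- do.call(rbind, rows)
  rec$plant_id <- sprintf("P%04d", seq_len(nrow(rec)))
  rec$category <- if (stratum == "category") rec$level else NA_integer_
  rec$patch <- if (stratum == "patch") rec$level else NA_integer_
  rec$treatment <- "natural"
  rec[c("plant_id", "year", "category", "patch", "treatment", "fruited")]
}

#' Cross-tabulate plant records
#'
#' Counts flowering or fruiting plants by category or patch against year or
#' outcome, producing the contingency tables the chi-square tests consume.
#'
#' @param records Data frame of plant records.
#' @param rows `"category"` or `"patch"`.
#' @param cols `"year"` or `"outcome"` (fruited vs not).
#' @param value `"flowers"` (all flowering plants) or `"fruits"` (plants
#'   that fruited); ignored when `cols = "outcome"`.
#' @return Integer matrix with named dimensions.
#' @export
tabulate_records <- function(records, rows = c("category", "patch"),
                             cols = c("year", "outcome"),
                             value = c("flowers", "fruits")) {
  rows <- match.arg(rows); cols <- match.arg(cols); value <- match.arg(value)
  if (!nrow(records)) stop("no records to tabulate")
  r <- records[[rows]]
  bad <- !is.na(r) & !(r %in% 1:5)
  if (any(bad))
    stop("unknown ", rows, " codes: ",
         paste(unique(r[bad]), collapse = ", "))
  keep <- !is.na(r)
  records <- records[keep, ]; r <- r[keep]
  if (cols == "outcome") {
    tab <- table(factor(r, levels = sort(unique(r))),
                 factor(ifelse(records$fruited == 1, "fruited", "not_fruited"),
                        levels = c("fruited", "not_fruited")))
  } else {
    if (value == "fruits") {
      records <- records[records$fruited == 1, ]
      r <- records[[rows]]
    }
    tab <- table(factor(r, levels = sort(unique(r))), records$year)
  }
  m <- as.matrix(unclass(tab))
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c(rows, cols)
  m
}

#' Pearson chi-square test for an r x c table
#'
#' No continuity correction. Cells with expected counts below 5 are reported
#' in a warning but do not block the test.
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2.
#' @return List: `chi2`, `df`, `p`, `expected`.
#' @export
chisq_rxc <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5))
    warning(sum(ct$expected < 5), " cell(s) with expected count < 5")
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Chi-square goodness of fit
#'
#' Compares observed counts with a uniform expectation or with an
#' expectation proportional to supplied weights.
#'
#' @param counts Non-negative observed counts (length >= 2).
#' @param expected `"uniform"` or a numeric vector of positive weights.
#' @return List: `chi2`, `df`, `p`, `expected`.
#' @export
chisq_gof <- function(counts, expected = "uniform") {
  if (length(counts) < 2L) stop("need at least 2 cells")
  if (identical(expected, "uniform")) {
    p <- rep(1 / length(counts), length(counts))
  } else {
    if (length(expected) != length(counts))
      stop("weights must match counts in length")
    if (any(expected <= 0)) stop("zero or negative expected cell")
    p <- expected / sum(expected)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, p = p))
  if (any(ct$expected < 5))
    warning(sum(ct$expected < 5), " cell(s) with expected count < 5")
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Chi-square-style heterogeneity of a set of values
#'
#' Computes sum((v - mean(v))^2 / mean(v)) with df = k - 1, treating the
#' values themselves (typically percentage success figures) as if they were
#' counts. This mirrors a construction found in field studies but is not a
#' standard test -- percentages are not Poisson counts -- so a methodological
#' warning is emitted on every call.
#'
#' @param values Non-negative numeric values, mean > 0.
#' @return List: `chi2`, `df`, `p`.
#' @export
chisq_on_values <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(values < 0)) stop("negative values")
  m <- mean(values)
  if (m == 0) stop("zero mean")
  warning("chisq_on_values treats arbitrary values as counts; ",
          "not a standard chi-square test", call. = FALSE)
  chi2 <- sum((values - m)^2 / m)
  df <- length(values) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Ordinary least-squares regression of fruits on flowers
#'
#' @param x Predictor (e.g. flower counts per stratum); must vary.
#' @param y Response (e.g. fruit counts).
#' @return List: `slope`, `intercept`, `r_squared`, `model` (the `lm` fit).
#' @export
linreg <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       model = fit)
}

#' Association measures between an ordinal code and a binary outcome
#'
#' Computes five standard measures on individual-level data: Cramer's
#' V-squared (chi-square / (N (min(r,c) - 1))), Pearson's r on the raw
#' codes, Spearman's rho on midranks, Kendall's tau-b with tie correction,
#' and Goodman-Kruskal's tau as the proportional reduction in error when
#' predicting the outcome from the code.
#'
#' @param code Integer-valued classifier per individual (e.g. colour
#'   category).
#' @param outcome Binary outcome per individual (0/1).
#' @return Named list of the five measures; all `NA` when either variable
#'   is constant.
#' @export
association_measures <- function(code, outcome) {
  if (length(code) != length(outcome)) stop("lengths differ")
  if (!all(outcome %in% 0:1)) stop("outcome must be binary 0/1")
  if (length(unique(code)) < 2L || length(unique(outcome)) < 2L)
    return(list(cramers_v2 = NA_real_, pearson_r = NA_real_,
                spearman_rho = NA_real_, kendall_tau_b = NA_real_,
                goodman_kruskal_tau = NA_real_))
  tab <- table(code, outcome)
  N <- sum(tab)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  v2 <- unname(chi2) / (N * (min(dim(tab)) - 1L))
  # Goodman-Kruskal tau, outcome as the predicted variable
  colp <- colSums(tab) / N
  e_marginal <- 1 - sum(colp^2)
  rowp <- rowSums(tab)
  e_conditional <- 1 - sum(tab^2 / rowp) / N
  gk_tau <- (e_marginal - e_conditional) / e_marginal
  list(cramers_v2 = v2,
       pearson_r = stats::cor(code, outcome),
       spearman_rho = stats::cor(code, outcome, method = "spearman"),
       kendall_tau_b = stats::cor(code, outcome, method = "kendall"),
       goodman_kruskal_tau = gk_tau)
}

#' Fruiting success rates
#'
#' Pooled success (100 x total fruits / total flowers), per-year
#' percentages, and their mean with standard error across years
#' (sd / sqrt(n_years); for two years this equals the half-range). Field
#' tables mix the pooled and mean-of-years conventions, so both are
#' reported. Strata with zero flowers are returned as `NA`.
#'
#' @param records Data frame of plant records (needs `year`, `fruited`, and
#'   the stratum column unless `by = "overall"`).
#' @param by `"category"`, `"patch"` or `"overall"`.
#' @return Data frame: one row per stratum level with `pooled_pct`,
#'   per-year columns, `mean_pct`, `se_pct`.
#' @export
success_rates <- function(records, by = c("category", "patch", "overall")) {
  by <- match.arg(by)
  if (!nrow(records)) stop("no records")
  grp <- if (by == "overall") rep("overall", nrow(records)) else records[[by]]
  keep <- !is.na(grp)
  records <- records[keep, ]; grp <- grp[keep]
  years <- sort(unique(records$year))
  levels_ <- sort(unique(grp))
  rows <- lapply(levels_, function(lv) {
    rec <- records[grp == lv, ]
    fl <- sum(!is.na(rec$fruited)); fr <- sum(rec$fruited, na.rm = TRUE)
    yearly <- vapply(years, function(y) {
      r <- rec[rec$year == y, ]
      if (!nrow(r)) return(NA_real_)
      100 * sum(r$fruited) / nrow(r)
    }, numeric(1))
    ok <- !is.na(yearly)
    out <- data.frame(level = lv,
                      pooled_pct = if (fl > 0) 100 * fr / fl else NA_real_,
                      mean_pct = if (any(ok)) mean(yearly[ok]) else NA_real_,
                      se_pct = if (sum(ok) > 1)
                        stats::sd(yearly[ok]) / sqrt(sum(ok)) else NA_real_)
    for (k in seq_along(years)) out[[paste0("pct_", years[k])]] <- yearly[k]
    out
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis rank test on viability groups
#'
#' Tie-corrected H with a chi-square approximation for the p value. Returns
#' H = 0 (p = 1) when every observation is identical, where the tie
#' correction would otherwise be undefined.
#'
#' @param groups List of numeric vectors (e.g. viability percentages per
#'   parent category).
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  obs <- unlist(groups)
  if (length(obs) < 2L) stop("need at least 2 observations")
  if (length(unique(obs)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Capsule-formation summary of artificial crosses
#'
#' Per unordered parent-category combination: the percentage of evaluable
#' crosses (grazed, lost and moldy capsules excluded) that formed a capsule,
#' and the evaluable count. The overall rate counts capsules over all
#' crosses, evaluable or not.
#'
#' @param crosses Data frame with `pollen_category`, `ovule_category` and
#'   `capsule_fate` in `{capsule, none, grazed, moldy, lost}`.
#' @return List: `cells` (data frame with `category_a <= category_b`,
#'   `n_evaluable`, `n_capsule`, `capsule_pct`; `NA` percentage where no
#'   cross was evaluable) and `overall_pct` (whole percent).
#' @export
capsule_summary <- function(crosses) {
  need <- c("pollen_category", "ovule_category", "capsule_fate")
  if (!all(need %in% names(crosses)))
    stop("crosses need columns: ", paste(need, collapse = ", "))
  a <- pmin(crosses$pollen_category, crosses$ovule_category)
  b <- pmax(crosses$pollen_category, crosses$ovule_category)
  evaluable <- crosses$capsule_fate %in% c("capsule", "none")
  formed <- crosses$capsule_fate == "capsule"
  key <- paste(a, b, sep = "x")
  cells <- do.call(rbind, lapply(unique(key), function(k) {
    i <- key == k
    ne <- sum(evaluable[i]); nc <- sum(formed[i])
    data.frame(category_a = a[i][1L], category_b = b[i][1L],
               n_evaluable = ne, n_capsule = nc,
               capsule_pct = if (ne > 0) round(100 * nc / ne) else NA_real_)
  }))
  cells <- cells[order(cells$category_a, cells$category_b), ]
  rownames(cells) <- NULL
  list(cells = cells,
       overall_pct = round(100 * sum(formed) / nrow(crosses)))
}
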