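#' Build a pipeline run configuration
#'
#' Collects the inputs and settings for [run_pipeline()]. Any stage whose
#' input path is `NULL` is skipped. A configuration can also be read from a
#' YAML file with [read_run_config()]; explicit arguments here mirror the
#' file keys.
#'
#' @param spectra Path to a reflectance spectra file (vision stage).
#' @param records Path to a plant-records file (reproduction stage).
#' @param markers Path to a marker-matrix file (markers stage).
#' @param fasta Path to an aligned FASTA (sequence-distance stage).
#' @param calibration `"builtin"` (the bundled discrimination pairs) or a
#'   path to a file with `distance` and `probability` columns.
#' @param background_level Adaptation background reflectance, in (0, 1].
#' @param theta Discrimination threshold, in (0.5, 1).
#' @param lambda_max Named UV/B/G receptor peak wavelengths (nm).
#' @param n_permutations AMOVA permutations.
#' @param seed Seed used by every stochastic stage.
#' @param output_dir Directory the report files are written to.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spectra = NULL, records = NULL, markers = NULL,
                       fasta = NULL, calibration = "builtin",
                       background_level = 0.10, theta = 0.70,
                       lambda_max = c(UV = 344, B = 436, G = 544),
                       n_permutations = 999, seed = 1,
                       output_dir = tempfile("polmorph_run_")) {
  cfg <- list(spectra = spectra, records = records, markers = markers,
              fasta = fasta, calibration = calibration,
              background_level = background_level, theta = theta,
              lambda_max = lambda_max, n_permutations = n_permutations,
              seed = as.integer(seed), output_dir = output_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$lambda_max)) raw$lambda_max <- unlist(raw$lambda_max)
  do.call(run_config, raw)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  core <- unclass(config)
  core$output_dir <- NULL  # output location must not change the run identity
  yaml::write_yaml(core, tf)
  unname(tools::md5sum(tf))
}

#' Validate pipeline inputs
#'
#' Returns every detected problem rather than stopping at the first:
#' missing files, malformed settings, schema violations in the records
#' file, and spectra that do not cover the 300-650 nm window.
#'
#' @param config A [run_config()].
#' @return Data frame with columns `stage` and `issue`; zero rows when
#'   clean.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  issues <- data.frame(stage = character(), issue = character())
  add <- function(stage, msg)
    issues <<- rbind(issues, data.frame(stage = stage, issue = msg))
  for (st in c("spectra", "records", "markers", "fasta")) {
    p <- config[[st]]
    if (!is.null(p) && !file.exists(p))
      add(st, paste0("input file not found: ", p))
  }
  if (config$theta <= 0.5 || config$theta >= 1)
    add("vision", "theta must be in (0.5, 1)")
  if (config$background_level <= 0 || config$background_level > 1)
    add("vision", "background_level must be in (0, 1]")
  if (!identical(config$calibration, "builtin") &&
      !file.exists(config$calibration))
    add("vision", paste0("calibration file not found: ", config$calibration))
  if (!is.null(config$spectra) && file.exists(config$spectra)) {
    sp <- tryCatch(suppressWarnings(read_spectra(config$spectra)),
                   error = function(e) e)
    if (inherits(sp, "error")) {
      add("spectra", conditionMessage(sp))
    } else {
      for (s in sp)
        if (!covers_standard_grid(s))
          add("spectra", paste0("sample '", s$label,
                                "' does not cover 300-650 nm"))
    }
  }
  if (!is.null(config$records) && file.exists(config$records)) {
    rec <- tryCatch(utils::read.table(config$records, header = TRUE,
                                      sep = ",", comment.char = "#",
                                      stringsAsFactors = FALSE),
                    error = function(e) e)
    if (inherits(rec, "error")) add("records", conditionMessage(rec))
    else {
      iss <- validate_records(rec)
      for (msg in iss$issue) add("records", msg)
    }
  }
  issues
}

write_table_with_header <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s seed: %d", hash, seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage whose input is configured and writes delimited-text
#' outputs plus a plain-text report into the output directory. Every table
#' carries the configuration hash and seed in a comment header, and a rerun
#' with the same configuration and inputs is byte-identical.
#'
#' Stages: `vision` (spectra to hexagon loci, pairwise distances and
#' threshold summaries under the calibrated psychometric function), `repro`
#' (records to contingency tables, chi-square tests, regressions and
#' success rates), `markers` (diversity statistics and AMOVA phi-PT),
#' `seqdist` (Jukes-Cantor distances and group diversities).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage results and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  issues <- validate_inputs(config)
  if (nrow(issues))
    stop("invalid inputs:\n",
         paste(sprintf("[%s] %s", issues$stage, issues$issue),
               collapse = "\n"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  paths <- character()
  results <- list()
  report <- c(sprintf("polmorph pipeline run (config %s, seed %d)", hash,
                      seed),
              sprintf("settings: background %.2f, theta %.2f, lambda_max %s",
                      config$background_level, config$theta,
                      paste(sprintf("%s=%g", names(config$lambda_max),
                                    config$lambda_max), collapse = " ")))
  out <- function(name) file.path(config$output_dir, name)

  if (!is.null(config$spectra)) {
    spectra <- read_spectra(config$spectra)
    loci <- hexagon_loci(spectra,
                         receptors = receptor_set(config$lambda_max),
                         background = flat_background(
                           config$background_level))
    paths <- c(paths, write_table_with_header(loci, out("loci.csv"), hash,
                                              seed))
    dmat <- pairwise_distances(loci)
    paths <- c(paths, write_table_with_header(
      data.frame(sample = rownames(dmat), as.data.frame(dmat),
                 check.names = FALSE),
      out("distances.csv"), hash, seed))
    cal <- if (identical(config$calibration, "builtin")) {
      discrimination_pairs()
    } else utils::read.csv(config$calibration, comment.char = "#")
    model <- fit_psychometric(cal$distance, cal$probability, seed = seed)
    if (all(loci$part %in% c("sepal", "labellum"))) {
      flower <- sub("_(sepal|labellum)$", "", loci$label)
      summ <- summarize_comparisons(dmat, loci$part, flower, model,
                                    config$theta)
      paths <- c(paths, write_table_with_header(
        summ, out("comparison_summary.csv"), hash, seed))
      results$comparisons <- summ
    } else {
      report <- c(report,
                  "vision: parts not labelled; comparison summary skipped")
    }
    results$loci <- loci; results$distances <- dmat; results$model <- model
    report <- c(report, sprintf(
      "vision: %d spectra; psychometric A=%.3f d0=%.4f s=%.4f RMSE=%.4f",
      length(spectra), model$A, model$d0, model$s, model$rmse))
  } else report <- c(report, "vision: skipped (no spectra input)")

  if (!is.null(config$records)) {
    rec <- read_plant_records(config$records)
    repro <- list()
    for (strat in c("category", "patch")) {
      if (all(is.na(rec[[strat]]))) next
      flowers <- tabulate_records(rec, rows = strat, cols = "year",
                                  value = "flowers")
      fruits <- tabulate_records(rec, rows = strat, cols = "year",
                                 value = "fruits")
      reg <- linreg(rowSums(flowers), rowSums(fruits))
      rates <- success_rates(rec, by = strat)
      het <- if (ncol(flowers) >= 2) chisq_rxc(flowers) else NULL
      repro[[strat]] <- list(flowers = flowers, fruits = fruits,
                             regression = reg, rates = rates,
                             heterogeneity = het)
      report <- c(report, sprintf(
        "repro[%s]: fruit = %.4f flower %+.4f, R2 = %.4f%s",
        strat, reg$slope, reg$intercept, reg$r_squared,
        if (!is.null(het)) sprintf("; heterogeneity chi2 = %.3f (df %d)",
                                   het$chi2, het$df) else ""))
      paths <- c(paths, write_table_with_header(
        rates, out(sprintf("success_rates_%s.csv", strat)), hash, seed))
    }
    overall <- success_rates(rec, by = "overall")
    report <- c(report, sprintf("repro: overall fruiting %.1f%%",
                                overall$pooled_pct[1]))
    results$repro <- repro
    results$overall_rate <- overall
  } else report <- c(report, "repro: skipped (no records input)")

  if (!is.null(config$markers)) {
    m <- read_marker_matrix(config$markers)
    div <- diversity_stats(m)
    am <- amova_phipt(m, n_permutations = config$n_permutations, seed = seed)
    paths <- c(paths, write_table_with_header(
      div$per_locus, out("marker_diversity.csv"), hash, seed))
    report <- c(report, sprintf(
      "markers: Ne=%.3f He=%.3f uHe=%.3f I=%.3f; phi_PT=%.3f (p=%.3f, %d perms)",
      div$summary["Ne", "mean"], div$summary["He", "mean"],
      div$summary["uHe", "mean"], div$summary["I", "mean"],
      am$phi_pt, am$p_value, am$n_permutations))
    results$markers <- list(diversity = div, amova = am)
  } else report <- c(report, "markers: skipped (no matrix input)")

  if (!is.null(config$fasta)) {
    aln <- read_alignment(config$fasta)
    jc <- jc_distance(aln)
    paths <- c(paths, write_table_with_header(
      data.frame(id = rownames(jc$d), as.data.frame(jc$d),
                 check.names = FALSE),
      out("jc_distances.csv"), hash, seed))
    gd <- if (length(unique(aln$group)) >= 2)
      group_diversities(aln, seed = seed) else NULL
    if (!is.null(gd))
      report <- c(report, sprintf(
        "seqdist: d_within(mean)=%.4f d_total=%.4f coeff_diff=%.3f (SE %.3f)",
        gd$d_s, gd$total, gd$coefficient, gd$coefficient_se))
    results$seqdist <- list(jc = jc, groups = gd)
  } else report <- c(report, "seqdist: skipped (no fasta input)")

  writeLines(report, out("report.txt"))
  paths <- c(paths, out("report.txt"))
  results$paths <- paths
  results$config_hash <- hash
  invisible(results)
}
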