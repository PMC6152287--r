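pkg_version <- function() {
  as.character(utils::packageVersion("adipodiscrim"))
}

scenario_hash <- function(scenario) {
  if (!is.null(scenario$path) && file.exists(scenario$path)) {
    unname(tools::md5sum(scenario$path))
  } else {
    "inline"
  }
}

provenance_header <- function(scenario, seed) {
  c(sprintf("adipodiscrim %s", pkg_version()),
    sprintf("seed=%d scenario=%s hash=%s", seed, scenario$name,
            scenario_hash(scenario)))
}

#' Simulate a cohort and write it to CSV
#'
#' Pipeline front end for [generate_cohort()] + [write_cohort()].  The file
#' carries a provenance header (`#` comments: package version, seed,
#' scenario name and hash) and is byte-identical across reruns with the
#' same inputs.
#'
#' @param path Output CSV path.
#' @param scenario A `cohort_scenario` (default: packaged scenario).
#' @param seed Master seed.
#' @param ... Size/structure overrides passed to [generate_cohort()]
#'   (`n_diabetic`, `n_healthy`, `fraction_female`, `within_patient_r`).
#' @return The generated `cohort`, invisibly.
#' @export
simulate_cohort <- function(path, scenario = load_scenario(), seed = 1L, ...) {
  coh <- generate_cohort(scenario, seed = seed, ...)
  write_cohort(coh, path, header = provenance_header(scenario, seed))
  invisible(coh)
}

#' Descriptive analysis of a cohort
#'
#' Reproduces the descriptive layer of the study: per-arm summary of each
#' parameter (mean and SD for normal-family parameters, median and quartiles
#' for the skewed ones), the two Student's t comparisons per parameter
#' (healthy vs untreated, independent; untreated vs month-6, paired), and
#' the absolute correlation matrix of the per-patient differences.
#' Skewed (lognormal-family) parameters are flagged in the t-test table,
#' since a t comparison on them is conventional but questionable.
#'
#' @param cohort A `cohort` or a path to a cohort CSV.
#' @param out_dir Optional directory; if given, writes `summary.csv`,
#'   `ttests.csv`, `delta_correlations.csv` and `deltas.csv`.
#' @return List with `summary`, `ttests`, `correlations` (a
#'   [correlation_matrix()] or `NULL`), `deltas`.
#' @export
analyze_cohort <- function(cohort, out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"))
  catalog <- cohort$catalog
  d <- cohort$data
  arms <- list(healthy = d[d$group == "healthy", , drop = FALSE],
               baseline = d[d$timepoint == "baseline", , drop = FALSE],
               month6 = d[d$timepoint == "month6", , drop = FALSE])

  summ <- do.call(rbind, lapply(1:21, function(i) {
    col <- paste0("w", i)
    do.call(rbind, lapply(names(arms), function(a) {
      v <- arms[[a]][[col]]
      if (!length(v)) return(NULL)
      data.frame(parameter = col, name = catalog$name[i], arm = a,
                 family = catalog$family[i], n = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 median = stats::median(v),
                 q1 = unname(stats::quantile(v, 0.25)),
                 q3 = unname(stats::quantile(v, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL

  ttests <- NULL
  have_diab <- nrow(arms$baseline) > 0
  for (i in 1:21) {
    col <- paste0("w", i)
    if (nrow(arms$healthy) >= 2 && nrow(arms$baseline) >= 2) {
      ht <- t_test_independent(arms$healthy[[col]], arms$baseline[[col]])
      ttests <- rbind(ttests, data.frame(
        parameter = col, comparison = "healthy_vs_baseline", test = "independent",
        t = ht$t, df = ht$df, p = ht$p, skewed = catalog$family[i] == "lognormal",
        stringsAsFactors = FALSE))
    }
    if (have_diab && nrow(arms$baseline) >= 2) {
      bl <- arms$baseline
      m6 <- arms$month6[match(bl$patient_id, arms$month6$patient_id), , drop = FALSE]
      ht <- tryCatch(t_test_paired(bl[[col]], m6[[col]]), error = function(e) NULL)
      if (!is.null(ht)) {
        ttests <- rbind(ttests, data.frame(
          parameter = col, comparison = "baseline_vs_month6", test = "paired",
          t = ht$t, df = ht$df, p = ht$p, skewed = catalog$family[i] == "lognormal",
          stringsAsFactors = FALSE))
      }
    }
  }

  if (have_diab) {
    deltas <- compute_delta(cohort)
    cm <- if (nrow(deltas) >= 3) correlation_matrix(deltas) else NULL
  } else {
    warning("cohort has no diabetic patients: difference stage is empty")
    deltas <- NULL
    cm <- NULL
  }

  out <- list(summary = summ, ttests = ttests, correlations = cm,
              deltas = deltas)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(ttests)) {
      utils::write.csv(ttests, file.path(out_dir, "ttests.csv"), row.names = FALSE)
    }
    if (!is.null(cm)) {
      utils::write.csv(as.data.frame(unclass(cm)),
                       file.path(out_dir, "delta_correlations.csv"))
    }
    if (!is.null(deltas)) {
      utils::write.csv(deltas, file.path(out_dir, "deltas.csv"), row.names = FALSE)
    }
  }
  out
}

#' Run the subset search on a cohort and write reports
#'
#' Pipeline front end for [run_search()]: writes the full per-task result
#' table as CSV and the per-kind top-10 ranking as JSON.
#'
#' @param cohort A `cohort` or a path to a cohort CSV.
#' @param config A [search_config()].
#' @param out_dir Optional output directory (`search_results.csv`,
#'   `search_top.json`).
#' @return The `subset_search` object.
#' @export
search_cohort <- function(cohort, config = search_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  sr <- run_search(cohort, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sr$results, file.path(out_dir, "search_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_tasks = sr$n_tasks, top = sr$top),
      file.path(out_dir, "search_top.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  sr
}
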