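#' Per-patient treatment differences
#'
#' For every diabetic patient, the difference vector of the 21 parameters,
#' month-6 value minus baseline value.  Healthy controls are excluded.
#'
#' @param cohort A `cohort` with complete diabetic pairs.
#' @return A data frame of class `delta_table` with columns `patient_id`,
#'   `gender`, `dw1`..`dw21`, one row per diabetic patient.
#' @export
compute_delta <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data[cohort$data$group == "diabetic", , drop = FALSE]
  b <- d[d$timepoint == "baseline", , drop = FALSE]
  m <- d[d$timepoint == "month6", , drop = FALSE]
  if (!setequal(b$patient_id, m$patient_id)) {
    odd <- c(setdiff(b$patient_id, m$patient_id),
             setdiff(m$patient_id, b$patient_id))
    stop("unpaired diabetic patient: ", odd[1], call. = FALSE)
  }
  m <- m[match(b$patient_id, m$patient_id), , drop = FALSE]
  out <- data.frame(patient_id = b$patient_id, gender = b$gender,
                    stringsAsFactors = FALSE)
  for (i in 1:21) {
    out[[paste0("dw", i)]] <- m[[paste0("w", i)]] - b[[paste0("w", i)]]
  }
  rownames(out) <- NULL
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Absolute correlation matrix of the treatment differences
#'
#' The 21x21 matrix of absolute pairwise Pearson correlations between the
#' per-patient differences, the screen used to spot structurally redundant
#' parameter pairs (weight--BMI, insulin--HOMA-IR, ...) before the
#' discriminant search.  A constant difference column yields undefined
#' correlations; those entries are reported as 0 with a warning.
#'
#' @param deltas A `delta_table` from [compute_delta()] with at least 3 rows.
#' @return A 21x21 matrix of class `correlation_matrix` with entries in
#'   \[0, 1\], unit diagonal, and attribute `n` (number of patients).
#' @seealso [correlation_band()]
#' @export
correlation_matrix <- function(deltas) {
  stopifnot(inherits(deltas, "delta_table"))
  if (nrow(deltas) < 3L) stop("need at least 3 patients", call. = FALSE)
  D <- as.matrix(deltas[paste0("dw", 1:21)])
  const <- apply(D, 2, stats::sd) == 0
  C <- suppressWarnings(abs(stats::cor(D)))
  if (any(const)) {
    warning("constant difference column(s) ",
            paste0("dw", which(const), collapse = ", "),
            ": undefined correlations reported as 0")
    C[is.na(C)] <- 0
  }
  diag(C) <- 1
  dimnames(C) <- list(paste0("dw", 1:21), paste0("dw", 1:21))
  structure(C, n = nrow(deltas), class = c("correlation_matrix", "matrix", "array"))
}

#' Verbal strength band of a correlation
#'
#' Five-band verbal scale used for reporting the correlation screen:
#' feeble < 0.2 <= weak < 0.4 <= moderate < 0.6 <= strong < 0.8 <=
#' almost-complete.  The breaks are a convention, not an estimate, and can
#' be overridden.
#'
#' @param r Correlations (absolute values are taken).
#' @param breaks Four increasing cut points in (0, 1).
#' @return A factor with the five band labels.
#' @export
correlation_band <- function(r, breaks = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(length(breaks) == 4L, !is.unsorted(breaks))
  cut(abs(r), breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c("feeble", "weak", "moderate", "strong", "almost-complete"))
}

#' Student's t-test for independent samples
#'
#' Pooled-variance two-sample t-test (two-sided), as used to compare the
#' healthy and diabetic groups parameter by parameter.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @return List with elements `t`, `df`, `p`.
#' @export
t_test_independent <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Student's t-test for paired samples
#'
#' One-sample t-test on the within-patient differences (after minus before),
#' two-sided, as used to compare the diabetic group before and after the
#' six-month therapy.
#'
#' @param before,after Numeric vectors of equal length at least 2.
#' @return List with elements `t`, `df`, `p`.
#' @export
t_test_paired <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors must have equal length", call. = FALSE)
  if (length(before) < 2L) stop("need >= 2 pairs", call. = FALSE)
  d <- after - before
  if (stats::sd(d) == 0) {
    stop("zero variance of differences: paired t undefined", call. = FALSE)
  }
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
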