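# run a block of code under a local RNG seed, restoring the caller's stream
with_local_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Patient-level train/test split
#'
#' Splits the diabetic patients (not rows: both timepoints of a patient stay
#' on the same side) into a learning set of `round(n * train_fraction)`
#' patients and a test set of the rest.  The 40-patient study design with
#' the conventional 2/3 fraction gives 27 learning and 13 test patients.
#'
#' @param cohort A `cohort` with at least 3 diabetic patients.
#' @param train_fraction Fraction in (0, 1), default 2/3.
#' @param seed Integer seed; the split is deterministic given the seed and
#'   does not disturb the caller's RNG stream.
#' @return List with character vectors `train` and `test` (patient ids),
#'   disjoint and exhaustive.
#' @export
split_patients <- function(cohort, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  ids <- unique(cohort$data$patient_id[cohort$data$group == "diabetic"])
  n <- length(ids)
  if (n < 3L) stop("need at least 3 diabetic patients to split", call. = FALSE)
  n_train <- round(n * train_fraction)
  if (n_train < 1L || n_train >= n) {
    stop("train_fraction leaves an empty train or test set", call. = FALSE)
  }
  perm <- with_local_seed(seed, sample.int(n))
  list(train = ids[perm[seq_len(n_train)]],
       test = ids[perm[(n_train + 1L):n]])
}

#' Enumerate feature subsets
#'
#' All non-empty subsets of `{1..p}` with at most `max_k` elements, in
#' deterministic order: increasing cardinality, then lexicographic.  For
#' large `p` the list is big (over a million entries at `p = 21`,
#' `max_k = 10`); [count_tasks()] counts without enumerating, and
#' [run_search()] streams per-cardinality blocks internally.
#'
#' @param p Number of features.
#' @param max_k Cardinality cap, `1 <= max_k <= p`.
#' @return List of integer vectors.
#' @export
enumerate_subsets <- function(p, max_k) {
  stopifnot(p >= 1, max_k >= 1, max_k <= p)
  out <- vector("list", sum(choose(p, seq_len(max_k))))
  pos <- 0L
  for (k in seq_len(max_k)) {
    cmb <- utils::combn(p, k)
    for (c_i in seq_len(ncol(cmb))) {
      pos <- pos + 1L
      out[[pos]] <- cmb[, c_i]
    }
  }
  out
}

#' Number of (subset, classifier) tasks
#'
#' Pure arithmetic: `n_kinds * sum_{k=1..max_k} C(p, k)`.  The full
#' enumeration over 21 features and 5 classifier kinds gives
#' `5 * (2^21 - 1) = 10,485,755` tasks; capping at 10 simultaneous features
#' gives `5 * (2^20 - 1) = 5,242,875`.
#'
#' @param p Number of features.
#' @param max_k Cardinality cap.
#' @param n_kinds Number of classifier kinds (default 5).
#' @return The task count (numeric).
#' @export
count_tasks <- function(p, max_k, n_kinds = 5L) {
  stopifnot(p >= 1, max_k >= 1, max_k <= p, n_kinds >= 1)
  n_kinds * sum(choose(p, seq_len(max_k)))
}

#' Search configuration
#'
#' @param max_cardinality Largest subset size searched (default 10, the
#'   study's cap given 40 patients).
#' @param kinds Classifier kinds to evaluate (default all five).
#' @param train_fraction Learning-set fraction of patients (default 2/3).
#' @param seed Seed for the patient split.
#' @param policy A [ridge_policy()].  Under `strict = TRUE`, singular fits
#'   mark the task `failed` instead of being ridged.
#' @param parameters Parameter indices eligible for subsets (default 1:21).
#' @param top_k Number of top results retained per kind (default 10).
#' @param train_accuracy If `TRUE`, also score accuracy on the learning
#'   rows (reported alongside, never used for ranking).
#' @param verbose Print progress per cardinality block.
#' @return List of class `search_config`.
#' @export
search_config <- function(max_cardinality = 10L, kinds = discriminant_kinds(),
                          train_fraction = 2 / 3, seed = 1L,
                          policy = ridge_policy(), parameters = 1:21,
                          top_k = 10L, train_accuracy = FALSE,
                          verbose = FALSE) {
  kinds <- match.arg(kinds, discriminant_kinds(), several.ok = TRUE)
  stopifnot(max_cardinality >= 1, all(parameters %in% 1:21),
            !anyDuplicated(parameters), top_k >= 1)
  if (max_cardinality > length(parameters)) {
    max_cardinality <- length(parameters)
  }
  structure(list(max_cardinality = as.integer(max_cardinality), kinds = kinds,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 policy = policy, parameters = as.integer(sort(parameters)),
                 top_k = as.integer(top_k), train_accuracy = train_accuracy,
                 verbose = verbose),
            class = "search_config")
}

# observation matrix and labels for the diabetic rows of a cohort:
# one row per patient x timepoint, features = raw parameter values,
# class = timepoint (baseline vs month6), positive class = month6.
diabetic_design <- function(cohort) {
  d <- cohort$data[cohort$data$group == "diabetic", , drop = FALSE]
  list(X = as.matrix(d[w_columns()]),
       y = factor(d$timepoint, levels = c("baseline", "month6")),
       patient_id = d$patient_id)
}

confusion_counts <- function(truth, pred, positive = "month6") {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Evaluate one (subset, classifier) task
#'
#' Fits the classifier of the given kind on the training patients'
#' baseline/month-6 rows restricted to the feature subset, predicts the
#' held-out test rows, and scores the confusion counts and accuracy
#' `ACC = (TN + TP) / (FN + FP + TN + TP)` with month-6 as the positive
#' class.  A singular fit under a strict ridge policy yields
#' `status = "failed"` with `acc = NA`.
#'
#' @param cohort A `cohort`.
#' @param subset Integer vector of parameter indices (non-empty).
#' @param kind One classifier kind.
#' @param split A list with `train`/`test` patient ids, from
#'   [split_patients()].
#' @param policy A [ridge_policy()].
#' @param train_accuracy Also compute accuracy on the training rows.
#' @return List of class `subset_result`: `subset`, `kind`, `confusion`
#'   (TP/TN/FP/FN), `acc`, `sensitivity`, `specificity`, `ridge`, `status`,
#'   and optionally `train_acc`.
#' @export
evaluate_task <- function(cohort, subset, kind, split,
                          policy = ridge_policy(), train_accuracy = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  subset <- sort(as.integer(subset))
  if (length(subset) == 0L) stop("empty feature subset", call. = FALSE)
  if (!all(subset %in% 1:21)) stop("subset indices must be in 1..21", call. = FALSE)
  kind <- match.arg(kind, discriminant_kinds())
  des <- diabetic_design(cohort)
  in_train <- des$patient_id %in% split$train
  in_test <- des$patient_id %in% split$test
  Xtr <- des$X[in_train, subset, drop = FALSE]
  Xte <- des$X[in_test, subset, drop = FALSE]
  ytr <- des$y[in_train]
  yte <- des$y[in_test]

  model <- tryCatch(
    discriminant_fit(Xtr, ytr, kind = kind, policy = policy),
    error = function(e) e)
  if (inherits(model, "error")) {
    return(structure(list(subset = subset, kind = kind,
                          confusion = c(TP = NA, TN = NA, FP = NA, FN = NA),
                          acc = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, ridge = NA_real_,
                          status = "failed", message = conditionMessage(model)),
                     class = "subset_result"))
  }
  pred <- predict(model, Xte)
  cm <- confusion_counts(yte, pred)
  res <- list(subset = subset, kind = kind, confusion = cm,
              acc = (cm["TP"] + cm["TN"]) / sum(cm),
              sensitivity = if ((cm["TP"] + cm["FN"]) > 0)
                cm["TP"] / (cm["TP"] + cm["FN"]) else NA_real_,
              specificity = if ((cm["TN"] + cm["FP"]) > 0)
                cm["TN"] / (cm["TN"] + cm["FP"]) else NA_real_,
              ridge = model$ridge, status = "ok")
  res$acc <- unname(res$acc)
  res$sensitivity <- unname(res$sensitivity)
  res$specificity <- unname(res$specificity)
  if (train_accuracy) {
    res$train_acc <- mean(predict(model, Xtr) == as.character(ytr))
  }
  structure(res, class = "subset_result")
}

#' Exhaustive (subset x classifier) search
#'
#' Evaluates every feature subset up to the configured cardinality with
#' every configured classifier kind on a single patient-level train/test
#' split, and ranks results per kind by held-out accuracy.  Ties are broken
#' toward smaller subsets, then lexicographically.  Execution is chunked by
#' cardinality; a rerun with the same cohort and config reproduces the
#' result exactly.
#'
#' @param cohort A `cohort` with diabetic pairs.
#' @param config A [search_config()].
#' @return List of class `subset_search`: `results` (one data frame row per
#'   task: subset, k, kind, TP/TN/FP/FN, acc, sensitivity, specificity,
#'   ridge, status), `top` (per-kind data frames of the `top_k` best),
#'   `n_tasks`, `split`, `config`.
#' @export
run_search <- function(cohort, config = search_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "search_config"))
  split <- split_patients(cohort, config$train_fraction, config$seed)
  des <- diabetic_design(cohort)
  in_train <- des$patient_id %in% split$train
  in_test <- des$patient_id %in% split$test
  ytr <- des$y[in_train]
  yte <- des$y[in_test]

  pars <- config$parameters
  expected <- count_tasks(length(pars), config$max_cardinality,
                          length(config$kinds))
  chunks <- list()
  n_done <- 0
  for (k in seq_len(config$max_cardinality)) {
    cmb <- utils::combn(pars, k)
    block <- vector("list", ncol(cmb) * length(config$kinds))
    bi <- 0L
    for (c_i in seq_len(ncol(cmb))) {
      subset <- cmb[, c_i]
      Xtr <- des$X[in_train, subset, drop = FALSE]
      Xte <- des$X[in_test, subset, drop = FALSE]
      for (kind in config$kinds) {
        bi <- bi + 1L
        model <- tryCatch(
          discriminant_fit(Xtr, ytr, kind = kind, policy = config$policy),
          error = function(e) e)
        if (inherits(model, "error")) {
          block[[bi]] <- data.frame(
            subset = paste(subset, collapse = "+"), k = k, kind = kind,
            TP = NA, TN = NA, FP = NA, FN = NA, acc = NA_real_,
            sensitivity = NA_real_, specificity = NA_real_,
            ridge = NA_real_, status = "failed", stringsAsFactors = FALSE)
        } else {
          cm <- confusion_counts(yte, predict(model, Xte))
          row <- data.frame(
            subset = paste(subset, collapse = "+"), k = k, kind = kind,
            TP = cm["TP"], TN = cm["TN"], FP = cm["FP"], FN = cm["FN"],
            acc = unname((cm["TP"] + cm["TN"]) / sum(cm)),
            sensitivity = unname(cm["TP"] / (cm["TP"] + cm["FN"])),
            specificity = unname(cm["TN"] / (cm["TN"] + cm["FP"])),
            ridge = model$ridge, status = "ok", stringsAsFactors = FALSE)
          if (config$train_accuracy) {
            row$train_acc <- mean(predict(model, Xtr) == as.character(ytr))
          }
          block[[bi]] <- row
        }
      }
    }
    chunks[[k]] <- do.call(rbind, block)
    n_done <- n_done + nrow(chunks[[k]])
    if (config$verbose) {
      message(sprintf("cardinality %d done: %d / %d tasks", k, n_done, expected))
    }
  }
  results <- do.call(rbind, chunks)
  rownames(results) <- NULL
  stopifnot(nrow(results) == expected)

  # rank: acc desc, then smaller subset, then lexicographic (zero-padded key)
  lex_key <- vapply(strsplit(results$subset, "+", fixed = TRUE),
                    function(s) paste(sprintf("%02d", as.integer(s)), collapse = "-"),
                    character(1))
  top <- lapply(stats::setNames(nm = config$kinds), function(kd) {
    r <- results[results$kind == kd & results$status == "ok", , drop = FALSE]
    key <- lex_key[results$kind == kd & results$status == "ok"]
    ord <- order(-r$acc, r$k, key)
    out <- r[ord[seq_len(min(config$top_k, nrow(r)))], , drop = FALSE]
    rownames(out) <- NULL
    out
  })

  structure(list(results = results, top = top, n_tasks = expected,
                 split = split, config = config),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> %d tasks (%d kinds, max cardinality %d)\n",
              x$n_tasks, length(x$config$kinds), x$config$max_cardinality))
  for (kd in names(x$top)) {
    t1 <- x$top[[kd]]
    if (nrow(t1)) {
      cat(sprintf("  %-13s best ACC = %.3f for {%s}\n", kd, t1$acc[1], t1$subset[1]))
    }
  }
  invisible(x)
}
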