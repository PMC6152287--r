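#' Cohort container
#'
#' A cohort is a table of patient-by-timepoint observations of the 21
#' parameters, together with the parameter catalog.  Healthy controls are
#' observed once (`timepoint == "single"`); diabetic patients exactly twice
#' (`"baseline"` and `"month6"`, i.e. before and after the six-month insulin
#' course).  `"day180"` is accepted as an alias of `"month6"` on input.
#'
#' @param data Data frame with columns `patient_id`, `group`
#'   (`"healthy"`/`"diabetic"`), `gender` (`"F"`/`"M"`), `timepoint`
#'   (`"single"`/`"baseline"`/`"month6"`) and numeric columns `w1`..`w21`.
#' @param catalog A [parameter_catalog()].
#' @return An object of class `cohort`: a list with elements `data` and
#'   `catalog`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
new_cohort <- function(data, catalog = parameter_catalog()) {
  assert_catalog(catalog)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if ("timepoint" %in% names(data)) {
    data$timepoint[data$timepoint == "day180"] <- "month6"
  }
  validate_cohort_data(data, catalog)
  out <- list(data = data, catalog = catalog)
  class(out) <- "cohort"
  out
}

w_columns <- function() paste0("w", 1:21)

#' @export
print.cohort <- function(x, ...) {
  d <- x$data
  nd <- length(unique(d$patient_id[d$group == "diabetic"]))
  nh <- length(unique(d$patient_id[d$group == "healthy"]))
  cat(sprintf("<cohort> %d records: %d diabetic patients (paired), %d healthy controls\n",
              nrow(d), nd, nh))
  invisible(x)
}

validate_cohort_data <- function(data, catalog) {
  required <- c("patient_id", "group", "gender", "timepoint", w_columns())
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  chk_enum <- function(field, allowed) {
    bad <- which(!(data[[field]] %in% allowed))
    if (length(bad)) {
      stop(sprintf("row %d: invalid %s %s (allowed: %s)",
                   bad[1], field, dQuote(data[[field]][bad[1]]),
                   paste(allowed, collapse = "/")), call. = FALSE)
    }
  }
  chk_enum("group", c("healthy", "diabetic"))
  chk_enum("gender", c("F", "M"))
  chk_enum("timepoint", c("single", "baseline", "month6"))

  bad <- which(data$group == "healthy" & data$timepoint != "single")
  if (length(bad)) {
    stop(sprintf("row %d: field timepoint: healthy subject with timepoint %s",
                 bad[1], dQuote(data$timepoint[bad[1]])), call. = FALSE)
  }
  bad <- which(data$group == "diabetic" & data$timepoint == "single")
  if (length(bad)) {
    stop(sprintf("row %d: field timepoint: diabetic patient with timepoint \"single\"",
                 bad[1]), call. = FALSE)
  }

  for (col in w_columns()) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      stop(sprintf("row %d: field %s: non-numeric value",
                   which(is.na(suppressWarnings(as.numeric(v))))[1], col),
           call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("row %d: field %s: missing or non-finite value",
                   which(!is.finite(v))[1], col), call. = FALSE)
    }
  }
  for (i in positive_parameters(catalog)) {
    col <- paste0("w", i)
    bad <- which(data[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("row %d: field %s: value must be strictly positive",
                   bad[1], col), call. = FALSE)
    }
  }

  key <- paste(data$patient_id, data$timepoint)
  if (anyDuplicated(key)) {
    stop(sprintf("row %d: duplicate (patient_id, timepoint) pair",
                 which(duplicated(key))[1]), call. = FALSE)
  }

  ids <- data$patient_id
  n_ids <- length(unique(ids))
  if (length(unique(paste(ids, data$group))) != n_ids) {
    first <- ids[!duplicated(paste(ids, data$group))]
    stop(sprintf("patient %s: group differs between rows",
                 first[duplicated(first)][1]), call. = FALSE)
  }
  if (length(unique(paste(ids, data$gender))) != n_ids) {
    first <- ids[!duplicated(paste(ids, data$gender))]
    stop(sprintf("patient %s: gender differs between rows",
                 first[duplicated(first)][1]), call. = FALSE)
  }
  hid <- ids[data$group == "healthy"]
  if (anyDuplicated(hid)) {
    stop(sprintf("patient %s: healthy subject with 2 timepoints (expected 1)",
                 hid[duplicated(hid)][1]), call. = FALSE)
  }
  db <- sort(ids[data$group == "diabetic" & data$timepoint == "baseline"])
  dm <- sort(ids[data$group == "diabetic" & data$timepoint == "month6"])
  if (!identical(db, dm)) {
    odd <- c(setdiff(db, dm), setdiff(dm, db))
    stop(sprintf("patient %s: diabetic patient with 1 timepoint (expected baseline and month6)",
                 odd[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cohort from CSV
#'
#' Expects a header row `patient_id,group,gender,timepoint,w1,...,w21`, comma
#' separator, `"."` decimal point.  Lines starting with `#` (provenance
#' headers written by [simulate_cohort()]) are ignored.  The table is fully
#' validated; malformed input raises an error naming the offending row and
#' field.  Missing values are not supported.
#'
#' @param path CSV file path.
#' @param catalog A [parameter_catalog()].
#' @return A [new_cohort()] object, row order preserved.
#' @export
read_cohort <- function(path, catalog = parameter_catalog()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character")
  required <- c("patient_id", "group", "gender", "timepoint", w_columns())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in w_columns()) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("row %d: field %s: non-numeric cell %s",
                   bad[1], col, dQuote(raw[[col]][bad[1]])), call. = FALSE)
    }
    raw[[col]] <- v
  }
  new_cohort(raw, catalog)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: numeric values are written with 15 significant
#' digits so that a read/write round trip reproduces the cohort to better
#' than 1e-12 relative error.
#'
#' @param cohort A `cohort`.
#' @param path Output path.
#' @param header Optional character vector of provenance lines, written as
#'   leading `#` comments.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, header = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  d <- cohort$data
  for (col in w_columns()) d[[col]] <- format(d[[col]], digits = 15, trim = TRUE)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
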