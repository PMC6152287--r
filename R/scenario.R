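group_timepoints <- function() c("healthy", "baseline", "month6")

#' Load a cohort simulation scenario
#'
#' A scenario bundles everything [generate_cohort()] needs: per-parameter
#' marginal summaries for each of the three group/timepoint arms (healthy
#' controls, untreated diabetics, diabetics after six months of therapy),
#' pairwise latent correlation targets, gender multipliers, and cohort
#' sizes.  Scenarios are YAML files; the packaged default
#' (`detemir_2017.yaml`) encodes the published summary table and pairwise
#' correlations of the insulin-detemir study cohort.
#'
#' @param path Path to a scenario YAML file, or `NULL` (default) for the
#'   packaged default scenario.
#' @param catalog A [parameter_catalog()].
#' @return A validated object of class `cohort_scenario`.
#' @examples
#' sc <- load_scenario()
#' sc$marginals$baseline[[20]]  # leptin in untreated diabetics
#' @export
load_scenario <- function(path = NULL, catalog = parameter_catalog()) {
  if (is.null(path)) {
    path <- system.file("extdata", "detemir_2017.yaml",
                        package = "adipodiscrim", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  sc <- as_cohort_scenario(raw, catalog)
  sc$path <- path
  sc
}

#' Construct a scenario from a plain list
#'
#' Validates and normalises the list representation of a scenario (the same
#' shape as the YAML file, see [load_scenario()]).  Marginal coverage must be
#' complete: every parameter 1..21 in each of the three arms, with a
#' mean/sd pair for normal-family parameters and a median/q1/q3 triple for
#' lognormal-family parameters.
#'
#' @param x List with elements `marginals`, and optionally `correlations`,
#'   `gender_effects`, `n_diabetic`, `n_healthy`, `fraction_female`,
#'   `within_patient_r`, `name`.
#' @param catalog A [parameter_catalog()].
#' @return An object of class `cohort_scenario`.
#' @export
as_cohort_scenario <- function(x, catalog = parameter_catalog()) {
  assert_catalog(catalog)
  gts <- group_timepoints()

  marg <- stats::setNames(
    lapply(gts, function(g) vector("list", 21L)), gts)
  for (m in x$marginals) {
    i <- as.integer(m$index)
    if (is.na(i) || i < 1L || i > 21L) stop("marginal with bad index", call. = FALSE)
    fam <- catalog$family[i]
    for (g in gts) {
      spec <- m[[g]]
      if (is.null(spec)) next
      if (fam == "normal") {
        if (is.null(spec$mean) || is.null(spec$sd)) {
          stop(sprintf("parameter w%d (%s): normal marginal needs mean and sd", i, g),
               call. = FALSE)
        }
        if (spec$sd < 0) stop(sprintf("parameter w%d (%s): sd < 0", i, g), call. = FALSE)
        marg[[g]][[i]] <- list(family = "normal",
                               mean = as.numeric(spec$mean),
                               sd = as.numeric(spec$sd))
      } else {
        if (is.null(spec$median) || is.null(spec$q1) || is.null(spec$q3)) {
          stop(sprintf("parameter w%d (%s): lognormal marginal needs median, q1, q3", i, g),
               call. = FALSE)
        }
        p <- lognormal_params_from_quartiles(spec$median, spec$q1, spec$q3)
        marg[[g]][[i]] <- list(family = "lognormal",
                               median = as.numeric(spec$median),
                               q1 = as.numeric(spec$q1),
                               q3 = as.numeric(spec$q3),
                               mu = unname(p["mu"]), sigma = unname(p["sigma"]))
      }
    }
  }
  for (g in gts) {
    miss <- which(vapply(marg[[g]], is.null, logical(1)))
    if (length(miss)) {
      stop(sprintf("scenario is missing marginal(s) for arm %s: %s",
                   g, paste0("w", miss, collapse = ", ")), call. = FALSE)
    }
  }

  corr <- stats::setNames(lapply(gts, function(g)
    data.frame(i = integer(), j = integer(), r = numeric())), gts)
  default_r <- 0
  if (!is.null(x$correlations)) {
    default_r <- if (is.null(x$correlations$default_r)) 0 else x$correlations$default_r
    for (t in x$correlations$targets) {
      grps <- if (is.null(t$groups)) gts else unlist(t$groups)
      bad <- setdiff(grps, gts)
      if (length(bad)) stop("unknown correlation group: ", bad[1], call. = FALSE)
      for (g in grps) {
        corr[[g]] <- rbind(corr[[g]],
                           data.frame(i = as.integer(t$i), j = as.integer(t$j),
                                      r = as.numeric(t$r)))
      }
    }
  }

  gmult <- stats::setNames(lapply(gts, function(g) rep(1, 21L)), gts)
  for (e in x$gender_effects) {
    grps <- if (is.null(e$groups)) gts else unlist(e$groups)
    for (g in grps) {
      if (e$multiplier <= 0) stop("gender multiplier must be > 0", call. = FALSE)
      gmult[[g]][as.integer(e$index)] <- as.numeric(e$multiplier)
    }
  }

  num_or <- function(v, d) if (is.null(v)) d else as.numeric(v)
  sc <- list(
    name = if (is.null(x$name)) "unnamed" else x$name,
    n_diabetic = as.integer(num_or(x$n_diabetic, 40)),
    n_healthy = as.integer(num_or(x$n_healthy, 27)),
    fraction_female = num_or(x$fraction_female, 0.5),
    within_patient_r = num_or(x$within_patient_r, 0.8),
    marginals = marg,
    corr_targets = corr,
    default_r = default_r,
    gender_multipliers = gmult,
    catalog = catalog
  )
  if (sc$fraction_female < 0 || sc$fraction_female > 1) {
    stop("fraction_female must be in [0, 1]", call. = FALSE)
  }
  if (sc$within_patient_r < 0 || sc$within_patient_r >= 1) {
    stop("within_patient_r must be in [0, 1)", call. = FALSE)
  }
  class(sc) <- "cohort_scenario"
  sc
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat(sprintf("<cohort_scenario> %s: %d diabetic (paired) + %d healthy, %.0f%% female, within-patient r = %.2f\n",
              x$name, x$n_diabetic, x$n_healthy, 100 * x$fraction_female,
              x$within_patient_r))
  invisible(x)
}
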