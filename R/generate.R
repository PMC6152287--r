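# deterministic substream seed for one patient: keeps earlier patients'
# draws fixed when the cohort is enlarged.  All intermediates stay < 2^53.
substream_seed <- function(master, stream, counter) {
  as.integer((master %% 2147483629) * 69069 + stream * 40503 + counter) %% 2147483629L
}

# per-gender multiplicative factors (a_F, a_M) normalised so the gender
# mixture keeps the arm mean: a_F = g*c, a_M = c, c = 1/(f*g + 1 - f).
gender_factors <- function(g, f) {
  cc <- 1 / (f * g + 1 - f)
  c(F = g * cc, M = cc)
}

#' Generate a synthetic cohort by Gaussian copula
#'
#' Draws a cohort with the dependence and marginal structure of the study:
#' per arm (healthy / untreated diabetic / month-6 diabetic), a 21-variate
#' latent normal with the scenario's correlation matrix is transformed
#' through each parameter's marginal quantile function (normal or
#' lognormal).  For a diabetic patient the baseline and month-6 latent
#' vectors share a common factor with weight `within_patient_r`, producing
#' paired observations; the two timepoints' marginals are the arms' own
#' published summaries, so the treatment effect is induced by the marginal
#' shift, not by an additive term.
#'
#' Gender multipliers (female-to-male ratio per parameter and arm) are
#' applied as a two-point mixture that preserves the arm mean exactly; for
#' normal-family parameters the within-gender SD is shrunk so the pooled SD
#' is preserved as well.  Draws for the handful of strictly positive
#' normal-family parameters (weight through HbA1c) falling at or below zero
#' are rejected and redrawn coordinate-wise; under the packaged scenario
#' every such mean sits more than 9 SD above zero, so this path is
#' essentially never taken.
#'
#' Reproducibility: each patient consumes an independent substream derived
#' from `seed` and the patient counter, so the first `k` patients of an
#' `n`-patient cohort are identical to a `k`-patient cohort at the same
#' seed.
#'
#' @param scenario A `cohort_scenario` from [load_scenario()] or
#'   [as_cohort_scenario()].
#' @param n_diabetic,n_healthy Cohort sizes (defaults from the scenario).
#' @param fraction_female,within_patient_r Overrides for the scenario values.
#' @param seed Integer master seed.
#' @return A [new_cohort()] with `n_healthy + 2 * n_diabetic` records:
#'   healthy subjects first, then baseline/month-6 row pairs per diabetic
#'   patient.
#' @examples
#' coh <- generate_cohort(load_scenario(), n_diabetic = 5, n_healthy = 3, seed = 1)
#' coh$data[, 1:6]
#' @export
generate_cohort <- function(scenario,
                            n_diabetic = scenario$n_diabetic,
                            n_healthy = scenario$n_healthy,
                            fraction_female = scenario$fraction_female,
                            within_patient_r = scenario$within_patient_r,
                            seed = 1L) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  if (n_diabetic < 0 || n_healthy < 0) stop("cohort sizes must be >= 0", call. = FALSE)
  if (n_diabetic + n_healthy == 0) stop("empty cohort requested", call. = FALSE)
  catalog <- scenario$catalog
  rho <- within_patient_r

  R <- lapply(group_timepoints(), function(g)
    build_latent_correlation(scenario$corr_targets[[g]], p = 21L,
                             default_r = scenario$default_r))
  names(R) <- group_timepoints()
  S <- lapply(R, sqrtm_psd)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  draw_block <- function(n, stream, ncols) {
    U <- matrix(0, n, ncols)
    sex <- character(n)
    for (i in seq_len(n)) {
      set.seed(substream_seed(seed, stream, i))
      sex[i] <- if (stats::runif(1) < fraction_female) "F" else "M"
      U[i, ] <- stats::rnorm(ncols)
    }
    list(U = U, sex = sex)
  }

  # marginal transform of one latent column for one arm
  transform_col <- function(z, i, gt, sex) {
    m <- scenario$marginals[[gt]][[i]]
    g <- scenario$gender_multipliers[[gt]][i]
    a <- rep(1, length(z))
    if (g != 1 && fraction_female > 0 && fraction_female < 1) {
      fac <- gender_factors(g, fraction_female)
      a <- ifelse(sex == "F", fac["F"], fac["M"])
    }
    if (m$family == "normal") {
      sw <- m$sd
      if (any(a != 1)) {
        ea2 <- fraction_female * gender_factors(g, fraction_female)["F"]^2 +
          (1 - fraction_female) * gender_factors(g, fraction_female)["M"]^2
        sw2 <- (m$sd^2 + m$mean^2) / ea2 - m$mean^2
        if (sw2 < 0) {
          stop(sprintf(
            "gender multiplier %.3g for w%d (%s) is incompatible with sd %.3g",
            g, i, gt, m$sd), call. = FALSE)
        }
        sw <- sqrt(sw2)
      }
      a * (m$mean + sw * z)
    } else {
      a * exp(m$mu + m$sigma * z)
    }
  }

  pos_set <- positive_parameters(catalog)

  arm_values <- function(Z, gt, sex) {
    V <- matrix(0, nrow(Z), 21L)
    for (i in 1:21) V[, i] <- transform_col(Z[, i], i, gt, sex)
    V
  }

  # coordinate-wise rejection for strictly positive normal-family parameters
  fix_positivity <- function(V, gt, sex) {
    for (i in intersect(pos_set, which(catalog$family == "normal"))) {
      guard <- 0
      while (any(bad <- V[, i] <= 0)) {
        V[bad, i] <- transform_col(stats::rnorm(sum(bad)), i, gt, sex[bad])
        guard <- guard + 1
        if (guard > 1000) {
          stop(sprintf("positivity rejection did not converge for w%d (%s)", i, gt),
               call. = FALSE)
        }
      }
    }
    V
  }

  rows <- list()

  if (n_healthy > 0) {
    h <- draw_block(n_healthy, stream = 1L, ncols = 21L)
    Zh <- h$U %*% S[["healthy"]]
    set.seed(substream_seed(seed, 3L, 0L)) # auxiliary stream for rejections
    Vh <- fix_positivity(arm_values(Zh, "healthy", h$sex), "healthy", h$sex)
    dh <- data.frame(patient_id = sprintf("H%05d", seq_len(n_healthy)),
                     group = "healthy", gender = h$sex, timepoint = "single",
                     stringsAsFactors = FALSE)
    dh[w_columns()] <- as.data.frame(Vh)
    rows$healthy <- dh
  }

  if (n_diabetic > 0) {
    d <- draw_block(n_diabetic, stream = 2L, ncols = 42L)
    U <- d$U[, 1:21, drop = FALSE]
    V <- d$U[, 22:42, drop = FALSE]
    Zb <- U %*% S[["baseline"]]
    Zm <- (rho * U + sqrt(1 - rho^2) * V) %*% S[["month6"]]
    set.seed(substream_seed(seed, 3L, 1L))
    Vb <- fix_positivity(arm_values(Zb, "baseline", d$sex), "baseline", d$sex)
    Vm <- fix_positivity(arm_values(Zm, "month6", d$sex), "month6", d$sex)
    ids <- sprintf("D%05d", seq_len(n_diabetic))
    db <- data.frame(patient_id = ids, group = "diabetic", gender = d$sex,
                     timepoint = "baseline", stringsAsFactors = FALSE)
    db[w_columns()] <- as.data.frame(Vb)
    dm <- db
    dm$timepoint <- "month6"
    dm[w_columns()] <- as.data.frame(Vm)
    # interleave baseline/month6 per patient
    idx <- as.vector(rbind(seq_len(n_diabetic), n_diabetic + seq_len(n_diabetic)))
    rows$diabetic <- rbind(db, dm)[idx, , drop = FALSE]
  }

  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  new_cohort(data, catalog)
}
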