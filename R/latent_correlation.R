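#' Lognormal parameters from median and quartiles
#'
#' Skewed analytes (urinary albumin, insulin, HOMA indices) are published as
#' median (Q1--Q3).  Under a lognormal model, `log X` is normal with
#' `mu = log(median)` and `sigma = log(q3/q1) / (2 * qnorm(0.75))`, so the
#' implied distribution reproduces the median exactly and the quartile ratio
#' `q3/q1` exactly.  Degenerate input (`q1 == median == q3`) yields a point
#' mass (`sigma = 0`).
#'
#' @param median,q1,q3 Positive reals with `q1 <= median <= q3`.
#' @return Named numeric vector `c(mu, sigma)`.
#' @examples
#' p <- lognormal_params_from_quartiles(10.6, 4.7, 23.8) # fasting insulin
#' qlnorm(c(.25, .75), p[["mu"]], p[["sigma"]])          # 4.7, 23.8
#' @export
lognormal_params_from_quartiles <- function(median, q1, q3) {
  if (!all(is.finite(c(median, q1, q3))) || any(c(median, q1, q3) <= 0)) {
    stop("median, q1, q3 must be finite and strictly positive", call. = FALSE)
  }
  if (q1 > median || median > q3) {
    stop("quartiles must satisfy q1 <= median <= q3", call. = FALSE)
  }
  c(mu = log(median), sigma = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Assemble a latent correlation matrix from pairwise targets
#'
#' Builds the 21x21 (or `p` x `p`) correlation matrix of the Gaussian copula
#' from a list of pairwise targets, filling unspecified pairs with
#' `default_r`.  If the assembled matrix is not positive semi-definite it is
#' repaired by projection onto the nearest correlation matrix
#' (Higham's alternating projections, via [Matrix::nearPD]).
#'
#' @param targets Data frame with columns `i`, `j` (parameter indices) and
#'   `r` (target correlations, `|r| < 1`).  May have zero rows.
#' @param p Matrix dimension (default 21).
#' @param default_r Correlation assigned to unspecified pairs (default 0).
#' @return A `p` x `p` symmetric PSD matrix with unit diagonal.  Attributes:
#'   `repaired` (logical) and `min_eigenvalue` of the raw matrix.
#' @export
build_latent_correlation <- function(targets, p = 21L, default_r = 0) {
  R <- matrix(default_r, p, p)
  diag(R) <- 1
  if (!is.null(targets) && nrow(targets) > 0) {
    if (!all(c("i", "j", "r") %in% names(targets))) {
      stop("`targets` needs columns i, j, r", call. = FALSE)
    }
    key <- paste(pmin(targets$i, targets$j), pmax(targets$i, targets$j))
    for (k in unique(key[duplicated(key)])) {
      rs <- targets$r[key == k]
      if (length(unique(rs)) > 1L) {
        stop("conflicting correlation targets for pair (", k, "): ",
             paste(rs, collapse = " vs "), call. = FALSE)
      }
    }
    if (any(targets$i == targets$j)) stop("target pair on the diagonal", call. = FALSE)
    if (any(abs(targets$r) >= 1)) stop("|r| must be < 1", call. = FALSE)
    if (any(targets$i < 1 | targets$i > p | targets$j < 1 | targets$j > p)) {
      stop("target index outside 1..", p, call. = FALSE)
    }
    for (k in seq_len(nrow(targets))) {
      R[targets$i[k], targets$j[k]] <- targets$r[k]
      R[targets$j[k], targets$i[k]] <- targets$r[k]
    }
  }
  min_eig <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  repaired <- FALSE
  if (min_eig < -1e-10) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE, conv.tol = 1e-10,
                                  maxit = 500)$mat)
    repaired <- TRUE
  }
  # clip any residual tiny negative eigenvalue from numerics
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 0) {
    R <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
    s <- sqrt(diag(R))
    R <- R / tcrossprod(s)
  }
  R <- (R + t(R)) / 2
  diag(R) <- 1
  dimnames(R) <- list(paste0("w", 1:p), paste0("w", 1:p))
  attr(R, "repaired") <- repaired
  attr(R, "min_eigenvalue") <- min_eig
  R
}

# symmetric PSD square root (eigendecomposition; p is small)
sqrtm_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}
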