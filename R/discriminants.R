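#' Ridge policy for near-singular covariance estimates
#'
#' With d features and only a couple of dozen training observations per
#' class, stratified covariance estimates are frequently ill-conditioned.
#' When a required covariance matrix has condition number above `max_cond`,
#' `lambda * mean(diag) ` is added to the diagonal, with `lambda` escalating
#' by `factor` from `lambda0` up to `lambda_max`.  Under `strict = TRUE` no
#' ridge is applied and the fit fails instead (so a subset search can mark
#' the task failed and move on).
#'
#' @param lambda0 Initial ridge fraction (default 1e-6).
#' @param lambda_max Largest ridge fraction tried (default 1e-2).
#' @param factor Escalation factor (default 10).
#' @param max_cond Condition-number threshold (default 1e12).
#' @param strict If `TRUE`, a singular fit is an error rather than ridged.
#' @return List of class `ridge_policy`.
#' @export
ridge_policy <- function(lambda0 = 1e-6, lambda_max = 1e-2, factor = 10,
                         max_cond = 1e12, strict = FALSE) {
  stopifnot(lambda0 > 0, lambda_max >= lambda0, factor > 1, max_cond > 1)
  structure(list(lambda0 = lambda0, lambda_max = lambda_max, factor = factor,
                 max_cond = max_cond, strict = strict),
            class = "ridge_policy")
}

discriminant_kinds <- function() {
  c("linear", "diaglinear", "quadratic", "diagquadratic", "mahalanobis")
}

# condition number of a symmetric PSD matrix from its eigenvalues
sym_condition <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}

regularize_cov <- function(S, policy, what) {
  lambda_used <- 0
  if (sym_condition(S) > policy$max_cond) {
    if (policy$strict) {
      stop(sprintf("singular %s covariance (strict ridge policy)", what),
           call. = FALSE)
    }
    lambda <- policy$lambda0
    tr_d <- mean(diag(S))
    if (tr_d <= 0) tr_d <- 1
    repeat {
      S2 <- S + lambda * tr_d * diag(nrow(S))
      if (sym_condition(S2) <= policy$max_cond || lambda >= policy$lambda_max) {
        S <- S2
        lambda_used <- lambda
        break
      }
      lambda <- lambda * policy$factor
    }
    if (sym_condition(S) > policy$max_cond) {
      stop(sprintf("%s covariance still singular at lambda = %g", what, lambda_used),
           call. = FALSE)
    }
  }
  list(S = S, lambda = lambda_used)
}

#' Fit a two-class Gaussian discriminant
#'
#' Implements the five classical variants from their density and distance
#' formulas:
#' \describe{
#'   \item{linear}{multivariate normal per class with a pooled covariance
#'     estimate (LDA);}
#'   \item{diaglinear}{pooled covariance diagonalised (Gaussian naive
#'     Bayes with shared variances);}
#'   \item{quadratic}{per-class (stratified) covariance estimates (QDA);}
#'   \item{diagquadratic}{stratified covariances diagonalised (Gaussian
#'     naive Bayes);}
#'   \item{mahalanobis}{nearest class by Mahalanobis distance under the
#'     stratified covariances, ignoring priors and determinants.}
#' }
#' Class means are sample means; priors are empirical class frequencies (or
#' uniform); covariances use unbiased denominators, `n_k - 1` per class and
#' `n - 2` pooled.
#'
#' @param x Numeric matrix, `n` observations by `d` features.
#' @param y Class labels, exactly 2 distinct values, each with at least 2
#'   observations.  The first class in sorted order (or factor-level order)
#'   is the tie-break winner in [predict.discriminant_model()].
#' @param kind One of `"linear"`, `"diaglinear"`, `"quadratic"`,
#'   `"diagquadratic"`, `"mahalanobis"`.
#' @param priors `"empirical"` (default) or `"uniform"`.
#' @param policy A [ridge_policy()].
#' @return Object of class `discriminant_model`: kind, classes, priors,
#'   means (2 x d), covariance(s), and the ridge `lambda` actually applied.
#' @export
discriminant_fit <- function(x, y, kind = discriminant_kinds(),
                             priors = c("empirical", "uniform"),
                             policy = ridge_policy()) {
  kind <- match.arg(kind)
  priors <- match.arg(priors)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  classes <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(as.character(y)))
  y <- as.character(y)
  if (length(classes) != 2L) {
    stop("exactly 2 classes required, got ", length(classes), call. = FALSE)
  }
  n_k <- table(factor(y, levels = classes))
  if (any(n_k < 2L)) {
    stop("each class needs at least 2 observations", call. = FALSE)
  }
  d <- ncol(x)
  mu <- matrix(0, 2L, d, dimnames = list(classes, colnames(x)))
  for (j in 1:2) mu[j, ] <- colMeans(x[y == classes[j], , drop = FALSE])
  pri <- if (priors == "empirical") as.numeric(n_k) / length(y) else c(0.5, 0.5)
  S_k <- lapply(classes, function(k) {
    xc <- x[y == k, , drop = FALSE]
    crossprod(sweep(xc, 2, colMeans(xc))) / (nrow(xc) - 1)
  })
  names(S_k) <- classes

  lambda <- 0
  if (kind %in% c("linear", "diaglinear")) {
    S <- Reduce(`+`, Map(function(S, n) (n - 1) * S, S_k, as.list(as.numeric(n_k)))) /
      (length(y) - 2)
    if (kind == "diaglinear") S <- diag(diag(S), d)
    reg <- regularize_cov(S, policy, kind)
    cov <- list(pooled = reg$S)
    lambda <- reg$lambda
  } else {
    if (kind == "diagquadratic") S_k <- lapply(S_k, function(S) diag(diag(S), d))
    regs <- lapply(seq_along(S_k), function(j)
      regularize_cov(S_k[[j]], policy, paste0(kind, " class ", classes[j])))
    cov <- stats::setNames(lapply(regs, `[[`, "S"), classes)
    lambda <- max(vapply(regs, `[[`, numeric(1), "lambda"))
  }

  structure(list(kind = kind, classes = classes, priors = pri, means = mu,
                 cov = cov, ridge = lambda, d = d),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s, classes %s vs %s, d = %d, priors %.3f/%.3f%s\n",
              x$kind, x$classes[1], x$classes[2], x$d, x$priors[1], x$priors[2],
              if (x$ridge > 0) sprintf(", ridge lambda = %g", x$ridge) else ""))
  invisible(x)
}

#' Per-class decision values
#'
#' Returns the discriminant score of each observation for each class.  For
#' the pooled-covariance kinds this is the linear discriminant function
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`; for the stratified kinds
#' the quadratic score `-log det(S_k)/2 - (x - mu_k)' S_k^-1 (x - mu_k)/2 +
#' log pi_k`; for `mahalanobis` the negated squared Mahalanobis distance
#' (no determinant, no prior).  Classification takes the column-wise
#' maximum.
#'
#' @param model A `discriminant_model`.
#' @param x Numeric matrix, `m` x `d`.
#' @return An `m` x 2 matrix, columns named by class.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "discriminant_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$d) {
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 model$d, ncol(x)), call. = FALSE)
  }
  out <- matrix(0, nrow(x), 2L, dimnames = list(NULL, model$classes))
  if (model$kind %in% c("linear", "diaglinear")) {
    Sinv <- solve(model$cov$pooled)
    for (j in 1:2) {
      mu <- model$means[j, ]
      a <- Sinv %*% mu
      out[, j] <- x %*% a - 0.5 * sum(mu * a) + log(model$priors[j])
    }
  } else {
    for (j in 1:2) {
      mu <- model$means[j, ]
      S <- model$cov[[j]]
      Sinv <- solve(S)
      xc <- sweep(x, 2, mu)
      maha <- rowSums((xc %*% Sinv) * xc)
      out[, j] <- if (model$kind == "mahalanobis") {
        -maha
      } else {
        -0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) - 0.5 * maha +
          log(model$priors[j])
      }
    }
  }
  out
}

#' Predict class labels
#'
#' Argmax of the two decision values; exact ties go to the first listed
#' class (deterministic).
#'
#' @param object A `discriminant_model`.
#' @param x Numeric matrix, `m` x `d`.
#' @param ... Unused.
#' @return Character vector of `m` predicted labels.
#' @export
predict.discriminant_model <- function(object, x, ...) {
  dv <- decision_values(object, x)
  unname(ifelse(dv[, 1] >= dv[, 2], object$classes[1], object$classes[2]))
}

#' Serialize a discriminant model to JSON
#'
#' Audit trail for fitted models: kind, classes, priors, means, covariance
#' matrices and the ridge actually applied.
#'
#' @param model A `discriminant_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly if written to `path`).
#' @export
discriminant_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "discriminant_model"))
  obj <- list(kind = model$kind, classes = model$classes,
              priors = model$priors, means = model$means,
              cov = lapply(model$cov, unclass), ridge = model$ridge)
  js <- jsonlite::toJSON(obj, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
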