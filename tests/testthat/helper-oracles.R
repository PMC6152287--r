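# brute-force reference used throughout: class scores from first principles
# (plain Gaussian log-density via determinant() and solve(), plus the
# Mahalanobis distance rule), computed independently of the fitting code.
oracle_scores <- function(kind, x, mu, S_list, priors) {
  x <- as.matrix(x)
  out <- matrix(0, nrow(x), 2)
  for (j in 1:2) {
    S <- S_list[[j]]
    xc <- sweep(x, 2, mu[j, ])
    maha <- rowSums((xc %*% solve(S)) * xc)
    out[, j] <- if (kind == "mahalanobis") {
      -maha
    } else {
      -0.5 * ncol(x) * log(2 * pi) -
        0.5 * as.numeric(determinant(S, logarithm = TRUE)$modulus) -
        0.5 * maha + log(priors[j])
    }
  }
  out
}

# per-kind covariance estimates from first principles
oracle_covs <- function(kind, x, y, classes) {
  by_class <- lapply(classes, function(k) x[y == k, , drop = FALSE])
  S_k <- lapply(by_class, function(m) stats::cov(m))
  n_k <- vapply(by_class, nrow, integer(1))
  if (kind %in% c("linear", "diaglinear")) {
    S <- ((n_k[1] - 1) * S_k[[1]] + (n_k[2] - 1) * S_k[[2]]) / (sum(n_k) - 2)
    if (kind == "diaglinear") S <- diag(diag(S), ncol(x))
    list(S, S)
  } else {
    if (kind == "diagquadratic") S_k <- lapply(S_k, function(S) diag(diag(S), ncol(x)))
    S_k
  }
}
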