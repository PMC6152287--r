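test_that("one-dimensional fit matches the hand-computed pooled model", {
  x <- matrix(c(-1, -1, 1, 1, 3, 3, 5, 5), ncol = 1)
  y <- rep(c("A", "B"), each = 4)
  m <- discriminant_fit(x, y, kind = "linear")
  expect_equal(unname(m$means[, 1]), c(0, 4))
  expect_equal(m$priors, c(0.5, 0.5))
  expect_equal(unname(m$cov$pooled[1, 1]), 4 / 3) # per-class var 4/3, pooled

  # midpoint is equidistant: decision values tie, first class wins
  dv <- decision_values(m, matrix(2))
  expect_equal(unname(dv[1, 1]), unname(dv[1, 2]))
  expect_equal(predict(m, matrix(2)), "A")
  expect_equal(predict(m, matrix(c(1.9, 2.1), ncol = 1)), c("A", "B"))
})

test_that("identical class covariances collapse quadratic onto linear", {
  withr::with_seed(31, {
    x1 <- matrix(rnorm(40), ncol = 2)
    x <- rbind(x1, sweep(x1, 2, c(3, -1), `+`)) # class B is a pure shift
    y <- rep(c("A", "B"), each = 20)
    lin <- discriminant_fit(x, y, "linear")
    quad <- discriminant_fit(x, y, "quadratic")
    expect_equal(quad$cov$A, quad$cov$B)
    expect_equal(quad$cov$A, lin$cov$pooled)
    grid <- matrix(rnorm(200), ncol = 2)
    expect_identical(predict(quad, grid), predict(lin, grid))

    dl <- discriminant_fit(x, y, "diaglinear")
    expect_equal(dl$cov$pooled, diag(diag(lin$cov$pooled), 2))
  })
})

test_that("decision values agree with the Gaussian log-density oracle", {
  withr::with_seed(32, {
    for (rep in 1:20) {
      d <- sample(1:3, 1)
      n <- sample(10:30, 1)
      x <- matrix(rnorm(2 * n * d), ncol = d)
      y <- rep(c("A", "B"), each = n)
      x[y == "B", ] <- x[y == "B", ] + 1
      grid <- matrix(rnorm(15 * d), ncol = d)
      for (kind in c("linear", "diaglinear", "quadratic", "diagquadratic",
                     "mahalanobis")) {
        m <- discriminant_fit(x, y, kind)
        dv <- decision_values(m, grid)
        or <- oracle_scores(kind, grid, m$means,
                            oracle_covs(kind, x, y, c("A", "B")), m$priors)
        # scores match up to a class-independent offset per row
        expect_equal(dv[, 1] - dv[, 2], or[, 1] - or[, 2], tolerance = 1e-9)
      }
    }
  })
})

test_that("a point at a class mean is claimed by that class (mahalanobis)", {
  withr::with_seed(33, {
    x <- matrix(rnorm(60), ncol = 2)
    y <- rep(c("A", "B"), each = 15)
    x[y == "B", ] <- x[y == "B", ] + 5
    m <- discriminant_fit(x, y, "mahalanobis")
    dv <- decision_values(m, m$means)
    expect_equal(unname(dv[1, 1]), 0)
    expect_equal(unname(dv[2, 2]), 0)
    expect_equal(predict(m, m$means), c("A", "B"))
  })
})

test_that("well-separated classes are perfectly recovered by all kinds", {
  withr::with_seed(34, {
    x <- rbind(matrix(rnorm(40), ncol = 2),
               matrix(rnorm(40, mean = 10), ncol = 2))
    y <- rep(c("A", "B"), each = 20)
    for (kind in c("linear", "diaglinear", "quadratic", "diagquadratic",
                   "mahalanobis")) {
      m <- discriminant_fit(x, y, kind)
      expect_identical(predict(m, x), y)
    }
  })
})

test_that("predictions equal the brute-force rule on many random instances", {
  withr::with_seed(35, {
    n_checked <- 0
    for (case in 1:120) {
      d <- sample(1:3, 1)
      n1 <- sample(5:30, 1)
      n2 <- sample(5:30, 1)
      x <- rbind(matrix(rnorm(n1 * d), ncol = d),
                 matrix(rnorm(n2 * d, mean = runif(1, 0, 2),
                              sd = runif(1, 0.5, 2)), ncol = d))
      y <- c(rep("A", n1), rep("B", n2))
      test_x <- matrix(rnorm(10 * d, sd = 2), ncol = d)
      for (kind in c("linear", "diaglinear", "quadratic", "diagquadratic",
                     "mahalanobis")) {
        m <- discriminant_fit(x, y, kind)
        or <- oracle_scores(kind, test_x, m$means,
                            oracle_covs(kind, x, y, c("A", "B")), m$priors)
        expect_identical(predict(m, test_x),
                         ifelse(or[, 1] >= or[, 2], "A", "B"))
        n_checked <- n_checked + 1
      }
    }
    expect_gte(n_checked, 500)
  })
})

test_that("linear and quadratic predictions match MASS on random instances", {
  skip_if_not_installed("MASS")
  withr::with_seed(36, {
    for (case in 1:50) {
      d <- sample(1:3, 1)
      n <- sample(8:30, 1)
      x <- rbind(matrix(rnorm(n * d), ncol = d),
                 matrix(rnorm(n * d, mean = 1.5), ncol = d))
      y <- rep(c("A", "B"), each = n)
      test_x <- matrix(rnorm(12 * d, sd = 2), ncol = d)
      colnames(x) <- colnames(test_x) <- paste0("v", 1:d)

      m <- discriminant_fit(x, y, "linear")
      ref <- MASS::lda(x, grouping = y)
      expect_identical(predict(m, test_x),
                       as.character(predict(ref, test_x)$class))

      mq <- discriminant_fit(x, y, "quadratic")
      refq <- MASS::qda(x, grouping = y)
      expect_identical(predict(mq, test_x),
                       as.character(predict(refq, test_x)$class))
    }
  })
})

test_that("predictions are invariant under invertible affine maps", {
  withr::with_seed(37, {
    d <- 3
    x <- rbind(matrix(rnorm(60), ncol = d), matrix(rnorm(60, 1), ncol = d))
    y <- rep(c("A", "B"), each = 20)
    test_x <- matrix(rnorm(30), ncol = d)
    A <- matrix(rnorm(9), 3) + 3 * diag(3)
    b <- c(2, -1, 0.5)
    tx <- function(m) sweep(m %*% t(A), 2, b, `+`)
    for (kind in c("linear", "diaglinear", "quadratic", "diagquadratic",
                   "mahalanobis")) {
      p0 <- predict(discriminant_fit(x, y, kind), test_x)
      p1 <- predict(discriminant_fit(tx(x), y, kind), tx(test_x))
      if (kind %in% c("diaglinear", "diagquadratic")) {
        # diagonalised covariances are equivariant only under diagonal maps
        D <- diag(c(2, 0.5, 3))
        txd <- function(m) sweep(m %*% D, 2, b, `+`)
        p1 <- predict(discriminant_fit(txd(x), y, kind), txd(test_x))
      }
      expect_identical(p1, p0)
    }
  })
})

test_that("mahalanobis equals the quadratic argmax at equal priors and determinants", {
  withr::with_seed(38, {
    d <- 2
    x1 <- matrix(rnorm(80), ncol = d)
    th <- pi / 5
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) # rotation: det kept
    x2 <- matrix(rnorm(80), ncol = d) %*% R + 1.2
    x <- rbind(x1, x2)
    y <- rep(c("A", "B"), each = 40)
    test_x <- matrix(rnorm(60, sd = 2), ncol = d)
    mq <- discriminant_fit(x, y, "quadratic")
    mm <- discriminant_fit(x, y, "mahalanobis")
    det_ratio <- det(mq$cov$A) / det(mq$cov$B)
    # sample determinants are close but not equal; compare on the points
    # where the determinant term cannot flip the decision
    dvq <- decision_values(mq, test_x)
    dvm <- decision_values(mm, test_x)
    margin <- abs(dvm[, 1] - dvm[, 2]) / 2
    clear <- margin > abs(0.5 * log(det_ratio))
    expect_gt(mean(clear), 0.8)
    expect_identical(predict(mq, test_x)[clear], predict(mm, test_x)[clear])
  })
})

test_that("diagonal-variant predictions converge to full variants on diagonal data", {
  withr::with_seed(39, {
    n <- 10000
    d <- 3
    x <- rbind(matrix(rnorm(n * d, sd = rep(c(1, 2, 0.5), each = n)), ncol = d),
               matrix(rnorm(n * d, mean = 0.6, sd = rep(c(1, 2, 0.5), each = n)),
                      ncol = d))
    y <- rep(c("A", "B"), each = n)
    test_x <- matrix(rnorm(3000, sd = 1.5), ncol = d)
    p_full <- predict(discriminant_fit(x, y, "linear"), test_x)
    p_diag <- predict(discriminant_fit(x, y, "diaglinear"), test_x)
    expect_lt(mean(p_full != p_diag), 0.01)
    q_full <- predict(discriminant_fit(x, y, "quadratic"), test_x)
    q_diag <- predict(discriminant_fit(x, y, "diagquadratic"), test_x)
    expect_lt(mean(q_full != q_diag), 0.01)
  })
})

test_that("singular covariances are ridged (and refused under strict policy)", {
  withr::with_seed(40, {
    base <- matrix(rnorm(40), ncol = 2)
    x <- cbind(base, base[, 1]) # third column duplicates the first
    y <- rep(c("A", "B"), each = 10)
    m <- discriminant_fit(x, y, "linear")
    expect_gt(m$ridge, 0)
    expect_length(predict(m, x), 20)

    expect_error(
      discriminant_fit(x, y, "linear", policy = ridge_policy(strict = TRUE)),
      "singular")
    expect_error(
      discriminant_fit(x, y, "quadratic", policy = ridge_policy(strict = TRUE)),
      "singular")
  })
})

test_that("degenerate class sizes and priors are handled", {
  x <- matrix(1:10, ncol = 1)
  expect_error(discriminant_fit(x, c("A", rep("B", 9)), "linear"),
               "at least 2")
  expect_error(discriminant_fit(x, rep("A", 10), "linear"), "2 classes")

  y <- c(rep("A", 4), rep("B", 6))
  m <- discriminant_fit(x, y, "linear")
  expect_equal(m$priors, c(0.4, 0.6))
  mu <- discriminant_fit(x, y, "linear", priors = "uniform")
  expect_equal(mu$priors, c(0.5, 0.5))
})

test_that("models serialize to JSON with full audit detail", {
  withr::with_seed(41, {
    x <- matrix(rnorm(40), ncol = 2)
    y <- rep(c("A", "B"), each = 10)
    m <- discriminant_fit(x, y, "quadratic")
    js <- jsonlite::fromJSON(discriminant_to_json(m))
    expect_equal(js$kind, "quadratic")
    expect_equal(js$classes, c("A", "B"))
    expect_equal(unname(as.matrix(js$means)), unname(m$means))
    expect_equal(unname(as.matrix(js$cov$A)), unname(m$cov$A), tolerance = 1e-12)
  })
})
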