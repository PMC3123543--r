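test_that("standardize centers, scales, and inverts exactly", {
  m <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2, dimnames = list(NULL, c("a", "b")))
  s <- standardize(m)
  expect_equal(s$values[, "a"], c(-1, 0, 1))
  expect_equal(s$means[["a"]], 2)
  expect_equal(s$sds[["a"]], 1)
  back <- sweep(sweep(s$values, 2, s$sds, "*"), 2, s$means, "+")
  expect_equal(back, m, tolerance = 1e-12)

  m2 <- cbind(m, konst = c(5, 5, 5))
  expect_error(standardize(m2), "konst")
})

test_that("single-predictor PLS equals simple least squares", {
  set.seed(2)
  x <- stats::rnorm(10)
  y <- 2 - 3 * x + stats::rnorm(10, sd = 0.1)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "m1"))
  assoc <- back_transform_coefficients(fit_pls(X, y, ncomp = 1))
  ls <- stats::lm(y ~ x)
  expect_equal(unname(assoc$beta[1, 1]), unname(stats::coef(ls)[2]),
               tolerance = 1e-10)
  expect_equal(unname(assoc$intercepts[1]), unname(stats::coef(ls)[1]),
               tolerance = 1e-10)
})

test_that("full-component PLS equals OLS on full-rank designs (both algorithms)", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(8:15, 1); p <- sample(2:5, 1); m <- sample(1:3, 1)
    X <- matrix(stats::rnorm(n * p), n, p)
    Y <- matrix(stats::rnorm(n * m), n, m)
    Xs <- standardize(X); Ys <- standardize(Y)
    ols <- solve(crossprod(Xs$values), crossprod(Xs$values, Ys$values))
    for (alg in c("nipals", "simpls")) {
      f <- fit_pls(Xs, Ys, ncomp = p, algorithm = alg)
      expect_equal(f$coef_std, ols, tolerance = 1e-6,
                   ignore_attr = TRUE)
      # orthogonal scores
      g <- crossprod(f$scores)
      expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
    }
  }
})

test_that("NIPALS and SIMPLS agree where they are defined to agree", {
  set.seed(8)
  # single response: identical for any number of components
  X <- matrix(stats::rnorm(12 * 6), 12, 6)
  y <- stats::rnorm(12)
  for (l in 1:4) {
    bn <- fit_pls(X, y, ncomp = l, algorithm = "nipals")$coef_std
    bs <- fit_pls(X, y, ncomp = l, algorithm = "simpls")$coef_std
    expect_equal(bn, bs, tolerance = 1e-6)
  }
  # multi-response at full rank both equal OLS (checked above); at
  # intermediate l the two algorithms differ by construction for m > 1.
})

test_that("perfectly collinear predictors share the coefficient", {
  set.seed(3)
  x <- stats::rnorm(10)
  X <- cbind(a = x, b = x + c(rep(0, 10)))  # identical columns
  y <- -x + stats::rnorm(10, sd = 0.05)
  f <- fit_pls(X, y, ncomp = 1)
  expect_equal(f$coef_std[1, 1], f$coef_std[2, 1], tolerance = 1e-10)
})

test_that("residual variance is non-increasing in the number of components", {
  set.seed(13)
  X <- matrix(stats::rnorm(14 * 5), 14, 5)
  Y <- matrix(stats::rnorm(14 * 3), 14, 3)
  Xs <- standardize(X); Ys <- standardize(Y)
  rss <- vapply(1:5, function(l) {
    f <- fit_pls(Xs, Ys, ncomp = l)
    sum((Ys$values - Xs$values %*% f$coef_std)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("beta is equivariant under predictor rescaling", {
  set.seed(21)
  X <- matrix(stats::rnorm(11 * 4), 11, 4,
              dimnames = list(NULL, paste0("m", 1:4)))
  Y <- matrix(stats::rnorm(11 * 2), 11, 2,
              dimnames = list(NULL, paste0("g", 1:2)))
  b1 <- back_transform_coefficients(fit_pls(X, Y, ncomp = 2))$beta
  X2 <- X; X2[, 3] <- X[, 3] * 5
  b2 <- back_transform_coefficients(fit_pls(X2, Y, ncomp = 2))$beta
  expect_equal(b2[, 3], b1[, 3] / 5, tolerance = 1e-10)
  expect_equal(b2[, -3], b1[, -3], tolerance = 1e-10)
})

test_that("back_transform_coefficients rescales and predicts consistently", {
  # forced arithmetic: standardized slope 0.5, sd_y 2, sd_x 4 -> beta 0.25
  fit <- structure(list(
    coef_std = matrix(0.5, 1, 1, dimnames = list("x1", "y1")),
    x_stats = list(means = c(x1 = 10), sds = c(x1 = 4)),
    y_stats = list(means = c(y1 = 3), sds = c(y1 = 2))
  ), class = "PLSFit")
  assoc <- back_transform_coefficients(fit)
  expect_equal(unname(assoc$beta[1, 1]), 0.25)
  expect_equal(unname(assoc$intercepts[1]), 3 - 0.25 * 10)

  # all-zero coefficients -> intercept = mean of Y
  fit$coef_std[] <- 0
  assoc0 <- back_transform_coefficients(fit)
  expect_equal(unname(assoc0$beta[1, 1]), 0)
  expect_equal(unname(assoc0$intercepts[1]), 3)

  # prediction equivalence: original-scale predictions match
  # inverse-standardized predictions from the standardized fit
  set.seed(6)
  X <- matrix(stats::rnorm(12 * 3, mean = 7), 12, 3,
              dimnames = list(NULL, paste0("m", 1:3)))
  Y <- matrix(stats::rnorm(12 * 2, mean = 9), 12, 2,
              dimnames = list(NULL, paste0("g", 1:2)))
  f <- fit_pls(X, Y, ncomp = 2)
  a <- back_transform_coefficients(f)
  yhat_orig <- predict_associations(a, X)
  Xs <- standardize(X)
  yhat_std <- Xs$values %*% f$coef_std
  yhat_back <- sweep(sweep(yhat_std, 2, f$y_stats$sds, "*"),
                     2, f$y_stats$means, "+")
  expect_equal(yhat_orig, yhat_back, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("predict_associations computes the linear combination", {
  assoc <- structure(list(
    beta = matrix(c(2, -1, 0.5, 3), 2, 2,
                  dimnames = list(c("g1", "g2"), c("m1", "m2"))),
    intercepts = c(g1 = 1, g2 = -2),
    mirna_ids = c("m1", "m2"), mrna_ids = c("g1", "g2")
  ), class = "AssociationMatrix")
  Xn <- matrix(c(1, 2, 3, 4), 2, 2)
  # hand-computed: y[s,i] = b0_i + sum_j beta[i,j] x[s,j]
  expect_equal(unname(predict_associations(assoc, Xn)),
               cbind(c(1 + 2 * 1 + 0.5 * 3, 1 + 2 * 2 + 0.5 * 4),
                     c(-2 - 1 + 3 * 3, -2 - 2 + 3 * 4)))
  # zero beta -> constant columns
  assoc$beta[] <- 0
  expect_true(all(predict_associations(assoc, Xn)[, 1] == 1))
  expect_error(predict_associations(assoc, matrix(1, 2, 3)), "columns")
})

test_that("fit_pls validates its preconditions", {
  X <- matrix(stats::rnorm(8 * 3), 8, 3)
  Y <- stats::rnorm(8)
  expect_error(fit_pls(X, Y, ncomp = 4), "ncomp")
  expect_error(fit_pls(X[1:2, ], Y[1:2], ncomp = 1), "at least 3 samples")
  expect_error(fit_pls(X, Y[1:5], ncomp = 1), "same number")
})

test_that("stacked PLS1 association scores agree with single-response fit_pls", {
  synth <- toy_paired(p = 5, m = 4, seed = 17)
  assoc <- pls_association_scores(synth$paired, ncomp = 3)
  X <- t(synth$paired$mirna$values)
  for (i in 1:4) {
    y <- t(synth$paired$mrna$values)[, i]
    single <- back_transform_coefficients(fit_pls(X, y, ncomp = 3))
    expect_equal(unname(assoc$beta[i, ]), unname(single$beta[1, ]),
                 tolerance = 1e-8)
    expect_equal(unname(assoc$intercepts[i]), unname(single$intercepts[1]),
                 tolerance = 1e-8)
  }
})
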