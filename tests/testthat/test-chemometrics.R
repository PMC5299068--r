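test_that("the first NIPALS weight equals the PLS1 closed form", {
  set.seed(81)
  for (i in 1:100) {
    x <- scale(matrix(rnorm(24), 6, 4), scale = FALSE)
    y <- rep(c(1, -1), 3)
    fit <- nipals_pls_fit(x, y, 1)
    w_ref <- crossprod(x, y)
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    expect_lt(max(abs(fit$weights[, 1] - w_ref)), 1e-8)
  }
})

test_that("NIPALS scores are mutually orthogonal and recover exact signals", {
  set.seed(82)
  x <- scale(matrix(rnorm(80), 10, 8), scale = FALSE)
  y <- rnorm(10)
  fit <- nipals_pls_fit(x, y, 4)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # y proportional to a column of an orthogonal design, noise-free ->
  # one component reproduces it exactly
  xo <- qr.Q(qr(x))[, 1:5]
  y2 <- 2 * xo[, 3]
  fit2 <- nipals_pls_fit(xo, y2, 1)
  pred <- pls_predict(fit2, xo)
  expect_lt(max(abs(pred$y_hat - y2)), 1e-8)
  expect_error(nipals_pls_fit(x, rep(1, 10), 1), "zero variance")
})

test_that("NIPALS agrees with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(83)
  for (i in 1:10) {
    x <- scale(matrix(rnorm(40), 8, 5), scale = FALSE)
    y <- scale(rnorm(8), scale = FALSE)[, 1]
    ours <- nipals_pls_fit(x, y, 3)
    ref <- mixOmics::pls(x, y, ncomp = 3, mode = "regression", scale = FALSE)
    for (a in 1:3) {
      s <- sign(sum(ours$scores[, a] * ref$variates$X[, a]))
      expect_lt(max(abs(ours$scores[, a] - s * ref$variates$X[, a])), 1e-8)
    }
  }
})

test_that("prediction follows the coefficient form with the +1 tie rule", {
  x <- matrix(c(1, -1), 2, 1)
  y <- c(1, -1)
  fit <- nipals_pls_fit(x, y, 1)
  expect_equal(pls_predict(fit, matrix(0.5))$y_hat, 0.5, tolerance = 1e-12)
  at_center <- pls_predict(fit, matrix(0))
  expect_equal(at_center$y_hat, 0)
  expect_equal(at_center$class, 1)          # tie goes to +1
  expect_error(pls_predict(fit, matrix(0, 1, 3)), "features")
})

test_that("Q2 matches its closed forms", {
  expect_equal(q2_score(c(1, -1), c(1, -1), 0), 1)
  expect_equal(q2_score(c(1, -1), c(0, 0), 0), 0)
  expect_equal(q2_score(c(1, -1), c(0.5, -0.5), 0), 0.75)
  expect_error(q2_score(c(1, 1), c(0, 0), 1), "stratify")
})

test_that("the OPLS filter removes only y-orthogonal variation", {
  set.seed(84)
  x <- scale(matrix(rnorm(200), 20, 10), scale = FALSE)
  y <- rep(c(1, -1), 10)
  f0 <- opls_filter(x, y, 0)
  expect_identical(f0$x_filtered, x)
  f <- opls_filter(x, y, 3)
  yc <- y - mean(y)
  for (j in seq_len(ncol(f$t_orth))) {
    r <- sum(f$t_orth[, j] * yc) /
      sqrt(sum(f$t_orth[, j]^2) * sum(yc^2))
    expect_lt(abs(r), 1e-8)
  }
})

test_that("one filter component removes a planted orthogonal direction", {
  set.seed(85)
  n <- 24
  d1 <- c(1, rep(0, 9)); d2 <- c(0, 1, rep(0, 8))
  y <- rep(c(1, -1), n / 2)
  g <- rnorm(n, sd = 4)
  g <- residuals(lm(g ~ y))                 # exactly y-orthogonal
  x <- outer(y, d1) + outer(g, d2) + matrix(rnorm(n * 10, sd = 0.05), n)
  x <- scale(x, scale = FALSE)
  f <- opls_filter(x, y, 1)
  var_before <- var(x %*% d2)
  var_after <- var(f$x_filtered %*% d2)
  expect_lt(var_after / var_before, 0.01)
})

test_that("component selection returns 1 for separable data and stays in bounds", {
  set.seed(86)
  x <- cbind(c(rnorm(8, -3), rnorm(8, 3)), matrix(rnorm(16 * 4), 16))
  y <- rep(c(-1, 1), each = 8)
  expect_equal(choose_n_components(x, y, max_components = 8), 1L)
  xn <- matrix(rnorm(16 * 10), 16)
  k <- choose_n_components(xn, y, max_components = 8)
  expect_gte(k, 1L)
  expect_lte(k, 8L)
  expect_error(choose_n_components(x[1:2, ], y[1:2]), ">= 3")
})

test_that("k = 1 yields a plain 2-component PLS-DA on unfiltered data", {
  set.seed(87)
  x <- matrix(rnorm(16 * 6), 16)
  y <- rep(c(1, -1), 8)
  m <- fit_final_opls_da(x, y, 1, scale = "none")
  expect_equal(m$filter$n_orthogonal, 0L)
  sc <- dysbiome:::scale_train(x, "none")
  plain <- nipals_pls_fit(sc$x, y, 2)
  expect_equal(abs(m$pls$weights), abs(plain$weights), tolerance = 1e-10)
  # prediction on training data reproduces stored scores
  pr <- predict_opls(m, x)
  recon <- pls_predict(m$pls, m$filter$x_filtered)
  expect_equal(pr$y_hat, recon$y_hat, tolerance = 1e-10)
})

test_that("filtering never weakens the predictive score's link to y", {
  set.seed(88)
  wins <- 0L
  for (s in 1:20) {
    n <- 20
    y <- rep(c(1, -1), n / 2)
    g <- residuals(lm(rnorm(n, sd = 3) ~ y))
    x <- outer(y, rnorm(8)) + outer(g, rnorm(8)) +
      matrix(rnorm(n * 8, sd = 0.3), n)
    sc <- dysbiome:::scale_train(x, "pareto")
    unfiltered <- nipals_pls_fit(sc$x, y, 1)
    m <- fit_final_opls_da(x, y, 2, scale = "pareto")
    r_plain <- abs(cor(unfiltered$scores[, 1], y))
    r_opls <- abs(cor(m$pls$scores[, 1], y))
    if (r_opls >= r_plain - 1e-10) wins <- wins + 1L
  }
  expect_gte(wins, 10L)   # median across seeds must not degrade
})

test_that("back-scaled loadings recover planted markers and flip with coding", {
  set.seed(89)
  hits <- 0L
  for (s in 1:20) {
    x <- matrix(rnorm(16 * 12), 16)
    y <- rep(c(-1, 1), each = 8)
    x[y == 1, 5] <- x[y == 1, 5] + 4
    m <- fit_final_opls_da(x, y, 1, scale = "pareto")
    bl <- backscaled_loadings(m)
    if (which.max(abs(bl)) == 5L) hits <- hits + 1L
    bl_flip <- backscaled_loadings(fit_final_opls_da(x, -y, 1,
                                                     scale = "pareto"))
    expect_equal(unname(bl_flip), -unname(bl), tolerance = 1e-8)
  }
  expect_gte(hits, 18L)
  # unit scale factors leave loadings untouched
  m2 <- fit_final_opls_da(matrix(rnorm(32), 8), rep(c(1, -1), 4), 1,
                          scale = "none")
  expect_equal(unname(backscaled_loadings(m2)),
               unname(m2$pls$loadings[, 1]))
})
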