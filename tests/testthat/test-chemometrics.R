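test_that("preprocessing centers, scales, and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  xp <- mv_preprocess(x)
  expect_equal(unname(colMeans(xp)), c(0, 0))
  expect_equal(unname(apply(xp, 2, sd)), c(1, 1))
  expect_equal(unname(xp[, "a"]), c(-1, 0, 1))

  centered <- mv_preprocess(x, uv_scale = FALSE)
  twice <- mv_preprocess(centered, uv_scale = FALSE)
  expect_equal(as.numeric(twice), as.numeric(centered))

  set.seed(1)
  r <- matrix(rnorm(50), 10, 5)
  rp <- mv_preprocess(r)
  expect_equal(max(abs(colMeans(rp))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(rp, 2, sd)), rep(1, 5))
})

test_that("constant columns are dropped with a warning, all-constant errors", {
  x <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_warning(xp <- mv_preprocess(x), "constant")
  expect_equal(colnames(xp), "b")
  expect_error(suppressWarnings(mv_preprocess(cbind(a = c(1, 1)))),
               "constant")
})

test_that("pca matches the SVD oracle up to component sign", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(160), 20, 8)
    m <- fit_pca(x, 4, cv_groups = 0)
    xs <- scale(x)
    sv <- svd(xs)
    expect_equal(abs(m$loadings), abs(sv$v[, 1:4]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(m$scores),
                 abs(sv$u[, 1:4] %*% diag(sv$d[1:4])), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(m$r2x, sv$d[1:4]^2 / sum(sv$d^2), tolerance = 1e-8)
    # loadings orthonormal, scores orthogonal
    expect_equal(crossprod(m$loadings), diag(4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    off <- crossprod(m$scores) - diag(diag(crossprod(m$scores)))
    expect_equal(max(abs(off)), 0, tolerance = 1e-8)
    expect_true(all(diff(m$r2x_cum) >= 0) && all(m$r2x_cum <= 1 + 1e-12))
  }
})

test_that("a rank-1 matrix is explained by one component", {
  set.seed(2)
  x <- outer(rnorm(10), rnorm(4))
  m <- fit_pca(x, 1, center = FALSE, uv_scale = FALSE, cv_groups = 0)
  expect_equal(m$r2x_cum, 1, tolerance = 1e-12)
})

test_that("latent rank is recovered from low-noise factor structure", {
  x <- gen_descriptor_table(30, 12, latent_rank = 3, noise_sd = 0.05,
                            seed = 8)
  m <- fit_pca(x, 4)
  expect_gt(m$r2x_cum[3], 0.95)
  expect_gt(m$q2_cum[3], 0.9)  # real structure is predictive under CV
})

test_that("pca component count is bounded and validated", {
  expect_error(fit_pca(matrix(rnorm(20), 5, 4), 5), "exceeds")
})

test_that("dmodx is zero in-plane, maximal for an orthogonal outlier", {
  set.seed(31)
  x <- matrix(rnorm(120), 20, 6)
  m <- fit_pca(x, 2, center = FALSE, uv_scale = FALSE, cv_groups = 0)

  # a new observation lying exactly in the model plane has DModX 0
  in_plane <- m$scores[3, ] %*% t(m$loadings)
  expect_equal(dmodx(m, in_plane)$dmodx, 0, tolerance = 1e-10)

  # an observation displaced orthogonally to the plane dominates the cohort
  ortho <- qr.Q(qr(cbind(m$loadings, rnorm(6))))[, 3]
  x2 <- rbind(x, x[20, ] + 10 * ortho)
  d2 <- dmodx(m, x2)
  expect_equal(which.max(d2$dmodx), 21L)

  # random data: mean DModX near 1 under the chosen normalization
  m3 <- fit_pca(matrix(rnorm(600), 50, 12), 3, cv_groups = 0)
  expect_equal(mean(m3$dmodx$dmodx), 1, tolerance = 0.15)
})

test_that("pls with a single proportional predictor fits perfectly", {
  x <- cbind(v = c(1, 2, 3, 4, 5))
  y <- 2 * x[, 1] + 3
  m <- fit_pls(x, y, n_lv = 1, cv = "none")
  expect_equal(m$r2y, 1, tolerance = 1e-12)
  expect_gt(m$coefficients[["v"]], 0)
  expect_equal(m$fitted, y, tolerance = 1e-10)
})

test_that("full-rank pls reproduces least squares", {
  set.seed(12)
  x <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- as.numeric(x %*% c(1, -2, 0.5, 0, 3) + rnorm(20))
  m <- fit_pls(x, y, n_lv = 5, cv = "none")
  ls_fit <- lm(y ~ x)
  expect_equal(m$fitted, unname(fitted(ls_fit)), tolerance = 1e-8)
  expect_equal(m$r2y, summary(ls_fit)$r.squared, tolerance = 1e-8)
})

test_that("pls agrees with the mixOmics reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("V", 1:10)))
  y <- as.numeric(x %*% c(2, -1, rep(0, 8)) + rnorm(20))
  mine <- fit_pls(x, y, n_lv = 2, cv = "none")
  ref <- suppressMessages(
    mixOmics::pls(x, y, ncomp = 2, mode = "regression", scale = TRUE))
  expect_equal(predict(mine, x),
               unname(predict(ref, x)$predict[, , 2]), tolerance = 1e-10)
  expect_equal(abs(unname(mine$t)), abs(unname(ref$variates$X)),
               tolerance = 1e-8)
})

test_that("loo q2 equals an explicit refit oracle at full rank", {
  set.seed(14)
  x <- matrix(rnorm(60), 15, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- as.numeric(x %*% c(2, -1, 1, 0.5) + rnorm(15, sd = 0.8))
  m <- fit_pls(x, y, n_lv = 4)
  # oracle: leave-one-out ordinary least squares (full-rank equivalence)
  press <- 0
  for (i in seq_len(nrow(x))) {
    fit <- lm(y[-i] ~ x[-i, ])
    pred <- sum(c(1, x[i, ]) * coef(fit))
    press <- press + (y[i] - pred)^2
  }
  expect_equal(m$q2_cum, 1 - press / sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("pls validates rank, constant response, and lv count", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_pls(x, rep(1, 10), n_lv = 1), "constant")
  expect_error(fit_pls(x[, c(1, 1)], rnorm(10), n_lv = 4), "rank")
})

test_that("q2 is non-positive on average when y is independent of x", {
  set.seed(77)
  q2s <- replicate(20, {
    x <- matrix(rnorm(100), 20, 5)
    fit_pls(x, rnorm(20), n_lv = 2)$q2_cum
  })
  expect_lte(mean(q2s), 0)
})

test_that("permutation test separates signal from chance correlation", {
  set.seed(9)
  x <- matrix(rnorm(200), 20, 10)
  y <- as.numeric(x %*% c(3, -3, 2, rep(0, 7)) + rnorm(20, sd = 0.5))
  pt <- permutation_test(x, y, n_lv = 2, n_perm = 30, seed = 5)
  expect_equal(pt$results$correlation[1], 1)
  perm_rows <- pt$results[-1, ]
  expect_true(all(perm_rows$r2y < pt$results$r2y[1]))
  expect_true(all(perm_rows$q2 < pt$results$q2[1]))
  expect_lt(pt$q2_intercept, 0.05)

  # seeded runs are bit-reproducible
  pt2 <- permutation_test(x, y, n_lv = 2, n_perm = 30, seed = 5)
  expect_identical(pt$results, pt2$results)

  expect_error(permutation_test(x, rep(1, 20), n_lv = 1, seed = 1),
               "constant")
  expect_warning(permutation_test(x, y, n_lv = 1, n_perm = 5, seed = 1),
                 "permutations")
})

test_that("broom-style accessors summarize the models", {
  set.seed(2)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- as.numeric(x %*% c(1, 2, -1, 0) + rnorm(20))
  pls <- fit_pls(x, y, n_lv = 2)
  expect_equal(nrow(tidy(pls)), 4)
  expect_equal(glance(pls)$r2y, pls$r2y)
  pca <- fit_pca(x, 2)
  expect_equal(nrow(tidy(pca)), 2)
  expect_equal(glance(pca)$r2x_cum, pca$r2x_cum[2])
})
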