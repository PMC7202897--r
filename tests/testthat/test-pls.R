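# NIPALS PLS: exactness on latent data, oracles, diagnostics, VIP,
# permutation validation, prediction and augmentation.

make_latent_xy <- function(seed, n = 8, p = 11, m = 3, noise = 0) {
  set.seed(seed)
  Tlat <- matrix(rnorm(n * 2), n, 2)
  X <- Tlat %*% matrix(rnorm(2 * p), 2, p) + noise * matrix(rnorm(n * p), n, p)
  Y <- Tlat %*% matrix(rnorm(2 * m), 2, m) + noise * matrix(rnorm(n * m), n, m)
  colnames(X) <- paste0("f", seq_len(p)); colnames(Y) <- paste0("r", seq_len(m))
  list(X = X, Y = Y)
}

test_that("noise-free latent structure is fit exactly", {
  d <- make_latent_xy(1)
  fit <- suppressWarnings(pls_fit(d$X, d$Y, 2))
  expect_gte(fit$r2[2], 0.999)
  # scores orthogonality
  G <- crossprod(fit$T)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # R2 non-decreasing
  expect_true(all(diff(fit$r2) >= -1e-12))
})

test_that("one component on one predictor reduces to simple regression", {
  set.seed(2)
  x <- rnorm(10); y <- 2 * x + rnorm(10, 0, 0.3)
  fit <- pls_fit(matrix(x, dimnames = list(NULL, "x")), y, 1)
  co <- coef(fit)
  lmfit <- lm(y ~ x)
  expect_equal(unname(co["x", 1]), unname(coef(lmfit)["x"]), tolerance = 1e-9)
  expect_equal(unname(co["(intercept)", 1]), unname(coef(lmfit)[1]),
               tolerance = 1e-9)
})

test_that("first NIPALS weights equal the dominant eigenvector of X'YY'X", {
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4); Y <- matrix(rnorm(12), 6, 2)
  fit <- pls_fit(X, Y, 2)
  Xs <- scale(X); Ys <- scale(Y)
  M <- t(Xs) %*% Ys %*% t(Ys) %*% Xs
  w1 <- eigen(M, symmetric = TRUE)$vectors[, 1]
  expect_lt(max(abs(abs(w1) - abs(fit$W[, 1]))), 1e-6)
})

test_that("cross-check against an independent PLS implementation", {
  d <- make_latent_xy(4, n = 9, noise = 0.4)
  fit <- pls_fit(d$X, d$Y, 3)
  m <- mixOmics::pls(d$X, d$Y, ncomp = 3, mode = "regression", scale = TRUE)
  pr_ref <- predict(m, d$X)$predict[, , 3]
  expect_lt(max(abs(predict(fit, d$X, ncomp = 3) - pr_ref)), 1e-8)
})

test_that("Q2 diagnostics separate signal from noise", {
  d <- make_latent_xy(5, n = 8)
  dg <- suppressWarnings(q2_loocv(d$X, d$Y, 2))
  expect_gte(dg$Q2[2], 0.95)
  expect_true(all(dg$Q2 <= dg$R2 + 1e-9))

  q2_null <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(88), 8, 11); Yn <- rnorm(8)
    suppressWarnings(q2_loocv(Xn, Yn, 2))$Q2[2]
  }, numeric(1))
  expect_lte(mean(q2_null), 0)
})

test_that("component choice follows the within-delta rule", {
  expect_equal(choose_components(list(Q2 = c(0.3, 0.7, 0.71, 0.65))), 2L)
  expect_equal(choose_components(list(Q2 = c(0.4, 0.75, 0.74))), 2L)
  expect_equal(choose_components(list(Q2 = c(0.2, 0.5, 0.6, 0.7))), 4L)
  expect_warning(a <- choose_components(list(Q2 = c(-0.4, -0.2))),
                 "overfitting")
  expect_equal(a, 1L)
})

test_that("VIP identities and hand-computed oracle", {
  # single component, equal |weights| -> every VIP is 1
  set.seed(6)
  z <- rnorm(12)
  X <- cbind(a = z + rnorm(12, 0, 1e-8), b = -z + rnorm(12, 0, 1e-8))
  fit1 <- pls_fit(X, z, 1)
  expect_equal(unname(vip_scores(fit1)[, "overall"]), c(1, 1),
               tolerance = 1e-3)

  d <- make_latent_xy(7, n = 10, p = 4, m = 2, noise = 0.5)
  fit <- pls_fit(d$X, d$Y, 2)
  v <- vip_scores(fit)
  expect_equal(unname(colSums(v^2)), rep(4, 3), tolerance = 1e-6)

  # direct scalar evaluation of the formula
  ssy_overall <- colSums(fit$ssy)
  for (j in 1:4) {
    acc <- 0
    for (a in 1:2) acc <- acc + ssy_overall[a] * fit$W[j, a]^2
    expect_equal(unname(v[j, "overall"]),
                 unname(sqrt(4 * acc / sum(ssy_overall))), tolerance = 1e-9)
  }
})

test_that("autoscaling absorbs predictor rescaling", {
  d <- make_latent_xy(8, n = 9, noise = 0.3)
  fit <- pls_fit(d$X, d$Y, 2)
  X2 <- d$X; X2[, 3] <- X2[, 3] * 1000
  fit2 <- pls_fit(X2, d$Y, 2)
  new0 <- d$X[5, , drop = FALSE] * 1.1
  new2 <- new0; new2[, 3] <- new2[, 3] * 1000
  expect_equal(predict(fit2, new2), predict(fit, new0), tolerance = 1e-9)
  expect_equal(vip_scores(fit2), vip_scores(fit), tolerance = 1e-9)
})

test_that("permutation test flags strong links and stays calibrated on noise", {
  d <- make_latent_xy(9, n = 8)
  pt <- pls_permutation_test(d$X, d$Y, 2, n_perm = 200, seed = 5)
  expect_lte(pt$p_value, 0.05)
  pt2 <- pls_permutation_test(d$X, d$Y, 2, n_perm = 200, seed = 5)
  expect_identical(pt$null, pt2$null)

  ps <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    Xn <- matrix(rnorm(48), 8, 6); Yn <- rnorm(8)
    suppressWarnings(
      pls_permutation_test(Xn, Yn, 2, n_perm = 100, seed = s))$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("prediction identities and percent-error reporting", {
  d <- make_latent_xy(10)
  fit <- suppressWarnings(pls_fit(d$X, d$Y, 2))
  # training row of an exact model reproduces itself
  rep1 <- predict_report(fit, d$X[3, , drop = FALSE], d$Y[3, ],
                         condition = "row3")
  expect_true(all(rep1$percent_error < 0.5))
  # the column-mean point maps to the response means
  pred_mean <- predict(fit, t(colMeans(d$X)))
  expect_equal(drop(pred_mean), colMeans(d$Y), tolerance = 1e-9)
  # zero actual -> undefined percent error, not infinite
  rep0 <- predict_report(fit, d$X[3, , drop = FALSE],
                         c(0, d$Y[3, 2], d$Y[3, 3]))
  expect_true(is.na(rep0$percent_error[1]))
  expect_error(predict(fit, d$X[, 1:5]), "missing predictor")
})

test_that("augmentation refits cleanly and is a no-op for zero rows", {
  d <- make_latent_xy(11, n = 10, noise = 0.2)
  fit <- pls_fit(d$X[1:7, ], d$Y[1:7, ], 2)
  expect_identical(augment_and_refit(fit, d$X[0, , drop = FALSE],
                                     d$Y[0, , drop = FALSE]), fit)
  fit2 <- augment_and_refit(fit, d$X[8:10, ], d$Y[8:10, ])
  expect_equal(nrow(fit2$T), 10)
  rep2 <- predict_report(fit2, d$X[8:10, ], d$Y[8:10, ])
  expect_lt(median(rep2$percent_error), 25)
  expect_error(augment_and_refit(fit, d$X[8:10, 1:4], d$Y[8:10, ]),
               "lack predictor")
})

test_that("degenerate inputs are rejected or repaired with warnings", {
  d <- make_latent_xy(12)
  Xz <- cbind(d$X, zv = rep(1, 8))
  expect_warning(fit <- pls_fit(Xz, d$Y, 2), "zero-variance")
  expect_false("zv" %in% fit$predictors)
  expect_warning(pls_fit(d$X, d$Y, 7), "truncated")
  expect_error(pls_fit(d$X[1:2, ], d$Y[1:2, ], 1), "at least 3")
  expect_error(pls_fit(d$X, cbind(d$Y, flat = rep(2, 8)), 1), "zero-variance resp")
})
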