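# Boosted-stump classification: AUROC, AdaBoost internals, labeling rules,
# feature ranking and group models.

test_that("AUROC agrees with pair counting and its invariances", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1)), 1.0)
  expect_equal(auroc(c(0.8, 0.3, 0.6, 0.1), c(1, 1, -1, -1)), 0.75)
  expect_equal(auroc(rep(0.4, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    y <- c(rep(1, 3), rep(-1, 3), sample(c(-1, 1), n - 6, replace = TRUE))
    s <- sample(round(rnorm(n), 1))   # coarse scores induce ties
    expect_equal(auroc(s, y), bf_auroc(s, y), tolerance = 1e-12)
    expect_equal(auroc(s, -y), 1 - auroc(s, y), tolerance = 1e-12)
    expect_equal(auroc(exp(3 * s), y), auroc(s, y), tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AdaBoost round-1 stump matches exhaustive search, alpha closed form", {
  set.seed(12)
  X <- matrix(round(rnorm(40), 1), 20, 2)
  y <- ifelse(X[, 1] + 0.8 * X[, 2] + 0.3 * rnorm(20) > 0, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  fit <- adaboost(X, y, n_estimators = 1)
  oracle <- bf_best_stump(X, y, rep(1 / 20, 20))
  expect_equal(fit$stumps$error[1], oracle$err, tolerance = 1e-12)
  expect_equal(fit$stumps$threshold[1], oracle$threshold)
  expect_equal(fit$stumps$feature[1], oracle$feature)

  # weighted error 1/4 -> alpha = 0.5 ln 3
  X4 <- matrix(c(1, 2, 3, 4), 4, 1)
  y4 <- c(-1, -1, 1, 1)
  fit4 <- adaboost(X4, c(1, -1, 1, 1), n_estimators = 1)
  # best stump (x > 2.5, +1) errs on exactly one of four uniform points
  expect_equal(fit4$stumps$error[1], 0.25)
  expect_equal(fit4$alphas[1], 0.5 * log(3), tolerance = 1e-12)

  sep <- adaboost(X4, y4, n_estimators = 50)
  expect_equal(nrow(sep$stumps), 1)   # perfect stump stops training
  expect_equal(sep$train_error, 0)

  expect_error(adaboost(X4, c(1, 1, 1, 1)), "both classes")
})

test_that("full boosted model matches an independent re-implementation", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(12:25, 1)
    X <- matrix(round(rnorm(2 * n), 1), n, 2)
    y <- ifelse(X[, 1] - X[, 2] + rnorm(n) > 0, 1, -1)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    fit <- adaboost(X, y, n_estimators = 12)
    expect_equal(predict(fit, X, type = "class"),
                 bf_adaboost_predict(X, y, 12))
  }
})

test_that("exponential loss is non-increasing over rounds at unit rate", {
  set.seed(44)
  X <- matrix(rnorm(120), 40, 3)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(40, 0, 0.8) > 0, 1, -1)
  fit <- adaboost(X, y, n_estimators = 25, learning_rate = 1)
  st <- fit$stumps
  F <- rep(0, 40)
  loss <- sum(exp(-y * F))
  for (t in seq_len(nrow(st))) {
    F <- F + fit$alphas[t] *
      ifelse(X[, st$feature[t]] > st$threshold[t], st$polarity[t], -st$polarity[t])
    l2 <- sum(exp(-y * F))
    expect_lte(l2, loss + 1e-9)
    loss <- l2
  }
})

test_that("low/high labeling reads 'above' strictly", {
  sm <- data.frame(condition = c("a", "b", "c"),
                   mean_speed = c(0.6, 0.5, 0.2),
                   mean_invasion = c(12, 9, 10))
  lab_s <- label_conditions(sm, "speed")
  expect_equal(unname(lab_s$labels), c("high", "low", "low"))
  expect_equal(lab_s$threshold, 0.5)
  lab_i <- label_conditions(sm, "invasion")
  expect_equal(unname(lab_i$labels), c("high", "low", "low"))
  lab_8 <- label_conditions(sm, "invasion", threshold = 8)
  expect_equal(unname(lab_8$labels), c("high", "high", "high"))
  expect_error(label_conditions(sm[, 1:2], "invasion"), "mean_invasion")
})

test_that("single-feature ranking finds the one informative feature", {
  set.seed(55)
  n <- 120
  cells <- data.frame(condition = rep(c("lo1", "lo2", "hi1", "hi2"),
                                      each = n / 4))
  for (f in shape_feature_names()) cells[[f]] <- rnorm(n)
  hi <- cells$condition %in% c("hi1", "hi2")
  cells$eccentricity <- rnorm(n, ifelse(hi, 3, 0), 0.4)  # only true signal
  sm <- data.frame(condition = c("lo1", "lo2", "hi1", "hi2"),
                   mean_speed = c(0.3, 0.4, 0.7, 0.8))
  lab <- label_conditions(sm, "speed")
  rk <- rank_single_features(cells, lab)
  expect_equal(rk$feature[1], "eccentricity")
  expect_gt(rk$auroc[1], 0.95)
  expect_true(all(rk$auroc[rk$feature != "eccentricity"] < 0.9))

  # ranking invariant to feature column order
  shuffled <- cells[, c("condition", rev(shape_feature_names()))]
  rk2 <- rank_single_features(shuffled, lab)
  expect_identical(rk2$feature, rk$feature)

  # all-noise features hover at chance
  cells$eccentricity <- rnorm(n)
  rk0 <- rank_single_features(cells, lab,
                              n_estimators = 1)  # single stump = honest null
  expect_true(all(abs(rk0$auroc - 0.5) < 0.25))
})

test_that("feature groups and hyperparameter grid behave consistently", {
  set.seed(66)
  config <- elongation_signal_config(n_cells = 25)
  study <- generate_study(config, master_seed = 101, n_replicates = 3)
  tabs <- study_tables(study)
  lab <- label_conditions(tabs$summaries, "speed")
  expect_setequal(unname(lab$labels[c("C1", "C5")]), c("low", "high"))

  rep <- evaluate_feature_groups(tabs$features, lab)
  expect_identical(rep$group, c("all", "size", "irregularity", "elongation"))
  all_row <- rep[rep$group == "all", ]
  expect_gt(all_row$auroc_cv, 0.9)
  expect_gt(rep$auroc_cv[rep$group == "elongation"],
            rep$auroc_cv[rep$group == "size"])

  expect_warning(
    evaluate_feature_groups(tabs$features, lab,
                            groups = list(dup = c("area", "area"))),
    "duplicate")
  expect_error(
    evaluate_feature_groups(tabs$features, lab, groups = list(none = character(0))),
    "empty")

  g11 <- adaboost_grid_search(tabs$features, lab, learning_rates = 1,
                              estimator_counts = 50L)
  expect_equal(g11$auroc_cv, all_row$auroc_cv, tolerance = 1e-12)
  expect_equal(g11$auroc_train, all_row$auroc_train, tolerance = 1e-12)
  expect_true(g11$is_default)
})

test_that("migration-metric groups can classify invasion labels", {
  set.seed(70)
  cells <- data.frame(condition = rep(c("w", "x", "y", "z"), each = 20),
                      speed = rnorm(80, rep(c(0.3, 0.4, 0.6, 0.7), each = 20), 0.05),
                      persistence = runif(80))
  sm <- data.frame(condition = c("w", "x", "y", "z"),
                   mean_invasion = c(4, 6, 12, 15))
  lab <- label_conditions(sm, "invasion")
  rep <- evaluate_feature_groups(cells, lab,
                                 groups = list(speed = "speed",
                                               persistence = "persistence",
                                               both = c("speed", "persistence")))
  expect_gt(rep$auroc_cv[rep$group == "speed"], 0.9)
  expect_lt(abs(rep$auroc_cv[rep$group == "persistence"] - 0.5), 0.25)
})
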