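# Low/high response labeling and boosted-stump classification with AUROC.
#
# Discrete AdaBoost (Freund & Schapire): at round t the weighted-error-
# minimizing decision stump is found exactly (thresholds are midpoints
# between consecutive sorted unique feature values), alpha_t = learning_rate
# * 0.5 * ln((1-eps)/eps), weights are exponentially reweighted and
# renormalized. Ties in weighted error resolve to the smaller threshold, then
# the lower feature index.

# Exact best stump under weights w (summing to 1). A stump predicts
# polarity for x > threshold and -polarity otherwise.
.best_stump <- function(X, y, w) {
  n <- nrow(X)
  best <- list(err = Inf, feature = NA_integer_, threshold = NA_real_,
               polarity = NA_real_)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    cuts <- which(diff(xs) > 0)
    if (!length(cuts)) next
    wp <- cumsum(w[ord] * (y[ord] == 1))   # positive weight below cut
    wn <- cumsum(w[ord] * (y[ord] == -1))
    ptot <- wp[n]; ntot <- wn[n]
    err_pos <- wp[cuts] + (ntot - wn[cuts])  # polarity +1: predict +1 above
    err_neg <- (ptot + ntot) - err_pos
    # tie-break: smallest threshold first (cuts are ascending), +1 polarity
    # preferred at the same threshold, lower feature index across features
    e_min <- pmin(err_pos, err_neg)
    i <- which(e_min <= min(e_min) + 1e-12)[1]  # fp-robust: smallest threshold
    if (e_min[i] < best$err - 1e-12) {
      best <- list(err = e_min[i], feature = j,
                   threshold = (xs[cuts[i]] + xs[cuts[i] + 1L]) / 2,
                   polarity = if (err_pos[i] <= err_neg[i]) 1 else -1)
    }
  }
  best
}

.stump_predict <- function(x, threshold, polarity) {
  ifelse(x > threshold, polarity, -polarity)
}

#' Fit a discrete AdaBoost model of decision stumps
#'
#' @param X Numeric matrix or data frame of per-cell features.
#' @param y Labels: +1/-1 numeric, logical, or a factor whose second level is
#'   the positive class. Both classes must be present.
#' @param n_estimators Maximum number of boosting rounds (default 50, the
#'   classifier's recommended default).
#' @param learning_rate Multiplier on the per-stump vote weights (default 1).
#' @return Object of class \code{adaboost}: \code{stumps} (data frame with
#'   feature, threshold, polarity), \code{alphas}, the settings, and the
#'   training error. Training stops early when a round's weighted error
#'   reaches 0.5 (stump discarded) or 0 (perfect stump recorded).
#' @export
adaboost <- function(X, y, n_estimators = 50L, learning_rate = 1) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stopf("X must be numeric")
  if (any(!is.finite(X))) stopf("X must be finite")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- .pm_one(y)
  if (length(unique(y)) < 2L) stopf("y must contain both classes")
  if (length(y) != nrow(X)) stopf("X and y sizes differ")
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_estimators)) {
    st <- .best_stump(X, y, w)
    if (!is.finite(st$err)) break
    if (st$err >= 0.5 - 1e-12) break
    eps <- min(max(st$err, 1e-12), 1 - 1e-12)
    alpha <- learning_rate * 0.5 * log((1 - eps) / eps)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    h <- .stump_predict(X[, st$feature], st$threshold, st$polarity)
    if (st$err <= 1e-12) break
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  sd_df <- data.frame(
    feature = vapply(stumps, `[[`, integer(1), "feature"),
    threshold = vapply(stumps, `[[`, numeric(1), "threshold"),
    polarity = vapply(stumps, `[[`, numeric(1), "polarity"),
    error = vapply(stumps, `[[`, numeric(1), "err"))
  sd_df$feature_name <- colnames(X)[sd_df$feature]
  fit <- structure(list(stumps = sd_df, alphas = alphas,
                        n_estimators = as.integer(n_estimators),
                        learning_rate = learning_rate,
                        feature_names = colnames(X)), class = "adaboost")
  fit$train_error <- mean(predict(fit, X, type = "class") != y)
  fit
}

.pm_one <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  if (is.factor(y)) return(ifelse(as.integer(y) == 2L, 1, -1))
  if (is.character(y)) return(ifelse(y == sort(unique(y))[2], 1, -1))
  if (!all(y %in% c(-1, 1))) stopf("numeric y must be coded -1/+1")
  as.numeric(y)
}

#' @export
print.adaboost <- function(x, ...) {
  cat(sprintf("AdaBoost stump ensemble: %d/%d stumps, learning rate %g, training error %.3f\n",
              nrow(x$stumps), x$n_estimators, x$learning_rate, x$train_error))
  if (nrow(x$stumps)) {
    tab <- sort(table(x$stumps$feature_name), decreasing = TRUE)
    cat("  stump features:", paste(sprintf("%s(%d)", names(tab), tab),
                                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict from an AdaBoost model
#'
#' @param object An \code{\link{adaboost}} fit.
#' @param newdata Feature matrix or data frame containing the training
#'   feature columns.
#' @param type \code{"score"} for the real-valued vote sum, \code{"class"}
#'   for its sign (+1/-1; score 0 maps to -1).
#' @param ... Unused.
#' @return Numeric vector of scores or class labels.
#' @export
predict.adaboost <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(if (is.data.frame(newdata))
    newdata[, object$feature_names, drop = FALSE] else newdata)
  score <- rep(0, nrow(X))
  st <- object$stumps
  for (t in seq_len(nrow(st))) {
    score <- score + object$alphas[t] *
      .stump_predict(X[, st$feature[t]], st$threshold[t], st$polarity[t])
  }
  if (type == "score") score else ifelse(score > 0, 1, -1)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs whose positive score exceeds the
#' negative score, with ties counted one half.
#'
#' @param scores Real-valued classifier scores.
#' @param labels Class labels (+1/-1, logical, or 2-level factor).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  y <- .pm_one(labels)
  npos <- sum(y == 1); nneg <- sum(y == -1)
  if (npos == 0 || nneg == 0) stopf("AUROC undefined: both classes required")
  r <- rank(scores)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Label conditions as low/high responders
#'
#' A condition is \code{high} iff its mean response strictly exceeds the
#' threshold ("above" is read literally; boundary equality is low). Default
#' thresholds: speed 0.5 um/min; invasion fold change 10 (8 is the
#' MDA-MB-468-like alternative).
#'
#' @param summaries Condition summary table with \code{mean_speed} /
#'   \code{mean_invasion}.
#' @param response \code{"speed"} or \code{"invasion"}.
#' @param threshold Classification threshold; \code{NULL} picks the default
#'   for the response.
#' @return Object of class \code{binary_labeling}: \code{labels} (named
#'   character vector, "low"/"high"), \code{response}, \code{threshold}.
#' @export
label_conditions <- function(summaries, response = c("speed", "invasion"),
                             threshold = NULL) {
  response <- match.arg(response)
  col <- if (response == "speed") "mean_speed" else "mean_invasion"
  if (!col %in% names(summaries)) stopf("summaries lack %s", col)
  v <- summaries[[col]]
  if (any(!is.finite(v))) stopf("missing %s for condition(s): %s", col,
                                paste(summaries$condition[!is.finite(v)],
                                      collapse = ", "))
  threshold <- threshold %||% if (response == "speed") 0.5 else 10
  if (threshold <= 0) stopf("threshold must be positive")
  labels <- ifelse(v > threshold, "high", "low")
  names(labels) <- as.character(summaries$condition)
  structure(list(labels = labels, response = response, threshold = threshold),
            class = "binary_labeling")
}

#' @export
print.binary_labeling <- function(x, ...) {
  cat(sprintf("binary %s labeling (threshold > %g): %d high, %d low\n",
              x$response, x$threshold, sum(x$labels == "high"),
              sum(x$labels == "low")))
  invisible(x)
}

# Per-cell +1/-1 labels inherited from each cell's condition.
.cell_labels <- function(cells, labeling) {
  cond <- as.character(cells$condition)
  missing <- setdiff(unique(cond), names(labeling$labels))
  if (length(missing)) stopf("unlabeled condition(s): %s",
                             paste(missing, collapse = ", "))
  ifelse(labeling$labels[cond] == "high", 1, -1)
}

# Pooled held-out scores under leave-one-condition-out cross-validation.
.loco_scores <- function(X, y, cond, n_estimators, learning_rate) {
  scores <- rep(NA_real_, length(y))
  for (cn in unique(cond)) {
    hold <- cond == cn
    ytr <- y[!hold]
    if (length(unique(ytr)) < 2L) { scores[hold] <- 0; next }
    fit <- adaboost(X[!hold, , drop = FALSE], ytr,
                    n_estimators = n_estimators,
                    learning_rate = learning_rate)
    scores[hold] <- predict(fit, X[hold, , drop = FALSE], type = "score")
  }
  scores
}

#' Rank single features as one-feature boosted classifiers
#'
#' Trains a one-feature AdaBoost model per feature and ranks features by
#' training-set AUROC, descending; ties break by feature name.
#'
#' @param cells Per-cell table with a \code{condition} column and feature
#'   columns.
#' @param labeling A \code{\link{label_conditions}} result.
#' @param features Feature columns to rank (default the 11 shape features).
#' @param n_estimators,learning_rate AdaBoost settings.
#' @return Data frame \code{feature, auroc} sorted by rank.
#' @export
rank_single_features <- function(cells, labeling,
                                 features = shape_feature_names(),
                                 n_estimators = 50L, learning_rate = 1) {
  y <- .cell_labels(cells, labeling)
  aucs <- vapply(features, function(f) {
    X <- as.matrix(cells[, f, drop = FALSE])
    fit <- adaboost(X, y, n_estimators = n_estimators,
                    learning_rate = learning_rate)
    auroc(predict(fit, X, type = "score"), y)
  }, numeric(1))
  out <- data.frame(feature = features, auroc = unname(aucs))
  out[order(-out$auroc, out$feature), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Evaluate feature-group classifiers
#'
#' For each feature group, reports the training-set AUROC and the
#' generalization AUROC under leave-one-condition-out cross-validation (all
#' cells of one condition held out per fold; the AUROC is computed on the
#' pooled held-out scores, since a single held-out condition has only one
#' class).
#'
#' @param cells Per-cell table with \code{condition} plus feature columns
#'   (shape features, or e.g. \code{speed}/\code{persistence} for migration
#'   groups).
#' @param labeling A \code{\link{label_conditions}} result.
#' @param groups Named list of character vectors of feature columns; default
#'   the all/size/irregularity/elongation shape families.
#' @param n_estimators,learning_rate AdaBoost settings.
#' @return Data frame \code{group, n_features, auroc_train, auroc_cv,
#'   n_cells}.
#' @export
evaluate_feature_groups <- function(cells, labeling,
                                    groups = shape_feature_groups(),
                                    n_estimators = 50L, learning_rate = 1) {
  y <- .cell_labels(cells, labeling)
  cond <- as.character(cells$condition)
  rows <- lapply(names(groups), function(gn) {
    feats <- groups[[gn]]
    if (!length(feats)) stopf("group '%s' is empty", gn)
    if (anyDuplicated(feats)) {
      warnf("group '%s' has duplicate feature(s); deduplicated", gn)
      feats <- unique(feats)
    }
    miss <- setdiff(feats, names(cells))
    if (length(miss)) stopf("group '%s' references missing column(s): %s",
                            gn, paste(miss, collapse = ", "))
    X <- as.matrix(cells[, feats, drop = FALSE])
    fit <- adaboost(X, y, n_estimators = n_estimators,
                    learning_rate = learning_rate)
    cv <- .loco_scores(X, y, cond, n_estimators, learning_rate)
    data.frame(group = gn, n_features = length(feats),
               auroc_train = auroc(predict(fit, X, type = "score"), y),
               auroc_cv = auroc(cv, y), n_cells = nrow(X))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hyperparameter grid search for the boosted classifier
#'
#' Full factorial grid of learning rate x number of estimators; each cell
#' reports the leave-one-condition-out AUROC (pooled held-out scores) and the
#' training AUROC on all 11 features (or the supplied columns). The
#' recommended default cell (learning rate 1, 50 estimators) is flagged.
#'
#' @param cells Per-cell table with \code{condition} and feature columns.
#' @param labeling A \code{\link{label_conditions}} result.
#' @param learning_rates,estimator_counts Non-empty grids.
#' @param features Feature columns to use.
#' @return Data frame \code{learning_rate, n_estimators, auroc_train,
#'   auroc_cv, is_default}.
#' @export
adaboost_grid_search <- function(cells, labeling,
                                 learning_rates = c(0.5, 1, 2),
                                 estimator_counts = c(10L, 50L, 100L),
                                 features = shape_feature_names()) {
  if (!length(learning_rates) || !length(estimator_counts)) {
    stopf("grids must be non-empty")
  }
  y <- .cell_labels(cells, labeling)
  cond <- as.character(cells$condition)
  X <- as.matrix(cells[, features, drop = FALSE])
  grid <- expand.grid(learning_rate = learning_rates,
                      n_estimators = estimator_counts)
  grid$auroc_train <- NA_real_; grid$auroc_cv <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- adaboost(X, y, n_estimators = grid$n_estimators[i],
                    learning_rate = grid$learning_rate[i])
    grid$auroc_train[i] <- auroc(predict(fit, X, type = "score"), y)
    cv <- .loco_scores(X, y, cond, grid$n_estimators[i], grid$learning_rate[i])
    grid$auroc_cv[i] <- auroc(cv, y)
  }
  grid$is_default <- grid$learning_rate == 1 & grid$n_estimators == 50L
  grid
}
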