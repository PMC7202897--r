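# NIPALS partial least squares regression from condition-level predictors to
# migration/invasion responses, with R2, leave-one-out Q2, permutation
# validation, VIP scores, component selection and new-condition prediction.
#
# Rows are conditions (per-condition means), not single cells. Both X and Y
# are autoscaled (mean 0, unit variance per column); components are extracted
# by NIPALS with deterministic initialization from the largest-variance Y
# column, deflating both blocks.

#' Fit a PLS regression model (NIPALS)
#'
#' @param X Condition x predictor matrix or data frame (no missing values,
#'   >= 3 rows). Zero-variance columns are dropped with a warning.
#' @param Y Condition x response matrix, data frame or vector.
#' @param ncomp Number of latent components (>= 1); truncated with a warning
#'   when it exceeds the rank of the scaled X.
#' @param tol,max_iter NIPALS convergence tolerance and iteration cap per
#'   component.
#' @return Object of class \code{ecm_pls}: scaling vectors, \code{W}
#'   (X weights, unit norm), \code{P} (X loadings), \code{Q} (Y loadings),
#'   \code{T} (scores), cumulative R2 (overall and per response), per-
#'   component explained Y variance (\code{ssy}), and the training data for
#'   augmentation.
#' @export
pls_fit <- function(X, Y, ncomp = 2L, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(NULL, "response"))
  Y <- as.matrix(Y); storage.mode(Y) <- "double"
  if (nrow(X) < 3L) stopf("PLS needs at least 3 rows")
  if (nrow(X) != nrow(Y)) stopf("X and Y row counts differ")
  if (anyNA(X) || anyNA(Y)) stopf("missing values are not allowed")
  if (ncomp < 1L) stopf("ncomp must be >= 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))

  x_sd <- apply(X, 2, stats::sd)
  if (any(x_sd == 0)) {
    warnf("dropping zero-variance predictor(s): %s",
          paste(colnames(X)[x_sd == 0], collapse = ", "))
    X <- X[, x_sd > 0, drop = FALSE]
    x_sd <- x_sd[x_sd > 0]
  }
  if (!ncol(X)) stopf("no predictors with non-zero variance")
  y_sd <- apply(Y, 2, stats::sd)
  if (any(y_sd == 0)) stopf("zero-variance response(s): %s",
                            paste(colnames(Y)[y_sd == 0], collapse = ", "))
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  Ys <- sweep(sweep(Y, 2, y_mean), 2, y_sd, "/")

  n <- nrow(Xs); p <- ncol(Xs); m <- ncol(Ys)
  a_max <- min(ncomp, n - 1L, p)
  if (a_max < ncomp) warnf("ncomp truncated from %d to %d", ncomp, a_max)
  W <- P <- matrix(0, p, a_max); Q <- matrix(0, m, a_max)
  TT <- matrix(0, n, a_max)
  Xd <- Xs; Yd <- Ys
  ssy_total <- sum(Ys^2)
  ssy_resp <- colSums(Ys^2)
  r2 <- numeric(0); r2_resp <- NULL
  a_used <- 0L
  for (a in seq_len(a_max)) {
    if (sum(Xd^2) < 1e-12 * max(sum(Xs^2), 1)) {
      warnf("ncomp truncated to %d: X exhausted (rank deficiency)", a_used)
      break
    }
    u <- Yd[, which.max(apply(Yd, 2, stats::var)), drop = TRUE]
    t_old <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u)) / sum(u^2)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-15) break
      w <- w / nw
      tt <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, tt)) / sum(tt^2)
      if (sum(q^2) < 1e-30) break
      u <- drop(Yd %*% q) / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(sqrt(sum(tt^2)), 1e-30)) {
        t_old <- tt; break
      }
      t_old <- tt
    }
    tt <- t_old
    if (sum(tt^2) < 1e-20) {
      warnf("ncomp truncated to %d: degenerate component", a_used)
      break
    }
    pp <- drop(crossprod(Xd, tt)) / sum(tt^2)
    q <- drop(crossprod(Yd, tt)) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, q)
    a_used <- a + 0L
    W[, a] <- w; P[, a] <- pp; Q[, a] <- q; TT[, a] <- tt
    r2 <- c(r2, 1 - sum(Yd^2) / ssy_total)
    r2_resp <- rbind(r2_resp, 1 - colSums(Yd^2) / ssy_resp)
  }
  if (a_used == 0L) stopf("no PLS component could be extracted")
  keep <- seq_len(a_used)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]; TT <- TT[, keep, drop = FALSE]
  ssy <- (Q^2) * rep(colSums(TT^2), each = m)  # m x A explained Y variance
  dimnames(ssy) <- list(colnames(Ys), NULL)
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Q) <- colnames(Y)
  colnames(r2_resp) <- colnames(Y)
  structure(list(x_mean = x_mean, x_scale = x_sd, y_mean = y_mean,
                 y_scale = y_sd, W = W, P = P, Q = Q, T = TT,
                 ncomp = a_used, r2 = r2, r2_response = r2_resp, ssy = ssy,
                 X = X, Y = Y,
                 predictors = colnames(X), responses = colnames(Y)),
            class = "ecm_pls")
}

# Regression coefficients on the autoscaled blocks for components 1..a.
.pls_beta <- function(fit, a = fit$ncomp) {
  k <- seq_len(a)
  W <- fit$W[, k, drop = FALSE]; P <- fit$P[, k, drop = FALSE]
  Q <- fit$Q[, k, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Predict responses for new conditions
#'
#' New predictor rows are autoscaled with the training statistics and the
#' prediction is back-transformed to original units.
#'
#' @param object An \code{ecm_pls} fit.
#' @param newdata Matrix or data frame containing the model's predictor
#'   columns.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Matrix of predicted responses in original units.
#' @export
predict.ecm_pls <- function(object, newdata, ncomp = NULL, ...) {
  a <- ncomp %||% object$ncomp
  if (a < 1L || a > object$ncomp) stopf("ncomp must be in 1..%d", object$ncomp)
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$predictors)) {
    colnames(newdata) <- object$predictors
  }
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$predictors, colnames(nd))
  if (length(miss)) stopf("missing predictor(s): %s", paste(miss, collapse = ", "))
  Xn <- as.matrix(nd[, object$predictors, drop = FALSE])
  storage.mode(Xn) <- "double"
  Xs <- sweep(sweep(Xn, 2, object$x_mean), 2, object$x_scale, "/")
  Yhat <- Xs %*% .pls_beta(object, a)
  sweep(sweep(Yhat, 2, object$y_scale, "*"), 2, object$y_mean, "+")
}

#' @export
coef.ecm_pls <- function(object, ncomp = NULL, ...) {
  a <- ncomp %||% object$ncomp
  B <- .pls_beta(object, a)
  Bo <- diag(1 / object$x_scale, nrow = length(object$x_scale)) %*% B %*%
    diag(object$y_scale, nrow = length(object$y_scale))
  dimnames(Bo) <- list(object$predictors, object$responses)
  intercept <- object$y_mean - drop(object$x_mean %*% Bo)
  rbind(`(intercept)` = intercept, Bo)
}

#' @export
residuals.ecm_pls <- function(object, ncomp = NULL, ...) {
  object$Y - predict(object, object$X, ncomp = ncomp)
}

#' @export
print.ecm_pls <- function(x, ...) {
  cat(sprintf("PLS model: %d predictors -> %s; %d component(s)\n",
              length(x$predictors), paste(x$responses, collapse = ", "),
              x$ncomp))
  cat("  cumulative R2:", paste(sprintf("%.3f", x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ecm_pls <- function(object, ...) {
  cat(sprintf("PLS (NIPALS, autoscaled): n = %d conditions, %d predictors, %d response(s), A = %d\n",
              nrow(object$T), length(object$predictors),
              length(object$responses), object$ncomp))
  tab <- data.frame(component = seq_len(object$ncomp),
                    R2_cumulative = object$r2)
  print(cbind(tab, object$r2_response), row.names = FALSE)
  v <- vip_scores(object)
  cat("predictors with overall VIP > 1:",
      paste(rownames(v)[v[, "overall"] > 1], collapse = ", "), "\n")
  invisible(object)
}

#' Scores plot of a PLS model
#'
#' @param x An \code{ecm_pls} fit.
#' @param comps Which two components to plot.
#' @param ... Passed to \code{plot}.
#' @export
plot.ecm_pls <- function(x, comps = c(1, 2), ...) {
  if (x$ncomp < 2) stopf("scores plot needs >= 2 components")
  graphics::plot(x$T[, comps[1]], x$T[, comps[2]],
                 xlab = sprintf("scores, component %d", comps[1]),
                 ylab = sprintf("scores, component %d", comps[2]), ...)
  labs <- rownames(x$X) %||% seq_len(nrow(x$T))
  graphics::text(x$T[, comps[1]], x$T[, comps[2]], labels = labs, pos = 3,
                 cex = 0.8)
  invisible(x)
}

#' Leave-one-condition-out Q2 diagnostics
#'
#' For every held-out row the model is refit on the remainder (scaling
#' recomputed per fold) and the held-out response predicted with 1..ncomp
#' components. Q2 = 1 - PRESS/TSS with TSS about the training-fold means,
#' reported cumulatively per component count; the overall Q2 averages the
#' per-response Q2 (each response on its own TSS scale). R2 comes from the
#' full-data fit.
#'
#' @inheritParams pls_fit
#' @return Object of class \code{pls_diagnostics}: \code{Q2} (overall, per
#'   component count), \code{Q2_response}, \code{R2}, \code{R2_response},
#'   \code{ncomp}.
#' @export
q2_loocv <- function(X, Y, ncomp = 2L) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(NULL, "response"))
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 4L) stopf("leave-one-out Q2 needs at least 4 rows")
  full <- pls_fit(X, Y, ncomp = ncomp)
  a_max <- full$ncomp
  m <- ncol(Y)
  press <- matrix(0, a_max, m); tss <- rep(0, m)
  flagged <- FALSE
  for (i in seq_len(n)) {
    ytr <- Y[-i, , drop = FALSE]
    sd_tr <- apply(ytr, 2, stats::sd)
    if (any(sd_tr == 0)) { flagged <- TRUE; next }
    fit <- suppressWarnings(pls_fit(X[-i, , drop = FALSE], ytr, ncomp = a_max))
    for (a in seq_len(a_max)) {
      aa <- min(a, fit$ncomp)
      yhat <- predict(fit, X[i, , drop = FALSE], ncomp = aa)
      press[a, ] <- press[a, ] + (Y[i, ] - drop(yhat))^2
    }
    tss <- tss + (Y[i, ] - colMeans(ytr))^2
  }
  if (flagged) warnf("fold(s) with zero-variance response skipped; Q2 partial")
  q2_resp <- 1 - sweep(press, 2, tss, "/")
  colnames(q2_resp) <- colnames(full$Y)
  structure(list(Q2 = rowMeans(q2_resp), Q2_response = q2_resp,
                 R2 = full$r2, R2_response = full$r2_response,
                 ncomp = a_max), class = "pls_diagnostics")
}

#' @export
print.pls_diagnostics <- function(x, ...) {
  print(data.frame(A = seq_len(x$ncomp), R2 = x$R2, Q2 = x$Q2),
        row.names = FALSE)
  invisible(x)
}

#' Choose the number of PLS components from Q2 diagnostics
#'
#' Picks the smallest component count whose Q2 is within \code{delta} of the
#' maximum Q2, excluding counts where Q2 drops by more than \code{delta} from
#' the previous count (overfitting: R2 keeps rising while Q2 falls). If every
#' Q2 is negative the model is flagged as overfit and 1 is returned with a
#' warning.
#'
#' @param diag A \code{\link{q2_loocv}} result (ncomp >= 2).
#' @param delta Tolerance on Q2 (default 0.02).
#' @return Integer component count.
#' @export
choose_components <- function(diag, delta = 0.02) {
  q2 <- diag$Q2
  if (length(q2) < 2L) stopf("diagnostics must cover at least 2 components")
  if (all(q2 < 0)) {
    warnf("all Q2 negative: model does not predict (overfitting); returning 1")
    return(1L)
  }
  ok <- q2 >= max(q2) - delta
  no_drop <- c(TRUE, diff(q2) >= -delta)
  cand <- which(ok & no_drop)
  if (!length(cand)) cand <- which.max(q2)
  as.integer(min(cand))
}

#' VIP scores of a fitted PLS model
#'
#' VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a), where
#' SSY_a is the Y variance explained by component a: pooled over responses
#' for the overall score, and per response (using that response's Q loadings)
#' for the per-response variant. sum_j VIP_j^2 = p by construction.
#'
#' @param model An \code{ecm_pls} fit.
#' @return Matrix, predictors x (responses..., overall), of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "ecm_pls"))
  W2 <- model$W^2                           # columns already unit norm
  p <- nrow(W2)
  ssy <- model$ssy                          # m x A
  per_resp <- apply(ssy, 1, function(s) {
    sqrt(p * drop(W2 %*% s) / sum(s))
  })
  overall <- sqrt(p * drop(W2 %*% colSums(ssy)) / sum(ssy))
  out <- cbind(per_resp, overall = overall)
  rownames(out) <- model$predictors
  out
}

#' Permutation test of the PLS Q2
#'
#' Rows of Y are permuted relative to X and the leave-one-out Q2 recomputed
#' for each permutation, giving the null distribution of Q2 for a model with
#' no X-Y link. The empirical p-value uses the add-one correction
#' (b + 1) / (N + 1).
#'
#' @inheritParams pls_fit
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return Object of class \code{pls_permutation}: \code{observed},
#'   \code{null} (vector of permuted Q2), \code{p_value}, \code{n_perm}.
#' @export
pls_permutation_test <- function(X, Y, ncomp = 2L, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stopf("n_perm must be >= 100")
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                   dimnames = list(NULL, "response"))
  Y <- as.matrix(Y)
  obs <- q2_loocv(X, Y, ncomp = ncomp)
  a <- obs$ncomp
  observed <- obs$Q2[a]
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Yp <- Y[sample.int(nrow(Y)), , drop = FALSE]
      d <- try(suppressWarnings(q2_loocv(X, Yp, ncomp = a)), silent = TRUE)
      if (inherits(d, "try-error")) -Inf else d$Q2[d$ncomp]
    }, numeric(1))
  })
  structure(list(observed = observed, null = null,
                 p_value = (sum(null >= observed) + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm)), class = "pls_permutation")
}

#' @export
print.pls_permutation <- function(x, ...) {
  cat(sprintf("PLS permutation test: observed Q2 = %.3f, null mean = %.3f, p = %.4f (%d permutations)\n",
              x$observed, mean(x$null[is.finite(x$null)]), x$p_value,
              x$n_perm))
  invisible(x)
}

#' Predict a new condition and report percent error
#'
#' @param model An \code{ecm_pls} fit.
#' @param x_new One or more new predictor rows (must contain the model's
#'   predictor columns).
#' @param y_actual Optional matrix/vector of measured responses for the new
#'   condition(s).
#' @param condition Condition label(s) for the report.
#' @param ncomp Components to use.
#' @return Data frame \code{condition, response, predicted, actual,
#'   percent_error}; percent error = 100 |pred - actual| / |actual|, reported
#'   as NA (undefined) when the actual value is 0.
#' @export
predict_report <- function(model, x_new, y_actual = NULL, condition = NULL,
                           ncomp = NULL) {
  pred <- predict(model, x_new, ncomp = ncomp)
  nr <- nrow(pred)
  condition <- condition %||% (rownames(pred) %||% paste0("new", seq_len(nr)))
  if (!is.null(y_actual)) {
    if (is.null(dim(y_actual))) {
      y_actual <- matrix(y_actual, nrow = nr,
                         dimnames = list(NULL, model$responses))
    }
    y_actual <- as.matrix(y_actual)[, model$responses, drop = FALSE]
  }
  rows <- lapply(seq_len(nr), function(i) {
    act <- if (is.null(y_actual)) rep(NA_real_, ncol(pred)) else y_actual[i, ]
    pe <- ifelse(is.na(act) | act == 0, NA_real_,
                 100 * abs(pred[i, ] - act) / abs(act))
    data.frame(condition = condition[i], response = model$responses,
               predicted = unname(pred[i, ]), actual = unname(act),
               percent_error = unname(pe))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Augment the training set and refit at the same number of components
#'
#' Extends the training matrices with rows from another cell line (or new
#' conditions), recomputes the scaling and refits. With zero new rows the
#' model is returned unchanged.
#'
#' @param model An \code{ecm_pls} fit.
#' @param new_X,new_Y New rows sharing the model's predictor/response
#'   columns.
#' @return A refit \code{ecm_pls} model.
#' @export
augment_and_refit <- function(model, new_X, new_Y) {
  stopifnot(inherits(model, "ecm_pls"))
  if (is.null(new_X) || nrow(as.matrix(new_X)) == 0L) return(model)
  nx <- as.data.frame(new_X)
  miss <- setdiff(model$predictors, colnames(nx))
  if (length(miss)) stopf("new rows lack predictor(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(dim(new_Y))) {
    new_Y <- matrix(new_Y, nrow = nrow(nx),
                    dimnames = list(NULL, model$responses))
  }
  ny <- as.data.frame(new_Y)
  missy <- setdiff(model$responses, colnames(ny))
  if (length(missy)) stopf("new rows lack response(s): %s",
                           paste(missy, collapse = ", "))
  X2 <- rbind(model$X, as.matrix(nx[, model$predictors, drop = FALSE]))
  Y2 <- rbind(model$Y, as.matrix(ny[, model$responses, drop = FALSE]))
  pls_fit(X2, Y2, ncomp = model$ncomp)
}
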