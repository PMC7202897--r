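# Programmatic fixtures and independent brute-force oracles.

# Pixel set (x, y matrix) of a filled disk of radius r px, centred on an
# odd-sized canvas with `pad` background pixels around it.
disk_pixels <- function(r, pad = 3) {
  n <- 2 * r + 2 * pad + 1
  cx <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  as.matrix(g[(g$x - cx)^2 + (g$y - cx)^2 <= r^2, ])
}

# Pixel set of a filled axis-aligned ellipse with semi-axes a >= b px.
ellipse_pixels <- function(a, b, pad = 3) {
  nx <- 2 * a + 2 * pad + 1; ny <- 2 * b + 2 * pad + 1
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  as.matrix(g[((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1, ])
}

# Mask with pixel sets painted as labels on a canvas.
mask_from_pixels <- function(..., dim, pixel_size = 1) {
  sets <- list(...)
  labs <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(sets)) labs[sets[[i]]] <- i
  labeled_mask(labs, pixel_size)
}

# Pixel set of a rotated, radially perturbed ellipse (for oracle fuzzing).
perturbed_ellipse_pixels <- function(a, b, irr, phi, coefs, canvas = 181) {
  cx <- (canvas + 1) / 2
  g <- expand.grid(x = seq_len(canvas), y = seq_len(canvas))
  dx <- g$x - cx; dy <- g$y - cx
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  th <- atan2(v, u)
  re <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  f <- 0
  for (k in seq_along(coefs$c)) {
    f <- f + coefs$c[k] * cos((k + 1) * th) + coefs$s[k] * sin((k + 1) * th)
  }
  keep <- sqrt(u^2 + v^2) <= re * pmax(1 + irr * f, 0.25)
  as.matrix(g[keep, ])
}

# Independent brute-force shape oracles working directly on the pixel set.
bf_area <- function(px, pixel_size) nrow(px) * pixel_size^2
bf_extent <- function(px) {
  nrow(px) / ((max(px[, 1]) - min(px[, 1]) + 1) *
                (max(px[, 2]) - min(px[, 2]) + 1))
}
bf_eccentricity <- function(px) {
  x <- px[, 1] - mean(px[, 1]); y <- px[, 2] - mean(px[, 2])
  cm <- matrix(c(mean(x^2), mean(x * y), mean(x * y), mean(y^2)), 2, 2)
  ev <- eigen(cm, symmetric = TRUE)$values
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# O(n^2) pair-counting AUROC oracle.
bf_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive decision-stump oracle: best (feature, midpoint threshold,
# polarity) under weights w by full enumeration.
bf_best_stump <- function(X, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    xu <- sort(unique(X[, j]))
    if (length(xu) < 2) next
    for (thr in (xu[-1] + xu[-length(xu)]) / 2) {
      for (pol in c(1, -1)) {
        pred <- ifelse(X[, j] > thr, pol, -pol)
        err <- sum(w[pred != y])
        if (err < best$err - 1e-12) {
          best <- list(err = err, feature = j, threshold = thr, polarity = pol)
        }
      }
    }
  }
  best
}

# Independent discrete-AdaBoost re-implementation built on the exhaustive
# stump oracle (for whole-model equivalence at small n).
bf_adaboost_predict <- function(X, y, n_rounds) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  score <- rep(0, n)
  for (t in seq_len(n_rounds)) {
    st <- bf_best_stump(X, y, w)
    if (!is.finite(st$err) || st$err >= 0.5 - 1e-12) break
    eps <- min(max(st$err, 1e-12), 1 - 1e-12)
    alpha <- 0.5 * log((1 - eps) / eps)
    h <- ifelse(X[, st$feature] > st$threshold, st$polarity, -st$polarity)
    score <- score + alpha * h
    if (st$err <= 1e-12) break
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  sign(score)
}

# Study config where only elongation differs between the two classes
# (size and irregularity identical), speeds straddling the 0.5 um/min
# threshold so the class signal rides exclusively on elongation features.
elongation_signal_config <- function(n_cells = 40L) {
  lapply(1:6, function(i) {
    hi <- i > 3
    condition_spec(name = sprintf("C%d", i), n_cells = n_cells,
                   size_scale = 20, elongation = if (hi) 0.85 else 0.35,
                   irregularity = 0.12,
                   speed_base = if (hi) 0.7 else 0.3,
                   persistence_base = 0.4)
  })
}

# Per-condition summary tables of a generated study (features + motility +
# spheroids), shared by several end-to-end tests.
study_tables <- function(study) {
  ft <- do.call(rbind, lapply(names(study$masks), function(cn)
    profile_table(study$masks[[cn]], cn)))
  mt <- motility_table(study$trajectories)
  sm <- summarize_conditions(ft, mt, study$spheroids)
  list(features = ft, metrics = mt, summaries = sm)
}

# X/Y blocks of the strong-link recovery experiment: shape means predict
# speed, persistence and invasion fold change at the condition level.
recovery_xy <- function(seed, n_conditions = 8L, n_cells = 40L, ...) {
  config <- linked_study_config(n_conditions = n_conditions, seed = seed,
                                n_cells = n_cells, ...)
  config <- lapply(config, function(sp) { sp$noise_sd["fold"] <- 0.08; sp })
  study <- generate_study(config, master_seed = seed)
  tabs <- study_tables(study)
  sm <- tabs$summaries
  X <- as.matrix(sm[, shape_feature_names()])
  rownames(X) <- sm$condition
  Y <- as.matrix(sm[, c("mean_speed", "mean_persistence", "mean_invasion")])
  colnames(Y) <- c("speed", "persistence", "invasion")
  rownames(Y) <- sm$condition
  list(X = X, Y = Y, summaries = sm, truth = study$truth)
}

elong_irreg_features <- c("eccentricity", "aspect_ratio", "compactness",
                          "solidity", "extent", "form_factor")
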