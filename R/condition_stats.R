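# Condition-level aggregation, clustering of mean profiles, kNN graph and PCA.

#' Aggregate single-cell tables into per-condition summaries
#'
#' Per-condition means of the 11 shape features, 2D speed and persistence,
#' and the mean spheroid invasion fold change. Conditions missing a modality
#' are kept with NA for that modality and flagged with a warning; an empty
#' intersection of condition labels is an error.
#'
#' @param features Per-cell feature table (\code{\link{profile_table}}).
#' @param metrics Per-cell migration metrics (\code{\link{motility_table}}).
#' @param spheroids Spheroid table (\code{\link{generate_spheroids}} schema).
#' @param cell_line Optional named character vector mapping condition to cell
#'   line.
#' @return Data frame, one row per condition: \code{condition, cell_line,
#'   n_cells}, the 11 feature means, \code{mean_speed, mean_persistence,
#'   mean_invasion}.
#' @export
summarize_conditions <- function(features, metrics = NULL, spheroids = NULL,
                                 cell_line = NULL) {
  fn <- shape_feature_names()
  if (!all(fn %in% names(features))) stopf("features table lacks the 11 shape columns")
  conds <- unique(as.character(features$condition))
  if (!length(conds)) stopf("no conditions in features table")
  present <- conds
  if (!is.null(metrics)) present <- intersect(present, unique(as.character(metrics$condition)))
  if (!is.null(spheroids)) present <- intersect(present, unique(as.character(spheroids$condition)))
  if (!length(present)) stopf("empty intersection of condition labels across tables")
  if (length(setdiff(conds, present))) {
    warnf("condition(s) missing a modality: %s",
          paste(setdiff(conds, present), collapse = ", "))
  }
  rows <- lapply(conds, function(cn) {
    f <- features[features$condition == cn, fn, drop = FALSE]
    out <- data.frame(condition = cn,
                      cell_line = if (is.null(cell_line)) NA_character_ else
                        unname(cell_line[cn]),
                      n_cells = nrow(f))
    out <- cbind(out, as.data.frame(as.list(colMeans(f))))
    out$mean_speed <- if (is.null(metrics)) NA_real_ else
      mean(metrics$speed[metrics$condition == cn])
    out$mean_persistence <- if (is.null(metrics)) NA_real_ else
      mean(metrics$persistence[metrics$condition == cn], na.rm = TRUE)
    out$mean_invasion <- if (is.null(spheroids)) NA_real_ else {
      sp <- spheroids[spheroids$condition == cn, ]
      if (nrow(sp)) mean(fold_change(sp$area_day1_um2, sp$area_day5_um2))
      else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-correlation average-linkage clustering of mean profiles
#'
#' Mean-centers the condition x feature matrix column-wise, computes pairwise
#' distances 1 - Spearman rho between the requested items (conditions or
#' features), and agglomerates by average linkage. Items are pre-sorted
#' lexicographically so equal-height merges resolve deterministically to the
#' lexicographically smallest pair. Zero-variance items (Spearman undefined)
#' are dropped with a warning.
#'
#' @param summaries Condition summary table (\code{\link{summarize_conditions}})
#'   or a plain numeric matrix with rownames.
#' @param which Cluster \code{"conditions"} (rows) or \code{"features"}
#'   (columns).
#' @return List: \code{hclust} (merge tree), \code{order} (leaf labels in
#'   dendrogram order), \code{matrix} (mean-centered matrix with rows in item
#'   order), \code{distance}.
#' @export
cluster_heatmap <- function(summaries, which = c("conditions", "features")) {
  which <- match.arg(which)
  m <- .summary_matrix(summaries)
  m <- sweep(m, 2, colMeans(m))  # mean-center each feature
  items <- if (which == "conditions") m else t(m)
  items <- items[order(rownames(items)), , drop = FALSE]
  if (nrow(items) < 3L) stopf("need at least 3 items to cluster")
  sds <- apply(items, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping zero-variance item(s): %s",
          paste(rownames(items)[sds == 0], collapse = ", "))
    items <- items[sds > 0, , drop = FALSE]
  }
  rho <- stats::cor(t(items), method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = rownames(items)[hc$order],
       matrix = items, distance = d)
}

.summary_matrix <- function(summaries, cols = shape_feature_names()) {
  if (is.matrix(summaries)) return(summaries)
  if (!all(cols %in% names(summaries))) {
    stopf("summary table lacks columns: %s",
          paste(setdiff(cols, names(summaries)), collapse = ", "))
  }
  m <- as.matrix(summaries[, cols, drop = FALSE])
  rownames(m) <- as.character(summaries$condition)
  m
}

#' k-nearest-neighbour graph of single cells in shape space
#'
#' Features are z-scored over all cells pooled across conditions; the kNN
#' edge list is computed in Euclidean distance in the standardized space. 2D
#' coordinates come from a deterministic force-directed layout of the graph
#' (a visualization hook in the SPRING style; the layout itself is not a
#' tested quantity).
#'
#' @param features Per-cell feature table or numeric matrix.
#' @param k Number of neighbours (0 < k < number of cells).
#' @param layout_seed Seed for the force-directed layout.
#' @return List: \code{edges} (data frame from, to, dist), \code{coords}
#'   (n x 2), \code{k}, \code{metric}.
#' @export
knn_graph <- function(features, k = 5L, layout_seed = 1L) {
  x <- if (is.matrix(features)) features else
    as.matrix(features[, intersect(shape_feature_names(), names(features)),
                       drop = FALSE])
  n <- nrow(x)
  if (k <= 0) stopf("k must be positive")
  if (k >= n) stopf("k must be smaller than the number of cells")
  sds <- apply(x, 2, stats::sd)
  x <- scale(x[, sds > 0, drop = FALSE])
  from <- integer(0); to <- integer(0); dd <- numeric(0)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    ii <- start:min(start + block - 1L, n)
    d2 <- outer(rowSums(x[ii, , drop = FALSE]^2), rowSums(x^2), "+") -
      2 * x[ii, , drop = FALSE] %*% t(x)
    for (r in seq_along(ii)) {
      drow <- d2[r, ]
      drow[ii[r]] <- Inf
      nb <- order(drow)[seq_len(k)]
      from <- c(from, rep(ii[r], k)); to <- c(to, nb)
      dd <- c(dd, sqrt(pmax(drow[nb], 0)))
    }
  }
  edges <- data.frame(from = from, to = to, dist = dd)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  coords <- with_seed(layout_seed, igraph::layout_with_fr(g))
  list(edges = edges, coords = coords, k = as.integer(k),
       metric = "euclidean")
}

#' PCA of standardized shape features
#'
#' @param features Per-cell feature table or numeric matrix.
#' @param n_components Number of components to return (<= number of
#'   features).
#' @return List: \code{scores}, \code{loadings}, \code{variance_fraction}
#'   (non-increasing, summing to <= 1 over the returned components).
#' @export
shape_pca <- function(features, n_components = 2L) {
  x <- if (is.matrix(features)) features else
    as.matrix(features[, intersect(shape_feature_names(), names(features)),
                       drop = FALSE])
  if (n_components > ncol(x)) stopf("n_components exceeds number of features")
  if (nrow(x) < n_components) stopf("fewer cells than components")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping zero-variance feature(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(min(n_components, ncol(pc$x)))
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       variance_fraction = vf[k])
}
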