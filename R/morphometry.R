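# The 11 cell-shape descriptors from labeled masks, with border-cell exclusion.
#
# Conventions: the label grid is indexed [x, y]; pixel centers sit at integer
# coordinates; the centroid is the unweighted pixel-center mean; holes are
# filled before any computation; the boundary is a sub-pixel marching-squares
# polygon smoothed by two rounds of vertex averaging (a raw marching-squares
# staircase overestimates a disk perimeter by ~5%, which would make the
# circle's form-factor anchor of 1 unattainable).

#' Construct a labeled mask
#'
#' @param labels Integer matrix; 0 = background, k > 0 = pixels of cell k.
#'   Labels need not be contiguous.
#' @param pixel_size Micrometres per pixel (> 0, finite).
#' @return An object of class \code{labeled_mask}.
#' @export
labeled_mask <- function(labels, pixel_size) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  if (any(labels < 0)) stopf("labels must be non-negative")
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stopf("pixel_size must be finite and positive")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("labeled mask %d x %d px @ %.3g um/px, %d labels\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Write / read a 16-bit single-channel label TIFF
#'
#' @param mask A \code{\link{labeled_mask}} (labels must fit in 16 bits).
#' @param path Output file.
#' @return \code{write_mask}: invisibly, \code{path}.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (max(mask$labels) > 65535L) stopf("labels exceed 16-bit range")
  tiff::writeTIFF(t(mask$labels) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @param pixel_size Micrometres per pixel of the stored image.
#' @return \code{read_mask}: a \code{\link{labeled_mask}}.
#' @export
read_mask <- function(path, pixel_size) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labeled_mask(t(round(img)), pixel_size)
}

#' Extract interior cells from a labeled mask
#'
#' Returns every labeled region whose pixel set does not touch the first or
#' last row or column of the grid; regions touching any border are discarded
#' (cells clipped by the image edge have unmeasurable shape).
#'
#' @param mask A \code{\link{labeled_mask}}.
#' @return List with one element per retained cell: \code{id} (the label) and
#'   \code{pixels} (n x 2 integer matrix of x, y pixel coordinates). An
#'   all-background mask yields an empty list.
#' @export
extract_cells <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  labs <- mask$labels
  idx <- which(labs != 0L)
  if (!length(idx)) return(list())
  ai <- arrayInd(idx, dim(labs))
  vals <- labs[idx]
  nx <- nrow(labs); ny <- ncol(labs)
  by_label <- split(seq_along(vals), vals)
  out <- list()
  for (id in names(by_label)) {
    px <- ai[by_label[[id]], , drop = FALSE]
    if (any(px[, 1] == 1L | px[, 1] == nx | px[, 2] == 1L | px[, 2] == ny)) next
    colnames(px) <- c("x", "y")
    out[[length(out) + 1L]] <- list(id = as.integer(id), pixels = px)
  }
  out
}

# Closed-polygon vertex averaging (weights 1/4, 1/2, 1/4), used to relax the
# marching-squares staircase before measuring perimeter and hull.
.smooth_polygon <- function(x, y, iters = 2L) {
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  for (i in seq_len(iters)) {
    xp <- c(x[length(x)], x[-length(x)]); xn <- c(x[-1], x[1])
    yp <- c(y[length(y)], y[-length(y)]); yn <- c(y[-1], y[1])
    x <- (xp + 2 * x + xn) / 4; y <- (yp + 2 * y + yn) / 4
  }
  list(x = c(x, x[1]), y = c(y, y[1]))
}

.poly_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

.poly_area <- function(x, y) {
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Exact area-normalized central second moments of a closed polygon (Green's
# theorem). Used for the fitted ellipse: sub-pixel boundary moments avoid the
# lattice noise that inflates the eccentricity of small rasterized disks.
.poly_moments <- function(x, y) {
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  a <- x * y2 - x2 * y
  A <- sum(a) / 2
  cx <- sum((x + x2) * a) / (6 * A)
  cy <- sum((y + y2) * a) / (6 * A)
  ixx <- sum((x^2 + x * x2 + x2^2) * a) / 12
  iyy <- sum((y^2 + y * y2 + y2^2) * a) / 12
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * a) / 24
  list(area = abs(A),
       mu20 = ixx / A - cx^2, mu02 = iyy / A - cy^2,
       mu11 = ixy / A - cx * cy)
}

# Sub-pixel outer boundary polygon of a padded binary matrix via marching
# squares (grDevices::contourLines at level 0.5), smoothed.
.boundary_polygon <- function(binary, iters = 2L) {
  nx <- nrow(binary); ny <- ncol(binary)
  cl <- grDevices::contourLines(x = seq_len(nx), y = seq_len(ny),
                                z = binary, levels = 0.5)
  if (!length(cl)) stopf("no boundary found")
  lens <- vapply(cl, function(c0) .poly_length(c0$x, c0$y), numeric(1))
  outer <- cl[[which.max(lens)]]
  .smooth_polygon(outer$x, outer$y, iters = iters)
}

# Rotating-calipers style Feret diameters over convex-hull vertices: the
# maximum is the hull diameter, the minimum is the smallest width over hull
# edges (exact for convex polygons). Ties resolve to the first edge in hull
# order.
.feret <- function(hx, hy) {
  h <- length(hx)
  if (h == 1L) return(c(min = 0, max = 0))
  dmax <- 0
  for (i in seq_len(h - 1L)) {
    d <- sqrt((hx[(i + 1L):h] - hx[i])^2 + (hy[(i + 1L):h] - hy[i])^2)
    dmax <- max(dmax, d)
  }
  if (h == 2L) return(c(min = 0, max = dmax))
  wmin <- Inf
  for (i in seq_len(h)) {
    j <- if (i == h) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    el <- sqrt(ex^2 + ey^2)
    if (el < 1e-12) next
    w <- max(abs((hx - hx[i]) * ey - (hy - hy[i]) * ex) / el)
    if (w < wmin) wmin <- w
  }
  c(min = wmin, max = dmax)
}

#' Compute the 11 shape descriptors of one cell
#'
#' Definitions: area = pixel count x pixel_size^2; perimeter from the
#' smoothed marching-squares boundary polygon; eccentricity and aspect ratio
#' from the central-second-moment fitted ellipse; compactness = 2 pi x (mean
#' squared pixel distance from the centroid) / area, so a filled disk scores
#' exactly 1; extent = area fraction of the axis-aligned bounding box; form
#' factor = 4 pi area / perimeter^2; min/max Feret diameters by rotating
#' calipers on the convex hull of boundary vertices; mean radius = mean
#' interior distance-transform value (distance of each pixel to the closest
#' background pixel); solidity = area / convex-hull area. Holes are filled
#' first.
#'
#' @param pixels n x 2 integer matrix of x, y pixel coordinates (n >= 9;
#'   smaller regions are rejected as debris).
#' @param pixel_size Micrometres per pixel.
#' @return One-row data frame with the 11 features in canonical order
#'   (\code{\link{shape_feature_names}}). Degenerate one-pixel-wide regions
#'   get \code{aspect_ratio} capped at 100 and are flagged via the
#'   \code{degenerate} attribute.
#' @export
shape_profile <- function(pixels, pixel_size) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (nrow(pixels) < 9L) stopf("region with %d px rejected as debris (< 9 px)", nrow(pixels))
  if (!is.finite(pixel_size) || pixel_size <= 0) stopf("pixel_size must be positive")
  xr <- range(pixels[, 1]); yr <- range(pixels[, 2])
  nx <- xr[2] - xr[1] + 1L; ny <- yr[2] - yr[1] + 1L
  # local binary bbox with a 1-px zero pad (closes the boundary contour)
  bin <- matrix(0, nx + 2L, ny + 2L)
  bin[cbind(pixels[, 1] - xr[1] + 2L, pixels[, 2] - yr[1] + 2L)] <- 1
  bin <- EBImage::fillHull(bin)
  idx <- which(bin > 0)
  ai <- arrayInd(idx, dim(bin))
  n_px <- nrow(ai)
  area <- n_px * pixel_size^2

  cx <- mean(ai[, 1]); cy <- mean(ai[, 2])
  dx <- ai[, 1] - cx; dy <- ai[, 2] - cy
  # compactness is defined on the pixel set (mean squared pixel distance
  # from the centroid, disk-anchored at 1)
  compactness <- 2 * pi * (mean(dx^2) + mean(dy^2)) / n_px
  extent <- n_px / (nx * ny)

  poly <- .boundary_polygon(bin)
  # fitted ellipse from exact second moments of the sub-pixel boundary polygon
  pm <- .poly_moments(poly$x, poly$y)
  tr <- pm$mu20 + pm$mu02
  disc <- sqrt(max(tr^2 / 4 - (pm$mu20 * pm$mu02 - pm$mu11^2), 0))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 0)
  degenerate <- l2 < 1e-6
  eccentricity <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
  aspect_ratio <- if (degenerate) 100 else min(sqrt(l1 / l2), 100)
  per_px <- .poly_length(poly$x, poly$y)
  perimeter <- per_px * pixel_size
  form_factor <- 4 * pi * n_px / per_px^2

  vx <- poly$x[-length(poly$x)]; vy <- poly$y[-length(poly$y)]
  hidx <- grDevices::chull(vx, vy)
  hx <- vx[hidx]; hy <- vy[hidx]
  hull_area <- if (length(hx) >= 3L) .poly_area(hx, hy) else n_px
  solidity <- n_px / max(hull_area, n_px * 1e-12)
  fer <- .feret(hx, hy) * pixel_size

  dm <- EBImage::distmap(bin)
  mean_radius <- mean(dm[idx]) * pixel_size

  out <- data.frame(area = area, perimeter = perimeter,
                    mean_radius = mean_radius,
                    min_feret = unname(fer["min"]),
                    max_feret = unname(fer["max"]),
                    aspect_ratio = aspect_ratio,
                    eccentricity = eccentricity, compactness = compactness,
                    extent = extent, form_factor = form_factor,
                    solidity = solidity)
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-cell feature table for a set of masks
#'
#' Runs border exclusion and \code{\link{shape_profile}} over every retained
#' cell of every mask; one row per cell, fixed column order.
#'
#' @param masks A \code{\link{labeled_mask}} or list of them.
#' @param condition Condition label recorded in the first column.
#' @return Data frame with columns \code{condition, mask, cell} followed by
#'   the 11 features in canonical order.
#' @export
profile_table <- function(masks, condition = "cond") {
  if (inherits(masks, "labeled_mask")) masks <- list(masks)
  if (!length(masks)) stopf("at least one mask is required")
  rows <- list()
  for (mi in seq_along(masks)) {
    cells <- extract_cells(masks[[mi]])
    for (cell in cells) {
      prof <- shape_profile(cell$pixels, masks[[mi]]$pixel_size)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(condition = condition, mask = mi, cell = cell$id), prof)
    }
  }
  if (!length(rows)) {
    return(cbind(data.frame(condition = character(0), mask = integer(0),
                            cell = integer(0)),
                 stats::setNames(as.data.frame(matrix(numeric(0), 0, 11)),
                                 shape_feature_names())))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
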