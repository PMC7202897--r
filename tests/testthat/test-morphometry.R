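# Shape descriptors: analytic anchors, border exclusion, invariances and
# brute-force oracle agreement.

test_that("border-touching cells are excluded, interior cells kept", {
  interior <- disk_pixels(10, pad = 15)
  clipped <- disk_pixels(10, pad = 15)
  clipped[, 1] <- clipped[, 1] + 40   # pushes the disk into the right border
  clipped <- clipped[clipped[, 1] <= 51, ]
  m <- mask_from_pixels(interior, clipped, dim = c(51, 51))
  cells <- extract_cells(m)
  expect_length(cells, 1)
  expect_equal(cells[[1]]$id, 1L)

  expect_length(extract_cells(labeled_mask(matrix(0L, 20, 20), 1)), 0)

  # extreme pixel exactly on the border row -> excluded
  touch <- disk_pixels(10, pad = 0)
  mt <- mask_from_pixels(touch, dim = c(21, 21))
  expect_length(extract_cells(mt), 0)
})

test_that("analytic anchors: disk, square, ellipse", {
  pd <- shape_profile(disk_pixels(200), 1)
  expect_lt(abs(pd$form_factor - 1), 0.02)
  expect_lt(pd$eccentricity, 0.05)
  expect_lt(abs(pd$compactness - 1), 0.05)
  expect_lt(abs(pd$extent - pi / 4), 0.02)
  expect_lt(abs(pd$solidity - 1), 0.01)
  expect_lt(abs(pd$max_feret - 400) / 400, 0.01)

  sq <- expand.grid(x = 11:110, y = 11:110)
  ps <- shape_profile(as.matrix(sq), 1)
  expect_equal(ps$extent, 1.0)
  expect_lt(abs(ps$form_factor - pi / 4), 0.02)
  expect_lt(abs(ps$aspect_ratio - 1), 0.02)

  pe <- shape_profile(ellipse_pixels(100, 50), 1)
  expect_lt(abs(pe$eccentricity - 0.866), 0.01)
  expect_lt(abs(pe$aspect_ratio - 2) / 2, 0.02)
  expect_lt(abs(pe$max_feret - 200) / 200, 0.01)
  expect_lt(abs(pe$min_feret - 100) / 100, 0.02)
})

test_that("mean radius of a disk matches the analytic r/3 oracle", {
  p <- shape_profile(disk_pixels(90), 2)   # pixel_size 2 um
  expect_lt(abs(p$mean_radius - 60) / 60, 0.03)
})

test_that("isometry and pixel-size covariance hold", {
  set.seed(31)
  coefs <- list(c = rnorm(5, 0, 0.3), s = rnorm(5, 0, 0.3))
  px <- perturbed_ellipse_pixels(40, 25, 0.15, 0.4, coefs)
  p0 <- shape_profile(px, 1)

  shifted <- px; shifted[, 1] <- shifted[, 1] + 13; shifted[, 2] <- shifted[, 2] + 7
  p_sh <- shape_profile(shifted, 1)
  expect_equal(unlist(p_sh), unlist(p0), tolerance = 1e-10)

  rot <- cbind(px[, 2], max(px[, 1]) + 1L - px[, 1])  # 90 degree rotation
  p_rot <- shape_profile(rot, 1)
  for (f in shape_feature_names()) {
    expect_lt(abs(p_rot[[f]] - p0[[f]]) / max(abs(p0[[f]]), 1e-9), 0.02)
  }

  p2 <- shape_profile(px, 2)  # doubled pixel size
  expect_equal(p2$area, 4 * p0$area, tolerance = 1e-12)
  for (f in c("perimeter", "mean_radius", "min_feret", "max_feret")) {
    expect_equal(p2[[f]], 2 * p0[[f]], tolerance = 1e-12)
  }
  for (f in c("aspect_ratio", "eccentricity", "compactness", "extent",
              "form_factor", "solidity")) {
    expect_lt(abs(p2[[f]] - p0[[f]]) / abs(p0[[f]]), 0.01)
  }
})

test_that("solidity is 1 for convex shapes and falls with concavity", {
  expect_lt(abs(shape_profile(disk_pixels(60), 1)$solidity - 1), 0.01)
  expect_lt(abs(shape_profile(ellipse_pixels(70, 30), 1)$solidity - 1), 0.01)
  sol <- vapply(c(0, 10, 20, 28), function(w) {
    px <- disk_pixels(30, pad = 3)
    cx <- 34
    if (w > 0) {
      notch <- px[, 1] >= cx - 3 & px[, 1] <= cx + 3 & px[, 2] >= 67 - w
      px <- px[!notch, ]
    }
    shape_profile(px, 1)$solidity
  }, numeric(1))
  expect_true(all(diff(sol) < 0))
})

test_that("area, extent and eccentricity agree with pixel brute force", {
  set.seed(77)
  for (i in 1:100) {
    a <- runif(1, 18, 50); b <- runif(1, 12, 0.85 * a)
    irr <- runif(1, 0, 0.25)
    coefs <- list(c = rnorm(5, 0, 0.4), s = rnorm(5, 0, 0.4))
    px <- perturbed_ellipse_pixels(a, b, irr, runif(1, 0, pi), coefs,
                                   canvas = 141)
    psz <- runif(1, 0.3, 1.5)
    p <- shape_profile(px, psz)
    expect_lt(abs(p$area - bf_area(px, psz)) / bf_area(px, psz), 0.01)
    expect_lt(abs(p$extent - bf_extent(px)) / bf_extent(px), 0.01)
    ecc <- bf_eccentricity(px)
    expect_lt(abs(p$eccentricity - ecc), 0.01 * max(ecc, 0.1))
  }
})

test_that("holes are filled and degenerate regions handled", {
  px <- disk_pixels(20)
  holed <- px[(px[, 1] - 24)^2 + (px[, 2] - 24)^2 > 16, ]
  expect_equal(shape_profile(holed, 1)$area, shape_profile(px, 1)$area)

  # one-pixel-wide line: features computed where defined, large but finite
  # aspect ratio from the sub-pixel boundary (capped at 100 if the minor
  # axis vanishes)
  line <- cbind(x = 5:24, y = rep(5L, 20))
  pl <- shape_profile(line, 1)
  expect_true(is.finite(pl$aspect_ratio))
  expect_gte(pl$aspect_ratio, 10)
  expect_lte(pl$aspect_ratio, 100)
  expect_gt(pl$eccentricity, 0.99)

  expect_error(shape_profile(cbind(1:2, 1:2), 1), "debris")
})

test_that("profile tables have a stable schema", {
  specs <- disk_pixels(8, pad = 4)
  m1 <- mask_from_pixels(specs, specs + 30L, specs + 60L, dim = c(95, 95))
  m2 <- mask_from_pixels(specs + 5L, specs + 35L, specs + 65L, dim = c(95, 95))
  tab <- profile_table(list(m1, m2), "cond")
  expect_equal(nrow(tab), 6)
  expect_identical(names(tab), c("condition", "mask", "cell",
                                 shape_feature_names()))
  expect_true(all(is.finite(as.matrix(tab[, shape_feature_names()]))))
})

test_that("generated populations yield finite features throughout", {
  spec <- condition_spec("fuzz", n_cells = 60, elongation = 0.7,
                         irregularity = 0.35, seed = 13)
  tab <- rbind(profile_table(generate_cell_mask(spec, 1), "fuzz"),
               profile_table(generate_cell_mask(spec, 2), "fuzz"))
  expect_gt(nrow(tab), 30)
  X <- as.matrix(tab[, shape_feature_names()])
  expect_true(all(is.finite(X)))
  expect_true(all(tab$min_feret <= tab$max_feret + 1e-9))
  expect_true(all(tab$aspect_ratio >= 1))
  expect_true(all(tab$eccentricity >= 0 & tab$eccentricity < 1))
  expect_true(all(tab$solidity > 0 & tab$solidity <= 1.02))
  expect_true(all(tab$extent > 0 & tab$extent <= 1))
})
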