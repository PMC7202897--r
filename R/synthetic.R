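# Synthetic multi-condition studies: label masks, trajectories, spheroid areas,
# with a known latent coupling from cell shape to migration/invasion.

# Turning-angle SD -> expected path-ratio persistence of a 96-step fixed-length
# walk with wrapped-Gaussian heading increments. Calibrated once by Monte Carlo
# (40,000 tracks per sigma); the floor ~0.091 is the path ratio of a fully
# uncorrelated 96-step walk.
.persistence_cal <- list(
  sigma = c(0, 0.02, 0.04, 0.06, 0.08, 0.10, 0.13, 0.16, 0.20, 0.25, 0.30,
            0.36, 0.43, 0.52, 0.62, 0.75, 0.90, 1.10, 1.35, 1.70, 2.2, 3.0, pi),
  ep    = c(1.0000, 0.9968, 0.9873, 0.9719, 0.9503, 0.9232, 0.8749, 0.8190,
            0.7405, 0.6427, 0.5588, 0.4786, 0.4078, 0.3391, 0.2884, 0.2396,
            0.2008, 0.1662, 0.1385, 0.1144, 0.0992, 0.0914, 0.0911)
)

#' Turning-angle standard deviation for a target persistence
#'
#' Inverts the stored Monte-Carlo calibration between the SD of the
#' wrapped-Gaussian heading increment and the expected path-ratio persistence
#' (net over total displacement) of a 97-point, fixed-step trajectory.
#' Persistence targets below the uncorrelated-walk floor (~0.091) clamp to
#' \code{pi}.
#'
#' @param persistence Target expected persistence in [0, 1].
#' @return Turning-angle SD in radians (vectorised).
#' @export
persistence_sigma <- function(persistence) {
  if (any(persistence < 0 | persistence > 1)) {
    stopf("persistence must lie in [0, 1]")
  }
  cal <- .persistence_cal
  out <- numeric(length(persistence))
  for (i in seq_along(persistence)) {
    p <- persistence[i]
    if (p >= 1) out[i] <- 0
    else if (p <= min(cal$ep)) out[i] <- pi
    else out[i] <- stats::approx(rev(cal$ep), rev(cal$sigma), xout = p)$y
  }
  out
}

.default_noise_sd <- c(size = 0.15, elongation = 0.1, irregularity = 0.2,
                       speed = 0.15, persistence = 0.05, position = 0,
                       fold = 0.15)

#' Specify one synthetic study condition
#'
#' A condition is a cell line on one ECM substrate: a population of cells with
#' condition-specific size, elongation and boundary irregularity, a 2D
#' migration phenotype, and a 3D invasion response tied to the latent shape
#' factors through \code{invasion_link}.
#'
#' @param name Condition label, e.g. \code{"CollagenI"}.
#' @param cell_line Cell-line label.
#' @param n_cells Number of cells to draw for masks and trajectories.
#' @param size_scale Mean equivalent-disk radius, micrometres.
#' @param elongation Target mean eccentricity of the moment-fitted ellipse,
#'   in [0, 1).
#' @param irregularity Boundary-noise amplitude as a fraction of the local
#'   radius (>= 0).
#' @param speed_base Mean 2D migration speed, micrometres per minute.
#' @param persistence_base Target mean path-ratio persistence in [0, 1].
#' @param invasion_link Coefficients \code{c(beta_elong, beta_irreg,
#'   beta_size)} (optionally a fourth additive offset) mapping the latent
#'   shape factors \code{(elongation, irregularity, log(size_scale/20))} to
#'   the log scale of the mean spheroid fold change.
#' @param noise_sd Per-channel lognormal/Gaussian noise scales; a single
#'   number is recycled to every channel, a named vector overrides the
#'   defaults \code{c(size=0.15, elongation=0.1, irregularity=0.2, speed=0.15,
#'   persistence=0.05, position=0, fold=0.15)}.
#' @param seed Integer stream seed for this condition; when \code{NULL} it is
#'   derived from the study master seed and the condition name.
#' @return An object of class \code{condition_spec}.
#' @export
condition_spec <- function(name, cell_line = "MDA-MB-231", n_cells = 120,
                           size_scale = 20, elongation = 0.7,
                           irregularity = 0.15, speed_base = 0.4,
                           persistence_base = 0.4,
                           invasion_link = c(beta_elong = 0.8,
                                             beta_irreg = 2.5,
                                             beta_size = 0),
                           noise_sd = NULL, seed = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("condition name must be a non-empty string")
  }
  if (n_cells < 1) stopf("n_cells must be >= 1")
  if (elongation < 0 || elongation >= 1) stopf("elongation must lie in [0, 1)")
  if (size_scale <= 0) stopf("size_scale must be positive")
  if (irregularity < 0) stopf("irregularity must be >= 0")
  if (persistence_base < 0 || persistence_base > 1) {
    stopf("persistence_base must lie in [0, 1]")
  }
  if (speed_base < 0) stopf("speed_base must be >= 0")
  ns <- .default_noise_sd
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd))) {
      if (length(noise_sd) != 1L) stopf("unnamed noise_sd must be a single number")
      ns[] <- noise_sd
    } else {
      bad <- setdiff(names(noise_sd), names(ns))
      if (length(bad)) stopf("unknown noise_sd channel(s): %s", paste(bad, collapse = ", "))
      ns[names(noise_sd)] <- noise_sd
    }
  }
  if (any(ns < 0)) stopf("noise_sd entries must be >= 0")
  link <- as.numeric(invasion_link)
  if (!length(link) %in% c(3L, 4L)) {
    stopf("invasion_link must have 3 coefficients (plus optional offset)")
  }
  if (length(link) == 3L) link <- c(link, 0)
  names(link) <- c("beta_elong", "beta_irreg", "beta_size", "offset")
  structure(list(name = name, cell_line = cell_line,
                 n_cells = as.integer(n_cells), size_scale = size_scale,
                 elongation = elongation, irregularity = irregularity,
                 speed_base = speed_base, persistence_base = persistence_base,
                 invasion_link = link, noise_sd = ns,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("condition '%s' (%s): %d cells, r=%.1f um, elongation=%.2f, irregularity=%.2f\n",
              x$name, x$cell_line, x$n_cells, x$size_scale, x$elongation,
              x$irregularity))
  cat(sprintf("  speed=%.2f um/min, persistence=%.2f, invasion link = (%s)\n",
              x$speed_base, x$persistence_base,
              paste(sprintf("%.2f", x$invasion_link), collapse = ", ")))
  invisible(x)
}

.spec_seed <- function(spec) {
  if (is.null(spec$seed)) stopf("condition '%s' has no seed; set one or generate via generate_study()", spec$name)
  spec$seed
}

# Latent shape factors a condition exposes to the invasion link.
latent_factors <- function(spec) {
  c(elong = spec$elongation, irreg = spec$irregularity,
    size = log(spec$size_scale / 20))
}

# Draw per-cell geometric parameters for one mask's worth of cells.
.draw_cell_params <- function(spec, n) {
  ns <- spec$noise_sd
  r <- spec$size_scale * exp(pmin(pmax(stats::rnorm(n, 0, ns["size"]),
                                       -2.5 * ns["size"]), 2.5 * ns["size"]))
  # elongation jitter acts multiplicatively on log aspect ratio so that
  # elongation = 0 yields exact disks and the mean aspect ratio stays on target
  q_t <- 1 / sqrt(1 - spec$elongation^2)
  q <- pmin(exp(log(q_t) * exp(stats::rnorm(n, 0, ns["elongation"]))), 8)
  irr <- spec$irregularity * exp(stats::rnorm(n, 0, ns["irregularity"]))
  phi <- stats::runif(n, 0, pi)
  harmonics <- 2:6
  four <- lapply(seq_len(n), function(i) {
    ck <- stats::rnorm(length(harmonics), 0, 1 / harmonics)
    sk <- stats::rnorm(length(harmonics), 0, 1 / harmonics)
    nrm <- sqrt(sum(ck^2 + sk^2) / 2)
    if (nrm > 0) { ck <- ck / nrm; sk <- sk / nrm }
    list(c = ck, s = sk)
  })
  list(r = r, q = q, irr = irr, phi = phi, four = four, harmonics = harmonics)
}

# Polar boundary radius of cell i at angles theta (cell frame, micrometres).
.cell_radius <- function(pars, i, theta) {
  a <- pars$r[i] * sqrt(pars$q[i])
  b <- pars$r[i] / sqrt(pars$q[i])
  re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  f <- rep(0, length(theta))
  for (j in seq_along(pars$harmonics)) {
    k <- pars$harmonics[j]
    f <- f + pars$four[[i]]$c[j] * cos(k * theta) +
      pars$four[[i]]$s[j] * sin(k * theta)
  }
  re * pmin(pmax(1 + pars$irr[i] * f, 0.25), 1.9)
}

#' Generate one labeled cell-mask image
#'
#' Cells are perturbed ellipses: an ellipse whose axis ratio is set by the
#' condition's elongation, with a low-order Fourier radial perturbation of
#' amplitude \code{irregularity}, rasterised at \code{pixel_size}. Cells are
#' laid out on disjoint slots of a grid that tiles past the canvas edge, so
#' cells falling in overflow slots are clipped by the border (exercising
#' border-cell exclusion downstream). Deterministic given the condition seed
#' and \code{index}.
#'
#' @param spec A \code{\link{condition_spec}} carrying a seed.
#' @param index Mask index within the condition (each index is an independent
#'   deterministic stream).
#' @param n_cells Number of cells to attempt to place; defaults to the spec's
#'   \code{n_cells}, capped at the slot capacity of the canvas.
#' @param canvas Canvas side in pixels.
#' @param pixel_size Micrometres per pixel.
#' @return A \code{\link{labeled_mask}}; attribute \code{n_placed} gives the
#'   number of cells drawn onto the canvas.
#' @export
generate_cell_mask <- function(spec, index = 1L, n_cells = NULL,
                               canvas = 1024L, pixel_size = 0.65) {
  stopifnot(inherits(spec, "condition_spec"))
  if (spec$elongation >= 1) stopf("elongation must be < 1")
  if (spec$size_scale <= 0) stopf("size_scale must be positive")
  n_req <- as.integer(n_cells %||% spec$n_cells)
  with_seed(derive_seed(.spec_seed(spec), "mask", index), {
    pars <- .draw_cell_params(spec, n_req)
    tg <- seq(0, 2 * pi, length.out = 97L)[-97L]
    rho_max <- vapply(seq_len(n_req), function(i) max(.cell_radius(pars, i, tg)),
                      numeric(1))
    slot <- 2 * max(rho_max) / pixel_size + 6
    n_side <- ceiling(canvas / slot)
    capacity <- n_side^2
    if (capacity < 1) stopf("canvas too small for the requested cell size")
    n_place <- min(n_req, capacity)
    slots <- if (capacity > 1) sample.int(capacity, n_place) else 1L
    labels <- matrix(0L, canvas, canvas)
    for (i in seq_len(n_place)) {
      si <- slots[i] - 1L
      cx0 <- ((si %% n_side) + 0.5) * slot
      cy0 <- ((si %/% n_side) + 0.5) * slot
      rmax_px <- rho_max[i] / pixel_size
      jit <- max(slot / 2 - rmax_px - 2, 0)
      cx <- cx0 + stats::runif(1, -jit, jit)
      cy <- cy0 + stats::runif(1, -jit, jit)
      x0 <- max(1, floor(cx - rmax_px - 1)); x1 <- min(canvas, ceiling(cx + rmax_px + 1))
      y0 <- max(1, floor(cy - rmax_px - 1)); y1 <- min(canvas, ceiling(cy + rmax_px + 1))
      if (x0 > x1 || y0 > y1) next   # cell entirely outside the canvas
      xs <- x0:x1; ys <- y0:y1
      dx <- ((xs - 0.5) - cx) * pixel_size
      dy <- ((ys - 0.5) - cy) * pixel_size
      DX <- matrix(dx, length(xs), length(ys))
      DY <- matrix(dy, length(xs), length(ys), byrow = TRUE)
      u <- DX * cos(pars$phi[i]) + DY * sin(pars$phi[i])
      v <- -DX * sin(pars$phi[i]) + DY * cos(pars$phi[i])
      inside <- sqrt(u^2 + v^2) <= .cell_radius(pars, i, atan2(v, u))
      sub <- labels[xs, ys]
      sub[inside] <- i
      labels[xs, ys] <- sub
    }
    out <- labeled_mask(labels, pixel_size)
    attr(out, "n_placed") <- n_place
    out
  })
}

#' Generate persistent-random-walk trajectories for one condition
#'
#' Each of \code{n_cells} trajectories has 97 positions at 10-minute spacing
#' (16 h). Step length is fixed by the cell's speed; heading increments are
#' wrapped-Gaussian with SD chosen from the stored calibration so the expected
#' path-ratio persistence matches the cell's persistence target. Optional
#' Gaussian positional noise (channel \code{position}) is added to observed
#' coordinates.
#'
#' @param spec A \code{\link{condition_spec}} carrying a seed.
#' @param n_steps Number of steps (default 96, i.e. 97 positions).
#' @param dt_min Sampling interval in minutes.
#' @return Data frame with columns \code{condition, cell_id, t_min, x_um, y_um}.
#' @export
generate_trajectories <- function(spec, n_steps = 96L, dt_min = 10) {
  stopifnot(inherits(spec, "condition_spec"))
  ns <- spec$noise_sd
  with_seed(derive_seed(.spec_seed(spec), "tracks"), {
    n <- spec$n_cells
    speed <- spec$speed_base * exp(stats::rnorm(n, 0, ns["speed"]))
    pers <- pmin(pmax(spec$persistence_base +
                        stats::rnorm(n, 0, ns["persistence"]), 0), 1)
    sigma <- persistence_sigma(pers)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      step <- speed[i] * dt_min
      head0 <- stats::runif(1, 0, 2 * pi)
      turns <- stats::rnorm(n_steps, 0, sigma[i])
      headings <- head0 + cumsum(c(0, turns[-n_steps]))
      x <- c(0, cumsum(step * cos(headings)))
      y <- c(0, cumsum(step * sin(headings)))
      if (ns["position"] > 0) {
        x <- x + stats::rnorm(n_steps + 1, 0, ns["position"])
        y <- y + stats::rnorm(n_steps + 1, 0, ns["position"])
      }
      out[[i]] <- data.frame(condition = spec$name,
                             cell_id = sprintf("%s_c%03d", spec$name, i),
                             t_min = seq(0, by = dt_min, length.out = n_steps + 1),
                             x_um = x, y_um = y)
    }
    do.call(rbind, out)
  })
}

#' Generate spheroid invasion measurements for one condition
#'
#' Day-1 projected areas are lognormal about \code{day1_area}; day-5 areas are
#' day-1 areas times a fold change \code{1 + (base_fold - 1) *
#' exp(link . latent) * L}, with \code{L} mean-one lognormal noise
#' (channel \code{fold}) and the fold floored at 1.
#'
#' @param spec A \code{\link{condition_spec}} carrying a seed.
#' @param n_replicates Number of spheroid replicates (>= 1).
#' @param base_fold Fold change of a condition with zero latent link.
#' @param day1_area Mean day-1 spheroid area, square micrometres.
#' @return Data frame with columns
#'   \code{condition, replicate, area_day1_um2, area_day5_um2}.
#' @export
generate_spheroids <- function(spec, n_replicates = 12L, base_fold = 2,
                               day1_area = 150000) {
  stopifnot(inherits(spec, "condition_spec"))
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  s <- spec$noise_sd["fold"]
  with_seed(derive_seed(.spec_seed(spec), "spheroids"), {
    lp <- sum(spec$invasion_link[1:3] * latent_factors(spec)) +
      spec$invasion_link[4]
    d1 <- day1_area * exp(stats::rnorm(n_replicates, 0, 0.1))
    noise <- if (s > 0) exp(stats::rnorm(n_replicates, -s^2 / 2, s)) else rep(1, n_replicates)
    fold <- pmax(1 + (base_fold - 1) * exp(lp) * noise, 1)
    data.frame(condition = spec$name, replicate = seq_len(n_replicates),
               area_day1_um2 = d1, area_day5_um2 = d1 * fold)
  })
}

#' Analytic expected mean fold change of a condition
#'
#' The mean of the generator's fold-change distribution before flooring:
#' \code{1 + (base_fold - 1) * exp(link . latent)} (the lognormal noise is
#' mean-one by construction).
#'
#' @inheritParams generate_spheroids
#' @return Expected mean fold change.
#' @export
expected_fold_change <- function(spec, base_fold = 2) {
  lp <- sum(spec$invasion_link[1:3] * latent_factors(spec)) +
    spec$invasion_link[4]
  1 + (base_fold - 1) * exp(lp)
}

#' Assemble a complete synthetic study
#'
#' Generates masks, trajectories and spheroid measurements for every
#' condition, together with the latent truth record that downstream
#' parameter-recovery tests compare against. Pure construction: nothing is
#' written to disk (see \code{\link{write_study}}).
#'
#' @param config List of \code{\link{condition_spec}} objects (>= 2, unique
#'   names).
#' @param master_seed Integer master seed; per-condition streams are derived
#'   by hashing it with the condition name (specs carrying their own seed keep
#'   it).
#' @param n_replicates Spheroid replicates per condition.
#' @param canvas,pixel_size Mask canvas (pixels) and pixel size (um/px).
#' @param base_fold,day1_area Spheroid generator constants.
#' @return An object of class \code{ecm_study} with elements
#'   \code{conditions}, \code{masks}, \code{trajectories}, \code{spheroids},
#'   \code{truth}.
#' @export
generate_study <- function(config, master_seed = 1L, n_replicates = 12L,
                           canvas = 1024L, pixel_size = 0.65, base_fold = 2,
                           day1_area = 150000) {
  if (length(config) < 2L) stopf("a study needs at least 2 conditions")
  if (!all(vapply(config, inherits, logical(1), "condition_spec"))) {
    stopf("config must be a list of condition_spec objects")
  }
  nms <- vapply(config, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stopf("duplicate condition names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  masks <- list(); tracks <- list(); sph <- list(); truth <- list()
  for (spec in config) {
    if (is.null(spec$seed)) spec$seed <- derive_seed(master_seed, spec$name)
    cond_masks <- list(); placed <- 0L; idx <- 1L
    while (placed < spec$n_cells) {
      m <- generate_cell_mask(spec, index = idx,
                              n_cells = spec$n_cells - placed,
                              canvas = canvas, pixel_size = pixel_size)
      cond_masks[[idx]] <- m
      placed <- placed + attr(m, "n_placed")
      idx <- idx + 1L
      if (idx > 64L) break  # safety for tiny canvases
    }
    masks[[spec$name]] <- cond_masks
    tracks[[spec$name]] <- generate_trajectories(spec)
    sph[[spec$name]] <- generate_spheroids(spec, n_replicates = n_replicates,
                                           base_fold = base_fold,
                                           day1_area = day1_area)
    lf <- latent_factors(spec)
    truth[[spec$name]] <- data.frame(
      condition = spec$name, cell_line = spec$cell_line,
      latent_elong = lf["elong"], latent_irreg = lf["irreg"],
      latent_size = lf["size"],
      expected_fold = expected_fold_change(spec, base_fold),
      speed_base = spec$speed_base, persistence_base = spec$persistence_base,
      seed = spec$seed, row.names = NULL)
  }
  specs <- lapply(config, function(s) {
    if (is.null(s$seed)) s$seed <- derive_seed(master_seed, s$name)
    s
  })
  structure(list(conditions = specs, masks = masks,
                 trajectories = do.call(rbind, tracks),
                 spheroids = do.call(rbind, sph),
                 truth = do.call(rbind, truth),
                 master_seed = master_seed, pixel_size = pixel_size),
            class = "ecm_study")
}

#' @export
print.ecm_study <- function(x, ...) {
  cat(sprintf("synthetic ECM study: %d conditions, %d masks, %d track points, %d spheroids\n",
              length(x$conditions),
              sum(lengths(x$masks)), nrow(x$trajectories), nrow(x$spheroids)))
  print(x$truth[, c("condition", "cell_line", "expected_fold",
                    "speed_base", "persistence_base")], row.names = FALSE)
  invisible(x)
}

#' Default shape-linked multi-condition study configuration
#'
#' Draws per-condition shape parameters (elongation, irregularity, size) from
#' the study-wide ranges and couples migration and invasion to them: speed
#' rises with elongation, persistence with irregularity, and the mean spheroid
#' fold change follows the invasion link on the latent shape factors. This is
#' the ground-truth structure used by the parameter-recovery experiments.
#'
#' @param n_conditions Number of ECM conditions (>= 2).
#' @param seed Seed for drawing the condition parameters.
#' @param cell_line Cell-line label for all conditions.
#' @param n_cells Cells per condition.
#' @param invasion_link Link coefficients passed to every condition.
#' @param speed_offset Additive shift of every condition's speed (cell-line
#'   effect).
#' @param invasion_offset Additive shift on the log scale of the invasion
#'   link (cell-line effect).
#' @param prefix Condition-name prefix.
#' @param baseline When \code{TRUE}, the first condition is a fixed
#'   low-shape reference (\code{"noECM"}: elongation 0.35, irregularity
#'   0.08, size 20 um) rather than a random draw — the anchor row used when
#'   transferring a model to a new cell line.
#' @return List of \code{\link{condition_spec}} objects.
#' @export
linked_study_config <- function(n_conditions = 8L, seed = 1L,
                                cell_line = "SYN-231", n_cells = 120L,
                                invasion_link = c(0.8, 2.5, 0),
                                speed_offset = 0, invasion_offset = 0,
                                prefix = "ECM", baseline = FALSE) {
  if (n_conditions < 2L) stopf("need at least 2 conditions")
  with_seed(derive_seed(seed, "config", cell_line), {
    elong <- stats::runif(n_conditions, 0.30, 0.90)
    irr <- stats::runif(n_conditions, 0.05, 0.35)
    size <- stats::runif(n_conditions, 15, 28)
    if (baseline) { elong[1] <- 0.35; irr[1] <- 0.08; size[1] <- 20 }
    lapply(seq_len(n_conditions), function(i) {
      condition_spec(
        name = if (baseline && i == 1L) paste0(prefix, "_noECM")
               else sprintf("%s%02d", prefix, i),
        cell_line = cell_line,
        n_cells = n_cells, size_scale = size[i], elongation = elong[i],
        irregularity = irr[i],
        speed_base = max(0.1 + 0.6 * elong[i] + speed_offset, 0.02),
        persistence_base = min(0.25 + 0.8 * irr[i], 0.95),
        invasion_link = c(invasion_link[1:3], invasion_offset))
    })
  })
}

#' Write a synthetic study to disk in plain interchange formats
#'
#' Masks as 16-bit single-channel label TIFFs (0 = background), trajectories
#' and spheroids as CSV, the latent truth record as JSON.
#'
#' @param study An \code{ecm_study}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ecm_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cond in names(study$masks)) {
    for (i in seq_along(study$masks[[cond]])) {
      f <- file.path(dir, sprintf("mask_%s_%02d.tif", cond, i))
      write_mask(study$masks[[cond]][[i]], f)
      files <- c(files, f)
    }
  }
  f <- file.path(dir, "tracks.csv")
  utils::write.csv(study$trajectories, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "spheroids.csv")
  utils::write.csv(study$spheroids, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(study$truth, f, digits = NA, dataframe = "rows")
  files <- c(files, f)
  invisible(files)
}
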