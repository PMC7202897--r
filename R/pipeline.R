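# End-to-end pipeline: simulate -> features -> motility -> summarize ->
# classify / PLS, with a provenance manifest and fixed CSV schemas.

.write_csv9 <- function(df, path) {
  # fixed dialect: UTF-8, comma, '.' decimal, header; floats at 9 significant
  # digits for bit-stable cross-platform diffs
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 9))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

.default_pipeline_config <- function() {
  list(seed = 1L, out_dir = "ecmshape_run",
       n_conditions = 8L, n_cells = 120L, n_replicates = 12L,
       canvas = 1024L, pixel_size = 0.65,
       thresholds = list(speed = 0.5, invasion = 10),
       classifier = list(learning_rates = c(0.5, 1, 2),
                         estimator_counts = c(10L, 50L, 100L)),
       pls = list(ncomp = "auto", max_ncomp = 4L, n_perm = 200L,
                  predictors = "adhesion",
                  responses = c("speed", "persistence", "invasion")),
       verbose = TRUE)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Executes simulate -> features -> motility -> summarize -> classify -> PLS
#' in dependency order, writing each stage's outputs (CSV/JSON) and a
#' provenance manifest (package version, seed, input hashes, stage timings)
#' under \code{out_dir}. Re-running with the same config and seed reproduces
#' identical numeric payloads.
#'
#' @param config A config list, or the path of a YAML file holding one.
#'   Unspecified entries fall back to the defaults (8 linked conditions, 120
#'   cells each, 12 spheroid replicates, speed threshold 0.5 um/min,
#'   invasion threshold 10, classifier grid around the (1, 50) default,
#'   automatic PLS component choice, 200 permutations).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_pipeline_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, fmt, ...) {
    if (isTRUE(cfg$verbose)) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  manifest <- list(package = "ecmshape",
                   version = as.character(utils::packageVersion("ecmshape")),
                   seed = cfg$seed, stages = list(), files = list())
  run_stage <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    log_msg(stage, "starting")
    out <- tryCatch(fun(), error = function(e) {
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
    manifest$stages[[stage]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
                                      status = "ok")
    out
  }

  study <- run_stage("simulate", function() {
    conds <- if (!is.null(cfg$conditions)) {
      lapply(cfg$conditions, function(cc) do.call(condition_spec, cc))
    } else {
      linked_study_config(n_conditions = cfg$n_conditions, seed = cfg$seed,
                          n_cells = cfg$n_cells)
    }
    st <- generate_study(conds, master_seed = cfg$seed,
                         n_replicates = cfg$n_replicates,
                         canvas = cfg$canvas, pixel_size = cfg$pixel_size)
    write_study(st, file.path(cfg$out_dir, "simulated"))
    st
  })

  features <- run_stage("features", function() {
    tabs <- lapply(names(study$masks), function(cn)
      profile_table(study$masks[[cn]], condition = cn))
    out <- do.call(rbind, tabs)
    .write_csv9(out, file.path(cfg$out_dir, "features.csv"))
    out
  })

  metrics <- run_stage("motility", function() {
    out <- motility_table(study$trajectories)
    .write_csv9(out, file.path(cfg$out_dir, "metrics.csv"))
    out
  })

  summaries <- run_stage("summarize", function() {
    out <- summarize_conditions(features, metrics, study$spheroids)
    .write_csv9(out, file.path(cfg$out_dir, "summaries.csv"))
    out
  })

  classify <- run_stage("classify", function() {
    lab <- label_conditions(summaries, "speed",
                            threshold = cfg$thresholds$speed)
    groups <- evaluate_feature_groups(features, lab)
    ranking <- rank_single_features(features, lab)
    grid <- adaboost_grid_search(features, lab,
                                 learning_rates = cfg$classifier$learning_rates,
                                 estimator_counts = cfg$classifier$estimator_counts)
    .write_csv9(groups, file.path(cfg$out_dir, "classifier_groups.csv"))
    .write_csv9(ranking, file.path(cfg$out_dir, "classifier_ranking.csv"))
    .write_csv9(grid, file.path(cfg$out_dir, "classifier_grid.csv"))
    list(labeling = lab, groups = groups, ranking = ranking, grid = grid)
  })

  pls_out <- run_stage("pls", function() {
    resp_cols <- c(speed = "mean_speed", persistence = "mean_persistence",
                   invasion = "mean_invasion")[cfg$pls$responses]
    if (anyNA(summaries[, resp_cols])) {
      stopf("missing response input (check spheroid/track files): %s",
            paste(resp_cols[colSums(is.na(summaries[, resp_cols, drop = FALSE])) > 0],
                  collapse = ", "))
    }
    X <- .summary_matrix(summaries)
    Y <- as.matrix(summaries[, resp_cols, drop = FALSE])
    colnames(Y) <- cfg$pls$responses
    rownames(Y) <- rownames(X)
    a_max <- min(cfg$pls$max_ncomp, nrow(X) - 2L)
    diag <- q2_loocv(X, Y, ncomp = a_max)
    a <- if (identical(cfg$pls$ncomp, "auto")) choose_components(diag)
         else as.integer(cfg$pls$ncomp)
    fit <- pls_fit(X, Y, ncomp = a)
    vip <- vip_scores(fit)
    perm <- pls_permutation_test(X, Y, ncomp = a, n_perm = cfg$pls$n_perm,
                                 seed = derive_seed(cfg$seed, "perm"))
    model_json <- list(predictors = fit$predictors, responses = fit$responses,
                       ncomp = fit$ncomp, x_mean = fit$x_mean,
                       x_scale = fit$x_scale, y_mean = fit$y_mean,
                       y_scale = fit$y_scale, W = fit$W, P = fit$P, Q = fit$Q,
                       R2 = fit$r2, Q2 = diag$Q2, chosen_A = a,
                       permutation_p = perm$p_value)
    jsonlite::write_json(model_json, file.path(cfg$out_dir, "pls_model.json"),
                         digits = NA, auto_unbox = TRUE)
    .write_csv9(cbind(data.frame(predictor = rownames(vip)),
                      as.data.frame(vip)),
                file.path(cfg$out_dir, "pls_vip.csv"))
    list(fit = fit, diagnostics = diag, vip = vip, permutation = perm)
  })

  out_files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  out_files <- out_files[!grepl("manifest[.]json$", out_files)]
  manifest$files <- as.list(tools::md5sum(out_files))
  names(manifest$files) <- substring(names(manifest$files),
                                     nchar(cfg$out_dir) + 2L)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  log_msg("done", "outputs in %s", cfg$out_dir)
  invisible(c(manifest,
              list(study = study, features = features, metrics = metrics,
                   summaries = summaries, classify = classify, pls = pls_out)))
}
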