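#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return list with `data` (numeric array) and `voxel_size` (mm triple).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))])
}

#' Write a NIfTI volume
#'
#' @param data numeric/logical array (logical masks are written as 0/1).
#' @param voxel_size_mm voxel size triple in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(data, voxel_size_mm, path) {
  arr <- array(as.numeric(data), dim = dim(data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write / read a design table as TSV
#' @param design data frame.
#' @param path file path.
#' @return `write_design`: the path invisibly; `read_design`: data frame.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize / load a trained pattern model
#'
#' The voxel weights are written as a volume in the grid space and the
#' scalar parameters (offset, scaler min/max, C, metadata) as a JSON
#' sidecar next to it.
#'
#' @param model a `pattern_model`.
#' @param grid the `volume_grid` the weights live in.
#' @param prefix output path prefix; writes `<prefix>_weights.nii.gz` and
#'   `<prefix>_model.json`.
#' @return `write_model`: the prefix invisibly; `read_model`: the
#'   `pattern_model`.
#' @export
write_model <- function(model, grid, prefix) {
  stopifnot(inherits(model, "pattern_model"), inherits(grid, "volume_grid"))
  write_volume(masked_to_volume(grid, model$weights, fill = 0),
               grid$voxel_size, paste0(prefix, "_weights.nii.gz"))
  side <- list(offset = model$offset, C = model$C, meta = model$meta)
  if (!is.null(model$scaler))
    side$scaler <- list(min = model$scaler$min, max = model$scaler$max)
  jsonlite::write_json(side, paste0(prefix, "_model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_model
#' @export
read_model <- function(prefix, grid) {
  vol <- read_volume(paste0(prefix, "_weights.nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, "_model.json"),
                              simplifyVector = TRUE)
  scaler <- if (!is.null(side$scaler))
    structure(list(min = side$scaler$min, max = side$scaler$max),
              class = "range_scaler")
  structure(list(weights = volume_to_masked(grid, vol$data),
                 offset = side$offset, scaler = scaler, C = side$C,
                 meta = as.list(side$meta)),
            class = "pattern_model")
}

#' Default analysis configuration
#'
#' Demo-scale configuration for [run_pipeline()]; every numeric setting,
#' including all seeds, is explicit so a config fully determines the run.
#'
#' @param seed master seed; the per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    grid = list(shape = c(12, 12, 12), voxel_size_mm = c(2, 2, 2),
                mask_fill = 1),
    truth = list(n_shared = 60, n_ns = 40, n_fe = 40, n_arousal = 40,
                 noise_sd = 0.3, subject_sd = 0.3),
    n_subjects = 30,
    decoder = list(C = 1, n_folds = 10, n_repeats = 2),
    resampling = list(n_perm = 500, n_boot = 200, q = 0.05, min_mm3 = 100),
    searchlight = list(enabled = FALSE, radius_voxels = 2, n_folds = 5),
    thermal = list(n_subjects = 33, n_levels = 6, slope = 0.5,
                   rating_noise = 0.5)
  )
}

#' Load a configuration from YAML
#' @param path YAML file with the fields of [default_config()].
#' @return configuration list, with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(cfg$seed %||% 1)
  utils::modifyList(base, cfg)
}

#' Run the full shared-representation analysis pipeline
#'
#' Orchestrates the analysis on synthetic data in the order of the study
#' logic: simulate -> univariate group t-maps with FDR + extent and
#' permutation spatial similarity -> whole-brain within- and
#' between-modality decoding -> octant joint-weight summary -> bootstrap
#' reliability maps and conjunction -> optional searchlight ->
#' specificity on the emotion contrast -> modality-general pattern and
#' thermal transfer. All randomness flows from the config seeds; a run
#' log records every setting and the MD5 of the written config. A stage
#' failure is logged with its name and the dependent stages are skipped.
#'
#' @param config configuration list (see [default_config()]) or a path to
#'   a YAML config.
#' @param out_dir output directory (created if needed).
#' @return list of stage results (also written under `out_dir`),
#'   invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(paste("config md5:", unname(tools::md5sum(cfg_path))),
                 paste("master seed:", config$seed))
  results <- list()
  failed <- character(0)

  stage <- function(name, depends, fun) {
    if (length(intersect(depends, failed))) {
      log_lines <<- c(log_lines, paste("stage", name,
                                       "skipped (failed dependency)"))
      failed <<- c(failed, name)
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) {
      log_lines <<- c(log_lines,
                      paste0("stage ", name, " FAILED: ", conditionMessage(e)))
      failed <<- c(failed, name)
      NULL
    })
    if (!is.null(out)) log_lines <<- c(log_lines, paste("stage", name, "ok"))
    out
  }

  results$simulate <- stage("simulate", character(0), function() {
    grid <- make_grid(config$grid$shape, config$grid$voxel_size_mm,
                      config$grid$mask_fill, seed = config$seed)
    truth <- do.call(plant_patterns, c(list(grid = grid),
                                       config$truth,
                                       list(seed = config$seed + 1)))
    dataset <- simulate_subjects(truth, config$n_subjects,
                                 seed = config$seed + 2)
    thermal <- do.call(simulate_thermal,
                       c(list(truth = truth), config$thermal,
                         list(seed = config$seed + 3)))
    write_design(dataset$design, file.path(out_dir, "design.tsv"))
    write_design(thermal$design, file.path(out_dir, "thermal_design.tsv"))
    list(grid = grid, truth = truth, dataset = dataset, thermal = thermal)
  })

  results$univariate <- stage("univariate", "simulate", function() {
    sim <- results$simulate
    con <- lapply(c(NS = "NS", FE = "FE"), function(m)
      dataset_images(sim$dataset, m, "pain") -
        dataset_images(sim$dataset, m, "control"))
    maps <- lapply(con, group_ttest)
    thr <- lapply(maps, function(m) {
      extent_filter(fdr_threshold(m$p, config$resampling$q), sim$grid,
                    config$resampling$min_mm3)
    })
    overlap <- conjunction(thr$NS, thr$FE, maps$NS$stat, maps$FE$stat,
                           sign_consistent = TRUE)
    sim_test <- permutation_similarity(con$NS, con$FE,
                                       n_perm = config$resampling$n_perm,
                                       seed = config$seed + 4)
    for (m in names(maps))
      write_volume(masked_to_volume(sim$grid, maps[[m]]$stat, 0),
                   sim$grid$voxel_size,
                   file.path(out_dir, paste0("tmap_", m, ".nii.gz")))
    list(tmaps = maps, thresholded = thr, overlap = overlap,
         similarity = list(r_obs = sim_test$r_obs, p = sim_test$p,
                           n_perm = sim_test$n_perm))
  })

  results$decode <- stage("decode", "simulate", function() {
    sim <- results$simulate
    scheme <- make_cv_scheme(unique(sim$dataset$design$subject),
                             n_folds = config$decoder$n_folds,
                             n_repeats = config$decoder$n_repeats,
                             seed = config$seed + 5)
    evs <- list(
      within_NS = repeated_cv(sim$dataset, "NS", scheme, C = config$decoder$C),
      within_FE = repeated_cv(sim$dataset, "FE", scheme, C = config$decoder$C),
      NS_to_FE = cross_modality_eval(sim$dataset, "NS", "FE", scheme,
                                     C = config$decoder$C),
      FE_to_NS = cross_modality_eval(sim$dataset, "FE", "NS", scheme,
                                     C = config$decoder$C)
    )
    list(scheme = scheme, evals = lapply(evs, function(e)
      list(accuracy_2afc = e$accuracy_2afc,
           accuracy_single = e$accuracy_single,
           p_value = e$p_value, cohens_d = e$cohens_d)))
  })

  results$patterns <- stage("patterns", "simulate", function() {
    sim <- results$simulate
    models <- list(NS = train_final(sim$dataset, "NS"),
                   FE = train_final(sim$dataset, "FE"),
                   general = train_final(sim$dataset, c("NS", "FE")))
    for (m in names(models))
      write_model(models[[m]], sim$grid,
                  file.path(out_dir, paste0("pattern_", m)))
    oct <- octant_analysis(models$FE$weights, models$NS$weights)
    utils::write.csv(as.data.frame(oct),
                     file.path(out_dir, "octants.csv"), row.names = FALSE)
    list(models = models, octants = as.data.frame(oct),
         weight_correlation = spatial_correlation(models$NS$weights,
                                                  models$FE$weights))
  })

  results$bootstrap <- stage("bootstrap", "simulate", function() {
    sim <- results$simulate
    maps <- lapply(c(NS = "NS", FE = "FE"), function(m)
      bootstrap_weights(sim$dataset, m,
                        n_boot = config$resampling$n_boot,
                        seed = config$seed + 6,
                        q = config$resampling$q,
                        min_mm3 = config$resampling$min_mm3))
    conj <- conjunction(maps$NS$thresholded, maps$FE$thresholded)
    list(maps = maps, conjunction_count = sum(conj))
  })

  results$searchlight <- if (isTRUE(config$searchlight$enabled)) {
    stage("searchlight", "simulate", function() {
      sim <- results$simulate
      scheme <- make_cv_scheme(unique(sim$dataset$design$subject),
                               n_folds = config$searchlight$n_folds,
                               n_repeats = 1, seed = config$seed + 7)
      searchlight_crosspred(sim$dataset,
                            radius = list(voxels = config$searchlight$radius_voxels),
                            scheme = scheme, q = config$resampling$q)
    })
  } else NULL

  results$transfer <- stage("transfer", c("simulate", "patterns", "decode"),
                            function() {
    sim <- results$simulate
    spec <- lapply(c(NS = "NS", FE = "FE"), function(m)
      specificity_eval(sim$dataset, m, results$decode$scheme,
                       C = config$decoder$C))
    series <- expression_series(results$patterns$models$general, sim$thermal)
    nlev <- config$thermal$n_levels
    list(
      specificity = lapply(spec, function(e)
        list(accuracy_2afc = e$accuracy_2afc, p_value = e$p_value)),
      thermal_level_cor = expression_correlation(series, "level"),
      thermal_rating_cor = expression_correlation(series, "rating"),
      high_vs_low = unclass(level_contrast_2afc(series, c(1, 2),
                                                c(nlev - 1, nlev)))[
        c("accuracy_2afc", "p_value", "cohens_d")]
    )
  })

  summary <- list(
    univariate = results$univariate$similarity,
    decoding = results$decode$evals,
    weight_correlation = results$patterns$weight_correlation,
    octants = results$patterns$octants,
    bootstrap_conjunction_voxels = results$bootstrap$conjunction_count,
    transfer = results$transfer[c("specificity", "thermal_level_cor",
                                  "thermal_rating_cor", "high_vs_low")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE)
  writeLines(log_lines, log_path)
  invisible(results)
}
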