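# End-to-end orchestration: featurize -> phylo -> screen -> tune ->
# interpret -> predict -> select -> surface, each stage writing plain-text
# artifacts plus a JSON manifest (input hashes, config hash, seed) so runs
# are reproducible and resumable. Stage seeds derive deterministically from
# the master seed and the stage name, so adding stages never perturbs the
# randomness of earlier ones.

#' Pipeline run configuration
#'
#' All thresholds default to the values used throughout the package
#' (screening 1.30 / 0.30; candidate filter pH >= 7.0, >= 3 learners,
#' 1.1 < CD < 1.5; superposition threshold 2 A; surface cutoff 30 A^2;
#' ligand radius 5 A).
#'
#' @param out_dir Run directory.
#' @param seed Master seed; stage seeds derive from it.
#' @param synthetic A \code{synthetic_config} for the simulate stage.
#' @param roster Learner names to screen/tune.
#' @param cutoffs A \code{screen_cutoffs}.
#' @param filter A \code{candidate_filter_config}.
#' @param validation_size Benchmark split size; default 5.
#' @param inner_folds,outer_folds Nested CV settings; defaults 5 and 3.
#' @param importance_repetitions Permutation importance repetitions for the
#'   interpret stage; default 100.
#' @param shap_sample_size,shap_instances Shapley draws per instance and
#'   instances explained; defaults 50 and 20.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            roster = c("rf", "gbt", "knn", "glmnet",
                                       "hinge"),
                            cutoffs = screen_cutoffs(),
                            filter = candidate_filter_config(),
                            validation_size = 5L,
                            inner_folds = 5L, outer_folds = 3L,
                            importance_repetitions = 100L,
                            shap_sample_size = 50L, shap_instances = 20L,
                            log_level = c("info", "quiet")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, roster = roster,
                 cutoffs = cutoffs, filter = filter,
                 validation_size = as.integer(validation_size),
                 inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 importance_repetitions =
                   as.integer(importance_repetitions),
                 shap_sample_size = as.integer(shap_sample_size),
                 shap_instances = as.integer(shap_instances),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

pipeline_log <- function(config, ...) {
  if (config$log_level == "info") {
    message(sprintf("[phoptima] %s", sprintf(...)))
  }
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

stage_manifest_path <- function(out_dir, stage) {
  file.path(out_dir, stage, "manifest.json")
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.character(h), basename(paths))
}

# Returns TRUE when the stage can be skipped; errors when a recorded input
# hash no longer matches (stale provenance).
stage_up_to_date <- function(config, stage, inputs) {
  mp <- stage_manifest_path(config$out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(man$config_hash, unname(config_hash(config)))) {
    return(FALSE)
  }
  current <- hash_files(inputs)
  recorded <- unlist(man$inputs)
  if (length(recorded) != length(current) ||
      !identical(sort(names(recorded)), sort(names(current)))) {
    return(FALSE)
  }
  if (!all(recorded[names(current)] == current)) {
    stop(sprintf(
      "stage '%s' is stale: input hash mismatch for %s", stage,
      paste(names(current)[recorded[names(current)] != current],
            collapse = ", ")), call. = FALSE)
  }
  TRUE
}

write_stage_manifest <- function(config, stage, inputs) {
  man <- list(stage = stage, seed = derive_seed(config$seed, stage),
              config_hash = unname(config_hash(config)),
              inputs = as.list(hash_files(inputs)))
  jsonlite::write_json(man, stage_manifest_path(config$out_dir, stage),
                       auto_unbox = TRUE, pretty = TRUE)
}

run_stage <- function(config, stage, inputs, fun) {
  dir.create(file.path(config$out_dir, stage), recursive = TRUE,
             showWarnings = FALSE)
  if (stage_up_to_date(config, stage, inputs)) {
    pipeline_log(config, "stage %-10s up to date, skipped", stage)
    return(invisible(FALSE))
  }
  pipeline_log(config, "stage %-10s running", stage)
  fun(derive_seed(config$seed, stage))
  write_stage_manifest(config, stage, inputs)
  invisible(TRUE)
}

#' Run the full analysis pipeline on a synthetic benchmark
#'
#' Executes simulate, featurize, phylo, screen, tune, interpret, predict,
#' select and surface in order under \code{config$out_dir}; each stage
#' writes CSV/TSV artifacts plus a JSON manifest and is skipped on rerun
#' when its manifest still matches the config and input hashes. A stage
#' whose recorded input hashes no longer match the files on disk raises an
#' error naming the stale stage.
#'
#' @param config A \code{pipeline_config}.
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(out, "simulate")

  run_stage(config, "simulate", character(0), function(seed) {
    sc <- config$synthetic
    sc$seed <- seed
    generate_benchmark(sc, out_dir = sim_dir)
  })
  sim_files <- c(file.path(sim_dir, c("sequences.fasta", "metadata.csv",
                                      "tree.nwk")))

  feat_csv <- file.path(out, "featurize", "features.csv")
  run_stage(config, "featurize", sim_files, function(seed) {
    records <- merge_metadata(read_fasta(sim_files[1]),
                              read_metadata(sim_files[2]))
    tree <- ape::read.tree(sim_files[3])
    ss2_files <- list.files(file.path(sim_dir, "ss2"),
                            full.names = TRUE)
    ss2 <- stats::setNames(lapply(ss2_files, read_ss2),
                           sub("\\.ss2$", "", basename(ss2_files)))
    raw <- build_raw_features(records, ss2 = ss2,
                              leaf_lengths = leaf_branch_lengths(tree))
    schema <- default_feature_schema(
      config$synthetic$habitat_levels)
    ft <- encode_feature_table(raw, schema)
    df <- data.frame(id = ft$ids, ft$matrix, check.names = FALSE)
    utils::write.csv(df, feat_csv, row.names = FALSE)
    utils::write.csv(data.frame(column = colnames(ft$matrix),
                                feature_type = ft$feature_type),
                     file.path(out, "featurize", "feature_types.csv"),
                     row.names = FALSE)
  })

  coph_csv <- file.path(out, "phylo", "cophenetic.csv")
  run_stage(config, "phylo", sim_files[3], function(seed) {
    tree <- ape::read.tree(sim_files[3])
    cd <- cophenetic_distances(tree)
    utils::write.csv(data.frame(id = rownames(cd), cd,
                                check.names = FALSE),
                     coph_csv, row.names = FALSE)
  })

  screen_csv <- file.path(out, "screen", "screen.csv")
  run_stage(config, "screen", c(feat_csv, sim_files[2]),
            function(seed) {
    dat <- pipeline_features(feat_csv, sim_files[2])
    sp <- benchmark_split(dat$records, config$validation_size, seed)
    report <- screen_learners(
      dat$x[sp$train$id, , drop = FALSE], sp$train$ph_optimum,
      dat$x[sp$validation$id, , drop = FALSE],
      sp$validation$ph_optimum,
      roster = stats::setNames(lapply(config$roster, make_learner),
                               config$roster),
      cutoffs = config$cutoffs, seed = seed)
    utils::write.csv(as.data.frame(report), screen_csv,
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(list(train = sp$train$id,
                                     validation = sp$validation$id)),
               file.path(out, "screen", "split.json"))
  })

  tune_csv <- file.path(out, "tune", "tuning.csv")
  models_rds <- file.path(out, "tune", "models.rds")
  run_stage(config, "tune", c(feat_csv, sim_files[2], screen_csv),
            function(seed) {
    dat <- pipeline_features(feat_csv, sim_files[2])
    report <- utils::read.csv(screen_csv)
    chosen <- report$learner[report$selected]
    if (length(chosen) == 0) chosen <- config$roster
    models <- lapply(chosen, function(nm) {
      nested_cv(nm, dat$x, dat$records$ph_optimum,
                inner_folds = config$inner_folds,
                outer_folds = config$outer_folds,
                seed = derive_seed(seed, nm))
    })
    names(models) <- chosen
    saveRDS(models, models_rds)
    utils::write.csv(data.frame(
      learner = chosen,
      mean_outer_rmse = vapply(models, `[[`, 0.0, "mean_outer_rmse"),
      outer_rmse = vapply(models, function(m)
        paste(sprintf("%.4f", m$outer_rmse), collapse = ";"), ""),
      params = vapply(models, function(m)
        paste(sprintf("%s=%s", names(m$best_params),
                      vapply(m$best_params, format, "")),
              collapse = ";"), "")),
      tune_csv, row.names = FALSE)
  })

  imp_csv <- file.path(out, "interpret", "importance.csv")
  run_stage(config, "interpret", c(feat_csv, sim_files[2], tune_csv),
            function(seed) {
    dat <- pipeline_features(feat_csv, sim_files[2])
    types <- utils::read.csv(file.path(out, "featurize",
                                       "feature_types.csv"))
    models <- readRDS(models_rds)
    best <- models[[which.min(vapply(models, `[[`, 0.0,
                                     "mean_outer_rmse"))]]
    imp <- permutation_importance(
      best, dat$x, dat$records$ph_optimum,
      repetitions = config$importance_repetitions, seed = seed,
      feature_type = types$feature_type)
    utils::write.csv(as.data.frame(imp), imp_csv, row.names = FALSE)
    shap <- mean_abs_shap(best, dat$x,
                          sample_size = config$shap_sample_size,
                          n_instances = config$shap_instances,
                          seed = seed,
                          feature_type = types$feature_type)
    utils::write.csv(as.data.frame(shap),
                     file.path(out, "interpret", "shap.csv"),
                     row.names = FALSE)
    w <- rbind(
      data.frame(report = "permutation",
                 type = names(feature_type_weights(imp)),
                 weight = feature_type_weights(imp)),
      data.frame(report = "shap",
                 type = names(feature_type_weights(shap)),
                 weight = feature_type_weights(shap)))
    utils::write.csv(w, file.path(out, "interpret",
                                  "feature_type_weights.csv"),
                     row.names = FALSE)
  })

  pred_csv <- file.path(out, "predict", "predictions.csv")
  run_stage(config, "predict", c(feat_csv, tune_csv), function(seed) {
    dat <- pipeline_features(feat_csv, sim_files[2])
    models <- readRDS(models_rds)
    preds <- predict_batch(models, dat$x)
    utils::write.csv(data.frame(id = rownames(preds), preds,
                                check.names = FALSE),
                     pred_csv, row.names = FALSE)
  })

  run_stage(config, "select", c(pred_csv, coph_csv, sim_files[2]),
            function(seed) {
    preds <- utils::read.csv(pred_csv, check.names = FALSE)
    pm <- as.matrix(preds[, -1, drop = FALSE])
    rownames(pm) <- preds$id
    cdf <- utils::read.csv(coph_csv, check.names = FALSE)
    cd <- as.matrix(cdf[, -1, drop = FALSE])
    rownames(cd) <- cdf$id
    meta <- read_metadata(sim_files[2])
    alk <- meta$id[meta$ph_optimum >= 9]
    neu <- meta$id[meta$ph_optimum >= 6.5 & meta$ph_optimum < 7.5]
    cand <- setdiff(rownames(pm), c(alk, neu))
    verdicts <- select_candidates(pm[cand, , drop = FALSE], cd, alk, neu,
                                  config$filter)
    utils::write.table(verdicts,
                       file.path(out, "select", "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  run_stage(config, "surface", character(0), function(seed) {
    toy <- generate_toy_structure(40, "helix", seed = seed)
    toy2 <- generate_toy_structure(40, "extended", seed = seed)
    sasa <- shrake_rupley_sasa(toy$structure)
    surf <- surface_residues(sasa)
    comp <- surface_group_composition(toy$structure, surf)
    utils::write.csv(data.frame(sasa,
                                surface = sasa$resno %in% surf),
                     file.path(out, "surface", "sasa.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(group = names(comp), count = comp),
                     file.path(out, "surface", "surface_groups.csv"),
                     row.names = FALSE)
    sup <- superpose_structures(toy$structure, toy2$structure,
                                pairs = cbind(1:40, 1:40))
    ua <- unaligned_residues(sup$distances, ids = 1:40)
    utils::write.table(
      data.frame(residue = 1:40, distance = sup$distances,
                 aligned = !(1:40 %in% ua$unaligned$id)),
      file.path(out, "surface", "superposition.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  })

  pipeline_log(config, "run complete: %s", out)
  invisible(out)
}

# Load the encoded feature table and labeled records for modelling stages.
pipeline_features <- function(feat_csv, meta_csv) {
  df <- utils::read.csv(feat_csv, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df$id
  meta <- read_metadata(meta_csv)
  records <- protein_records(
    id = meta$id, sequence = "M", species = meta$species,
    is_mature = TRUE, habitat = meta$habitat,
    docking_rank = meta$docking_rank, ph_optimum = meta$ph_optimum)
  records <- records[match(df$id, records$id), , drop = FALSE]
  list(x = x, records = records)
}
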