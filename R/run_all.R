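# End-to-end phantom study: simulate a cohort, split by subject, balance,
# train both cascade stages, evaluate metrics, build nosologic maps for the
# held-out grids, score them with Dice against ground truth, compare the
# CNN maps with a nearest-centroid reference, and persist every artefact.

#' Configuration for a full phantom run
#'
#' @param phantom a [phantom_config()].
#' @param n_control,n_treated,n_longitudinal,timepoints_per_longitudinal
#'   cohort composition (see [generate_cohort()]).
#' @param test_fraction subject fraction held out (default 0.25), used when
#'   `test_subjects` is `NULL`.
#' @param test_subjects explicit held-out subject ids.  The default holds
#'   out one control and one treated subject, mirroring the deliberate
#'   composition of a therapy-response test set (both tumour kinds
#'   represented); set to `NULL` for a random subject-level split.
#' @param smote_k SMOTE neighbour count (default 5).
#' @param stage1,stage2 lists with `arch` (a [cnn_architecture()]) and
#'   `learning_rate`; defaults are the tuned stage architectures with
#'   learning rates 0.00081 and 0.00075.
#' @param batch_size,max_epochs,early_stop_patience shared training knobs.
#' @param n_trials random-search trials per stage; 0 (default) skips tuning
#'   and uses the configured architectures directly.
#' @param out_dir artefact directory.
#' @param seed global seed from which all stage seeds are derived.
#' @return An object of class `run_config` (YAML-serialisable).
#' @export
run_config <- function(phantom = phantom_config(),
                       n_control = 3L, n_treated = 3L, n_longitudinal = 1L,
                       timepoints_per_longitudinal = 3L,
                       test_fraction = 0.25,
                       test_subjects = c("S001", "S004"), smote_k = 5L,
                       stage1 = list(arch = stage1_architecture(),
                                     learning_rate = 0.00081),
                       stage2 = list(arch = stage2_architecture(),
                                     learning_rate = 0.00075),
                       batch_size = 32L, max_epochs = 30L,
                       early_stop_patience = 5L, n_trials = 0L,
                       out_dir = tempfile("mrsinet_run_"), seed = 1L) {
  structure(list(phantom = phantom, n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 n_longitudinal = as.integer(n_longitudinal),
                 timepoints_per_longitudinal =
                   as.integer(timepoints_per_longitudinal),
                 test_fraction = test_fraction,
                 test_subjects = test_subjects,
                 smote_k = as.integer(smote_k),
                 stage1 = stage1, stage2 = stage2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 n_trials = as.integer(n_trials),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

run_log <- function(...) message(sprintf(...))

#' Run the complete phantom study
#'
#' Executes the full pipeline under one seed and writes all artefacts to
#' `config$out_dir`: the cohort (ASCII + manifest), the split plan, one
#' metrics table per stage (CNN and nearest-centroid reference), per-test-
#' grid nosologic maps and Dice reports for both methods, a per-class
#' method comparison, Grad-CAM class-average overlays, and a run manifest
#' (YAML) recording every hyperparameter and seed.  Rerunning with the
#' same config and seed reproduces the artefacts.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the fitted models, metrics, maps,
#'   reports, comparison and `out_dir`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(config$seed, 8L)
  stage_txt <- "simulate"
  res <- tryCatch({
    run_log("[simulate] generating cohort (seed %d)", seeds[1])
    cohort <- generate_cohort(config$n_control, config$n_treated,
                              config$n_longitudinal,
                              config$timepoints_per_longitudinal,
                              config$phantom, seed = seeds[1])
    write_cohort(cohort, file.path(config$out_dir, "cohort"))

    stage_txt <- "split"
    plan <- if (is.null(config$test_subjects)) {
      split_cohort(cohort, config$test_fraction, seed = seeds[2])
    } else {
      ids <- subject_ids(cohort)
      if (!all(config$test_subjects %in% ids))
        stopf("run_all: test_subjects %s not in the cohort",
              paste(setdiff(config$test_subjects, ids), collapse = ", "))
      structure(list(train_subjects = sort(setdiff(ids, config$test_subjects)),
                     test_subjects = sort(config$test_subjects),
                     seed = seeds[2]), class = "split_plan")
    }
    jsonlite::write_json(unclass(plan),
                         file.path(config$out_dir, "split_plan.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    fit_stage <- function(stage, scfg, seed_train, seed_val, seed_smote) {
      stage_txt <<- paste0("train_", stage)
      ds <- assemble_stage(cohort, plan, stage)
      sp <- validation_split(ds$train, 0.2, seed = seed_val)
      fit_ds <- smote_balance(sp$fit, config$smote_k, seed = seed_smote)
      cfg <- train_config(scfg$learning_rate, config$batch_size,
                          config$max_epochs, config$early_stop_patience,
                          seed = seed_train)
      if (config$n_trials > 0) {
        run_log("[tune %s] random search, %d trials", stage, config$n_trials)
        sr <- random_search(search_space(n_trials = config$n_trials,
                                         seed = seed_train),
                            fit_ds, sp$val, cfg)
        write.csv(sr$trials,
                  file.path(config$out_dir,
                            sprintf("search_%s.csv", stage)),
                  row.names = FALSE)
        fit <- sr$model
      } else {
        run_log("[train %s] %d rows (balanced), lr %g", stage,
                length(fit_ds$y), cfg$learning_rate)
        fit <- train_model(build_cnn(scfg$arch), fit_ds, sp$val, cfg)
      }
      ref <- nearest_centroid(fit_ds)
      metrics <- evaluate_metrics(fit, ds$test)
      ref_metrics <- evaluate_metrics(ref, ds$test)
      mt <- data.frame(
        model = c("1D-CNN", "nearest-centroid"),
        rbind(as.data.frame(metrics[c("accuracy", "sensitivity",
                                      "specificity", "precision", "f1",
                                      "f1_macro")]),
              as.data.frame(ref_metrics[c("accuracy", "sensitivity",
                                          "specificity", "precision", "f1",
                                          "f1_macro")])))
      write.csv(mt, file.path(config$out_dir,
                              sprintf("metrics_%s.csv", stage)),
                row.names = FALSE)
      list(fit = fit, ref = ref, test = ds$test, metrics = metrics,
           ref_metrics = ref_metrics, train = fit_ds)
    }

    s1 <- fit_stage("N_vs_RT", config$stage1, seeds[3], seeds[4], seeds[5])
    s2 <- fit_stage("R_vs_T", config$stage2, seeds[6], seeds[7], seeds[8])

    stage_txt <- "predict"
    test_grids <- list()
    for (s in cohort$subjects)
      if (s$id %in% plan$test_subjects)
        for (g in s$grids) test_grids[[length(test_grids) + 1L]] <- g
    maps <- list(); reports_cnn <- list(); reports_ref <- list()
    map_dir <- file.path(config$out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (g in test_grids) {
      stem <- if (is.na(g$day)) g$subject_id else
        sprintf("%s_day%03d", g$subject_id, g$day)
      m_cnn <- classify_grid(g, s1$fit, s2$fit)
      m_ref <- classify_grid(g, s1$ref, s2$ref)
      write_nosologic_map(m_cnn, file.path(map_dir, paste0(stem, "_cnn.csv")))
      rep_cnn <- evaluate_map(m_cnn, g)
      rep_ref <- evaluate_map(m_ref, g)
      jsonlite::write_json(unclass(rep_cnn),
                           file.path(map_dir, paste0(stem, "_dice.json")),
                           auto_unbox = TRUE, pretty = TRUE)
      maps[[stem]] <- m_cnn
      reports_cnn[[stem]] <- rep_cnn
      reports_ref[[stem]] <- rep_ref
    }

    stage_txt <- "compare"
    comparison <- compare_methods(reports_cnn, reports_ref,
                                  names_ab = c("1D-CNN", "nearest-centroid"))
    write.csv(as.data.frame(comparison),
              file.path(config$out_dir, "method_comparison.csv"),
              row.names = FALSE)

    stage_txt <- "explain"
    ov1 <- gradcam_class_average(
      s1$fit, s1$test$x[s1$test$y == 1, , drop = FALSE])
    ov2 <- gradcam_class_average(
      s2$fit, s2$test$x[s2$test$y == 1, , drop = FALSE])
    write.csv(data.frame(ppm = ppm_values(cohort$axis),
                         stage1_mean_spectrum = ov1$mean_spectrum,
                         stage1_mean_map = ov1$mean_map,
                         stage2_mean_spectrum = ov2$mean_spectrum,
                         stage2_mean_map = ov2$mean_map),
              file.path(config$out_dir, "gradcam_overlays.csv"),
              row.names = FALSE)

    manifest <- list(
      package_version = as.character(utils::packageVersion("mrsinet")),
      r_version = R.version.string,
      seed = config$seed, derived_seeds = seeds,
      test_fraction = config$test_fraction, smote_k = config$smote_k,
      batch_size = config$batch_size, max_epochs = config$max_epochs,
      early_stop_patience = config$early_stop_patience,
      n_trials = config$n_trials,
      stage1 = list(filters = config$stage1$arch$conv_filters,
                    kernels = config$stage1$arch$conv_kernels,
                    dense = config$stage1$arch$dense_units,
                    learning_rate = config$stage1$learning_rate),
      stage2 = list(filters = config$stage2$arch$conv_filters,
                    kernels = config$stage2$arch$conv_kernels,
                    dense = config$stage2$arch$dense_units,
                    learning_rate = config$stage2$learning_rate))
    yaml::write_yaml(manifest, file.path(config$out_dir, "run_manifest.yaml"))

    list(cohort = cohort, plan = plan, stage1 = s1, stage2 = s2,
         maps = maps, dice_cnn = reports_cnn, dice_ref = reports_ref,
         comparison = comparison, out_dir = config$out_dir)
  }, error = function(e) {
    stopf("run_all failed at stage '%s': %s (partial artefacts in %s)",
          stage_txt, conditionMessage(e), config$out_dir)
  })
  invisible(res)
}
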