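#' Pipeline configuration for an end-to-end run
#'
#' Defaults are the desk profile: 12 phantoms on a 48^3 grid with an 80/20
#' train/test split, the small default regressor and a reduced training
#' schedule, chosen so the full chain (simulate, dosimetry, three training
#' tasks, ensemble inference, voxel/gamma/region evaluation) runs on one
#' CPU in minutes. The full-scale protocol values (128^3 grid, 64^3
#' patches, 200 epochs, learning rate 1e-3) are available through
#' `profile = "paper"`-style overrides of `recipe_args` and `training`.
#'
#' @param n_phantoms number of simulated cases (default 12).
#' @param test_fraction held-out fraction (default 0.2, ceiling applied).
#' @param grid_shape simulation grid (default `c(48, 48, 48)`).
#' @param spacing_mm voxel size (default 4.795 mm).
#' @param training a [training_config] (default [desk_training_config()]).
#' @param model a [degradation_model].
#' @param tasks task names to train (default all three).
#' @param gamma_criteria_list criteria for evaluation (default
#'   [sirt_gamma_criteria()]).
#' @param recipe_args named list of extra arguments to [phantom_recipe()].
#' @param seed base seed; every stochastic stage derives from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_phantoms = 12L, test_fraction = 0.2,
                            grid_shape = c(48L, 48L, 48L),
                            spacing_mm = 4.795,
                            training = desk_training_config(),
                            model = degradation_model(),
                            tasks = c("AC", "SC", "ASC"),
                            gamma_criteria_list = sirt_gamma_criteria(),
                            recipe_args = list(), seed = 1L) {
  stopifnot(n_phantoms >= 4, test_fraction > 0, test_fraction < 1)
  if (training$folds < 2) stop("pipeline_config: folds must be >= 2", call. = FALSE)
  structure(list(n_phantoms = as.integer(n_phantoms),
                 test_fraction = test_fraction,
                 grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 training = training, model = model, tasks = tasks,
                 gamma_criteria_list = gamma_criteria_list,
                 recipe_args = recipe_args, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Randomised recipe for case i: geometry and uptake jittered around the
# defaults so cases differ anatomically, seeded deterministically.
case_recipe <- function(config, i) {
  with_seed(config$seed + 17L * i, {
    tumour_centre <- c(0.63, 0.46, 0.48) +
      runif(3, -0.05, 0.05) * c(1, 1, 1.2)
    args <- list(
      shape = config$grid_shape, spacing_mm = config$spacing_mm,
      tumours = list(list(center = tumour_centre,
                          radius_mm = runif(1, 22, 38))),
      uptake_ratio = runif(1, 3, 8),
      injected_activity_gbq = runif(1, 1.2, 3.0),
      seed = config$seed + 1000L + i)
    args <- utils::modifyList(args, config$recipe_args)
    do.call(phantom_recipe, args)
  })
}

#' Run the full pipeline end to end
#'
#' Simulates paired NC/AC/ASC phantom cases, computes LDM dose maps, splits
#' cases into training and held-out sets, trains the requested correction
#' tasks with the five-fold ensemble, runs sliding-window ensemble
#' inference on the held-out cases, and evaluates voxel metrics, gamma pass
#' rates and region dosimetry for both the uncorrected input and the model
#' output against the reference. Writes cohort CSV tables and a JSON run
#' manifest when `out_dir` is given.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional output directory for tables and the manifest.
#' @param verbose print per-stage progress.
#' @return list with `cases` (ids and split), `models`, `voxel_table`,
#'   `gamma_table`, `region_table`, `summary` (per-task input/output MAE
#'   and the MAE reduction), and `manifest`.
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir = NULL,
                           verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  n <- config$n_phantoms
  say("simulating %d phantoms ...", n)
  cases <- lapply(seq_len(n), function(i) {
    rec <- case_recipe(config, i)
    trip <- generate_task_triplet(rec, config$model)
    list(id = sprintf("case%03d", i), recipe = rec, triplet = trip)
  })
  n_test <- max(1L, ceiling(config$test_fraction * n))
  test_idx <- with_seed(config$seed + 7L, sort(sample.int(n, n_test)))
  train_idx <- setdiff(seq_len(n), test_idx)
  split <- list(train = vapply(cases[train_idx], `[[`, "", "id"),
                test = vapply(cases[test_idx], `[[`, "", "id"))
  stopifnot(length(intersect(split$train, split$test)) == 0)

  models <- list()
  voxel_rows <- list()
  gamma_rows <- list()
  region_rows <- list()
  summary_rows <- list()
  for (task_name in config$tasks) {
    task <- correction_task(task_name)
    say("training task %s (%d folds) ...", task_name, config$training$folds)
    dataset <- lapply(cases[train_idx], function(cs)
      list(id = cs$id,
           input = cs$triplet$doses[[task$input_state]],
           reference = cs$triplet$doses[[task$reference_state]]))
    model <- train_correction(dataset, task, config$training)
    models[[task_name]] <- model
    say("evaluating task %s on %d held-out cases ...", task_name,
        length(test_idx))
    in_mae <- numeric(0); out_mae <- numeric(0)
    for (cs in cases[test_idx]) {
      input <- cs$triplet$doses[[task$input_state]]
      refd <- cs$triplet$doses[[task$reference_state]]
      pred <- predict(model, input)
      body <- region_mask(cs$triplet$masks, "body")
      for (variant in c("input", "predicted")) {
        pv <- if (variant == "input") input else pred
        vr <- voxel_report(pv, refd, mask = body)
        voxel_rows[[length(voxel_rows) + 1L]] <- data.frame(
          task = task_name, case = cs$id, variant = variant,
          me = vr$me, mae = vr$mae, rmse = vr$rmse, psnr_db = vr$psnr_db,
          ssim = vr$ssim, re_pct = vr$re_pct, rae_pct = vr$rae_pct)
        gt <- gamma_pass_table(refd, pv, cs$triplet$masks,
                               config$gamma_criteria_list,
                               regions = c("tumour", "wnl"))
        gt$task <- task_name; gt$case <- cs$id; gt$variant <- variant
        gamma_rows[[length(gamma_rows) + 1L]] <- gt
        rr <- region_report(pv, refd, cs$triplet$masks)
        rr$task <- task_name; rr$case <- cs$id; rr$variant <- variant
        region_rows[[length(region_rows) + 1L]] <- rr
      }
      in_mae <- c(in_mae, voxel_rows[[length(voxel_rows) - 1L]]$mae)
      out_mae <- c(out_mae, voxel_rows[[length(voxel_rows)]]$mae)
    }
    summary_rows[[task_name]] <- data.frame(
      task = task_name,
      input_mae = mean(in_mae), predicted_mae = mean(out_mae),
      mae_reduction_pct = 100 * (1 - mean(out_mae) / mean(in_mae)))
  }
  out <- list(cases = list(ids = vapply(cases, `[[`, "", "id"),
                           split = split),
              models = models,
              voxel_table = do.call(rbind, voxel_rows),
              gamma_table = do.call(rbind, gamma_rows),
              region_table = do.call(rbind, region_rows),
              summary = do.call(rbind, summary_rows))
  rownames(out$summary) <- NULL
  out$manifest <- list(
    seed = config$seed, n_phantoms = n, grid_shape = config$grid_shape,
    spacing_mm = config$spacing_mm, split = split,
    tasks = config$tasks,
    training = unclass(config$training),
    degradation = unclass(config$model),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out$voxel_table, file.path(out_dir, "voxel_metrics.csv"),
              row.names = FALSE)
    write.csv(out$gamma_table, file.path(out_dir, "gamma_pass_rates.csv"),
              row.names = FALSE)
    write.csv(out$region_table, file.path(out_dir, "region_dosimetry.csv"),
              row.names = FALSE)
    write.csv(out$summary, file.path(out_dir, "task_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
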