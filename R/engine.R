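#' Correction task definition
#'
#' The three learnable corrections bind an input correction state to a
#' reference state: AC predicts attenuation-corrected maps from uncorrected
#' ones (NC to AC), SC predicts attenuation-and-scatter-corrected maps from
#' attenuation-corrected ones (AC to ASC, i.e. it performs the scatter
#' correction), and ASC predicts fully corrected maps from uncorrected ones
#' (NC to ASC). No other state pair is constructible.
#'
#' @param name "AC", "SC" or "ASC".
#' @return an object of class `correction_task` with `name`, `input_state`,
#'   `reference_state`.
#' @export
correction_task <- function(name = c("AC", "SC", "ASC")) {
  name <- match.arg(name)
  states <- switch(name,
                   AC = c("NC", "AC"),
                   SC = c("AC", "ASC"),
                   ASC = c("NC", "ASC"))
  structure(list(name = name, input_state = states[1],
                 reference_state = states[2]),
            class = "correction_task")
}

#' Training configuration
#'
#' Defaults mirror the full-scale protocol: 64^3 patches, Adam with an
#' initial learning rate of 1e-3 and weight decay 1e-4, batch size 2, L1
#' loss, 200 epochs, dropout 0.1, 5 folds, dose normalisation by 200 Gy
#' without clipping, and rotation/flip augmentation only (no deformable
#' augmentation, which would corrupt quantitative values).
#' [desk_training_config()] gives a small CPU profile for the same engine.
#'
#' @param patch_size cubic patch edge, voxels.
#' @param learning_rate,weight_decay,batch_size,epochs,dropout Adam / L1
#'   optimisation hyper-parameters.
#' @param folds number of cross-validation folds (>= 2).
#' @param normalisation_max_gy dose mapped to 1.0 (no clipping above).
#' @param patches_per_volume random patches drawn per case per epoch.
#' @param augment apply random 90-degree rotations and axis flips.
#' @param seed base seed for fold assignment, patch sampling and dropout.
#' @return an object of class `training_config`.
#' @export
training_config <- function(patch_size = 64L, learning_rate = 1e-3,
                            weight_decay = 1e-4, batch_size = 2L,
                            epochs = 200L, dropout = 0.1, folds = 5L,
                            normalisation_max_gy = 200,
                            patches_per_volume = 8L, augment = TRUE,
                            seed = 1L) {
  if (folds < 2) stop("training_config: folds must be >= 2", call. = FALSE)
  stopifnot(patch_size >= 4, learning_rate > 0, batch_size >= 1, epochs >= 1,
            dropout >= 0, dropout < 1, normalisation_max_gy > 0)
  structure(list(patch_size = as.integer(patch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 folds = as.integer(folds),
                 normalisation_max_gy = normalisation_max_gy,
                 patches_per_volume = as.integer(patches_per_volume),
                 augment = augment, seed = as.integer(seed)),
            class = "training_config")
}

#' Desk-scale training profile
#'
#' Small-volume CPU profile for the same engine: 32^3 patches, 10 epochs, a
#' larger step size suited to the small default regressor, no dropout.
#'
#' @param ... overrides passed to [training_config()].
#' @return a [training_config].
#' @export
desk_training_config <- function(...) {
  defaults <- list(patch_size = 32L, learning_rate = 0.01, epochs = 10L,
                   dropout = 0, patches_per_volume = 6L, batch_size = 2L)
  args <- utils::modifyList(defaults, list(...))
  do.call(training_config, args)
}

#' Normalise a dose map for training
#'
#' Linear map dose / max_gy: 0 Gy to 0, `max_gy` to 1, values above `max_gy`
#' above 1 (no clipping). [denormalise_dose()] is its exact inverse.
#'
#' @param dose a [dose_map] (or any [volume3d] with non-negative values).
#' @param max_gy normalisation maximum (default 200 Gy).
#' @return a unitless [volume3d].
#' @export
normalise_dose <- function(dose, max_gy = 200) {
  stopifnot(is_volume3d(dose))
  if (max_gy <= 0) stop("normalise_dose: max_gy must be > 0", call. = FALSE)
  volume3d(dose$values / max_gy, spacing = dose$spacing,
           origin = dose$origin, unit = "normalised")
}

#' Invert the training normalisation
#' @param image a unitless [volume3d].
#' @param max_gy the normalisation maximum used.
#' @return a [volume3d] in Gy.
#' @export
denormalise_dose <- function(image, max_gy = 200) {
  stopifnot(is_volume3d(image))
  if (max_gy <= 0) stop("denormalise_dose: max_gy must be > 0", call. = FALSE)
  volume3d(image$values * max_gy, spacing = image$spacing,
           origin = image$origin, unit = "Gy")
}

#' Deterministic k-fold assignment
#'
#' Shuffles the case ids under the seed and deals them round-robin, so fold
#' sizes differ by at most one and each case sits in exactly one validation
#' fold.
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices (1..n_folds) named by case id.
#' @export
make_folds <- function(case_ids, n_folds = 5L, seed = 1L) {
  if (length(case_ids) < n_folds)
    stop("make_folds: fewer cases than folds", call. = FALSE)
  if (anyDuplicated(case_ids)) stop("make_folds: duplicate case ids", call. = FALSE)
  perm <- with_seed(seed, sample.int(length(case_ids)))
  fold <- integer(length(case_ids))
  fold[perm] <- rep_len(seq_len(n_folds), length(case_ids))
  stats::setNames(fold, as.character(case_ids))
}

# --- patch machinery --------------------------------------------------------

pad_to <- function(a, target) {
  d <- dim(a)
  if (all(d >= target)) return(a)
  out <- array(0, pmax(d, target))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  out
}

rot90_xy <- function(a, k) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    a <- aperm(a, c(2, 1, 3))
    a <- a[dim(a)[1]:1, , , drop = FALSE]
  }
  a
}

flip_axis <- function(a, ax) {
  idx <- list(TRUE, TRUE, TRUE)
  idx[[ax]] <- dim(a)[ax]:1
  do.call(`[`, c(list(a), idx, drop = FALSE))
}

apply_patch_transform <- function(a, tr) {
  for (ax in 1:3) if (tr$flip[ax]) a <- flip_axis(a, ax)
  rot90_xy(a, tr$rot)
}

draw_patch_transform <- function(augment) {
  if (!augment) return(list(flip = c(FALSE, FALSE, FALSE), rot = 0L))
  list(flip = runif(3) < 0.5, rot = sample(0:3, 1))
}

crop_patch <- function(a, corner, p) {
  a[corner[1]:(corner[1] + p - 1),
    corner[2]:(corner[2] + p - 1),
    corner[3]:(corner[3] + p - 1), drop = FALSE]
}

#' Sample paired training patches
#'
#' Draws `n` random cubic patches at shared positions from a paired input /
#' reference volume, applying the same random 90-degree rotation and flips
#' to both members of each pair. Volumes smaller than the patch are
#' zero-padded, so the patch shape is always `patch_size^3`.
#'
#' @param input,reference [volume3d]s on a shared grid.
#' @param config a [training_config] (`patch_size`, `augment`).
#' @param n number of pairs.
#' @param seed integer seed.
#' @return list of `n` lists with elements `input` and `reference`
#'   (3D arrays of side `patch_size`).
#' @export
sample_training_patches <- function(input, reference, config, n = 8L,
                                    seed = 1L) {
  stopifnot(is_volume3d(input), is_volume3d(reference))
  stop_if_grid_mismatch(input, reference, "patch pair volumes")
  p <- config$patch_size
  x <- pad_to(input$values, rep(p, 3))
  y <- pad_to(reference$values, rep(p, 3))
  d <- dim(x)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      corner <- vapply(1:3, function(ax) sample.int(d[ax] - p + 1L, 1L), 1L)
      tr <- draw_patch_transform(config$augment)
      list(input = apply_patch_transform(crop_patch(x, corner, p), tr),
           reference = apply_patch_transform(crop_patch(y, corner, p), tr))
    })
  })
}

# Internal: sample paired patches from a feature stack (4D: channel first)
# and a reference array, shared positions and transforms.
sample_feature_patches <- function(feats, ref, p, n, augment) {
  d <- dim(ref)
  lapply(seq_len(n), function(i) {
    corner <- vapply(1:3, function(ax)
      sample.int(max(d[ax] - p + 1L, 1L), 1L), 1L)
    tr <- draw_patch_transform(augment)
    fx <- lapply(feats, function(fa)
      apply_patch_transform(crop_patch(pad_to(fa, rep(p, 3)), corner, p), tr))
    list(features = fx,
         reference = apply_patch_transform(
           crop_patch(pad_to(ref, rep(p, 3)), corner, p), tr))
  })
}

# --- training / inference ---------------------------------------------------

prepare_case <- function(case, task, config, regressor) {
  if (correction_state(case$input) != task$input_state ||
      correction_state(case$reference) != task$reference_state)
    stop(sprintf(
      "task %s expects input state %s and reference state %s, got %s / %s",
      task$name, task$input_state, task$reference_state,
      correction_state(case$input), correction_state(case$reference)),
      call. = FALSE)
  xn <- normalise_dose(case$input, config$normalisation_max_gy)
  yn <- normalise_dose(case$reference, config$normalisation_max_gy)
  list(feats = regressor$features(xn$values, xn$spacing),
       ref = yn$values)
}

#' Train a correction model (five-fold ensemble)
#'
#' Fits one regressor per cross-validation fold on that fold's training
#' split, minimising L1 loss on normalised random patches with Adam, and
#' returns the ensemble whose prediction is the voxelwise mean of the fold
#' members. Per-fold training curves are retained.
#'
#' @param dataset list of cases, each `list(id, input, reference)` with
#'   [dose_map]s whose correction states match the task.
#' @param task a [correction_task].
#' @param config a [training_config].
#' @param regressor a regressor specification (default
#'   [regressor_voxfeat()]).
#' @return an object of class `correction_model`.
#' @seealso [predict.correction_model()]
#' @export
train_correction <- function(dataset, task, config = desk_training_config(),
                             regressor = regressor_voxfeat()) {
  stopifnot(inherits(task, "correction_task"),
            inherits(config, "training_config"))
  ids <- vapply(dataset, function(cs) as.character(cs$id), "")
  prepared <- lapply(dataset, prepare_case, task = task, config = config,
                     regressor = regressor)
  folds <- make_folds(ids, config$folds, seed = config$seed)
  members <- vector("list", config$folds)
  history <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    train_idx <- which(folds != f)
    val_idx <- which(folds == f)
    fit <- with_seed(config$seed + 1000L * f, {
      fit_regressor(regressor, prepared[train_idx], prepared[val_idx], config)
    })
    members[[f]] <- fit$model
    history[[f]] <- fit$history
  }
  structure(list(task = task, config = config,
                 regressor = regressor, members = members,
                 fold_assignment = folds, history = history),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> task %s (%s -> %s), %d-fold ensemble of '%s'\n",
              x$task$name, x$task$input_state, x$task$reference_state,
              length(x$members), x$regressor$name))
  fin <- vapply(x$history, function(h) utils::tail(h$train_loss, 1), 0)
  cat(sprintf("  final per-fold training L1: %s\n",
              paste(sprintf("%.4g", fin), collapse = ", ")))
  invisible(x)
}

#' @export
summary.correction_model <- function(object, ...) {
  fin_tr <- vapply(object$history, function(h) utils::tail(h$train_loss, 1), 0)
  fin_va <- vapply(object$history, function(h) h$val_loss %||% NA_real_, 0)
  out <- list(task = object$task$name,
              folds = length(object$members),
              regressor = object$regressor$name,
              train_loss = fin_tr, val_loss = fin_va,
              epochs = object$config$epochs)
  class(out) <- "summary.correction_model"
  out
}

#' @export
print.summary.correction_model <- function(x, ...) {
  cat(sprintf("Correction model, task %s: %d folds of '%s', %d epochs\n",
              x$task, x$folds, x$regressor, x$epochs))
  cat(sprintf("  fold train L1: %s\n",
              paste(sprintf("%.4g", x$train_loss), collapse = ", ")))
  cat(sprintf("  fold   val L1: %s\n",
              paste(sprintf("%.4g", x$val_loss), collapse = ", ")))
  invisible(x)
}

sliding_window_starts <- function(n, p, stride) {
  if (n <= p) return(1L)
  s <- seq.int(1L, n - p + 1L, by = stride)
  if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
  s
}

#' Predict a corrected dose map
#'
#' Sliding-window inference at the training patch size with 50% overlap and
#' uniform averaging in overlaps; fold-member patch outputs are averaged
#' voxelwise (the ensemble), the result denormalised to Gy and clamped at
#' zero. The input's correction state must match the model's task.
#'
#' @param object a [correction_model].
#' @param newdata a [dose_map] in the task's input state.
#' @param ... unused.
#' @return a [dose_map] in the task's reference state.
#' @export
predict.correction_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "dose_map"))
  task <- object$task
  if (correction_state(newdata) != task$input_state)
    stop(sprintf("model for task %s expects input state %s, got %s",
                 task$name, task$input_state, correction_state(newdata)),
         call. = FALSE)
  cfg <- object$config
  if (any(dim(newdata$values) < 1)) stop("predict: empty input", call. = FALSE)
  xn <- normalise_dose(newdata, cfg$normalisation_max_gy)
  feats <- object$regressor$features(xn$values, xn$spacing)
  d0 <- dim(xn$values)
  p <- cfg$patch_size
  feats <- lapply(feats, pad_to, target = rep(p, 3))
  d <- dim(feats[[1]])
  stride <- max(1L, p %/% 2L)
  acc <- array(0, d)
  wsum <- array(0, d)
  sx <- sliding_window_starts(d[1], p, stride)
  sy <- sliding_window_starts(d[2], p, stride)
  sz <- sliding_window_starts(d[3], p, stride)
  for (ix in sx) for (iy in sy) for (iz in sz) {
    fp <- lapply(feats, function(fa)
      fa[ix:(ix + p - 1), iy:(iy + p - 1), iz:(iz + p - 1), drop = FALSE])
    # running mean: exactly the member output when all members coincide
    pred <- predict_regressor(object$regressor, object$members[[1]], fp)
    for (mi in seq_along(object$members)[-1]) {
      pm <- predict_regressor(object$regressor, object$members[[mi]], fp)
      pred <- pred + (pm - pred) / mi
    }
    acc[ix:(ix + p - 1), iy:(iy + p - 1), iz:(iz + p - 1)] <-
      acc[ix:(ix + p - 1), iy:(iy + p - 1), iz:(iz + p - 1)] + pred
    wsum[ix:(ix + p - 1), iy:(iy + p - 1), iz:(iz + p - 1)] <-
      wsum[ix:(ix + p - 1), iy:(iy + p - 1), iz:(iz + p - 1)] + 1
  }
  out <- acc / wsum
  out <- out[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  gy <- denormalise_dose(volume3d(out, spacing = newdata$spacing,
                                  origin = newdata$origin),
                         cfg$normalisation_max_gy)
  gy$values[gy$values < 0] <- 0
  dose_map(gy, correction_state = task$reference_state,
           provenance = sprintf("correction_model:%s", task$name))
}
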