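make_dose <- function(values, state, spacing = rep(4.795, 3)) {
  dose_map(volume3d(values, spacing = spacing), correction_state = state)
}

test_that("task definitions bind exactly the three state pairs", {
  expect_equal(correction_task("AC")[c("input_state", "reference_state")],
               list(input_state = "NC", reference_state = "AC"))
  expect_equal(correction_task("SC")[c("input_state", "reference_state")],
               list(input_state = "AC", reference_state = "ASC"))
  expect_equal(correction_task("ASC")[c("input_state", "reference_state")],
               list(input_state = "NC", reference_state = "ASC"))
  expect_error(correction_task("XX"))
})

test_that("normalisation maps 200 Gy to 1, does not clip, and inverts exactly", {
  d <- c(6, 6, 6)
  vals <- array(seq(0, 400, length.out = prod(d)), d)
  dm <- make_dose(vals, "NC")
  n <- normalise_dose(dm, 200)
  expect_equal(n$values[prod(d)], 2.0)          # 400 Gy -> 2.0, unclipped
  expect_equal(max(abs(denormalise_dose(n, 200)$values - vals)), 0)
  expect_equal(normalise_dose(make_dose(array(200, d), "NC"))$values[1], 1.0)
  expect_error(normalise_dose(dm, 0), "> 0")
})

test_that("fold assignment is balanced, deterministic and exhaustive", {
  f <- make_folds(sprintf("c%03d", 1:148), 5, seed = 3)
  expect_equal(sort(unname(table(f)), decreasing = TRUE),
               sort(c(30, 30, 30, 29, 29), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_identical(f, make_folds(sprintf("c%03d", 1:148), 5, seed = 3))
  f5 <- make_folds(letters[1:5], 5, seed = 1)
  expect_equal(sort(unname(table(f5))), rep(1L, 5), ignore_attr = TRUE)
  expect_error(make_folds(letters[1:3], 5), "fewer cases")
})

test_that("patch sampling pairs transforms and pads small volumes", {
  cfg <- desk_training_config(patch_size = 8L)
  d <- c(12, 12, 12)
  set.seed(1)
  x <- volume3d(array(runif(prod(d)), d), spacing = rep(1, 3))
  y <- volume3d(x$values * 2, spacing = rep(1, 3))
  ps <- sample_training_patches(x, y, cfg, n = 10, seed = 4)
  for (p in ps) {
    expect_equal(dim(p$input), c(8, 8, 8))
    # the same spatial transform was applied to both: ratio everywhere 2
    expect_lt(max(abs(p$reference - 2 * p$input)), 1e-12)
  }
  # constant pair stays constant
  cx <- volume3d(array(3, d), spacing = rep(1, 3))
  cy <- volume3d(array(5, d), spacing = rep(1, 3))
  pc <- sample_training_patches(cx, cy, cfg, n = 2, seed = 1)[[1]]
  expect_lt(diff(range(pc$input)), 1e-12)
  expect_equal(pc$reference[1], 5)
  # smaller-than-patch volume is padded to the patch shape
  tiny <- volume3d(array(1, c(4, 4, 4)), spacing = rep(1, 3))
  pt <- sample_training_patches(tiny, tiny, cfg, n = 1, seed = 1)[[1]]
  expect_equal(dim(pt$input), c(8, 8, 8))
})

test_that("task contract: mismatched correction states always raise", {
  d <- c(8, 8, 8)
  nc <- make_dose(array(1, d), "NC")
  asc <- make_dose(array(1, d), "ASC")
  ds <- lapply(1:5, function(i) list(id = i, input = asc, reference = asc))
  expect_error(
    train_correction(ds, correction_task("AC"),
                     desk_training_config(patch_size = 8L, epochs = 1L)),
    "expects input state")
  # predict also enforces the input state
  ds_ok <- lapply(1:5, function(i) list(id = i, input = nc, reference = asc))
  m <- train_correction(ds_ok, correction_task("ASC"),
                        desk_training_config(patch_size = 8L, epochs = 1L),
                        regressor = regressor_identity())
  expect_error(predict(m, asc), "expects input state")
})

test_that("ensemble of identical members equals the single-member output", {
  tr <- generate_task_triplet(test_recipe(seed = 3))
  cfg <- desk_training_config(patch_size = 16L, epochs = 1L, folds = 2L)
  ds <- list(list(id = 1, input = tr$doses$NC, reference = tr$doses$ASC),
             list(id = 2, input = tr$doses$NC, reference = tr$doses$ASC))
  m <- train_correction(ds, correction_task("ASC"), cfg,
                        regressor = regressor_identity())
  single <- m; single$members <- m$members[1]
  five <- m; five$members <- rep(m$members[1], 5)
  p1 <- predict(single, tr$doses$NC)
  p5 <- predict(five, tr$doses$NC)
  expect_identical(p1$values, p5$values)
})

test_that("sliding-window inference over a constant field is seam-free", {
  d <- c(20, 20, 20)
  cfg <- desk_training_config(patch_size = 8L, epochs = 1L, folds = 2L)
  const <- make_dose(array(50, d), "NC")
  ds <- list(list(id = 1, input = const, reference = make_dose(array(50, d), "ASC")),
             list(id = 2, input = const, reference = make_dose(array(50, d), "ASC")))
  m <- train_correction(ds, correction_task("ASC"), cfg,
                        regressor = regressor_identity())
  out <- predict(m, const)
  expect_lt(diff(range(out$values)), 1e-6)
  expect_equal(out$values[1], 50, tolerance = 1e-6)
})

test_that("inference accepts a spacing different from training", {
  tr <- generate_task_triplet(test_recipe(seed = 6))
  cfg <- desk_training_config(patch_size = 16L, epochs = 1L, folds = 2L)
  ds <- list(list(id = 1, input = tr$doses$NC, reference = tr$doses$ASC),
             list(id = 2, input = tr$doses$NC, reference = tr$doses$ASC))
  m <- train_correction(ds, correction_task("ASC"), cfg)
  other <- resample_to_grid(tr$doses$NC, 4.418, "continuous")
  other <- dose_map(other, "NC")
  out <- predict(m, other)
  expect_identical(dim(out$values), dim(other$values))
  expect_true(all(out$values >= 0))
})

test_that("training on an identity dataset does not increase the loss", {
  tr <- generate_task_triplet(test_recipe(seed = 2))
  same <- dose_map(volume3d(tr$doses$ASC$values,
                            spacing = tr$doses$ASC$spacing), "NC")
  cfg <- desk_training_config(patch_size = 16L, epochs = 4L, folds = 2L,
                              weight_decay = 0, seed = 5L)
  ds <- lapply(1:4, function(i)
    list(id = i, input = same, reference = tr$doses$ASC))
  m <- train_correction(ds, correction_task("ASC"), cfg)
  for (h in m$history) {
    expect_lte(utils::tail(h$train_loss, 1), h$train_loss[1] + 1e-8)
  }
  # reproducibility under fixed seeds
  m2 <- train_correction(ds, correction_task("ASC"), cfg)
  expect_identical(vapply(m$members, function(x) x$weights, numeric(6)),
                   vapply(m2$members, function(x) x$weights, numeric(6)))
})
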