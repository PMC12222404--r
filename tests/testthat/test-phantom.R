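test_that("phantom geometry and uptake ratio are realised as specified", {
  rec <- test_recipe(uptake_ratio = 5)
  ph <- build_phantom(rec)
  m <- ph$masks$masks
  expect_false(any(m$tumour & !m$wl))
  expect_false(any(m$wl & !m$body))
  expect_identical(m$wnl, m$wl & !m$tumour)
  act <- ph$true_activity$values
  expect_equal(mean(act[m$tumour]) / mean(act[m$wnl]), 5, tolerance = 1e-9)
  expect_true(any(m$lungs) && any(m$kidneys) && any(m$stomach))
  # mu map: soft tissue in body, lower in lungs, zero outside
  expect_equal(unique(ph$mu_map$values[m$lungs]), 0.003)
  expect_true(all(ph$mu_map$values[!m$body] == 0))
})

test_that("zero tumour radius yields a uniform whole liver", {
  rec <- test_recipe(tumours = list(list(center = c(0.63, 0.46, 0.48),
                                         radius_mm = 0)))
  ph <- build_phantom(rec)
  act <- ph$true_activity$values[ph$masks$masks$wl]
  expect_lt(diff(range(act)), 1e-12)
  expect_false(any(ph$masks$masks$tumour))
})

test_that("a tumour fully outside the liver is a recipe error", {
  expect_error(build_phantom(test_recipe(
    tumours = list(list(center = c(0.05, 0.05, 0.05), radius_mm = 10)))),
    "outside the liver")
  expect_error(phantom_recipe(uptake_ratio = 1), "exceed 1")
})

test_that("attenuation never increases a voxel and is depth-monotone", {
  rec <- test_recipe()
  ph <- build_phantom(rec)
  att <- apply_attenuation(ph$true_activity, ph$mu_map)
  expect_true(all(att$values <= ph$true_activity$values + 1e-12))
  # mu = 0 is the identity
  zero_mu <- volume3d(array(0, dim(ph$mu_map$values)),
                      spacing = ph$mu_map$spacing)
  ident <- apply_attenuation(ph$true_activity, zero_mu)
  expect_equal(ident$values, ph$true_activity$values, tolerance = 1e-12)
})

test_that("single axis-aligned ray reproduces Beer-Lambert exactly", {
  d <- c(20, 5, 5)
  mu0 <- 0.011
  mu <- volume3d(array(mu0, d), spacing = rep(4.795, 3))
  act <- volume3d(array(1, d), spacing = rep(4.795, 3))
  out <- apply_attenuation(act, mu, directions = matrix(c(1, 0), 1))
  # voxel centre at index i (1-based) is (d[1] - i + 0.5) voxels from the
  # +x exit face; closed form exp(-mu * depth_mm)
  for (i in c(1, 5, 12, 20)) {
    depth_mm <- (d[1] - i + 0.5) * 4.795
    expect_equal(out$values[i, 3, 3], exp(-mu0 * depth_mm), tolerance = 1e-9)
  }
  # surface voxel attenuated strictly less than a deep one
  expect_gt(out$values[20, 3, 3], out$values[2, 3, 3])
})

test_that("scatter conserves total counts and is identity at f = 0", {
  rec <- test_recipe()
  ph <- build_phantom(rec)
  act <- ph$true_activity
  sc <- apply_scatter(act, degradation_model(scatter_fraction = 0.35))
  expect_lt(abs(sum(sc$values) - sum(act$values)) / sum(act$values), 1e-12)
  id <- apply_scatter(act, degradation_model(scatter_fraction = 0))
  expect_identical(id$values, act$values)
})

test_that("a point source keeps at least (1 - f) of its counts under scatter", {
  d <- c(21, 21, 21)
  a <- array(0, d); a[11, 11, 11] <- 1000
  v <- volume3d(a, spacing = rep(4.795, 3))
  sc <- apply_scatter(v, degradation_model(scatter_fraction = 0.35))
  expect_gte(sc$values[11, 11, 11], 0.65 * 1000)
})

test_that("triplet generation is deterministic and degenerates to identity", {
  rec <- test_recipe(seed = 42)
  t1 <- generate_task_triplet(rec)
  t2 <- generate_task_triplet(rec)
  for (st in c("NC", "AC", "ASC"))
    expect_identical(t1$counts[[st]]$values, t2$counts[[st]]$values)
  # no degradation, no noise: all three states coincide
  none <- degradation_model(mu_soft = 0, mu_lung = 0, mu_bone = 0,
                            scatter_fraction = 0, poisson_noise = FALSE)
  t0 <- generate_task_triplet(rec, none)
  expect_equal(t0$counts$NC$values, t0$counts$ASC$values, tolerance = 1e-12)
  expect_equal(t0$counts$AC$values, t0$counts$ASC$values, tolerance = 1e-12)
})

test_that("correction states order tumour and WNL mean doses as expected", {
  tr <- generate_task_triplet(test_recipe(shape = c(40L, 40L, 40L), seed = 8))
  tum <- region_mask(tr$masks, "tumour")
  wnl <- region_mask(tr$masks, "wnl")
  tmad <- vapply(tr$doses, function(dm) mean(dm$values[tum]), 0)
  wmad <- vapply(tr$doses, function(dm) mean(dm$values[wnl]), 0)
  # tumour underdosed, WNL overdosed in uncorrected maps
  expect_lte(tmad[["NC"]], tmad[["AC"]])
  expect_lte(tmad[["AC"]], tmad[["ASC"]])
  expect_gte(wmad[["NC"]], wmad[["AC"]])
  expect_gte(wmad[["AC"]], wmad[["ASC"]])
})

test_that("WL deposited energy is identical across correction states", {
  tr <- generate_task_triplet(test_recipe(seed = 5))
  wl <- region_mask(tr$masks, "wl")
  e <- vapply(tr$doses, deposited_energy_j, 0, mask = wl)
  expect_lt(max(abs(e - e[1])) / e[1], 1e-10)
})
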