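test_that("identity region report is exact and uniform shifts are recovered", {
  tr <- generate_task_triplet(test_recipe(seed = 2))
  ref <- tr$doses$ASC
  rr <- region_report(ref, ref, tr$masks)
  expect_true(all(rr$me == 0 & rr$mae == 0 & rr$re_pct == 0))
  expect_equal(rr$mad_pred, rr$mad_ref)

  # uniform region: 50 -> 55 Gy gives MAD error 5 Gy, RE 10%, shift 5 Gy
  d <- c(8, 8, 8)
  masks <- segmentation_set(list(body = array(TRUE, d),
                                 wl = array(TRUE, d),
                                 tumour = array(FALSE, d)),
                            spacing = rep(4.795, 3))
  r50 <- dose_map(volume3d(array(50, d), spacing = rep(4.795, 3)), "ASC")
  p55 <- dose_map(volume3d(array(55, d), spacing = rep(4.795, 3)), "ASC")
  rr2 <- region_report(p55, r50, masks, regions = "wl")
  expect_equal(rr2$mad_pred - rr2$mad_ref, 5)
  expect_equal(rr2$re_pct, 10, tolerance = 1e-12)
  expect_equal(rr2$rae_pct, 10, tolerance = 1e-12)
  expect_equal(rr2$median_shift, 5)
})

test_that("WL MAD is the volume-weighted mean of tumour and WNL MADs", {
  tr <- generate_task_triplet(test_recipe(seed = 7))
  rr <- region_report(tr$doses$NC, tr$doses$ASC, tr$masks,
                      regions = c("tumour", "wnl", "wl"))
  g <- function(reg, col) rr[rr$region == reg, col]
  for (col in c("mad_ref", "mad_pred")) {
    wl_expect <- (g("tumour", col) * g("tumour", "n_voxels") +
                    g("wnl", col) * g("wnl", "n_voxels")) /
      g("wl", "n_voxels")
    expect_equal(g("wl", col), wl_expect, tolerance = 1e-12)
    expect_gte(g("wl", col), min(g("tumour", col), g("wnl", col)))
    expect_lte(g("wl", col), max(g("tumour", col), g("wnl", col)))
  }
})

test_that("DVH endpoints, monotonicity and layer-cake identity hold", {
  # uniform region: rectangle DVH
  d <- c(6, 6, 6)
  u <- dose_map(volume3d(array(50, d), spacing = rep(4.795, 3)), "ASC")
  mask <- array(TRUE, d)
  cv <- dvh(u, mask, dose_step_gy = 1)
  expect_equal(cv$volume_pct[cv$dose_gy <= 50], rep(100, 51))
  expect_equal(cv$volume_pct[cv$dose_gy > 50], 0)
  # half at 20, half at 100 -> V(50) = 50%
  h <- array(20, d); h[1:3, , ] <- 100
  hv <- dvh(dose_map(volume3d(h, spacing = rep(1, 3)), "ASC"), mask,
            dose_step_gy = 0.5)
  expect_equal(hv$volume_pct[hv$dose_gy == 50], 50)
  # property check on seeded random maps
  for (s in 1:20) {
    set.seed(s)
    vals <- array(rexp(prod(d), 1 / 40), d)
    dm <- dose_map(volume3d(vals, spacing = rep(4.795, 3)), "ASC")
    cv <- dvh(dm, mask, dose_step_gy = 0.5)
    expect_equal(cv$volume_pct[1], 100)
    expect_true(all(diff(cv$volume_pct) <= 1e-12))
    expect_equal(utils::tail(cv$volume_pct, 1), 0)
    expect_lt(abs(dvh_mad(cv) - mean(vals)), 0.5)
  }
  expect_error(dvh(u, array(FALSE, d)), "empty mask")
})

test_that("rank-sum test matches exhaustive enumeration and flags shifts", {
  res <- compare_mad_distributions(c(1, 2, 3), c(10, 11, 12))
  oracle <- enumerate_ranksum(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$u, 0)
  expect_equal(oracle$u, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(oracle$p, 0.1, tolerance = 1e-12)
  expect_false(res$significant)

  set.seed(3)
  a <- rnorm(20, 50, 5)
  res2 <- compare_mad_distributions(a, a + 30)
  expect_lt(res2$p_value, 0.05)
  expect_true(res2$significant)

  res3 <- compare_mad_distributions(a, a)
  expect_gt(res3$p_value, 0.05)
  expect_warning(compare_mad_distributions(rep(1, 3), rep(1, 4)),
                 "degenerate")
})

test_that("uncorrected maps underdose the tumour and overdose the WNL consistently", {
  tum_nc <- c(); tum_asc <- c(); wnl_nc <- c(); wnl_asc <- c()
  for (s in 1:8) {
    tr <- generate_task_triplet(test_recipe(seed = 100 + s))
    tum <- region_mask(tr$masks, "tumour")
    wnl <- region_mask(tr$masks, "wnl")
    tum_nc <- c(tum_nc, mean(tr$doses$NC$values[tum]))
    tum_asc <- c(tum_asc, mean(tr$doses$ASC$values[tum]))
    wnl_nc <- c(wnl_nc, mean(tr$doses$NC$values[wnl]))
    wnl_asc <- c(wnl_asc, mean(tr$doses$ASC$values[wnl]))
  }
  # sign pattern holds case by case, and the tumour MAD distributions of
  # the two correction states are statistically separable
  expect_true(all(tum_nc < tum_asc))
  expect_true(all(wnl_nc > wnl_asc))
  expect_lt(compare_mad_distributions(tum_nc, tum_asc)$p_value, 0.05)
})
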