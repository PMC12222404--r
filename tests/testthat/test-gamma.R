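mk_dose <- function(vals, spacing = rep(4.795, 3)) {
  dose_map(volume3d(vals, spacing = spacing), "ASC")
}

test_that("identical maps give gamma zero and 100% pass for all three criteria", {
  set.seed(1)
  d <- c(12, 12, 12)
  v <- mk_dose(array(runif(prod(d), 0, 100), d))
  for (cr in sirt_gamma_criteria()) {
    g <- gamma_map(v, v, cr)
    expect_equal(max(g$gamma), 0)
    expect_equal(g$pass_rate_pct, 100)
  }
})

test_that("single-voxel dose perturbation matches the one-term closed form", {
  d <- c(9, 9, 9)
  ref <- array(0, d); ref[5, 5, 5] <- 100
  ev <- ref; ev[5, 5, 5] <- 100.5
  g <- gamma_map(mk_dose(ref), mk_dose(ev), gamma_criteria(4.795, 1))
  # dose term 0.5 Gy / (1% of 100 Gy) = 0.5 at zero distance
  expect_equal(g$gamma[5, 5, 5], 0.5, tolerance = 1e-9)
  expect_lte(g$gamma[5, 5, 5], 1)
})

test_that("a one-voxel displacement passes when DTA equals the voxel size", {
  d <- c(9, 9, 9)
  ref <- array(0, d); ref[5, 5, 5] <- 100
  ev <- array(0, d); ev[6, 5, 5] <- 100
  g <- gamma_map(mk_dose(ref), mk_dose(ev), gamma_criteria(4.795, 1))
  expect_lte(g$gamma[5, 5, 5], 1)
})

test_that("optimised gamma equals the exhaustive brute force on seeded pairs", {
  for (s in 1:10) {
    set.seed(s)
    d <- c(9, 9, 9)
    ref <- array(runif(prod(d), 0, 100), d)
    ev <- pmax(ref + array(rnorm(prod(d), 0, 4), d), 0)
    cr <- gamma_criteria(4.795, 1)
    g <- gamma_map(mk_dose(ref), mk_dose(ev), cr)
    oracle <- bruteforce_gamma(ref, ev, rep(4.795, 3), 4.795, 0.01,
                               max(ref))
    expect_lt(max(abs(g$gamma - oracle)), 1e-9)
  }
  # looser criteria on a couple of pairs (larger search neighbourhoods)
  for (s in 1:2) {
    set.seed(100 + s)
    d <- c(7, 7, 7)
    ref <- array(runif(prod(d), 0, 100), d)
    ev <- pmax(ref + array(rnorm(prod(d), 0, 8), d), 0)
    for (cr in list(gamma_criteria(10, 5), gamma_criteria(15, 10))) {
      g <- gamma_map(mk_dose(ref), mk_dose(ev), cr)
      oracle <- bruteforce_gamma(ref, ev, rep(4.795, 3), cr$dta_mm,
                                 cr$dd_pct / 100, max(ref))
      expect_lt(max(abs(g$gamma - oracle)), 1e-9)
    }
  }
})

test_that("pass rates are monotone non-decreasing across the criteria triple", {
  for (s in 1:20) {
    set.seed(s)
    d <- c(10, 10, 10)
    ref <- array(runif(prod(d), 0, 100), d)
    ev <- pmax(ref + array(rnorm(prod(d), 0, runif(1, 1, 10)), d), 0)
    rates <- vapply(sirt_gamma_criteria(), function(cr)
      gamma_map(mk_dose(ref), mk_dose(ev), cr)$pass_rate_pct, 0)
    expect_lte(rates[1], rates[2] + 1e-12)
    expect_lte(rates[2], rates[3] + 1e-12)
  }
})

test_that("a 0.5% global scale error passes the strictest criterion everywhere", {
  set.seed(77)
  d <- c(10, 10, 10)
  ref <- array(runif(prod(d), 0, 100), d)
  ev <- 1.005 * ref
  g <- gamma_map(mk_dose(ref), mk_dose(ev), gamma_criteria(4.795, 1))
  expect_equal(g$pass_rate_pct, 100)
})

test_that("gamma is asymmetric in its arguments in general", {
  set.seed(5)
  d <- c(8, 8, 8)
  ref <- array(runif(prod(d), 0, 100), d)
  ev <- pmax(ref + array(rnorm(prod(d), 0, 10), d), 0)
  g1 <- gamma_map(mk_dose(ref), mk_dose(ev), gamma_criteria(4.795, 1))
  g2 <- gamma_map(mk_dose(ev), mk_dose(ref), gamma_criteria(4.795, 1))
  expect_gt(max(abs(g1$gamma - g2$gamma)), 0)
})

test_that("low-dose threshold and local normalisation are honoured", {
  set.seed(6)
  d <- c(8, 8, 8)
  ref <- array(runif(prod(d), 0, 100), d)
  ev <- ref * 1.02
  cr <- gamma_criteria(4.795, 1, low_dose_threshold_pct = 10)
  g <- gamma_map(mk_dose(ref), mk_dose(ev), cr)
  excluded <- ref < 0.10 * max(ref)
  expect_true(all(is.na(g$gamma[excluded])))
  expect_true(all(!is.na(g$gamma[!excluded])))
  glocal <- gamma_map(mk_dose(ref), mk_dose(ev),
                      gamma_criteria(4.795, 1, normalisation = "local"))
  expect_true(is.finite(glocal$pass_rate_pct))
})

test_that("gamma pass table reports every region and criteria combination", {
  tr <- generate_task_triplet(test_recipe(seed = 4))
  tab <- gamma_pass_table(tr$doses$ASC, tr$doses$ASC, tr$masks,
                          regions = c("tumour", "wnl"))
  expect_equal(nrow(tab), 9)  # 3 criteria x (whole image + 2 regions)
  expect_true(all(tab$pass_rate_pct == 100))
  expect_error(gamma_map(tr$doses$ASC,
                         mk_dose(array(0, c(2, 2, 2)), rep(4.795, 3)),
                         gamma_criteria(4.795, 1)), "shared grid")
})
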