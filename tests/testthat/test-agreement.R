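mk_pairs <- function(inv, est, component = "sbp") {
  n <- length(inv)
  invd <- data.frame(sbp = inv, map = inv, dbp = inv)
  estd <- data.frame(sbp = est, map = est, dbp = est)
  paired_measurements(sprintf("P%03d", seq_len(n)), invd, estd)
}

test_that("Bland-Altman reproduces hand-computed statistics", {
  # diffs {-2, 0, 2}: mean 0, sample SD 2, LoA -3.92 / +3.92
  inv <- c(100, 110, 120)
  a <- bland_altman(mk_pairs(inv, inv - c(-2, 0, 2)), "SBP")
  expect_equal(a$mean_diff, 0)
  expect_equal(a$sd_diff, 2)
  expect_equal(a$loa_lower, -3.92)
  expect_equal(a$loa_upper, 3.92)
  # all diffs zero
  a0 <- bland_altman(mk_pairs(inv, inv), "SBP")
  expect_equal(c(a0$mean_diff, a0$sd_diff, a0$loa_lower, a0$loa_upper),
               c(0, 0, 0, 0))
  expect_error(bland_altman(mk_pairs(100, 99)), "at least 2")
})

test_that("the LoA identity holds on random data", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    inv <- rnorm(n, 140, 20)
    est <- inv - rnorm(n, 1, 6)
    a <- bland_altman(mk_pairs(inv, est), "SBP")
    expect_equal(a$loa_upper, a$mean_diff + 1.96 * a$sd_diff)
    expect_equal(a$loa_lower, a$mean_diff - 1.96 * a$sd_diff)
    expect_equal(a$r_squared, a$r^2)
    expect_true(all(diff(a$bins$count) >= 0))   # cumulative bins
  }
})

test_that("zero-variance series flag the correlation as degenerate", {
  a <- bland_altman(mk_pairs(rep(120, 5), rep(118, 5)), "SBP")
  expect_true(a$r_degenerate)
  expect_true(is.na(a$r))
})

test_that("error bins match direct counts and printed percentages", {
  # 145 errors with 89 below 5, 123 below 10, 144 below 15
  e <- c(runif(89, 0, 4.9), runif(34, 5.05, 9.9), runif(21, 10.05, 14.9),
         20)
  stopifnot(length(e) == 145)
  b <- error_bins(e)
  expect_equal(b$count, c(89L, 123L, 144L))
  expect_equal(b$pct_rounded, c(61.4, 84.8, 99.3))
  expect_equal(error_bins(rep(0, 7))$pct, c(100, 100, 100))
  expect_equal(error_bins(c(1, 6, 12, 20))$pct_rounded, c(25.0, 50.0, 75.0))
})

test_that("error bins equal a brute-force count on random vectors", {
  set.seed(11)
  for (i in 1:1000) {
    e <- rnorm(sample(1:60, 1), sample(-3:3, 1), runif(1, 0.1, 12))
    b <- error_bins(e)
    brute <- sapply(c(5, 10, 15), function(L) {
      cnt <- 0L
      for (v in e) if (abs(v) < L) cnt <- cnt + 1L
      cnt
    })
    expect_identical(b$count, brute)
    expect_equal(b$pct, 100 * brute / length(e))
  }
})

test_that("normal-model tolerable-error probability matches the CDF", {
  expect_equal(iso2018_probability(0.71, 5.95), 90.5, tolerance = 0.05)
  expect_equal(iso2018_probability(0, 10), 100 * (pnorm(1) - pnorm(-1)))
  expect_equal(iso2018_probability(0, 0), 100)
  expect_equal(iso2018_probability(11, 0), 0)
  expect_error(iso2018_probability(0, -1), "sd_diff")
})

test_that("protocol grading applies the stated thresholds", {
  mk_res <- function(m, s, pct = c(90, 99, 100)) {
    structure(list(component = "SBP", n = 145, mean_diff = m, sd_diff = s,
                   loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                   r = 0.93, r_squared = 0.86, intercept = 0, slope = 1,
                   ba_intercept = 0, ba_slope = 0, r_degenerate = FALSE,
                   bins = data.frame(limit = c(5, 10, 15),
                                     count = round(1.45 * pct),
                                     pct = pct, pct_rounded = round(pct, 1))),
              class = "agreement_result")
  }
  g <- grade_component(mk_res(0.71, 5.95))
  expect_true(g$artery_pass)
  expect_true(g$aami2013_pass)
  expect_true(g$iso2018_pass)
  expect_false(grade_component(mk_res(6, 5))$artery_pass)
  # ARTERY strict, AAMI-2013 inclusive at the boundary
  g5 <- grade_component(mk_res(5, 8))
  expect_false(g5$artery_pass)
  expect_true(g5$aami2013_pass)
  # BHS grades from cumulative thresholds
  expect_equal(grade_component(mk_res(0, 3, c(81.4, 98.6, 100)))$bhs_grade,
               "A")
  expect_equal(grade_component(mk_res(0, 6, c(61.4, 84.8, 99.3)))$bhs_grade,
               "B")    # 84.8 misses the 85% grade-A requirement
  expect_equal(grade_component(mk_res(0, 9, c(45, 70, 88)))$bhs_grade, "C")
  expect_equal(grade_component(mk_res(0, 15, c(30, 50, 70)))$bhs_grade, "D")
})

test_that("grading is monotone: larger errors never improve a grade", {
  set.seed(3)
  inv <- rnorm(100, 140, 20)
  err <- rnorm(100, 0.5, 4)
  lvl <- c(D = 0, C = 1, B = 2, A = 3)
  prev <- Inf
  for (k in c(1, 1.5, 2.5, 4)) {
    a <- bland_altman(mk_pairs(inv, inv - k * err), "SBP")
    g <- grade_component(a)
    cur <- lvl[[g$bhs_grade]]
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("range conformity reproduces the reference distribution table", {
  # 145 invasive cSBP values split 3 / 58 / 46 / 38 across the ranges
  v <- c(runif(3, 85, 100), runif(58, 100.1, 139.9), runif(46, 140, 159.9),
         runif(38, 160, 220))
  rc <- range_conformity(v, "SBP")
  expect_equal(rc$table$count, c(3L, 58L, 46L, 38L))
  expect_equal(rc$table$pct, c(2.1, 40.0, 31.7, 26.2))
  expect_equal(rc$recruitment_ratio_pct, 171)
  expect_equal(range_conformity(runif(85, 60, 200), "SBP")$recruitment_ratio_pct,
               100)
  # DBP partition
  d <- c(runif(23, 45, 60), runif(105, 60.1, 84.9), runif(15, 85, 99.9),
         runif(2, 100, 107))
  rcd <- range_conformity(d, "DBP")
  expect_equal(rcd$table$count, c(23L, 105L, 15L, 2L))
  expect_equal(rcd$table$pct, c(15.9, 72.4, 10.3, 1.4))
})

test_that("paired measurements reject duplicates and bad pressures", {
  expect_error(paired_measurements(
    c("a", "a"), data.frame(sbp = c(1, 1) * 120, map = c(1, 1) * 95,
                            dbp = c(1, 1) * 80),
    data.frame(sbp = c(1, 1) * 120, map = c(1, 1) * 95,
               dbp = c(1, 1) * 80)), "duplicate")
  expect_error(paired_measurements(
    "a", data.frame(sbp = -5, map = 95, dbp = 80),
    data.frame(sbp = 120, map = 95, dbp = 80)), "positive")
})
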