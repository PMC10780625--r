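test_that("mean sensitivity matches hand computations and its bounds", {
  expect_equal(mean_sensitivity(c(5, 5, 5, 5)), 0)
  expect_equal(mean_sensitivity(c(1, 3, 1)), 1)        # (1 + 1) / 2
  expect_equal(mean_sensitivity(c(1, 2)), 2 / 3)       # 2*1/3
  expect_error(mean_sensitivity(c(1, 0, 1)), "positive")
  expect_error(mean_sensitivity(1), "at least 2")
  set.seed(301)
  for (i in 1:20) {
    ms <- mean_sensitivity(exp(rnorm(50)))
    expect_gte(ms, 0); expect_lte(ms, 2)
  }
})

test_that("first-order autocorrelation behaves on known series", {
  expect_lt(first_order_autocorrelation(c(1, 2, 1, 2, 1, 2)), 0)
  expect_gt(first_order_autocorrelation(1:100), 0.9)
  set.seed(302)
  x <- as.numeric(arima.sim(list(ar = 0.75), 1e4))
  expect_lt(abs(first_order_autocorrelation(x) - 0.75), 0.03)
  expect_error(first_order_autocorrelation(rep(1, 10)), "variance")
})

test_that("coefficient of variation reproduces published group summaries", {
  # CV = 100 sd / mean applied to a published mean/sd pair
  expect_equal(round(cv_percent(12.56, 6.61), 1), 52.6)
  expect_equal(round(cv_percent(27.61, 6.44), 1), 23.3)
  expect_equal(coefficient_of_variation(rep(3.7, 10)), 0)
  x <- c(2, 4, 6)
  expect_equal(coefficient_of_variation(x), 100 * sd(x) / mean(x))
  expect_error(coefficient_of_variation(c(-2, 1)), "positive mean")
})

test_that("master correlation keeps synchronized and drops shuffled series", {
  yrs <- 1950:1997
  master <- setNames(exp(rnorm(length(yrs), 0, 0.2)), yrs)
  same <- correlation_with_master(master, master, min_overlap = 20)
  expect_equal(same$r, 1)
  expect_true(same$keep)
  anti <- setNames(2 * mean(master) - master, yrs)  # negated anomalies
  r <- correlation_with_master(anti, master, min_overlap = 20)
  expect_equal(r$r, -1)
  expect_false(r$keep)
  short <- correlation_with_master(master[1:5], master, min_overlap = 20)
  expect_true(short$undatable)
})

test_that("pith-offset geometry matches the sagitta formula", {
  expect_equal(estimate_pith_offset(8, 1, 1)$radius_mm, 8.5)
  # constructed circle geometry: core stopped 5 mm short of the pith,
  # innermost rings 1 mm wide; arc of the r = 5 circle with sagitta 1
  # has chord 2*sqrt(5^2 - 4^2) = 6
  est <- estimate_pith_offset(6, 1, inner_widths = c(1, 1))
  expect_equal(est$radius_mm, 5)
  expect_equal(est$missing_rings, 5)
  # near-pith core: tiny remaining radius rounds to zero missing rings
  expect_equal(estimate_pith_offset(2, 1, inner_widths = 2)$missing_rings, 0)
  expect_error(estimate_pith_offset(8, 0, 1), "sagitta")
})

test_that("age correction recovers a known line and clamps predictions", {
  ages <- c(10, 30, 50, 90, 130)
  m <- fit_age_correction(ages, 16 - 0.1 * ages)
  expect_equal(predict(m, c(10, 130)), c(15L, 3L))
  # constant differences: intercept c, slope 0
  mc <- fit_age_correction(c(10, 20, 30), rep(7, 3))
  expect_equal(unname(coef(mc$fit)), c(7, 0))
  expect_error(fit_age_correction(c(10, 10, 10), 1:3), "degenerate")
  # noisy line: slope within 2 standard errors
  set.seed(303)
  a <- runif(50, 10, 140)
  mz <- fit_age_correction(a, 16 - 0.1 * a + rnorm(50))
  se <- summary(mz$fit)$coefficients[2, 2]
  expect_lt(abs(coef(mz$fit)[2] + 0.1), 2 * se)
})

test_that("age classes follow the Y/M/O bounds and the regeneration rule", {
  expect_equal(assign_age_class(c(40, 41, 80, 81)), c("Y", "M", "M", "O"))
  expect_equal(assign_age_class(3, adult = FALSE), "ER")
  expect_true(is.na(assign_age_class(2, adult = FALSE)))
})

test_that("age structure bins preserve counts and expose cohort gaps", {
  expect_equal(age_structure(50, 5),
               data.frame(midpoint = seq(2.5, 47.5, 5),
                          count = c(rep(0L, 9), 1L)))
  set.seed(304)
  ages <- sample(5:140, 200, replace = TRUE)
  expect_equal(sum(age_structure(ages)$count), 200)
  # bimodal establishment separated by a demographic gap
  bimodal <- c(round(runif(24, 108, 140)), round(runif(80, 14, 72)))
  h <- age_structure(bimodal, 5)
  gap <- h$count[h$midpoint > 75 & h$midpoint < 105]
  expect_true(all(gap == 0))
  expect_gte(diff(range(h$midpoint[h$midpoint > 75 & h$midpoint < 105])) + 5,
             30)
})

test_that("biometric screen applies the 2-of-3 and strict >20-ring rules", {
  set.seed(305)
  n <- 30
  tr <- data.frame(id = sprintf("t%02d", 1:n), age = rep(25, n),
                   dbh_cm = rnorm(n, 20, 2), h_m = rnorm(n, 10, 1),
                   cw_m2 = rnorm(n, 30, 3))
  rings <- setNames(rep(30L, n), tr$id)
  # a tree above the mean on all three parameters is kept
  tr$dbh_cm[1] <- 30; tr$h_m[1] <- 15; tr$cw_m2[1] <- 45
  scr <- biometric_screen(tr, rings)
  expect_true(scr$keep[1])
  # exactly 20 rings is discarded: the rule is strictly more than 20
  rings[2] <- 20L
  scr2 <- biometric_screen(tr, rings)
  expect_false(scr2$keep[2])
  expect_true(all(scr2$keep[-2] == scr$keep[-2]))
  # singleton age group passes by default but is flagged
  tr2 <- rbind(tr, data.frame(id = "t99", age = 95, dbh_cm = 1, h_m = 1,
                              cw_m2 = 1))
  scr3 <- biometric_screen(tr2, c(rings, t99 = 50L))
  expect_true(scr3$keep[scr3$id == "t99"])
  expect_true(scr3$sd_undefined[scr3$id == "t99"])
})

test_that("planted defective cores and stunted trees are recovered exactly", {
  sc <- ring_scenario(n_per_class = c(Y = 56, M = 31, O = 24),
                      n_shuffled = 26, seed = 306)
  sr <- generate_ring_series(sc, test_climate())
  expect_equal(length(sr), 222)
  scr <- crossdating_screen(sr)
  expect_setequal(scr$core[!scr$keep], attr(sr, "shuffled_cores"))
  expect_equal(sum(!scr$keep), 26)

  sc2 <- ring_scenario(p_pith = 1, seed = 307)
  sr2 <- generate_ring_series(sc2, test_climate())
  ages <- attr(sr2, "tree_ages")
  stunt <- plant_stunted_ids(ages, n = 33, seed = 308)
  tr <- generate_tree_records(ages, stunted_ids = stunt, seed = 309)
  tr$cw_m2 <- crown_area(tr$cr_n_m, tr$cr_e_m, tr$cr_s_m, tr$cr_w_m)
  rings <- setNames(vapply(merge_cores(sr2),
                           function(s) length(s$widths), numeric(1)),
                    names(merge_cores(sr2)))
  bs <- biometric_screen(
    data.frame(id = tr$id, age = ages[tr$id], dbh_cm = tr$dbh_cm,
               h_m = tr$h_m, cw_m2 = tr$cw_m2), rings)
  expect_setequal(bs$id[!bs$keep], stunt)
  expect_equal(sum(bs$keep), 70)
})

test_that("detrending fits the curve it divides by", {
  # negexp self-fit: widths exactly a exp(-bt) + k give indices of 1
  t <- 1:80
  w <- 2.5 * exp(-0.07 * t) + 1.1
  s <- ring_series("t", "c", 1900, w)
  ix <- detrend(s, "negexp")
  expect_equal(ix$index, rep(1, 80), tolerance = 1e-6)
  # constant series under spline: flat fit, indices 1
  sc <- ring_series("t", "c", 1900, rep(2, 40))
  expect_equal(detrend(sc, "spline")$index, rep(1, 40), tolerance = 1e-10)
  # nondecreasing widths: negexp falls back to the horizontal mean
  up <- ring_series("t", "c", 1900, seq(1, 3, length.out = 40))
  fb <- detrend(up, "negexp")
  expect_equal(fb$fit, rep(mean(up$widths), 40))
  expect_error(detrend(s, "spline", stiffness = 0), "stiffness")
  expect_error(detrend(ring_series("t", "c", 1900, rep(1, 5)), "spline"),
               "too short")
  # detrending preserves length; index mean near 1 for well-fit series
  set.seed(310)
  noisy <- ring_series("t", "c", 1900,
                       (2 * exp(-0.05 * (1:100)) + 1) * exp(rnorm(100, 0, 0.15)))
  for (m in c("spline", "negexp", "mean")) {
    ix <- detrend(noisy, m)
    expect_length(ix$index, 100)
    if (m != "mean") expect_lt(abs(mean(ix$index) - 1), 0.02)
  }
})

test_that("RCS normalizes a shared-curve cohort at every well-sampled age", {
  sc <- ring_scenario(n_per_class = c(M = 50),
                      age_range = list(M = c(30, 120)),
                      age_curve = list(M = c(a = 2, b = 0.05, k = 1.2)),
                      beta = zero_beta(), phi = 0, sigma = 0.05,
                      cores_per_tree = 1, core_sd = 0, p_pith = 0.3,
                      seed = 311)
  sr <- generate_ring_series(sc, test_climate())
  rc <- rcs_curve(sr)
  idx <- lapply(sr, detrend, method = "rcs", rc = rc)
  amax <- length(rc$curve)
  acc <- matrix(NA_real_, length(sr), amax)
  for (i in seq_along(sr))
    acc[i, seq_along(idx[[i]]$index) + sr[[i]]$pith_offset_rings] <-
      idx[[i]]$index
  depth <- colSums(!is.na(acc))
  mean_idx <- colMeans(acc, na.rm = TRUE)
  expect_lt(max(abs(mean_idx[depth >= 10] - 1)), 0.05)
})

test_that("chronology aggregation and statistics behave on known inputs", {
  s1 <- detrend(ring_series("a", "a1", 1950,
                            (2 * exp(-0.05 * (1:48)) + 1) *
                              exp(rnorm(48, 0, 0.1))), "negexp")
  expect_equal(build_chronology(list(s1))$index, s1$index)
  # two identical series: CC and CM exactly 1
  ch2 <- build_chronology(list(s1, s1))
  expect_equal(ch2$stats$CC, 1)
  expect_equal(ch2$stats$CM, 1)
  expect_error(build_chronology(list()), "no series")
})

test_that("standardization removes the persistence of the raw master", {
  cnt <- 0
  for (i in 1:20) {
    sc <- ring_scenario(n_per_class = c(M = 12),
                        age_range = list(M = c(60, 90)),
                        age_curve = list(M = c(a = 2, b = 0.05, k = 1.2)),
                        cores_per_tree = 1, seed = 330 + i)
    sr <- generate_ring_series(sc, test_climate())
    ch <- build_chronology(lapply(sr, detrend, method = "negexp"), raw = sr)
    cnt <- cnt + (ch$stats$AC1_std < ch$stats$AC1_raw)
  }
  expect_gte(cnt, 19)
})

test_that("cumulative DIB doubles ring sums and orders growth rates", {
  s <- ring_series("t", "c", 1990, c(1, 1, 1), pith_reached = TRUE)
  expect_equal(cumulative_dib(s)$dib, c(2, 4, 6))
  expect_equal(cumulative_dib(s, unit = "cm")$dib, c(0.2, 0.4, 0.6))
  expect_equal(nrow(cumulative_dib(s)), 3)
  set.seed(312)
  fast <- ring_series("f", "f", 1900, 3 * exp(-0.03 * (1:60)) + 1.5,
                      pith_reached = TRUE)
  slow <- ring_series("s", "s", 1900, 1.5 * exp(-0.15 * (1:60)) + 0.7,
                      pith_reached = TRUE)
  dib_f <- cumulative_dib(fast)$dib
  dib_s <- cumulative_dib(slow)$dib
  expect_true(all(dib_s < dib_f))
  expect_true(all(diff(dib_f) > 0))
})
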