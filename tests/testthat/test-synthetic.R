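test_that("point-pattern generator honours counts, window and seed", {
  sc <- spatial_scenario(n_per_class = c(Y = 30, M = 20, O = 10),
                         seed = 201)
  p1 <- generate_point_pattern(sc)
  p2 <- generate_point_pattern(sc)
  expect_identical(p1, p2)  # bit-identical under a fixed seed
  expect_equal(unname(table(p1$marks)[c("Y", "M", "O")]),
               c(30, 20, 10), ignore_attr = TRUE)
  expect_true(all(p1$x^2 + p1$y^2 <= 40^2))

  # empty class is vacuously fine
  p0 <- generate_point_pattern(
    spatial_scenario(n_per_class = c(Y = 0, M = 5), seed = 202))
  expect_false("Y" %in% p0$marks)
  expect_equal(p0$n, 5)
})

test_that("hardcore process respects the inhibition distance and fails when infeasible", {
  sc <- spatial_scenario(n_per_class = c(A = 10),
                         process_per_class = list(A = hardcore_process(5)),
                         seed = 203)
  p <- generate_point_pattern(sc)
  expect_true(min(dist(cbind(p$x, p$y))) >= 5)

  packed <- spatial_scenario(n_per_class = c(A = 500),
                             process_per_class = list(
                               A = hardcore_process(10)),
                             seed = 204)
  expect_error(generate_point_pattern(packed), "infeasible")
})

test_that("Thomas clusters shrink nearest-neighbour distances below Poisson", {
  nnd <- function(p) {
    dm <- as.matrix(dist(cbind(p$x, p$y))); diag(dm) <- Inf
    mean(apply(dm, 1, min))
  }
  sc <- spatial_scenario(n_per_class = c(A = 100),
                         process_per_class = list(
                           A = thomas_process(n_parents = 5,
                                              cluster_sd = 2)),
                         seed = 205)
  t_nnd <- nnd(generate_point_pattern(sc))
  set.seed(206)
  pois_nnd <- replicate(200, {
    u <- oracle_runif_disc(100, 40)
    nnd(point_pattern(u$x, u$y, stand_window(40)))
  })
  expect_lt(t_nnd, mean(pois_nnd))
})

test_that("Poisson intensity matches the configured n/A on average", {
  # per-class counts are conditioned on n, so intensity is exact by
  # construction; check points are uniform by quadrat halves instead
  set.seed(207)
  inner <- replicate(100, {
    p <- generate_point_pattern(
      spatial_scenario(n_per_class = c(A = 100), seed = sample.int(1e6, 1)))
    mean(p$x^2 + p$y^2 <= 40^2 / 2)  # inner disc holds half the area
  })
  se <- sd(inner) / sqrt(length(inner))
  expect_lt(abs(mean(inner) - 0.5), 3 * se)
})

test_that("climate generator is deterministic, complete and Mediterranean", {
  sc <- climate_scenario(years = 1990, seed = 208)
  cl <- generate_climate(sc)
  expect_equal(nrow(cl), 12)  # one-year range, exactly 12 rows
  expect_identical(cl, generate_climate(sc))
  expect_true(all(cl$p_mm >= 0))
  expect_true(all(cl$tmax_c >= cl$tmin_c))

  # zero sds reproduce the monthly means exactly
  sc0 <- climate_scenario(years = 1990:1992, p_sd = rep(0, 12),
                          tmax_sd = rep(0, 12), tmin_sd = rep(0, 12),
                          seed = 209)
  cl0 <- generate_climate(sc0)
  expect_equal(cl0$p_mm, rep(sc0$p_mean, 3))
  expect_equal(cl0$tmax_c, rep(sc0$tmax_mean, 3))

  # long-run annual total near the configured 644.6 mm, November peak
  cl1k <- generate_climate(climate_scenario(years = 1:1000, seed = 210))
  annual <- tapply(cl1k$p_mm, cl1k$year, sum)
  expect_lt(abs(mean(annual) - 644.6) / 644.6, 0.02)
  by_month <- tapply(cl1k$p_mm, cl1k$month, mean)
  expect_equal(unname(which.max(by_month)), 11)
  expect_equal(unname(which.min(by_month)), 7)
})

test_that("ring generator reduces to the deterministic age curve without noise", {
  sc <- ring_scenario(n_per_class = c(M = 3),
                      age_range = list(M = c(50, 50)),
                      age_curve = list(M = c(a = 2, b = 0.05, k = 1.2)),
                      beta = zero_beta(), phi = 0, sigma = 0,
                      cores_per_tree = 1, core_sd = 0, p_pith = 1,
                      seed = 211)
  sr <- generate_ring_series(sc, test_climate())
  g <- 2 * exp(-0.05 * (1:50)) + 1.2
  for (s in sr) {
    expect_equal(length(s$widths), 50)
    expect_equal(s$widths, round(g, 2))
  }
})

test_that("ring generator reproduces the AR(1) persistence it is given", {
  cl <- generate_climate(climate_scenario(years = 970:1998, seed = 212))
  sc <- ring_scenario(n_per_class = c(O = 1),
                      age_range = list(O = c(1000, 1000)),
                      age_curve = list(O = c(a = 2, b = 0.05, k = 1.2)),
                      beta = zero_beta(), phi = 0.7, sigma = 0.3,
                      cores_per_tree = 1, core_sd = 0, p_pith = 1,
                      seed = 213)
  s <- generate_ring_series(sc, cl)[[1]]
  g <- 2 * exp(-0.05 * seq_along(s$widths)) + 1.2
  ac1 <- first_order_autocorrelation(log(s$widths) - log(g))
  expect_lt(abs(ac1 - 0.7), 0.05)
})

test_that("a planted single-regressor climate signal is recoverable", {
  beta <- zero_beta()
  beta["p_oct_prev"] <- 0.8
  sc <- ring_scenario(n_per_class = c(M = 50),
                      age_range = list(M = c(40, 40)),
                      age_curve = list(M = c(a = 2, b = 0.05, k = 1.2)),
                      beta = beta, phi = 0, sigma = 0.3,
                      cores_per_tree = 1, core_sd = 0, p_pith = 1,
                      seed = 214)
  sr <- generate_ring_series(sc, test_climate())
  g <- 2 * exp(-0.05 * (1:40)) + 1.2
  logdet <- colMeans(t(sapply(sr, function(s) log(s$widths) - log(g))))
  yrs <- series_years(sr[[1]])
  Z <- scale(build_regressor_matrix(test_climate(), min(yrs), max(yrs)))
  cors <- abs(cor(logdet, Z))
  expect_equal(colnames(Z)[which.max(cors)], "p_oct_prev")
})

test_that("series length, positivity and climate coverage are enforced", {
  sc <- ring_scenario(seed = 215)
  sr <- generate_ring_series(sc, test_climate())
  ages <- attr(sr, "tree_ages")
  expect_true(all(sapply(sr, function(s) all(s$widths > 0))))
  # measured rings + pith offset equals the tree age
  for (s in sr[1:20])
    expect_equal(length(s$widths) + s$pith_offset_rings,
                 unname(ages[s$tree]))
  short <- generate_climate(climate_scenario(years = 1990:1998, seed = 216))
  expect_error(generate_ring_series(sc, short), "does not cover")
})

test_that("with no climate signal, true-curve detrending centres indices at 1", {
  sc <- ring_scenario(n_per_class = c(M = 30),
                      age_range = list(M = c(60, 60)),
                      age_curve = list(M = c(a = 2, b = 0.05, k = 1.2)),
                      beta = zero_beta(), phi = 0, sigma = 0.15,
                      cores_per_tree = 1, core_sd = 0, p_pith = 1,
                      seed = 217)
  sr <- generate_ring_series(sc, test_climate())
  g <- 2 * exp(-0.05 * (1:60)) + 1.2
  idx <- unlist(lapply(sr, function(s) s$widths / g))
  se <- sd(idx) / sqrt(length(idx))
  # lognormal mean exp(sigma^2/2) of about 1.011
  expect_lt(abs(mean(idx) - exp(0.15^2 / 2)), 3 * se)
})
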