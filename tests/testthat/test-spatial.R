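test_that("K and L reproduce hand-enumerated pair counts", {
  w <- stand_window(40)
  # points (0,0), (3,0), (0,4): ordered pairs within 4 m are the 3- and the
  # two 4-m pairs counted both ways; the 5-m pair is excluded
  p <- point_pattern(c(0, 3, 0), c(0, 0, 4), w)
  k <- ripley_K(p, d_max = 5)
  expect_equal(k$K[4], pi * 40^2 * 4 / 9)
  expect_equal(k$L[4], sqrt(1600 * 4 / 9) - 4)
  expect_equal(k$K[1], 0)  # no pairs within 1 m

  # single point: no pairs, K identically zero, flagged not failed
  p1 <- point_pattern(0, 0, w)
  expect_warning(k1 <- ripley_K(p1, d_max = 10), "fewer than 2")
  expect_true(all(k1$K == 0))
  expect_true(k1$degenerate)
})

test_that("Besag transform satisfies its identities", {
  d <- 1:10
  expect_equal(besag_L(pi * d^2, d), rep(0, 10))  # CSR identity
  expect_equal(besag_L(0, 5), -5)
  expect_error(besag_L(-1, 1), "nonnegative")
})

test_that("production estimators equal the naive pair-counting oracle", {
  w <- stand_window(40)
  grid <- 1:20
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(3:50, 1)
    u <- oracle_runif_disc(n, 40)
    p <- point_pattern(u$x, u$y, w)
    expect_equal(ripley_K(p, d_max = 20)$K, naive_K(u$x, u$y, w$area, grid))
    # bivariate: split the same points into two arbitrary classes
    m <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(m)) < 2) next
    pm <- point_pattern(u$x, u$y, w, marks = m)
    i1 <- m == "a"
    expect_equal(bivariate_K12(pm, "a", "b", d_max = 20)$K,
                 naive_K12(u$x[i1], u$y[i1], u$x[!i1], u$y[!i1],
                           w$area, grid))
  }
})

test_that("K is invariant under rigid motion and K12 symmetric in classes", {
  w <- stand_window(40)
  set.seed(102)
  u <- oracle_runif_disc(40, 30)  # keep room to translate
  p <- point_pattern(u$x, u$y, w)
  th <- 0.83
  rot <- point_pattern(u$x * cos(th) - u$y * sin(th),
                       u$x * sin(th) + u$y * cos(th), w)
  shift <- point_pattern(u$x + 5, u$y - 4, w)
  expect_equal(ripley_K(p, d_max = 20)$K, ripley_K(rot, d_max = 20)$K)
  expect_equal(ripley_K(p, d_max = 20)$K, ripley_K(shift, d_max = 20)$K)

  m <- rep(c("a", "b"), each = 20)
  pm <- point_pattern(u$x, u$y, w, marks = m)
  expect_equal(bivariate_K12(pm, "a", "b", d_max = 20)$K,
               bivariate_K12(pm, "b", "a", d_max = 20)$K)
  expect_error(bivariate_K12(pm, "a", "zzz", d_max = 10), "zzz")
})

test_that("cross-K on a two-point pattern matches the manual count", {
  w <- stand_window(40)
  pm <- point_pattern(c(0, 0), c(0, 10), w, marks = c("a", "b"))
  k <- bivariate_K12(pm, "a", "b", d_max = 12)
  expect_equal(k$K[5], 0)          # no cross pairs within 5 m
  expect_equal(k$K[10], w$area)    # the single pair, combined estimator
})

test_that("isotropically corrected K under CSR tracks the pi d^2 closed form", {
  # the plain estimator is edge-biased by construction (valid for
  # envelope inference because data and null share the statistic); the
  # CSR closed form is the oracle for the corrected estimator
  w <- stand_window(40)
  grid <- 1:20
  set.seed(103)
  nsim <- 150
  Ks <- matrix(NA_real_, nsim, length(grid))
  for (i in seq_len(nsim)) {
    u <- oracle_runif_disc(200, 40)
    Ks[i, ] <- ripley_K(point_pattern(u$x, u$y, w), d_max = 20,
                        correction = "isotropic")$K
  }
  mK <- colMeans(Ks)
  se <- apply(Ks, 2, sd) / sqrt(nsim)
  expect_true(all(abs(mK - pi * grid^2) <= 3 * se + 0.01 * pi * grid^2))
  # and the plain estimator is biased low at large d, as expected
  set.seed(104)
  Kp <- colMeans(t(replicate(60, {
    u <- oracle_runif_disc(200, 40)
    ripley_K(point_pattern(u$x, u$y, w), d_max = 20)$K
  })))
  expect_lt(Kp[20], pi * 400)
})

test_that("envelopes classify strong clustering and inhibition", {
  sc <- spatial_scenario(n_per_class = c(A = 100),
                         process_per_class = list(
                           A = thomas_process(n_parents = 5,
                                              cluster_sd = 2)),
                         seed = 104)
  e <- csr_envelope(generate_point_pattern(sc), seed = 105)
  expect_true(any(e$classification[2:10] == "clustered"))
  expect_true(all(e$env_low <= e$env_high))

  sc2 <- spatial_scenario(n_per_class = c(A = 60),
                          process_per_class = list(
                            A = hardcore_process(6)),
                          seed = 106)
  e2 <- csr_envelope(generate_point_pattern(sc2), seed = 107)
  expect_true(any(e2$classification[1:5] == "regular"))
})

test_that("bivariate null detects planted attraction and repulsion", {
  w <- stand_window(40)
  set.seed(108)
  u <- oracle_runif_disc(60, 40)
  # attraction: class b jittered within 1 m of class a
  ang <- runif(60, 0, 2 * pi); rr <- runif(60, 0, 1)
  x2 <- u$x + rr * cos(ang); y2 <- u$y + rr * sin(ang)
  sc <- pmin(1, 39.99 / sqrt(x2^2 + y2^2)); x2 <- x2 * sc; y2 <- y2 * sc
  pa <- point_pattern(c(u$x, x2), c(u$y, y2), w,
                      marks = rep(c("a", "b"), each = 60))
  ea <- bivariate_null_envelope(pa, "a", "b", seed = 109)
  expect_true(any(ea$classification[1:3] == "attraction"))

  # repulsion: class b at least 8 m from every class a point
  scr <- spatial_scenario(n_per_class = c(a = 40, b = 40),
                          cross_class_rule = list(type = "repulsion",
                                                  min_distance = 8),
                          seed = 110)
  er <- bivariate_null_envelope(generate_point_pattern(scr), "a", "b",
                                seed = 111)
  expect_true(any(er$classification[1:8] == "repulsion"))
})

test_that("K is nondecreasing and L consistent across random patterns", {
  w <- stand_window(40)
  set.seed(112)
  for (rep in 1:20) {
    u <- oracle_runif_disc(sample(2:80, 1), 40)
    k <- ripley_K(point_pattern(u$x, u$y, w), d_max = 40)
    expect_true(all(diff(k$K) >= 0))
    expect_equal(k$L, sqrt(k$K / pi) - k$d)
  }
})
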