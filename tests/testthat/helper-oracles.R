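# Independent brute-force oracles, deliberately naive: plain double loops,
# no shared code with the production estimators.

naive_K <- function(x, y, A, grid) {
  n <- length(x)
  K <- numeric(length(grid))
  for (g in seq_along(grid)) {
    cnt <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= grid[g]) cnt <- cnt + 1
    }
    K[g] <- A * cnt / n^2
  }
  K
}

naive_K12 <- function(x1, y1, x2, y2, A, grid) {
  n1 <- length(x1); n2 <- length(x2)
  cross <- function(xa, ya, xb, yb, d) {
    cnt <- 0
    for (i in seq_along(xa)) for (j in seq_along(xb))
      if (sqrt((xa[i] - xb[j])^2 + (ya[i] - yb[j])^2) <= d) cnt <- cnt + 1
    cnt
  }
  K <- numeric(length(grid))
  for (g in seq_along(grid)) {
    k12 <- A * cross(x1, y1, x2, y2, grid[g]) / (n1 * n2)
    k21 <- A * cross(x2, y2, x1, y1, grid[g]) / (n1 * n2)
    K[g] <- (n2 * k12 + n1 * k21) / (n1 + n2)
  }
  K
}

# CSR points on the disc, independent of the package's internals
oracle_runif_disc <- function(n, R) {
  r <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  list(x = r * cos(th), y = r * sin(th))
}

# Shared small fixtures ----------------------------------------------------

test_climate <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- generate_climate(climate_scenario(years = 1850:1998,
                                                 seed = 901))
    memo
  }
})

zero_beta <- function() stats::setNames(numeric(24), regressor_names())
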