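# Run code with a private RNG stream: set the seed if given, and restore the
# caller's .Random.seed afterwards so stages do not perturb each other.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Uniform points on the disc (CSR conditional on n).
runif_disc <- function(n, window) {
  r  <- window$radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  list(x = window$center[1] + r * cos(th),
       y = window$center[2] + r * sin(th))
}

# Fraction of the circle of radius t centred on a point at distance rho from
# the plot centre that falls inside the circular window (isotropic edge
# correction on a disc).
disc_boundary_fraction <- function(rho, t, R) {
  frac <- rep(1, length(t))
  out  <- rho + t > R
  if (any(out)) {
    arg <- (rho[out]^2 + t[out]^2 - R^2) / (2 * rho[out] * t[out])
    arg <- pmin(1, pmax(-1, arg))
    frac[out] <- acos(arg) / pi
  }
  frac
}

# Shared per-distance cumulative pair counter. Returns, for each grid value
# d, the weighted count of ordered pairs (i in rows, j in cols) with
# distance <= d (closed inequality).
count_pairs_leq <- function(dists, weights, grid) {
  o <- order(dists)
  ds <- dists[o]
  ws <- cumsum(weights[o])
  idx <- findInterval(grid, ds)
  out <- numeric(length(grid))
  out[idx > 0] <- ws[idx[idx > 0]]
  out
}

kfun_result <- function(d, K, L, type, n, n_sims = NULL,
                        env_low = NULL, env_high = NULL,
                        classification = NULL, degenerate = FALSE,
                        labels = NULL) {
  structure(list(d = d, K = K, L = L, type = type, n = n,
                 n_sims = n_sims, env_low = env_low, env_high = env_high,
                 classification = classification, degenerate = degenerate,
                 labels = labels),
            class = "kfun")
}

#' @export
print.kfun <- function(x, ...) {
  cat(sprintf("%s K-function on %s points, distances %g-%g m\n",
              if (x$type == "univariate") "Univariate" else "Bivariate",
              paste(x$n, collapse = "+"), min(x$d), max(x$d)))
  if (!is.null(x$labels))
    cat("classes:", paste(x$labels, collapse = " vs "), "\n")
  if (!is.null(x$env_low)) {
    cat(sprintf("envelope from %d simulations; per-distance classification:\n",
                x$n_sims))
    print(table(x$classification))
  }
  if (x$degenerate)
    cat("NOTE: fewer than 2 points; K is identically zero\n")
  invisible(x)
}

#' @export
as.data.frame.kfun <- function(x, ...) {
  df <- data.frame(d = x$d, K = x$K, L = x$L)
  if (!is.null(x$env_low)) {
    df$env_low <- x$env_low
    df$env_high <- x$env_high
    df$classification <- x$classification
  }
  df
}

#' @export
plot.kfun <- function(x, ..., main = NULL) {
  if (is.null(main))
    main <- if (x$type == "univariate") "Besag's L(d)" else "Bivariate L12(d)"
  ylim <- range(c(x$L, x$env_low, x$env_high), finite = TRUE)
  plot(x$d, x$L, type = "l", col = "red", lwd = 2,
       xlab = "distance d (m)", ylab = "L(d)", ylim = ylim, main = main, ...)
  graphics::abline(h = 0, col = "grey")
  if (!is.null(x$env_low)) {
    graphics::lines(x$d, x$env_low, lty = 3)
    graphics::lines(x$d, x$env_high, lty = 3)
  }
  invisible(x)
}

#' Univariate Ripley's K and Besag's L functions
#'
#' Estimates Ripley's K on a circular plot as
#' \deqn{K(d) = A \sum_{i \ne j} 1[d_{ij} \le d] / n^2,}
#' the plain pair-count estimator without edge-correction weights; its
#' variance-stabilized Besag transform \eqn{L(d) = \sqrt{K(d)/\pi} - d} is
#' returned alongside. Inference against a null model remains valid without
#' an edge correction because the identical statistic is applied to the data
#' and to every simulated null pattern; an isotropic correction for the
#' circular window is available via `correction = "isotropic"`.
#'
#' @param pattern A [point_pattern()].
#' @param d_max Largest distance evaluated (m). Defaults to the window
#'   radius, i.e. half the plot diameter, which limits edge effects.
#' @param step Grid step (m); distances are `seq(step, d_max, by = step)`.
#' @param correction `"none"` (default, the plain estimator) or
#'   `"isotropic"`.
#' @return A `kfun` object with per-distance `d`, `K`, `L`. If the pattern
#'   has fewer than 2 points, K is identically zero and the `degenerate`
#'   flag is set (a warning is emitted, not an error, so batch runs over
#'   sparse classes proceed).
#' @examples
#' w <- stand_window(40)
#' p <- point_pattern(c(0, 3, 0), c(0, 0, 4), w)
#' ripley_K(p, d_max = 5)$K[4] # pairs at 3,4,4 within 4 m
#' @seealso [csr_envelope()], [bivariate_K12()]
#' @export
ripley_K <- function(pattern, d_max = pattern$window$radius, step = 1,
                     correction = c("none", "isotropic")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "ppattern"), d_max > 0, step > 0)
  if (d_max > pattern$window$radius + 1e-9)
    stop("d_max must not exceed the window radius (half the plot diameter)")
  grid <- seq(step, d_max, by = step)
  n <- pattern$n
  if (n <= 1) {
    warning("pattern has fewer than 2 points; K(d) is identically 0")
    K <- rep(0, length(grid))
    return(kfun_result(grid, K, besag_L(K, grid), "univariate", n,
                       degenerate = TRUE))
  }
  A <- pattern$window$area
  if (correction == "none") {
    dv <- as.numeric(stats::dist(cbind(pattern$x, pattern$y)))
    cnt <- 2 * count_pairs_leq(dv, rep(1, length(dv)), grid)
  } else {
    dm <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
    rho <- sqrt((pattern$x - pattern$window$center[1])^2 +
                (pattern$y - pattern$window$center[2])^2)
    ii <- row(dm)[upper.tri(dm) | lower.tri(dm)]
    dd <- dm[upper.tri(dm) | lower.tri(dm)]
    wts <- 1 / disc_boundary_fraction(rho[ii], dd, pattern$window$radius)
    cnt <- count_pairs_leq(dd, wts, grid)
  }
  K <- A * cnt / n^2
  kfun_result(grid, K, besag_L(K, grid), "univariate", n)
}

#' Besag's variance-stabilizing L transform
#'
#' \eqn{L(d) = \sqrt{K(d)/\pi} - d}; zero for all d under complete spatial
#' randomness.
#'
#' @param K Nonnegative per-distance K values.
#' @param d Matching distances.
#' @return Per-distance L values.
#' @examples
#' besag_L(pi * (1:5)^2, 1:5) # CSR identity: all zero
#' @export
besag_L <- function(K, d) {
  stopifnot(length(K) == length(d))
  if (any(K < 0)) stop("K must be nonnegative")
  sqrt(K / pi) - d
}

# Pointwise quantile envelope over a matrix of simulated L curves
# (rows = sims), plus the three-way classification of the observed curve.
envelope_classify <- function(L_obs, L_sims, level, above, below, inside) {
  alpha <- (1 - level) / 2
  lo <- apply(L_sims, 2, stats::quantile, probs = alpha, names = FALSE)
  hi <- apply(L_sims, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  cls <- ifelse(L_obs > hi, above, ifelse(L_obs < lo, below, inside))
  list(low = lo, high = hi, classification = cls)
}

#' Monte Carlo CSR envelope for the univariate L function
#'
#' Simulates `n_sims` complete-spatial-randomness (homogeneous Poisson,
#' conditioned on the observed n) patterns in the same window, computes L(d)
#' for each with the identical estimator, and forms the pointwise empirical
#' quantile envelope at the requested confidence level. Observed L above the
#' envelope indicates significant clustering, below indicates a regular
#' (inhibited) pattern, inside indicates randomness.
#'
#' The envelope uses empirical quantiles at \eqn{(1 \pm level)/2}, not the
#' simulation min/max: with the conventional 99 simulations, min/max would
#' give a 2\% pointwise test rather than the nominal 5\%.
#'
#' @inheritParams ripley_K
#' @param n_sims Number of null simulations (default 99).
#' @param level Confidence level of the pointwise envelope (default 0.95).
#' @param seed Optional integer seed for the simulation stream.
#' @return A `kfun` object with `env_low`, `env_high` and a per-distance
#'   `classification` in `{clustered, random, regular}`.
#' @export
csr_envelope <- function(pattern, n_sims = 99, level = 0.95,
                         d_max = pattern$window$radius, step = 1,
                         seed = NULL, correction = c("none", "isotropic")) {
  correction <- match.arg(correction)
  stopifnot(n_sims >= 19, level > 0, level < 1)
  obs <- ripley_K(pattern, d_max = d_max, step = step, correction = correction)
  if (obs$degenerate) return(obs)
  n <- pattern$n
  L_sims <- with_seed(seed, {
    t(vapply(seq_len(n_sims), function(i) {
      u <- runif_disc(n, pattern$window)
      p <- point_pattern(u$x, u$y, pattern$window)
      ripley_K(p, d_max = d_max, step = step, correction = correction)$L
    }, numeric(length(obs$d))))
  })
  env <- envelope_classify(obs$L, L_sims, level,
                           "clustered", "regular", "random")
  kfun_result(obs$d, obs$K, obs$L, "univariate", n, n_sims = n_sims,
              env_low = env$low, env_high = env$high,
              classification = env$classification)
}

# Cross K-hat between two coordinate sets: A * (# pairs i in 1, j in 2 with
# d_ij <= d) / (n1 * n2), with optional isotropic weights centred on set 1.
cross_K_hat <- function(x1, y1, x2, y2, window, grid, correction) {
  n1 <- length(x1); n2 <- length(x2)
  dx <- outer(x1, x2, "-"); dy <- outer(y1, y2, "-")
  dd <- sqrt(dx^2 + dy^2)
  if (correction == "none") {
    wts <- rep(1, length(dd))
  } else {
    rho <- sqrt((x1 - window$center[1])^2 + (y1 - window$center[2])^2)
    wts <- 1 / disc_boundary_fraction(rho[row(dd)], as.numeric(dd),
                                      window$radius)
  }
  cnt <- count_pairs_leq(as.numeric(dd), wts, grid)
  window$area * cnt / (n1 * n2)
}

#' Bivariate (cross-type) Ripley's K12 and L12
#'
#' Cross K between two marked sub-patterns, combined symmetrically as
#' \deqn{K_{12}(d) = \frac{n_2 \hat K_{12}(d) + n_1 \hat K_{21}(d)}{n_1 + n_2},}
#' where \eqn{\hat K_{12}} counts class-2 neighbours of class-1 points with
#' denominator \eqn{n_1 n_2} (same estimator shape as the univariate K), and
#' \eqn{\hat K_{21}} swaps the roles. \eqn{L_{12}(d) = \sqrt{K_{12}(d)/\pi} - d}.
#' The combination is exactly symmetric in the two classes.
#'
#' @inheritParams ripley_K
#' @param class1,class2 Mark labels of the two sub-patterns.
#' @return A `kfun` object (`type = "bivariate"`, `n = c(n1, n2)`).
#' @export
bivariate_K12 <- function(pattern, class1, class2,
                          d_max = pattern$window$radius, step = 1,
                          correction = c("none", "isotropic")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "ppattern"))
  if (is.null(pattern$marks)) stop("pattern has no marks")
  for (cl in c(class1, class2))
    if (!any(pattern$marks == cl))
      stop("no points with mark '", cl, "'")
  if (d_max > pattern$window$radius + 1e-9)
    stop("d_max must not exceed the window radius")
  grid <- seq(step, d_max, by = step)
  i1 <- pattern$marks == class1
  i2 <- pattern$marks == class2
  n1 <- sum(i1); n2 <- sum(i2)
  K12h <- cross_K_hat(pattern$x[i1], pattern$y[i1],
                      pattern$x[i2], pattern$y[i2],
                      pattern$window, grid, correction)
  K21h <- cross_K_hat(pattern$x[i2], pattern$y[i2],
                      pattern$x[i1], pattern$y[i1],
                      pattern$window, grid, correction)
  K12 <- (n2 * K12h + n1 * K21h) / (n1 + n2)
  kfun_result(grid, K12, besag_L(K12, grid), "bivariate", c(n1, n2),
              labels = c(class1, class2))
}

#' Null envelope for bivariate association on a circular plot
#'
#' Tests spatial independence of two marked sub-patterns. Each null
#' realization keeps both classes' internal structure intact and randomizes
#' only their relative placement: class-2 points are rigidly rotated about
#' the plot centre by a uniform random angle, with an optional mirror
#' reflection. On a disc this plays the role the toroidal shift plays on a
#' rectangle (which is undefined on a circular window): the within-class
#' second-order structure and the window are preserved exactly.
#'
#' Observed L12 above the pointwise quantile envelope indicates attraction,
#' below indicates repulsion, inside indicates independence.
#'
#' @inheritParams bivariate_K12
#' @param n_sims Number of null rotations (default 99).
#' @param level Envelope confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @param mirror Include a random mirror reflection in the null (default
#'   TRUE).
#' @return A `kfun` object with envelope and per-distance classification in
#'   `{attraction, independent, repulsion}`.
#' @export
bivariate_null_envelope <- function(pattern, class1, class2, n_sims = 99,
                                    level = 0.95,
                                    d_max = pattern$window$radius, step = 1,
                                    seed = NULL, mirror = TRUE,
                                    correction = c("none", "isotropic")) {
  correction <- match.arg(correction)
  stopifnot(n_sims >= 19, level > 0, level < 1)
  obs <- bivariate_K12(pattern, class1, class2, d_max = d_max, step = step,
                       correction = correction)
  i1 <- pattern$marks == class1
  i2 <- pattern$marks == class2
  cx <- pattern$window$center[1]; cy <- pattern$window$center[2]
  x2 <- pattern$x[i2] - cx; y2 <- pattern$y[i2] - cy
  n1 <- sum(i1); n2 <- sum(i2)
  grid <- obs$d
  L_sims <- with_seed(seed, {
    t(vapply(seq_len(n_sims), function(s) {
      th <- stats::runif(1, 0, 2 * pi)
      yy <- if (mirror && stats::runif(1) < 0.5) -y2 else y2
      xr <- x2 * cos(th) - yy * sin(th) + cx
      yr <- x2 * sin(th) + yy * cos(th) + cy
      K12h <- cross_K_hat(pattern$x[i1], pattern$y[i1], xr, yr,
                          pattern$window, grid, correction)
      K21h <- cross_K_hat(xr, yr, pattern$x[i1], pattern$y[i1],
                          pattern$window, grid, correction)
      besag_L((n2 * K12h + n1 * K21h) / (n1 + n2), grid)
    }, numeric(length(grid))))
  })
  env <- envelope_classify(obs$L, L_sims, level,
                           "attraction", "repulsion", "independent")
  kfun_result(grid, obs$K, obs$L, "bivariate", c(n1, n2), n_sims = n_sims,
              env_low = env$low, env_high = env$high,
              classification = env$classification,
              labels = c(class1, class2))
}
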