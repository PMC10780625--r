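# Ring series -------------------------------------------------------------

#' A measured ring-width series
#'
#' One core's ring widths (mm, 0.01 mm resolution) on a contiguous run of
#' calendar years, with provenance and pith information.
#'
#' @param tree,core Tree and core identifiers.
#' @param first_year Calendar year of the innermost measured ring.
#' @param widths Strictly positive ring widths (mm), innermost first.
#' @param pith_reached Logical: does the core include the pith?
#' @param pith_offset_rings Estimated number of rings missing between the
#'   innermost measured ring and the pith (0 when the pith was reached).
#' @param coring_height Height of extraction (m), informational.
#' @return An object of class `ring_series`.
#' @examples
#' s <- ring_series("T1", "T1A", 1990, c(1.2, 1.1, 0.9))
#' series_years(s)
#' @export
ring_series <- function(tree, core, first_year, widths,
                        pith_reached = FALSE, pith_offset_rings = 0L,
                        coring_height = 1.3) {
  widths <- as.numeric(widths)
  if (length(widths) < 1) stop("series must contain at least one ring")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("ring widths must be strictly positive")
  if (pith_offset_rings < 0) stop("pith_offset_rings must be >= 0")
  structure(list(tree = as.character(tree), core = as.character(core),
                 first_year = as.integer(first_year), widths = widths,
                 pith_reached = isTRUE(pith_reached),
                 pith_offset_rings = as.integer(pith_offset_rings),
                 coring_height = coring_height),
            class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("Ring series %s (tree %s): %d rings, %d-%d, mean %.3f mm%s\n",
              x$core, x$tree, length(x$widths), x$first_year,
              x$first_year + length(x$widths) - 1L, mean(x$widths),
              if (x$pith_reached) ", pith" else
                sprintf(", pith offset %d", x$pith_offset_rings)))
  invisible(x)
}

#' Calendar years spanned by a series
#' @param x A `ring_series` or `ring_index`.
#' @return Integer vector of years, innermost ring first.
#' @export
series_years <- function(x) {
  x$first_year + seq_along(x$widths %||% x$index) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cambial age of each ring (1 = first ring at the pith), using the
# estimated pith offset for cores that missed the pith.
cambial_ages <- function(x) x$pith_offset_rings + seq_along(x$widths %||% x$index)

#' Average the cores of each tree into one tree-level series
#'
#' Ring widths of all cores of a tree are averaged year by year over the
#' union of their spans. The merged series keeps the smallest pith offset
#' among the cores and is flagged `pith_reached` if any core reached it.
#'
#' @param series List of [ring_series()].
#' @return List of tree-level `ring_series`, one per tree id.
#' @export
merge_cores <- function(series) {
  by_tree <- split(series, vapply(series, `[[`, "", "tree"))
  lapply(by_tree, function(ss) {
    yrs <- range(unlist(lapply(ss, series_years)))
    yy <- yrs[1]:yrs[2]
    acc <- matrix(NA_real_, length(ss), length(yy))
    for (i in seq_along(ss))
      acc[i, match(series_years(ss[[i]]), yy)] <- ss[[i]]$widths
    w <- colMeans(acc, na.rm = TRUE)
    keep <- !is.nan(w)
    ring_series(tree = ss[[1]]$tree, core = ss[[1]]$tree,
                first_year = yy[which(keep)[1]],
                widths = w[keep],
                pith_reached = any(vapply(ss, `[[`, TRUE, "pith_reached")),
                pith_offset_rings = min(vapply(ss, `[[`, 0L,
                                               "pith_offset_rings")))
  })
}

# Descriptive statistics ---------------------------------------------------

#' Mean sensitivity of a series
#'
#' The classical year-to-year variability statistic
#' \deqn{MS = \mathrm{mean}_t\, 2 |x_{t+1} - x_t| / (x_{t+1} + x_t),}
#' bounded in \[0, 2\]; 0 for a constant series, approaching 2 only when
#' consecutive values alternate towards zero.
#'
#' @param x Strictly positive widths or indices, in time order.
#' @return Mean sensitivity in \[0, 2\].
#' @examples
#' mean_sensitivity(c(1, 3, 1)) # 1
#' @export
mean_sensitivity <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 values")
  if (any(!is.finite(x)) || any(x <= 0)) stop("values must be positive")
  mean(2 * abs(diff(x)) / (x[-1] + x[-length(x)]))
}

#' First-order autocorrelation
#'
#' Pearson correlation between the series and itself lagged by one year,
#' the persistence statistic reported for raw and standardized
#' chronologies.
#'
#' @param x Numeric series, length at least 3.
#' @return Correlation in \[-1, 1\].
#' @export
first_order_autocorrelation <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3) stop("need at least 3 values")
  if (stats::sd(x[-1]) == 0 || stats::sd(x[-length(x)]) == 0)
    stop("zero variance: AC1 undefined")
  stats::cor(x[-length(x)], x[-1])
}

#' Coefficient of variation (percent)
#'
#' `coefficient_of_variation()` computes \eqn{100\, s / \bar x} from data
#' (sample sd); `cv_percent()` computes it from an already known mean and
#' sd, as when summarizing published group statistics.
#'
#' @param x Numeric values with positive mean.
#' @param mean,sd Group mean and standard deviation.
#' @return CV in percent.
#' @examples
#' cv_percent(12.56, 6.61) # 52.6 to one decimal
#' @export
coefficient_of_variation <- function(x) {
  m <- mean(x)
  if (m <= 0) stop("CV requires a positive mean")
  100 * stats::sd(x) / m
}

#' @rdname coefficient_of_variation
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean <= 0)) stop("CV requires a positive mean")
  100 * sd / mean
}

# Cross-dating screen ------------------------------------------------------

#' Correlation of a series with a master chronology
#'
#' Pearson correlation over the overlapping years, used to screen poorly
#' synchronized or undatable cores: a series correlating below `threshold`
#' (default 0.40) with the master is flagged for discard. With
#' `transform = "logdiff"` both series are first-differenced on the log
#' scale, emphasizing the high-frequency (climate-synchronous) signal the
#' way cross-dating programs do.
#'
#' @param series A [ring_series()] or a named numeric vector (names =
#'   years).
#' @param master Named numeric vector: master values by year.
#' @param min_overlap Minimum number of overlapping years (default 15);
#'   fewer makes the series `undatable`.
#' @param threshold Keep/discard correlation threshold.
#' @param transform `"none"` or `"logdiff"`.
#' @return List with `r`, `n_overlap`, `keep` (logical) and `undatable`
#'   (logical; `r` is `NA` then).
#' @export
correlation_with_master <- function(series, master, min_overlap = 15,
                                    threshold = 0.40,
                                    transform = c("none", "logdiff")) {
  transform <- match.arg(transform)
  if (inherits(series, "ring_series"))
    series <- stats::setNames(series$widths, series_years(series))
  yrs <- intersect(names(series), names(master))
  n_overlap <- length(yrs)  # overlap measured in years, before differencing
  if (n_overlap < min_overlap)
    return(list(r = NA_real_, n_overlap = n_overlap, keep = FALSE,
                undatable = TRUE))
  x <- as.numeric(series[yrs]); y <- as.numeric(master[yrs])
  if (transform == "logdiff") {
    # difference only across consecutive years
    yy <- as.integer(yrs)
    cons <- which(diff(yy) == 1L)
    x <- diff(log(x))[cons]; y <- diff(log(y))[cons]
  }
  r <- stats::cor(x, y)
  list(r = r, n_overlap = n_overlap, keep = r >= threshold,
       undatable = FALSE)
}

#' Screen a set of cores against their master
#'
#' Builds a mean-value master from all cores, correlates each core with
#' the master built from the remaining cores (leave-one-out), and flags
#' cores below the threshold or with insufficient overlap.
#'
#' @param series List of [ring_series()].
#' @inheritParams correlation_with_master
#' @return data.frame with columns `core`, `tree`, `r`, `n_overlap`,
#'   `keep`, `undatable`.
#' @export
crossdating_screen <- function(series, min_overlap = 15, threshold = 0.40,
                               transform = "logdiff") {
  yrs <- range(unlist(lapply(series, series_years)))
  yy <- yrs[1]:yrs[2]
  mat <- matrix(NA_real_, length(series), length(yy))
  for (i in seq_along(series))
    mat[i, match(series_years(series[[i]]), yy)] <- series[[i]]$widths
  res <- lapply(seq_along(series), function(i) {
    m <- colMeans(mat[-i, , drop = FALSE], na.rm = TRUE)
    ok <- is.finite(m)
    cw <- correlation_with_master(
      series[[i]], stats::setNames(m[ok], yy[ok]),
      min_overlap = min_overlap, threshold = threshold,
      transform = transform)
    data.frame(core = series[[i]]$core, tree = series[[i]]$tree,
               r = cw$r, n_overlap = cw$n_overlap, keep = cw$keep,
               undatable = cw$undatable, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Age estimation -----------------------------------------------------------

#' Missing rings at the pith from innermost-ring curvature
#'
#' The pith-locator geometry: an arc of the innermost measured ring with
#' chord \eqn{L} and sagitta \eqn{h} lies on a circle of radius
#' \eqn{\hat r = L^2/(8h) + h/2} centred at the pith. The number of rings
#' missing inward of the innermost measured ring is \eqn{\hat r} divided
#' by the mean width of the innermost `inner_widths`, rounded to the
#' nearest integer.
#'
#' @param chord Arc chord length (mm).
#' @param sagitta Arc height (mm); must be positive.
#' @param inner_widths Widths (mm) of the innermost measured rings used to
#'   extrapolate inward.
#' @return List with `radius_mm` (\eqn{\hat r}) and `missing_rings`.
#' @examples
#' estimate_pith_offset(8, 1, inner_widths = 1) # radius 8.5
#' @export
estimate_pith_offset <- function(chord, sagitta, inner_widths) {
  if (sagitta <= 0) stop("sagitta must be positive")
  if (chord <= 0) stop("chord must be positive")
  if (any(inner_widths <= 0)) stop("inner widths must be positive")
  r_hat <- chord^2 / (8 * sagitta) + sagitta / 2
  list(radius_mm = r_hat,
       missing_rings = max(0L, as.integer(round(r_hat / mean(inner_widths)))))
}

#' Regression correction for years-to-coring-height
#'
#' Trees need several years to reach coring height, so the ring count at
#' breast height underestimates tree age. From a subsample of trees cored
#' both near the ground and at breast height, the difference in ring count
#' is regressed (OLS) on the age at breast height; the fitted line then
#' predicts the number of years to add to every tree, rounded and clamped
#' at zero.
#'
#' @param age_at_dbh Ages (ring counts) at coring height.
#' @param ring_diff Ground-minus-breast-height ring-count differences.
#' @return An object of class `age_model` (stores the `lm` fit).
#' @examples
#' m <- fit_age_correction(c(10, 50, 130), 16 - 0.1 * c(10, 50, 130))
#' predict(m, c(10, 130)) # 15 and 3
#' @export
fit_age_correction <- function(age_at_dbh, ring_diff) {
  stopifnot(length(age_at_dbh) == length(ring_diff))
  if (length(age_at_dbh) < 3) stop("need at least 3 trees")
  if (stats::sd(age_at_dbh) == 0)
    stop("degenerate design: all ages equal")
  fit <- stats::lm(ring_diff ~ age_at_dbh)
  structure(list(fit = fit, coefficients = stats::coef(fit)),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("Years-to-coring-height model: diff = %.3f %+.4f * age\n",
              x$coefficients[1], x$coefficients[2]))
  invisible(x)
}

#' @param object An `age_model`.
#' @param newdata Ages at coring height to predict for.
#' @param ... Unused.
#' @return Integer years to add (rounded, never negative).
#' @rdname fit_age_correction
#' @export
predict.age_model <- function(object, newdata, ...) {
  p <- stats::predict(object$fit,
                      data.frame(age_at_dbh = as.numeric(newdata)))
  as.integer(pmax(0, round(unname(p))))
}

#' Assign the chronological age class
#'
#' Young (Y) up to 40 years, mature (M) 41 to 80 years, old (O) above 80.
#' Plants below the adult size threshold count as established regeneration
#' (ER) only from 3 years of age; younger plantlets get `NA`.
#'
#' @param age Corrected tree age(s), years.
#' @param adult Logical (recycled): adult tree (cored at breast height) or
#'   regeneration-sized plant.
#' @return Character vector in `{Y, M, O, ER, NA}`.
#' @examples
#' assign_age_class(c(40, 41, 80, 81)) # Y M M O
#' @export
assign_age_class <- function(age, adult = TRUE) {
  stopifnot(all(age >= 0))
  adult <- rep_len(adult, length(age))
  out <- ifelse(adult,
                ifelse(age <= 40, "Y", ifelse(age <= 80, "M", "O")),
                ifelse(age >= 3, "ER", NA_character_))
  as.character(out)
}

#' Age structure histogram
#'
#' Counts of trees per fixed-width age bin, labelled by the bin midpoint.
#'
#' @param ages Corrected tree ages.
#' @param bin_width Bin width in years (default 5).
#' @return data.frame with `midpoint` and `count`; bins partition
#'   `(0, max]` so the total count is preserved.
#' @export
age_structure <- function(ages, bin_width = 5) {
  stopifnot(all(ages > 0))
  top <- ceiling(max(ages) / bin_width) * bin_width
  breaks <- seq(0, top, by = bin_width)
  cnt <- table(cut(ages, breaks = breaks, include.lowest = FALSE))
  data.frame(midpoint = breaks[-length(breaks)] + bin_width / 2,
             count = as.integer(cnt))
}

# Biometric screen ---------------------------------------------------------

#' Screen trees for regular growth before chronology building
#'
#' Within 10-year age groups, a tree is retained only if at least two of
#' the three biometric parameters (DBH, H, CW) exceed the group mean minus
#' one standard deviation, and its ring count is strictly greater than
#' `min_rings`. Groups with a single tree have no defined sd; such trees
#' pass the biometric part by default and are flagged.
#'
#' @param trees data.frame with columns `id`, `age`, `dbh_cm`, `h_m` and
#'   `cw_m2` (crown projection area).
#' @param ring_counts Named integer vector: measured rings per tree id
#'   (longest core).
#' @param min_rings Strict lower bound on ring count (default 20: a tree
#'   with exactly 20 rings is discarded).
#' @param bin_width Age-group width in years (default 10).
#' @return data.frame with per-tree pass flags, the number of biometric
#'   criteria passed, `keep`, and `sd_undefined` for singleton groups.
#' @export
biometric_screen <- function(trees, ring_counts, min_rings = 20,
                             bin_width = 10) {
  need <- c("id", "age", "dbh_cm", "h_m", "cw_m2")
  if (!all(need %in% names(trees)))
    stop("trees must have columns ", paste(need, collapse = ", "))
  bins <- ceiling(trees$age / bin_width)
  pass <- matrix(FALSE, nrow(trees), 3,
                 dimnames = list(NULL, c("dbh", "h", "cw")))
  sd_undef <- logical(nrow(trees))
  for (b in unique(bins)) {
    i <- which(bins == b)
    for (j in 1:3) {
      v <- trees[[c("dbh_cm", "h_m", "cw_m2")[j]]][i]
      if (length(i) < 2) {
        pass[i, j] <- TRUE
        sd_undef[i] <- TRUE
      } else {
        pass[i, j] <- v > mean(v) - stats::sd(v)
      }
    }
  }
  rings <- as.integer(ring_counts[trees$id])
  n_pass <- rowSums(pass)
  data.frame(id = trees$id, age = trees$age,
             pass_dbh = pass[, 1], pass_h = pass[, 2], pass_cw = pass[, 3],
             n_biometric = n_pass, rings = rings,
             sd_undefined = sd_undef,
             keep = n_pass >= 2 & !is.na(rings) & rings > min_rings,
             stringsAsFactors = FALSE)
}

# Detrending ---------------------------------------------------------------

# Discrete cubic smoothing spline (second-difference penalty) with the
# smoothing parameter set from its frequency response: the filter
# H(f) = 1 / (1 + lambda (2 sin pi f)^4) attains `response` (default 50%)
# at wavelength `wl` years.
smooth_spline_fr <- function(y, wl, response = 0.5) {
  n <- length(y)
  if (wl <= 2 || n < 4) return(rep(mean(y), n))
  lambda <- (1 / response - 1) / (2 * sin(pi / wl))^4
  D <- diff(diag(n), differences = 2)
  g <- solve(diag(n) + lambda * crossprod(D), y)
  as.numeric(g)
}

fit_negexp <- function(w) {
  t <- seq_along(w)
  k0 <- max(min(w) * 0.9, 1e-3)
  a0 <- max(w[1] - k0, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(w ~ a * exp(-b * t) + k,
                      start = list(a = a0, b = 0.05, k = k0),
                      lower = c(a = 1e-8, b = 1e-8, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  g <- as.numeric(stats::fitted(fit))
  if (any(g <= 0) || g[length(g)] > g[1]) return(NULL)  # nondecreasing/invalid
  g
}

#' Regional curve for RCS standardization
#'
#' Aligns all series of a cohort by cambial age (using the estimated pith
#' offsets), averages the widths at each cambial age, and smooths the
#' resulting curve with a spline whose 50% frequency-response cutoff is
#' `smooth_frac` of the maximum cambial age — the smoothing prevents noise
#' amplification where the sample depth is low.
#'
#' @param series List of [ring_series()].
#' @param smooth_frac Cutoff wavelength as a fraction of the maximum
#'   cambial age (default 0.10).
#' @return An object of class `rcs_curve`: `cambial_age`, `curve` (mm),
#'   `depth` (series per cambial age).
#' @export
rcs_curve <- function(series, smooth_frac = 0.10) {
  amax <- max(vapply(series, function(s) max(cambial_ages(s)), numeric(1)))
  acc <- matrix(NA_real_, length(series), amax)
  for (i in seq_along(series))
    acc[i, cambial_ages(series[[i]])] <- series[[i]]$widths
  depth <- colSums(!is.na(acc))
  m <- colMeans(acc, na.rm = TRUE)
  sup <- which(depth > 0)
  m[-sup] <- NA
  # fill interior gaps by interpolation before smoothing
  filled <- stats::approx(sup, m[sup], xout = min(sup):max(sup))$y
  sm <- smooth_spline_fr(filled, wl = max(3, smooth_frac * amax))
  curve <- rep(NA_real_, amax)
  curve[min(sup):max(sup)] <- pmax(sm, 1e-6)
  structure(list(cambial_age = seq_len(amax), curve = curve, depth = depth),
            class = "rcs_curve")
}

#' Detrend a ring-width series to a dimensionless index
#'
#' Divides the widths by a fitted growth curve:
#' \describe{
#'   \item{spline}{a cubic smoothing spline with 50% frequency response at
#'     `stiffness` times the series length (default 0.67), the
#'     conventional conservative dendro choice;}
#'   \item{negexp}{the modified negative exponential
#'     \eqn{a e^{-bt} + k}, \eqn{a, b > 0, k \ge 0}, falling back to the
#'     horizontal mean line when the fit fails or is not a decreasing
#'     positive curve;}
#'   \item{rcs}{division by a shared regional curve at the ring's cambial
#'     age ([rcs_curve()]), which preserves common low-frequency signal;
#'     ages beyond the curve's support use its last supported value;}
#'   \item{mean}{the horizontal mean line.}
#' }
#'
#' @param series A [ring_series()].
#' @param method One of `"spline"`, `"negexp"`, `"rcs"`, `"mean"`.
#' @param stiffness Spline cutoff as a fraction of series length (> 0).
#' @param rc An [rcs_curve()]; required for `method = "rcs"`.
#' @return An object of class `ring_index`: `tree`, `core`, `first_year`,
#'   `index`, `fit` (the fitted curve, mm), `method`.
#' @export
detrend <- function(series, method = c("spline", "negexp", "rcs", "mean"),
                    stiffness = 0.67, rc = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(series, "ring_series"))
  w <- series$widths
  n <- length(w)
  if (method %in% c("spline", "negexp") && n < 10)
    stop("series too short (< 10 rings) for ", method, " detrending")
  fitv <- switch(method,
    spline = {
      if (stiffness <= 0) stop("spline stiffness must be > 0")
      g <- smooth_spline_fr(w, wl = stiffness * n)
      if (any(g <= 0)) rep(mean(w), n) else g
    },
    negexp = {
      g <- fit_negexp(w)
      if (is.null(g)) rep(mean(w), n) else g
    },
    rcs = {
      if (is.null(rc)) stop("rcs detrending needs a regional curve (rc)")
      ca <- cambial_ages(series)
      sup <- which(!is.na(rc$curve))
      idx <- pmin(pmax(ca, min(sup)), max(sup))
      rc$curve[idx]
    },
    mean = rep(mean(w), n))
  structure(list(tree = series$tree, core = series$core,
                 first_year = series$first_year,
                 index = w / fitv, fit = fitv, method = method),
            class = "ring_index")
}

#' @export
print.ring_index <- function(x, ...) {
  cat(sprintf("Ring index %s (%s detrending): %d years, %d-%d, mean %.3f\n",
              x$core, x$method, length(x$index), x$first_year,
              x$first_year + length(x$index) - 1L, mean(x$index)))
  invisible(x)
}

# Chronology ---------------------------------------------------------------

tukey_biweight_mean <- function(x, c = 9) {
  x <- x[is.finite(x)]
  if (length(x) == 1) return(x)
  med <- stats::median(x)
  s <- stats::median(abs(x - med))
  if (s == 0) return(med)
  u <- (x - med) / (c * s)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(med)
  sum(w * x) / sum(w)
}

#' Build a master chronology from detrended series
#'
#' Aggregates per-year indices across series (arithmetic mean by default,
#' Tukey's biweight robust mean optionally) and computes the standard
#' descriptive statistics: mean sensitivity of the master (MSm) and the
#' average over individual series (MSi), mean pairwise inter-series
#' correlation (CC, over overlaps of at least `min_overlap` years), mean
#' correlation of each series with the master (CM), and the first-order
#' autocorrelation of the standardized master (`ac1_std`) and, when the
#' raw series are supplied, of the raw-width master (`ac1_raw`).
#'
#' @param indices List of [detrend()] results (`ring_index`).
#' @param raw Optional list of the matching raw [ring_series()], used only
#'   for the raw-master statistics (MRW, `ac1_raw`).
#' @param aggregate `"mean"` or `"biweight"`.
#' @param label Age-class label carried in the result.
#' @param min_overlap Minimum pairwise overlap for CC (default 20 years).
#' @return An object of class `chronology`: `years`, `index`, `depth`,
#'   `stats` (list), `label`.
#' @export
build_chronology <- function(indices, raw = NULL,
                             aggregate = c("mean", "biweight"),
                             label = NA_character_, min_overlap = 20) {
  aggregate <- match.arg(aggregate)
  if (length(indices) < 1) stop("no series supplied")
  yrs <- range(unlist(lapply(indices, series_years)))
  yy <- yrs[1]:yrs[2]
  mat <- matrix(NA_real_, length(indices), length(yy))
  for (i in seq_along(indices))
    mat[i, match(series_years(indices[[i]]), yy)] <- indices[[i]]$index
  depth <- colSums(!is.na(mat))
  master <- apply(mat, 2, if (aggregate == "mean")
    function(v) mean(v, na.rm = TRUE) else
    function(v) tukey_biweight_mean(v))
  ok <- depth >= 1

  # inter-series correlation over pairwise overlaps
  cc <- NULL
  if (length(indices) >= 2) {
    pr <- c()
    for (i in seq_len(length(indices) - 1))
      for (j in (i + 1):length(indices)) {
        both <- !is.na(mat[i, ]) & !is.na(mat[j, ])
        if (sum(both) >= min_overlap)
          pr <- c(pr, stats::cor(mat[i, both], mat[j, both]))
      }
    cc <- if (length(pr)) mean(pr) else NA_real_
  }
  cm <- mean(vapply(seq_along(indices), function(i) {
    both <- !is.na(mat[i, ])
    stats::cor(mat[i, both], master[both])
  }, numeric(1)))

  msm <- mean_sensitivity(master[ok])
  msi <- mean(vapply(indices, function(s) mean_sensitivity(s$index),
                     numeric(1)))
  ac1_std <- first_order_autocorrelation(master[ok])

  mrw <- NA_real_; ac1_raw <- NA_real_
  if (!is.null(raw)) {
    rmat <- matrix(NA_real_, length(raw), length(yy))
    for (i in seq_along(raw))
      rmat[i, match(series_years(raw[[i]]), yy)] <- raw[[i]]$widths
    rmaster <- colMeans(rmat, na.rm = TRUE)
    rok <- colSums(!is.na(rmat)) >= 1
    ac1_raw <- first_order_autocorrelation(rmaster[rok])
    mrw <- mean(vapply(raw, function(s) mean(s$widths), numeric(1)))
  }

  structure(list(years = yy[ok], index = master[ok], depth = depth[ok],
                 label = label,
                 n_series = length(indices),
                 stats = list(MRW = mrw, MSm = msm, MSi = msi, CC = cc,
                              CM = cm, AC1_raw = ac1_raw,
                              AC1_std = ac1_std)),
            class = "chronology")
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("Chronology%s: %d series, %d-%d (%d yr)\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$n_series, min(x$years), max(x$years), length(x$years)))
  s <- x$stats
  cat(sprintf("  MRW %.3f mm | MSm %.3f MSi %.3f | CC %.3f CM %.3f | AC1 raw %.3f std %.3f\n",
              s$MRW, s$MSm, s$MSi,
              if (is.null(s$CC)) NA else s$CC, s$CM, s$AC1_raw, s$AC1_std))
  invisible(x)
}

#' @export
plot.chronology <- function(x, ..., main = NULL) {
  if (is.null(main))
    main <- paste("Standardized chronology",
                  if (!is.na(x$label)) x$label else "")
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$years, x$index, type = "l", ylab = "index", xlab = "", main = main)
  graphics::abline(h = 1, col = "grey")
  plot(x$years, x$depth, type = "s", ylab = "sample depth", xlab = "year")
  invisible(x)
}

# Cumulative growth --------------------------------------------------------

#' Cumulative diameter inside bark
#'
#' Twice the running sum of ring widths against cambial age, the
#' cumulative-growth curve used to compare growth rates of cohorts at the
#' same cambial age (meaningful for cores that include the pith, or after
#' applying the pith offset).
#'
#' @param series A [ring_series()].
#' @param unit `"mm"` or `"cm"`.
#' @return data.frame with `cambial_age` and `dib` (strictly increasing).
#' @examples
#' s <- ring_series("t", "c", 1990, c(1, 1, 1), pith_reached = TRUE)
#' cumulative_dib(s)$dib # 2 4 6 mm
#' @export
cumulative_dib <- function(series, unit = c("mm", "cm")) {
  unit <- match.arg(unit)
  dib <- 2 * cumsum(series$widths)
  if (unit == "cm") dib <- dib / 10
  data.frame(cambial_age = cambial_ages(series), dib = dib)
}
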