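# Biological-year regressor design ----------------------------------------

month_abb3 <- c("jan", "feb", "mar", "apr", "may", "jun",
                "jul", "aug", "sep", "oct", "nov", "dec")

# Biological-year month sequence: October..December of year t-1 then
# January..September of year t.
bioyear_months <- function() {
  data.frame(month = c(10:12, 1:9),
             lag = c(rep(1L, 3), rep(0L, 9)))
}

#' Column names of the 24-regressor biological-year design
#'
#' Precipitation first (`p_oct_prev` ... `p_sep`), then the chosen
#' temperature (`t_oct_prev` ... `t_sep`); `_prev` marks months of the year
#' preceding growth.
#'
#' @param temperature `"tmax"` or `"tmin"` (names are identical; the
#'   argument documents which design is meant).
#' @return Character vector of length 24.
#' @export
regressor_names <- function(temperature = c("tmax", "tmin")) {
  temperature <- match.arg(temperature)
  bm <- bioyear_months()
  suff <- ifelse(bm$lag == 1L, "_prev", "")
  c(paste0("p_", month_abb3[bm$month], suff),
    paste0("t_", month_abb3[bm$month], suff))
}

validate_climate <- function(climate) {
  need <- c("year", "month", "p_mm", "tmax_c", "tmin_c")
  if (!is.data.frame(climate) || !all(need %in% names(climate)))
    stop("climate must be a data.frame with columns ",
         paste(need, collapse = ", "))
  invisible(climate)
}

#' Build the biological-year climate design matrix
#'
#' One row per growth year from `start_year` to `end_year`; 24 columns:
#' the 12 monthly precipitation totals and the 12 monthly maximum (or
#' minimum) temperatures of the biological year, i.e. October of the year
#' preceding growth through September of the growth year. The P-Tmax and
#' P-Tmin designs differ only in their temperature columns.
#'
#' @param climate Monthly climate data.frame (`year`, `month`, `p_mm`,
#'   `tmax_c`, `tmin_c`).
#' @param start_year,end_year First and last growth year.
#' @param temperature `"tmax"` or `"tmin"`.
#' @return Numeric matrix (years x 24) with growth years as rownames; an
#'   error lists any missing year/month cells.
#' @examples
#' cl <- generate_climate(climate_scenario(years = 1956:1998, seed = 1))
#' dim(build_regressor_matrix(cl, 1958, 1997)) # 40 x 24
#' @export
build_regressor_matrix <- function(climate, start_year, end_year,
                                   temperature = c("tmax", "tmin")) {
  temperature <- match.arg(temperature)
  validate_climate(climate)
  stopifnot(start_year <= end_year)
  bm <- bioyear_months()
  years <- start_year:end_year
  key <- paste(climate$year, climate$month)
  tcol <- if (temperature == "tmax") "tmax_c" else "tmin_c"
  X <- matrix(NA_real_, length(years), 24,
              dimnames = list(years, regressor_names(temperature)))
  missing_cells <- character(0)
  for (i in seq_along(years)) {
    yrs <- years[i] - bm$lag
    idx <- match(paste(yrs, bm$month), key)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))
      missing_cells <- c(missing_cells,
                         paste0(yrs[bad], "-", sprintf("%02d", bm$month[bad])))
      next
    }
    X[i, 1:12] <- climate$p_mm[idx]
    X[i, 13:24] <- climate[[tcol]][idx]
  }
  if (length(missing_cells))
    stop("climate is missing months: ",
         paste(unique(missing_cells), collapse = ", "))
  X
}

# Bootstrap orthogonalized response function -------------------------------

#' Significance band from the r/s ratio
#'
#' Maps the ratio of the mean verification correlation to its standard
#' deviation onto the reported significance bands: `|r/s| >= 1.96` gives
#' `"<0.05"`, `|r/s| >= 1.645` gives `"<0.1"`, anything smaller `"ns"`.
#'
#' @param r_over_s Finite numeric ratio.
#' @return `"<0.05"`, `"<0.1"` or `"ns"`.
#' @examples
#' pband_label(2.13); pband_label(1.85); pband_label(0.89)
#' @export
pband_label <- function(r_over_s) {
  if (!is.finite(r_over_s)) stop("r/s must be finite")
  a <- abs(r_over_s)
  if (a >= 1.96) "<0.05" else if (a >= 1.645) "<0.1" else "ns"
}

#' Bootstrap orthogonalized response function
#'
#' Regresses chronology indices on the 24 monthly climate regressors with
#' principal-component orthogonalization and bootstrap inference:
#'
#' 1. Regressors are standardized and decomposed into principal
#'    components; components with eigenvalue above the mean eigenvalue are
#'    retained (configurable via `n_components`).
#' 2. In each of `n_boot` replicates, calibration years are resampled with
#'    replacement; the indices are regressed (OLS) on the retained
#'    component scores of the calibration years; coefficients are rotated
#'    back to the standardized-regressor space; the years never drawn
#'    (out-of-bag) form the verification set, on which the Pearson
#'    correlation between predicted and observed indices is computed.
#'    Replicates with an empty verification set are redrawn.
#' 3. Per-regressor bootstrap means and sds give the significance flag
#'    `|mean/sd| >= 1.96`; the mean verification correlation `R_V`, its
#'    ratio to its standard deviation `r/s`, and the significance band
#'    summarize the overall climate-growth relationship.
#'
#' Because regressors are standardized internally, rescaling any regressor
#' by a positive constant changes neither the flags nor `R_V`.
#'
#' @param chron A [build_chronology()] result, or a named numeric vector
#'   of indices (names = years).
#' @param X Regressor matrix from [build_regressor_matrix()]; its rownames
#'   must exactly match the chronology years used.
#' @param n_boot Number of bootstrap replications (default 1000).
#' @param n_components `NULL` for the mean-eigenvalue retention rule, or a
#'   fixed component count.
#' @param pca `"fixed"` (default): the principal components are computed
#'   once from the full climate matrix and only the regression is
#'   bootstrapped, the classical orthogonalized-response-function design;
#'   `"resample"`: standardization, PCA and retention are recomputed
#'   inside every replicate, which widens the coefficient spread and damps
#'   the spurious flags that component truncation can otherwise induce on
#'   regressors without signal.
#' @param seed Optional integer seed.
#' @return An object of class `response_function` with `coef` (per-regressor
#'   data.frame: `mean_coef`, `sd`, `t`, `significant`), `R_V`, `r_over_s`,
#'   `p_band`, `n_components`, `n_boot`, `years`.
#' @export
bootstrap_response_function <- function(chron, X, n_boot = 1000,
                                        n_components = NULL,
                                        pca = c("fixed", "resample"),
                                        seed = NULL) {
  pca <- match.arg(pca)
  y <- if (inherits(chron, "chronology"))
    stats::setNames(chron$index, chron$years) else chron
  if (is.null(names(y))) stop("indices must be named by year")
  if (!identical(sort(names(y)), sort(rownames(X))))
    stop("years of indices and regressor matrix differ")
  y <- y[rownames(X)]
  n <- length(y)

  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate (constant) regressor: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Z <- scale(X)
  eig0 <- eigen(stats::cor(X), symmetric = TRUE)
  keep0 <- if (is.null(n_components))
    which(eig0$values > mean(eig0$values)) else seq_len(n_components)
  if (n <= length(keep0) + 1)
    stop("too few years for ", length(keep0), " retained components")

  V0 <- eig0$vectors[, keep0, drop = FALSE]
  coefs <- matrix(NA_real_, n_boot, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  rver <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        cal <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(cal))
        if (length(oob) >= 2) break
      }
      if (pca == "fixed") {
        Vb <- V0
      } else {
        Zc <- Z[cal, , drop = FALSE]
        if (any(apply(Zc, 2, stats::sd) == 0)) next  # degenerate resample
        eb <- eigen(stats::cor(Zc), symmetric = TRUE)
        kb <- if (is.null(n_components))
          which(eb$values > mean(eb$values)) else seq_len(n_components)
        Vb <- eb$vectors[, kb, drop = FALSE]
      }
      fit <- stats::lm.fit(cbind(1, Z[cal, , drop = FALSE] %*% Vb), y[cal])
      gam <- fit$coefficients
      pred <- cbind(1, Z[oob, , drop = FALSE] %*% Vb) %*% gam
      r <- suppressWarnings(stats::cor(pred, y[oob]))
      rver[b] <- if (is.finite(r)) r else 0
      coefs[b, ] <- as.numeric(Vb %*% gam[-1])
    }
    ok <- stats::complete.cases(coefs)
    coefs <- coefs[ok, , drop = FALSE]
    rver <- rver[ok]
  })
  mean_coef <- colMeans(coefs)
  sd_coef <- apply(coefs, 2, stats::sd)
  tstat <- mean_coef / sd_coef
  R_V <- mean(rver)
  r_over_s <- R_V / stats::sd(rver)
  structure(list(
    coef = data.frame(regressor = colnames(X), mean_coef = mean_coef,
                      sd = sd_coef, t = tstat,
                      significant = abs(tstat) >= 1.96,
                      row.names = NULL, stringsAsFactors = FALSE),
    R_V = R_V, r_over_s = r_over_s, p_band = pband_label(r_over_s),
    n_components = length(keep0), n_boot = n_boot,
    years = as.integer(rownames(X)),
    verification_r = rver),
    class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("Bootstrap response function: %d regressors, %d components, %d replications\n",
              nrow(x$coef), x$n_components, x$n_boot))
  cat(sprintf("  R_V = %.3f, r/s = %.2f (p %s)\n",
              x$R_V, x$r_over_s, x$p_band))
  sig <- x$coef[x$coef$significant, ]
  if (nrow(sig)) {
    cat("  significant regressors (|mean/sd| >= 1.96):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %-12s %+0.3f (sd %.3f)\n",
                  sig$regressor[i], sig$mean_coef[i], sig$sd[i]))
  } else cat("  no significant regressors\n")
  invisible(x)
}

#' @export
summary.response_function <- function(object, ...) {
  cat(sprintf("R_V %.3f | r/s %.2f | p %s | %d/%d regressors significant\n",
              object$R_V, object$r_over_s, object$p_band,
              sum(object$coef$significant), nrow(object$coef)))
  invisible(object$coef)
}

#' @export
plot.response_function <- function(x, ..., main = "Response function") {
  t <- x$coef$t
  bp <- graphics::barplot(x$coef$mean_coef, names.arg = x$coef$regressor,
                          las = 2, cex.names = 0.6, main = main,
                          col = ifelse(x$coef$significant, "firebrick",
                                       "grey80"),
                          ylab = "mean bootstrap coefficient")
  graphics::abline(h = 0)
  invisible(x)
}
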