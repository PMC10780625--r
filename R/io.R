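# Stem map -----------------------------------------------------------------

#' Crown projection area from four cardinal radii
#'
#' Quarter-ellipse approximation: the crown is treated as four quarter
#' ellipses spanned by adjacent cardinal radii, so
#' \deqn{CW = \frac{\pi}{4}(r_N r_E + r_E r_S + r_S r_W + r_W r_N),}
#' which reduces to \eqn{\pi r^2} when all radii are equal.
#'
#' @param r_n,r_e,r_s,r_w Crown radii (m) to the north, east, south, west.
#' @return Crown projection area (m2).
#' @export
crown_area <- function(r_n, r_e, r_s, r_w) {
  pi / 4 * (r_n * r_e + r_e * r_s + r_s * r_w + r_w * r_n)
}

#' Read a stem-map CSV
#'
#' Field convention: each tree is recorded in polar coordinates from the
#' plot centre, azimuth in degrees clockwise from north, so
#' \eqn{x = r \sin\theta}, \eqn{y = r \cos\theta}. Required columns:
#' `id`, `azimuth_deg`, `distance_m`; optional: `dbh_cm`, `h_m`, crown
#' radii `cr_n_m`, `cr_e_m`, `cr_s_m`, `cr_w_m`, `age`, `age_class`.
#'
#' @param path CSV file path.
#' @param window_radius Plot radius (m); a tree farther than this from the
#'   centre raises an error naming its id.
#' @return List with `trees` (data.frame augmented with `x`, `y`, `cw_m2`,
#'   `cr_m` where crown radii are present) and `pattern` (a marked
#'   [point_pattern()]; marks come from `age_class` if present).
#' @export
read_stem_map <- function(path, window_radius = 40) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "azimuth_deg", "distance_m")
  if (!all(need %in% names(tr)))
    stop("stem map must have columns ", paste(need, collapse = ", "))
  bad <- tr$distance_m > window_radius + 1e-9
  if (any(bad))
    stop("tree(s) outside window radius: ",
         paste(tr$id[bad], collapse = ", "))
  th <- tr$azimuth_deg * pi / 180
  tr$x <- tr$distance_m * sin(th)
  tr$y <- tr$distance_m * cos(th)
  rcols <- c("cr_n_m", "cr_e_m", "cr_s_m", "cr_w_m")
  if (all(rcols %in% names(tr))) {
    tr$cw_m2 <- crown_area(tr$cr_n_m, tr$cr_e_m, tr$cr_s_m, tr$cr_w_m)
    tr$cr_m <- rowMeans(tr[rcols])
  }
  marks <- if ("age_class" %in% names(tr)) tr$age_class else NULL
  list(trees = tr,
       pattern = point_pattern(tr$x, tr$y, stand_window(window_radius),
                               marks = marks))
}

#' Write a stem-map CSV
#'
#' Converts window-local Cartesian coordinates of a marked pattern back to
#' the polar field convention (azimuth clockwise from north, degrees) and
#' joins any per-tree attributes by id.
#'
#' @param pattern A marked [point_pattern()].
#' @param path Output CSV path.
#' @param trees Optional data.frame of per-tree attributes with an `id`
#'   column aligned with the pattern's point order, or `NULL`.
#' @param ids Tree ids (default `T001`, ...).
#' @return The written data.frame, invisibly.
#' @export
write_stem_map <- function(pattern, path, trees = NULL,
                           ids = sprintf("T%03d", seq_len(pattern$n))) {
  r <- sqrt(pattern$x^2 + pattern$y^2)
  az <- (atan2(pattern$x, pattern$y) * 180 / pi) %% 360
  out <- data.frame(id = ids, azimuth_deg = round(az, 3),
                    distance_m = round(r, 3),
                    stringsAsFactors = FALSE)
  if (!is.null(pattern$marks)) out$age_class <- pattern$marks
  if (!is.null(trees)) {
    extra <- trees[match(out$id, trees$id),
                   setdiff(names(trees), c("id", names(out))), drop = FALSE]
    out <- cbind(out, extra)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

# Tucson RWL ---------------------------------------------------------------

#' Read and write Tucson (RWL) ring-width files
#'
#' The decadal Tucson layout: each line carries a series id, the calendar
#' year of its first value, then up to 10 ring widths in units of 0.01 mm,
#' the first line of a series running from its first year to the end of
#' that decade. Both the `999` and `-9999` end-of-series markers are
#' accepted on read; `999` is written. `write_rwl` followed by `read_rwl`
#' is the identity on years and widths (at the 0.01 mm resolution).
#'
#' @param path File path.
#' @param series List of [ring_series()] to write.
#' @return `read_rwl`: a list of [ring_series()] (pith flags and offsets
#'   are not representable in the format and default to `FALSE`/0).
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  acc <- list()
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 3)
      stop("malformed decade line ", ln, ": '", lines[ln], "'")
    id <- toks[1]
    year <- suppressWarnings(as.integer(toks[2]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(year) || anyNA(vals))
      stop("malformed decade line ", ln, ": '", lines[ln], "'")
    if (is.null(acc[[id]]))
      acc[[id]] <- list(first_year = year, values = numeric(0),
                        done = FALSE)
    stopmark <- vals %in% c(999, -9999)
    if (any(stopmark)) {
      vals <- vals[seq_len(which(stopmark)[1] - 1L)]
      acc[[id]]$done <- TRUE
    }
    acc[[id]]$values <- c(acc[[id]]$values, vals)
  }
  lapply(names(acc), function(id) {
    ring_series(tree = sub("[A-Za-z]$", "", id), core = id,
                first_year = acc[[id]]$first_year,
                widths = acc[[id]]$values / 100)
  })
}

#' @rdname read_rwl
#' @export
write_rwl <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    v <- as.integer(round(s$widths * 100))
    yrs <- series_years(s)
    i <- 1L
    while (i <= length(v)) {
      decade_end <- (yrs[i] %/% 10) * 10 + 9
      j <- min(length(v), i + (decade_end - yrs[i]))
      line <- sprintf("%-8s%4d%s", s$core, yrs[i],
                      paste(sprintf("%6d", v[i:j]), collapse = ""))
      if (j == length(v)) line <- paste0(line, sprintf("%6d", 999L))
      writeLines(line, con)
      i <- j + 1L
    }
  }
  invisible(path)
}

# Climate CSV --------------------------------------------------------------

#' Read and write the monthly climate CSV
#'
#' Plain CSV with columns `year`, `month`, `p_mm`, `tmax_c`, `tmin_c`.
#'
#' @param path File path.
#' @param climate Climate data.frame to write.
#' @return `read_climate`: the validated data.frame.
#' @export
read_climate <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_climate(cl)
  cl
}

#' @rdname read_climate
#' @export
write_climate <- function(climate, path) {
  validate_climate(climate)
  utils::write.csv(climate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
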