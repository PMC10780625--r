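#' Circular observation window
#'
#' Constructs the circular plot window in which a stem map was recorded.
#' All coordinates in the package are window-local metres, with the origin
#' at the plot centre.
#'
#' @param radius Plot radius in metres. Must be a single positive number.
#' @param center Numeric length-2 vector, centre of the plot. Kept at the
#'   origin throughout the package; exposed for completeness.
#'
#' @return An object of class `stand_window` with elements `radius`,
#'   `center` and `area` (\eqn{A = \pi r^2}, in square metres).
#' @examples
#' w <- stand_window(40)
#' w$area # about 5027 m2
#' @export
stand_window <- function(radius, center = c(0, 0)) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("window radius must be > 0")
  stopifnot(is.numeric(center), length(center) == 2L)
  structure(
    list(radius = as.numeric(radius),
         center = as.numeric(center),
         area   = pi * radius^2),
    class = "stand_window")
}

#' @export
print.stand_window <- function(x, ...) {
  cat(sprintf("Circular window: radius %.2f m, area %.1f m2\n",
              x$radius, x$area))
  invisible(x)
}

#' Marked planar point pattern
#'
#' A set of tree positions inside a circular window, optionally carrying a
#' categorical mark per point (the age class: `"Y"`, `"M"`, `"O"`, `"ER"`).
#'
#' @param x,y Numeric coordinate vectors (metres, window-local).
#' @param window A [stand_window()].
#' @param marks Optional character/factor vector of per-point labels, same
#'   length as `x`.
#'
#' @return An object of class `ppattern` with elements `x`, `y`, `marks`
#'   (character or `NULL`), `window` and `n`.
#' @examples
#' p <- point_pattern(c(0, 3, 0), c(0, 0, 4), stand_window(40))
#' p$n
#' @export
point_pattern <- function(x, y, window, marks = NULL) {
  stopifnot(inherits(window, "stand_window"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (anyNA(x) || anyNA(y)) stop("coordinates contain NA")
  r2 <- (x - window$center[1])^2 + (y - window$center[2])^2
  if (any(r2 > window$radius^2 * (1 + 1e-12)))
    stop("point(s) outside the window: index ",
         paste(which(r2 > window$radius^2 * (1 + 1e-12)), collapse = ", "))
  if (!is.null(marks)) {
    marks <- as.character(marks)
    if (length(marks) != length(x)) stop("marks length must equal number of points")
  }
  structure(list(x = x, y = y, marks = marks, window = window,
                 n = length(x)),
            class = "ppattern")
}

#' @export
print.ppattern <- function(x, ...) {
  cat(sprintf("Planar point pattern: %d points in a radius-%.1f m circular window\n",
              x$n, x$window$radius))
  if (!is.null(x$marks)) {
    tab <- table(x$marks)
    cat("marks: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.ppattern <- function(x, ..., main = "Point pattern") {
  th <- seq(0, 2 * pi, length.out = 256)
  plot(x$window$center[1] + x$window$radius * cos(th),
       x$window$center[2] + x$window$radius * sin(th),
       type = "l", asp = 1, xlab = "x (m)", ylab = "y (m)", main = main, ...)
  if (is.null(x$marks)) {
    graphics::points(x$x, x$y, pch = 16)
  } else {
    f <- factor(x$marks)
    graphics::points(x$x, x$y, pch = 16, col = as.integer(f))
    graphics::legend("topright", legend = levels(f), col = seq_along(levels(f)),
                     pch = 16, bty = "n")
  }
  invisible(x)
}

#' Extract one marked sub-pattern
#'
#' @param x A marked [point_pattern()].
#' @param mark Mark label to keep.
#' @param ... Unused.
#' @return A `ppattern` containing only the points with that mark.
#' @export
subset.ppattern <- function(x, mark, ...) subset_pattern(x, mark)

# Subset a pattern by mark label (internal).
subset_pattern <- function(p, label) {
  if (is.null(p$marks)) stop("pattern has no marks")
  keep <- p$marks == label
  if (!any(keep)) stop("no points with mark '", label, "'")
  point_pattern(p$x[keep], p$y[keep], p$window, marks = p$marks[keep])
}
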