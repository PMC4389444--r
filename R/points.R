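#' Planar point patterns
#'
#' A point pattern is a tibble with numeric columns `x` and `y` (metres) and,
#' optionally, a `label` column (`"case"` or `"control"`), carrying its
#' observation window as an attribute. All tidyverse verbs apply; functions
#' that need the window take it from the attribute or from an explicit
#' `window` argument.
#'
#' @param x,y Coordinate vectors (metres).
#' @param window Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param label Optional single string (`"case"` or `"control"`), recycled.
#' @return A tibble of class `rr_points`.
#' @export
point_pattern <- function(x, y, window, label = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  check_window(window)
  if (any(x < window[1] | x > window[2] | y < window[3] | y > window[4])) {
    stop("all points must lie inside the window", call. = FALSE)
  }
  pp <- tibble::tibble(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(label)) pp$label <- label
  attr(pp, "window") <- as.numeric(window)
  class(pp) <- c("rr_points", class(pp))
  pp
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 4 ||
      window[2] <= window[1] || window[4] <= window[3]) {
    stop("`window` must be numeric c(xmin, xmax, ymin, ymax) with positive extent",
         call. = FALSE)
  }
  invisible(window)
}

#' Observation window of a point pattern
#'
#' @param pp A point pattern (tibble with `x`, `y`).
#' @param window Optional explicit window overriding the attribute.
#' @return Numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
pattern_window <- function(pp, window = NULL) {
  w <- window %||% attr(pp, "window")
  if (is.null(w)) stop("point pattern carries no window; supply `window`", call. = FALSE)
  check_window(w)
}

window_area <- function(window) (window[2] - window[1]) * (window[4] - window[3])

#' Read and write point patterns as CSV
#'
#' CSV files have a header `x,y` (metres), one row per point, and may carry a
#' `label` column with values `case` or `control`.
#'
#' @param path File path.
#' @param window Window to attach (`c(xmin, xmax, ymin, ymax)`); if `NULL`,
#'   the bounding box of the points is used.
#' @return `read_points_csv()` returns an `rr_points` tibble;
#'   `write_points_csv()` returns `path` invisibly.
#' @export
read_points_csv <- function(path, window = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("CSV must have columns x,y", call. = FALSE)
  if (is.null(window)) window <- c(range(df$x), range(df$y))
  point_pattern(df$x, df$y, window = window,
                label = if ("label" %in% names(df)) df$label else NULL)
}

#' @rdname read_points_csv
#' @param pp Point pattern to write.
#' @export
write_points_csv <- function(pp, path) {
  utils::write.csv(as.data.frame(pp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
autoplot.rr_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [m]", y = "y [m]")
}
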