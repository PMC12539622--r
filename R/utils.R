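#' @keywords internal
"_PACKAGE"

# Internal validation helpers -------------------------------------------------

stop_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x),
          "'%s' must be a single non-missing number", name)
  stop_if(!allow_inf && !is.finite(x), "'%s' must be finite", name)
  stop_if(x < lower, "'%s' must be >= %s (got %s)", name, lower, x)
  stop_if(x > upper, "'%s' must be <= %s (got %s)", name, upper, x)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  stop_if(x != round(x), "'%s' must be an integer count", name)
  invisible(as.integer(x))
}

#' Ray-casting point-in-polygon test
#'
#' @param px,py point coordinates.
#' @param poly two-column matrix of polygon vertices (closed implicitly).
#' @return logical vector, one element per point.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Shoelace polygon area
#'
#' @param poly two-column matrix of vertices in order.
#' @return area (same squared units as the coordinates).
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  i2 <- c(2:n, 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}
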