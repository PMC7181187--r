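# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("axq_invalid_parameter", "error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(name, " must be a single positive finite number")
  }
  invisible(x)
}

check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop_invalid(name, " must lie in ", if (open) "(0, 1)" else "[0, 1]")
  }
  invisible(x)
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each query point to a polyline made of
#' straight segments between consecutive vertices. Works in 2-D or 3-D.
#'
#' @param points numeric matrix, one point per row.
#' @param verts numeric matrix of polyline vertices (>= 2 rows), same
#'   number of columns as `points`.
#' @return numeric vector of distances, one per point.
#' @keywords internal
dist_to_polyline <- function(points, verts) {
  points <- as.matrix(points)
  verts <- as.matrix(verts)
  if (nrow(verts) < 2L) stop_invalid("polyline needs at least 2 vertices")
  d <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(verts) - 1L)) {
    a <- verts[i, ]
    b <- verts[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(points, 2L, a)
    t <- if (len2 == 0) rep(0, nrow(points)) else pmin(1, pmax(0, rel %*% ab / len2))
    proj <- outer(drop(t), ab)
    d <- pmin(d, sqrt(rowSums((rel - proj)^2)))
  }
  d
}

# Cumulative arclength of a polyline (vector of length nrow(verts)).
polyline_arclength <- function(verts) {
  verts <- as.matrix(verts)
  seg <- sqrt(rowSums((verts[-1L, , drop = FALSE] - verts[-nrow(verts), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# Clip a polyline to an arclength interval [s0, s1], interpolating endpoints.
clip_polyline <- function(verts, s0, s1) {
  verts <- as.matrix(verts)
  s <- polyline_arclength(verts)
  s0 <- max(s0, 0)
  s1 <- min(s1, s[length(s)])
  if (s1 <= s0) stop_invalid("empty arclength interval")
  point_at <- function(si) {
    i <- max(which(s <= si))
    if (i == length(s)) return(verts[i, ])
    f <- (si - s[i]) / (s[i + 1L] - s[i])
    verts[i, ] + f * (verts[i + 1L, ] - verts[i, ])
  }
  inner <- which(s > s0 & s < s1)
  rbind(point_at(s0), verts[inner, , drop = FALSE], point_at(s1))
}

#' Centered moving average with shrinking edges
#'
#' At positions where the full window does not fit, the window shrinks to
#' the available samples (no padding is invented).
#'
#' @param x numeric vector.
#' @param width odd integer window width (frames).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, width = 3L) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop_invalid("width must be a positive odd integer")
  h <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Runs (rle) of TRUE in a logical vector; returns data.frame(start, end).
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}
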