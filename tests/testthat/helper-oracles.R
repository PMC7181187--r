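# Independent brute-force oracles. Deliberately naive implementations
# (plain loops, no shared code with the package internals) used to
# cross-check the optimized analysis operations.

# Exhaustive threshold-crossing scan: find the super-threshold run
# containing the argmax by checking every adjacent sample pair.
oracle_extent <- function(x, y, fraction) {
  thr <- fraction * max(y)
  i0 <- which.max(y)
  lo <- i0
  while (lo > 1 && y[lo - 1] >= thr) lo <- lo - 1
  hi <- i0
  while (hi < length(y) && y[hi + 1] >= thr) hi <- hi + 1
  start <- if (lo == 1) x[1] else {
    f <- (thr - y[lo - 1]) / (y[lo] - y[lo - 1]); x[lo - 1] + f * (x[lo] - x[lo - 1])
  }
  end <- if (hi == length(y)) x[length(y)] else {
    f <- (y[hi] - thr) / (y[hi] - y[hi + 1]); x[hi] + f * (x[hi + 1] - x[hi])
  }
  c(start = start, end = end)
}

# Plain-loop point-to-polyline distance.
oracle_dist <- function(p, verts) {
  best <- Inf
  for (i in seq_len(nrow(verts) - 1)) {
    a <- verts[i, ]; b <- verts[i + 1, ]
    ab <- b - a; len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else min(1, max(0, sum((p - a) * ab) / len2))
    best <- min(best, sqrt(sum((p - (a + t * ab))^2)))
  }
  best
}

oracle_bouton_count <- function(verts, vdf, overlap) {
  n <- 0L
  for (i in seq_len(nrow(vdf))) {
    p <- c(vdf$x_um[i], vdf$y_um[i], vdf$z_um[i])
    if (oracle_dist(p, verts) <= overlap + 1e-9) n <- n + 1L
  }
  n
}

# All-pairs agglomerative single linkage at cut height h: start from
# singletons, repeatedly merge the closest pair of clusters until the
# minimum inter-cluster (single-link) distance exceeds h.
oracle_single_linkage <- function(pts, h) {
  n <- nrow(pts)
  cl <- seq_len(n)
  d <- as.matrix(dist(pts))
  repeat {
    best <- c(Inf, 0, 0)
    for (a in unique(cl)) for (b in unique(cl)) {
      if (a >= b) next
      dm <- min(d[cl == a, cl == b, drop = FALSE])
      if (dm < best[1]) best <- c(dm, a, b)
    }
    if (!is.finite(best[1]) || best[1] > h) break
    cl[cl == best[3]] <- best[2]
  }
  cl
}

# Per-lag scaled-template least squares via lm(), one lag at a time.
oracle_cb_lag <- function(trace, w, lag) {
  seg <- trace[lag:(lag + length(w) - 1)]
  fit <- lm(seg ~ w)
  s <- unname(coef(fit)[2])
  se <- sqrt(sum(resid(fit)^2) / (length(w) - 1))
  c(scale = s, criterion = s / se)
}

# Raw finite-difference jerk (no smoothing): first local maximum above
# a fraction of the window maximum, before the AP peak.
oracle_jerk_threshold <- function(v, dt, i_spk, pre = 250) {
  i_pk <- i_spk
  while (i_pk < length(v) && v[i_pk + 1] >= v[i_pk]) i_pk <- i_pk + 1
  seg <- v[(i_spk - pre):i_pk]
  j <- diff(seg, differences = 3) / dt^3
  floor_j <- 0.2 * max(j)
  for (i in 2:(length(j) - 1)) {
    if (j[i] >= j[i - 1] && j[i] >= j[i + 1] && j[i] >= floor_j && j[i] > 0) {
      # the third difference over samples i..i+3 is centered at i + 1.5
      return((seg[i + 1] + seg[i + 2]) / 2)
    }
  }
  NA_real_
}

# Count well-separated local maxima in an image (3x3 neighborhood).
oracle_peak_count <- function(img, floor) {
  n <- 0L
  for (i in 2:(nrow(img) - 1)) for (j in 2:(ncol(img) - 1)) {
    v <- img[i, j]
    if (v < floor) next
    nb <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v >= max(nb)) n <- n + 1L
  }
  n
}

# Plain-loop 3-frame moving average with shrinking edges.
moving_average_ref <- function(x, h = 1) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    lo <- max(1, i - h); hi <- min(length(x), i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Convenience: build a circle polygon through exact vertex positions.
circle_polygon <- function(center, r, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
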