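#' Segment somata from a NeuN image
#'
#' Threshold (Otsu by default, or a manual per-image value), label
#' connected components, discard small ones, and extract each soma's
#' boundary polygon. The perimeter is the length of the boundary polygon
#' after light resampling of the pixel contour (every `contour_step`-th
#' contour point), which removes the systematic over-estimate of raw
#' 8-connected chain codes. Thresholds are per-image choices, so the
#' value actually used is recorded on every segment.
#'
#' @param neun_image numeric matrix (single plane, AU).
#' @param pixel_size_um pixel size, um/px.
#' @param threshold `"otsu"` or a numeric intensity threshold.
#' @param min_area_um2 minimum component area kept, um^2.
#' @param contour_step contour subsampling step, px.
#' @return list of `soma_segment` objects: `id`, `boundary_um` (polygon
#'   matrix), `perimeter_um`, `area_um2`, `centroid_um`, `threshold_used`.
#' @export
segment_somata <- function(neun_image, pixel_size_um = 0.2,
                           threshold = "otsu", min_area_um2 = 10,
                           contour_step = 3L) {
  thr <- resolve_threshold(neun_image, threshold)
  mask <- neun_image > thr
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  out <- list()
  contours <- EBImage::ocontour(lab)
  for (g in seq_len(max(labm))) {
    area <- sum(labm == g) * pixel_size_um^2
    if (area < min_area_um2) next
    ct <- contours[[g]]  # 0-based pixel coordinates (x = row, y = col)
    idx <- unique(c(seq(1L, nrow(ct), by = max(1L, contour_step)), nrow(ct)))
    poly <- ct[idx, , drop = FALSE] * pixel_size_um
    per <- polygon_perimeter(poly)
    cellpix <- which(labm == g, arr.ind = TRUE)
    out[[length(out) + 1L]] <- structure(
      list(id = length(out) + 1L,
           boundary_um = poly,
           perimeter_um = per,
           area_um2 = area,
           centroid_um = (colMeans(cellpix) - 1) * pixel_size_um,
           threshold_used = thr),
      class = "soma_segment"
    )
  }
  out
}

#' Segment synaptic puncta from a VGAT image
#'
#' Threshold, then split touching puncta with a distance-transform
#' watershed, and return punctum centroids and areas.
#'
#' @inheritParams segment_somata
#' @param vgat_image numeric matrix (single plane, AU).
#' @param min_area_px minimum punctum area in pixels.
#' @return object of class `puncta_set`: data.frame `puncta`
#'   (`id`, `x_um`, `y_um`, `area_um2`) plus `threshold_used`.
#' @export
segment_puncta <- function(vgat_image, pixel_size_um = 0.2,
                           threshold = "otsu", min_area_px = 4L) {
  thr <- resolve_threshold(vgat_image, threshold)
  mask <- vgat_image > thr
  empty <- structure(list(
    puncta = data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                        area_um2 = numeric()),
    threshold_used = thr), class = "puncta_set")
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = 0.5)
  labm <- EBImage::imageData(lab)
  rows <- list()
  for (g in seq_len(max(labm))) {
    pix <- which(labm == g, arr.ind = TRUE)
    if (nrow(pix) < min_area_px) next
    # intensity-weighted centroid, 0-based pixel-center convention
    w <- vgat_image[pix]
    ctr <- colSums((pix - 1) * w) / sum(w)
    rows[[length(rows) + 1L]] <- data.frame(
      id = length(rows) + 1L,
      x_um = ctr[1] * pixel_size_um, y_um = ctr[2] * pixel_size_um,
      area_um2 = nrow(pix) * pixel_size_um^2)
  }
  if (!length(rows)) return(empty)
  structure(list(puncta = do.call(rbind, rows), threshold_used = thr),
            class = "puncta_set")
}

#' Count perisomatic synaptic puncta
#'
#' A punctum is perisomatic if its centroid lies within `radius_um` of
#' the segmented soma region: distance 0 if the centroid falls inside the
#' soma polygon, otherwise the distance to the boundary; the comparison
#' is boundary-inclusive ("within" read as <=). Density is count per um
#' of soma perimeter.
#'
#' @param puncta a `puncta_set` from [segment_puncta()].
#' @param soma a `soma_segment` from [segment_somata()].
#' @param radius_um inclusion radius, um (default 1).
#' @return list with `count`, `density_per_um`, `perimeter_um`,
#'   `radius_um`, `included_ids`.
#' @export
count_perisomatic <- function(puncta, soma, radius_um = 1) {
  stopifnot(inherits(puncta, "puncta_set"), inherits(soma, "soma_segment"))
  if (radius_um < 0) stop_invalid("radius_um must be >= 0")
  if (soma$perimeter_um <= 0) {
    stop(errorCondition("degenerate soma: zero perimeter",
                        class = c("axq_degenerate_soma", "error")))
  }
  df <- puncta$puncta
  if (nrow(df) == 0L) {
    return(list(count = 0L, density_per_um = 0,
                perimeter_um = soma$perimeter_um, radius_um = radius_um,
                included_ids = integer()))
  }
  d <- vapply(seq_len(nrow(df)), function(i)
    point_region_distance(c(df$x_um[i], df$y_um[i]), soma$boundary_um),
    numeric(1))
  # boundary-inclusive ("within" read as <=), with a tiny numeric
  # tolerance for puncta sitting exactly at the radius
  inc <- which(d <= radius_um + 1e-9)
  list(count = length(inc), density_per_um = length(inc) / soma$perimeter_um,
       perimeter_um = soma$perimeter_um, radius_um = radius_um,
       included_ids = df$id[inc])
}

#' Build a soma segment from an explicit boundary polygon
#'
#' For somata delineated by hand (or analytically, in validation), as
#' opposed to segmented from a NeuN image.
#'
#' @param boundary_um n x 2 matrix of polygon vertices, um.
#' @param id segment id.
#' @return a `soma_segment`.
#' @export
soma_segment_from_polygon <- function(boundary_um, id = 1L) {
  boundary_um <- as.matrix(boundary_um)
  if (nrow(boundary_um) < 3L) stop_invalid("polygon needs >= 3 vertices")
  per <- polygon_perimeter(boundary_um)
  if (per <= 0) stop_invalid("degenerate polygon")
  x <- boundary_um[, 1]; y <- boundary_um[, 2]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  area <- abs(sum(x * ys - xs * y)) / 2
  structure(list(id = id, boundary_um = boundary_um, perimeter_um = per,
                 area_um2 = area,
                 centroid_um = c(mean(x), mean(y)),
                 threshold_used = NA_real_),
            class = "soma_segment")
}

resolve_threshold <- function(img, threshold) {
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) == 0) return(rng[2])  # flat image: nothing exceeds thr
    scl <- (img - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(scl), range = c(0, 1)) * diff(rng) + rng[1]
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else {
    stop_invalid("threshold must be \"otsu\" or a single number")
  }
}

# Perimeter of a closed polygon given as a matrix of vertices.
polygon_perimeter <- function(poly) {
  p2 <- rbind(poly, poly[1L, ])
  sum(sqrt(rowSums((p2[-1L, , drop = FALSE] - p2[-nrow(p2), , drop = FALSE])^2)))
}

# Distance from a point to a polygonal region: 0 inside, else distance
# to the closest boundary segment.
point_region_distance <- function(pt, poly) {
  if (point_in_polygon(pt, poly)) return(0)
  closed <- rbind(poly, poly[1L, ])
  min(dist_to_polyline(matrix(pt, 1), closed))
}

# Ray-casting point-in-polygon test (boundary points count as inside).
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  x <- pt[1]; y <- pt[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    if (point_on_segment(x, y, xi, yi, xj, yj)) return(TRUE)
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_on_segment <- function(x, y, x1, y1, x2, y2, tol = 1e-9) {
  cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
  if (abs(cross) > tol) return(FALSE)
  dot <- (x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)
  len2 <- (x2 - x1)^2 + (y2 - y1)^2
  dot >= -tol && dot <= len2 + tol
}
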