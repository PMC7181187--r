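#' Count varicosities overlapping an AIS and compute bouton density
#'
#' A varicosity counts as a bouton on the AIS if its distance to the AIS
#' polyline, restricted to the detected extent, is at most
#' `overlap_dist_um` (boundary-inclusive). Density is count per um of
#' detected AIS length.
#'
#' @param ais_verts n x 3 matrix of AIS polyline vertices, um.
#' @param extent an [detect_ais_extent()] result, or `NULL` to use the
#'   full polyline.
#' @param varicosities data.frame with columns `x_um`, `y_um`, `z_um`
#'   (and optionally `id`).
#' @param overlap_dist_um overlap distance, um (>= 0). The published rule
#'   is a manual judgement of "overlap"; this operationalizes it and the
#'   value used is returned alongside the counts.
#' @return list with `count`, `density_per_um`, `length_um`,
#'   `overlap_dist_um`, and the ids of included varicosities.
#' @export
count_boutons <- function(ais_verts, varicosities, extent = NULL,
                          overlap_dist_um = 0.5) {
  if (overlap_dist_um < 0) stop_invalid("overlap_dist_um must be >= 0")
  ais_verts <- as.matrix(ais_verts)
  if (!is.null(extent)) {
    stopifnot(inherits(extent, "ais_extent"))
    if (extent$length_um <= 0) {
      stop(errorCondition("zero-length AIS extent: density undefined",
                          class = c("axq_undefined_density", "error")))
    }
    verts <- clip_polyline(ais_verts, extent$start_um, extent$end_um)
    len <- extent$length_um
  } else {
    verts <- ais_verts
    len <- polyline_arclength(ais_verts)[nrow(ais_verts)]
    if (len <= 0) {
      stop(errorCondition("zero-length AIS: density undefined",
                          class = c("axq_undefined_density", "error")))
    }
  }
  if (nrow(varicosities) == 0L) {
    return(list(count = 0L, density_per_um = 0, length_um = len,
                overlap_dist_um = overlap_dist_um, ids = integer()))
  }
  pts <- as.matrix(varicosities[, c("x_um", "y_um", "z_um")])
  d <- dist_to_polyline(pts, verts)
  # boundary-inclusive, with a tiny tolerance so a varicosity placed
  # exactly at the overlap distance is never lost to rounding
  inc <- which(d <= overlap_dist_um + 1e-9)
  ids <- if ("id" %in% names(varicosities)) varicosities$id[inc] else inc
  list(count = length(inc), density_per_um = length(inc) / len,
       length_um = len, overlap_dist_um = overlap_dist_um, ids = ids)
}

#' Group varicosities into cartridges
#'
#' A cartridge is a collection of two or more boutons that project along
#' the same axis as the AIS they target. Operationally: single-linkage
#' clustering of varicosity positions at link distance `link_dist_um`;
#' clusters of size >= 2 whose principal axis is aligned with `ais_axis`
#' (absolute cosine >= `axis_cos_min`) become cartridges. Both cut-offs
#' are explicit choices (the published rule is verbal) and are echoed in
#' the result.
#'
#' @param varicosities data.frame with `x_um`, `y_um`, `z_um` (and `id`).
#' @param ais_axis unit 3-vector giving the AIS orientation.
#' @param link_dist_um single-linkage merge distance, um.
#' @param axis_cos_min minimum |cos| between cluster principal axis and
#'   `ais_axis`.
#' @return object of class `cartridge_set`: list with `cartridges` (list
#'   of member-id vectors), `sizes`, and the parameters used.
#' @export
group_cartridges <- function(varicosities, ais_axis = c(0, 0, 1),
                             link_dist_um = 5, axis_cos_min = 0.9) {
  check_positive(link_dist_um, "link_dist_um")
  check_fraction(axis_cos_min, "axis_cos_min")
  ais_axis <- ais_axis / sqrt(sum(ais_axis^2))
  n <- nrow(varicosities)
  ids <- if ("id" %in% names(varicosities)) varicosities$id else seq_len(n)
  empty <- structure(list(cartridges = list(), sizes = integer(),
                          link_dist_um = link_dist_um,
                          axis_cos_min = axis_cos_min),
                     class = "cartridge_set")
  if (n < 2L) return(empty)
  pts <- as.matrix(varicosities[, c("x_um", "y_um", "z_um")])
  cl <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                      h = link_dist_um)
  carts <- list(); sizes <- integer()
  for (g in unique(cl)) {
    m <- which(cl == g)
    if (length(m) < 2L) next
    ctr <- sweep(pts[m, , drop = FALSE], 2L, colMeans(pts[m, , drop = FALSE]))
    if (max(abs(ctr)) == 0) next  # coincident points: no axis defined
    v1 <- svd(ctr, nu = 0, nv = 1)$v[, 1]
    if (abs(sum(v1 * ais_axis)) >= axis_cos_min) {
      carts[[length(carts) + 1L]] <- ids[m]
      sizes <- c(sizes, length(m))
    }
  }
  structure(list(cartridges = carts, sizes = sizes,
                 link_dist_um = link_dist_um, axis_cos_min = axis_cos_min),
            class = "cartridge_set")
}

#' Chandelier-cell connection probability inside a cylinder
#'
#' Fraction of sampled AISs contacted by at least one ChC varicosity,
#' among AISs eligible for sampling: reference point within the cylinder
#' (lateral distance from the ChC soma <= radius, axial offset within
#' +/- height/2). `n_sample` AISs are drawn blindly (without replacement,
#' seeded); when fewer are eligible, all are used.
#'
#' @param field a `chc_field` (see [make_chc_field()]).
#' @param n_sample number of AISs to sample (default 30).
#' @param overlap_dist_um contact rule distance, um.
#' @param seed RNG seed for the blind sample.
#' @return list with `probability`, `n_eligible`, `n_sampled`,
#'   `sampled_ids`, `contacted_ids`, `overlap_dist_um`.
#' @export
connection_probability <- function(field, n_sample = 30,
                                   overlap_dist_um = field$overlap_dist_um %||% 0.5,
                                   seed = 1L) {
  stopifnot(inherits(field, "chc_field"))
  radius <- field$cylinder[["radius_um"]]
  height <- field$cylinder[["height_um"]]
  soma <- field$chc_soma
  refs <- t(vapply(field$ais_records, function(a) a$verts[1L, ], numeric(3)))
  lat <- sqrt((refs[, 1] - soma[1])^2 + (refs[, 2] - soma[2])^2)
  axial <- abs(refs[, 3] - soma[3])
  eligible <- which(lat <= radius & axial <= height / 2)
  if (length(eligible) == 0L) {
    stop(errorCondition("no AIS is eligible inside the cylinder",
                        class = c("axq_no_eligible_ais", "error")))
  }
  k <- min(n_sample, length(eligible))
  sampled <- withr::with_seed(seed, eligible[sample.int(length(eligible), k)])
  pts <- as.matrix(field$varicosities[, c("x_um", "y_um", "z_um")])
  contacted <- vapply(sampled, function(i) {
    if (nrow(pts) == 0L) return(FALSE)
    any(dist_to_polyline(pts, field$ais_records[[i]]$verts) <= overlap_dist_um)
  }, logical(1))
  list(probability = mean(contacted),
       n_eligible = length(eligible), n_sampled = k,
       sampled_ids = sampled, contacted_ids = sampled[contacted],
       overlap_dist_um = overlap_dist_um)
}
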