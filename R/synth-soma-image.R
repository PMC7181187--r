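#' Generate synthetic NeuN / VGAT single-plane images with known puncta
#'
#' Emulates a two-channel perisomatic-synapse image: disk-shaped somata
#' (NeuN channel) and Gaussian-spot puncta (VGAT channel) placed at
#' controlled distances from the soma boundaries. The truth records each
#' punctum's analytic distance to its soma boundary (0 for puncta on or
#' inside the boundary when measured as distance-to-region).
#'
#' @param cfg a [sim_config()]; `pixel_size_xy` sets the um/px scale.
#' @param img_size_px image side length in pixels.
#' @param soma_centers_um n x 2 matrix of soma centers, um; default: one
#'   centered soma.
#' @param soma_radius_um soma radius (all somata), um.
#' @param punctum_offsets_um distances of puncta from the soma boundary,
#'   um (negative = inside); one punctum per offset, placed around the
#'   first soma at evenly spaced angles unless `punctum_soma` says
#'   otherwise.
#' @param punctum_soma index of the parent soma for each offset.
#' @param punctum_sigma_um Gaussian spot SD, um.
#' @param noise_sd additive Gaussian noise SD on both channels (AU).
#' @return list with `neun`, `vgat` (matrices, AU) and `truth`
#'   (`punctum_xy_um`, `offset_um`, `region_distance_um`, soma geometry).
#' @export
make_soma_image <- function(cfg, img_size_px = 256,
                            soma_centers_um = NULL,
                            soma_radius_um = 8,
                            punctum_offsets_um = numeric(),
                            punctum_soma = rep(1L, length(punctum_offsets_um)),
                            punctum_sigma_um = 0.3,
                            noise_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  px <- cfg$pixel_size_xy
  side_um <- img_size_px * px
  if (is.null(soma_centers_um)) {
    soma_centers_um <- matrix(side_um / 2, 1, 2)
  }
  soma_centers_um <- as.matrix(soma_centers_um)
  ns <- nrow(soma_centers_um)
  if (ns > 1L) {
    dd <- as.matrix(stats::dist(soma_centers_um))
    diag(dd) <- Inf
    if (min(dd) <= 2 * soma_radius_um) {
      stop_invalid("requested soma geometry forces overlap")
    }
  }

  # pixel-center coordinates in um (0-based voxel convention)
  coord <- (seq_len(img_size_px) - 1L) * px
  gx <- matrix(coord, img_size_px, img_size_px)
  gy <- matrix(coord, img_size_px, img_size_px, byrow = TRUE)

  neun <- matrix(0, img_size_px, img_size_px)
  for (i in seq_len(ns)) {
    neun <- neun + 100 * ((gx - soma_centers_um[i, 1])^2 +
                            (gy - soma_centers_um[i, 2])^2 <= soma_radius_um^2)
  }

  np <- length(punctum_offsets_um)
  vgat <- matrix(0, img_size_px, img_size_px)
  pxy <- matrix(numeric(), 0, 2)
  if (np > 0L) {
    ang <- seq(0, 2 * pi, length.out = np + 1L)[seq_len(np)]
    pxy <- t(vapply(seq_len(np), function(j) {
      ctr <- soma_centers_um[punctum_soma[j], ]
      ctr + (soma_radius_um + punctum_offsets_um[j]) * c(cos(ang[j]), sin(ang[j]))
    }, numeric(2)))
    if (any(pxy < 0 | pxy > side_um)) stop_invalid("punctum outside image bounds")
    for (j in seq_len(np)) {
      vgat <- vgat + 150 * exp(-((gx - pxy[j, 1])^2 + (gy - pxy[j, 2])^2) /
                                 (2 * punctum_sigma_um^2))
    }
  }

  if (noise_sd > 0) {
    noise <- with_cfg_seed(cfg, list(
      n = matrix(stats::rnorm(img_size_px^2, 0, noise_sd), img_size_px),
      v = matrix(stats::rnorm(img_size_px^2, 0, noise_sd), img_size_px)
    ))
    neun <- pmax(neun + noise$n, 0)
    vgat <- pmax(vgat + noise$v, 0)
  }

  list(
    neun = neun, vgat = vgat,
    truth = list(
      soma_centers_um = soma_centers_um,
      soma_radius_um = soma_radius_um,
      punctum_xy_um = pxy,
      offset_um = punctum_offsets_um,
      region_distance_um = pmax(punctum_offsets_um, 0),
      pixel_size_um = px
    )
  )
}
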