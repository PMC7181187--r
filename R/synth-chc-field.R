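#' Generate a synthetic chandelier-cell field with known AIS contacts
#'
#' Places a ChC soma at the origin, `n_ais` target AIS polylines (roughly
#' vertical, the orientation of pyramidal-cell initial segments) both
#' inside and outside a soma-centered cylinder, and ChC varicosities. A
#' deterministic round of `contacted_fraction * n_ais` AISs are contacted:
#' each receives >= 1 varicosity placed on (within `on_ais_jitter` of) its
#' polyline. Background varicosities are kept at least
#' `4 * overlap_dist_um` away from every AIS so that the truth contact map
#' is unambiguous under the overlap rule.
#'
#' @param cfg a [sim_config()].
#' @param n_ais number of AIS records (>= 1).
#' @param contacted_fraction fraction of AISs contacted, in `[0, 1]`.
#' @param cylinder `(radius_um, height_um)` of the sampling cylinder.
#' @param boutons_per_contact mean of the (shifted Poisson, >= 1) bouton
#'   count per contacted AIS.
#' @param inside_fraction fraction of AISs whose reference point lies
#'   inside the cylinder.
#' @param n_background number of non-contacting varicosities.
#' @param ais_length_um length of each AIS polyline, um.
#' @param overlap_dist_um overlap distance the truth is defined against.
#' @param on_ais_jitter radial jitter of contacting varicosities, um.
#' @return list with elements `field` (class `chc_field`: `chc_soma`,
#'   `varicosities` data.frame, `ais_records` list, `cylinder`) and
#'   `truth` (`contact_map`, per-AIS `bouton_counts`, `inside` flags).
#' @export
make_chc_field <- function(cfg, n_ais = 30, contacted_fraction = 0.5,
                           cylinder = c(radius_um = 90, height_um = 100),
                           boutons_per_contact = 4,
                           inside_fraction = 1,
                           n_background = 20,
                           ais_length_um = 25,
                           overlap_dist_um = 0.5,
                           on_ais_jitter = 0.2) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_ais < 1L) stop_invalid("n_ais must be >= 1")
  check_fraction(contacted_fraction, "contacted_fraction")
  check_fraction(inside_fraction, "inside_fraction")
  radius <- unname(cylinder[1]); height <- unname(cylinder[2])

  with_cfg_seed(cfg, {
    n_in <- round(inside_fraction * n_ais)
    inside <- c(rep(TRUE, n_in), rep(FALSE, n_ais - n_in))

    # AIS reference points: uniform over the cylinder disc (inside) or an
    # annulus/outer slab (outside); AISs run roughly along -z with jitter.
    ais_records <- vector("list", n_ais)
    ref <- matrix(0, n_ais, 3)
    min_spacing <- 8  # um between AIS origins: neighboring somata do
                      # not overlap, which keeps contact truth unambiguous
    for (i in seq_len(n_ais)) {
      tries <- 0L
      repeat {
        if (inside[i]) {
          r <- radius * sqrt(stats::runif(1))
          z <- stats::runif(1, -height / 2 + ais_length_um, height / 2)
        } else {
          r <- stats::runif(1, radius * 1.1, radius * 1.6)
          z <- stats::runif(1, -height / 2, height / 2)
        }
        th <- stats::runif(1, 0, 2 * pi)
        p0 <- c(r * cos(th), r * sin(th), z)
        if (i == 1L || min(sqrt(rowSums(sweep(ref[seq_len(i - 1L), ,
                                                  drop = FALSE],
                                              2L, p0)^2))) > min_spacing) {
          break
        }
        tries <- tries + 1L
        if (tries > 5000L) stop_invalid("cannot place AIS without overlap; reduce n_ais")
      }
      ref[i, ] <- p0
      nseg <- 6L
      drift <- stats::rnorm(2, 0, 0.5)
      zz <- seq(0, -ais_length_um, length.out = nseg + 1L)
      verts <- cbind(p0[1] + drift[1] * (-zz) / ais_length_um,
                     p0[2] + drift[2] * (-zz) / ais_length_um,
                     p0[3] + zz)
      ais_records[[i]] <- list(id = i, verts = verts, radius_um = 0.4)
    }

    n_contact <- round(contacted_fraction * n_ais)
    contacted <- rep(FALSE, n_ais)
    contacted[sample.int(n_ais, n_contact)] <- TRUE

    vx <- list(); vid <- 0L
    bouton_counts <- integer(n_ais)
    clearance <- 4 * overlap_dist_um
    other_verts <- function(i) lapply(ais_records[-i], `[[`, "verts")
    for (i in which(contacted)) {
      k <- 1L + stats::rpois(1, max(boutons_per_contact - 1, 0))
      verts <- ais_records[[i]]$verts
      s <- polyline_arclength(verts)
      others <- other_verts(i)
      for (b in seq_len(k)) {
        # resample until the varicosity is clear of every other AIS, so
        # the constructed contact map stays exact under the overlap rule
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 2000L) stop_invalid("varicosity placement failed; field too dense")
          u <- stats::runif(1, 0.1, 0.9) * s[length(s)]
          j <- max(which(s <= u)); j <- min(j, nrow(verts) - 1L)
          f <- (u - s[j]) / (s[j + 1L] - s[j])
          p <- verts[j, ] + f * (verts[j + 1L, ] - verts[j, ])
          off <- stats::rnorm(3); off <- off / sqrt(sum(off^2)) *
            stats::runif(1, 0, on_ais_jitter)
          cand <- c(p + off)
          dmin <- if (length(others)) min(vapply(others, function(v)
            min(dist_to_polyline(matrix(cand, 1), v)), numeric(1))) else Inf
          if (dmin > clearance) break
        }
        vid <- vid + 1L
        vx[[vid]] <- cand
      }
      bouton_counts[i] <- k
    }

    # background varicosities, rejected until clear of every AIS
    all_verts <- lapply(ais_records, `[[`, "verts")
    placed <- 0L
    while (placed < n_background) {
      cand <- c(stats::runif(1, -radius, radius),
                stats::runif(1, -radius, radius),
                stats::runif(1, -height / 2, height / 2))
      dmin <- min(vapply(all_verts, function(v)
        min(dist_to_polyline(matrix(cand, 1), v)), numeric(1)))
      if (dmin > clearance) {
        vid <- vid + 1L
        vx[[vid]] <- cand
        placed <- placed + 1L
      }
    }

    vdf <- if (vid > 0L) {
      m <- do.call(rbind, vx)
      data.frame(id = seq_len(vid), x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
    } else {
      data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                 z_um = numeric())
    }

    field <- structure(
      list(chc_soma = c(0, 0, 0), varicosities = vdf,
           ais_records = ais_records,
           cylinder = c(radius_um = radius, height_um = height),
           overlap_dist_um = overlap_dist_um),
      class = "chc_field"
    )
    truth <- list(contact_map = stats::setNames(contacted, seq_len(n_ais)),
                  bouton_counts = bouton_counts,
                  inside = inside,
                  ais_ref = ref,
                  contact_fraction = mean(contacted))
    list(field = field, truth = truth)
  })
}
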