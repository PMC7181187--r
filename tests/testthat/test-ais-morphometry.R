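test_that("AIS extent detection is interpolation-exact on ideal profiles", {
  x <- seq(0, 40, by = 0.5)
  y <- pmax(0, 100 * (1 - abs(x - 20) / 20))
  e <- detect_ais_extent(fluorescence_profile(x, y))
  expect_equal(e$start_um, 4)
  expect_equal(e$end_um, 36)
  expect_equal(e$length_um, 32)
  expect_false(e$clamped_start || e$clamped_end)
  # boundary intensities sit exactly at 20% of the maximum
  expect_equal(approx(x, y, xout = c(e$start_um, e$end_um))$y,
               rep(0.2 * 100, 2))

  flat <- detect_ais_extent(fluorescence_profile(x, rep(5, length(x))))
  expect_equal(flat$start_um, 0)
  expect_equal(flat$end_um, 40)
  expect_true(flat$clamped_start && flat$clamped_end)

  expect_error(detect_ais_extent(fluorescence_profile(x, rep(0, length(x)))),
               class = "axq_no_signal")
  expect_error(detect_ais_extent(fluorescence_profile(x, y), fraction = 1),
               class = "axq_invalid_parameter")
})

test_that("noisy detection equals the exhaustive crossing-scan oracle", {
  for (s in 1:20) {
    out <- make_ais_profile(sim_config(seed = s), length_um = 28,
                            shape = "gaussian", noise_sd = 6)
    e <- detect_ais_extent(out$profile)
    o <- oracle_extent(out$profile$position_um, out$profile$intensity, 0.2)
    expect_equal(e$start_um, unname(o["start"]))
    expect_equal(e$end_um, unname(o["end"]))
  }
})

test_that("detected length is monotone in fraction and scale invariant", {
  for (s in 1:10) {
    out <- make_ais_profile(sim_config(seed = s), length_um = 30,
                            shape = "plateau", noise_sd = 4)
    lens <- vapply(c(0.2, 0.3, 0.5, 0.7),
                   function(f) detect_ais_extent(out$profile, f)$length_um,
                   numeric(1))
    expect_true(all(diff(lens) <= 1e-12))
    e1 <- detect_ais_extent(out$profile)
    scaled <- fluorescence_profile(out$profile$position_um,
                                   out$profile$intensity * 7.3)
    e2 <- detect_ais_extent(scaled)
    expect_equal(e1$start_um, e2$start_um)
    expect_equal(e1$end_um, e2$end_um)
  }
})

test_that("extent recovery error stays below the sampling step", {
  cfg <- sim_config(seed = 1)
  for (shape in c("triangular", "plateau", "gaussian")) {
    out <- make_ais_profile(cfg, length_um = 30, shape = shape, noise_sd = 0)
    e <- detect_ais_extent(out$profile)
    expect_lt(abs(e$length_um - out$truth$true_length_um), cfg$profile_step)
  }
  # SNR >= 10 (peak 100, noise 10), pre-smoothing engaged for noisy
  # input: median error < 2 steps over seeds
  errs <- vapply(1:40, function(s) {
    out <- make_ais_profile(sim_config(seed = s), length_um = 30,
                            shape = "gaussian", noise_sd = 10)
    abs(detect_ais_extent(out$profile, smooth_width = 9)$length_um -
          out$truth$true_length_um)
  }, numeric(1))
  expect_lt(median(errs), 2 * cfg$profile_step)
})

test_that("profiles sampled from a stack reflect the volume contents", {
  cube <- array(7, c(20, 20, 10))
  path <- cbind(c(1, 3), c(1, 3), c(2, 8))
  pr <- extract_profile(cube, path, voxel_size_um = c(1, 1, 1))
  expect_true(all(pr$intensity == 7))

  # bright tube along a known path: on-path signal beats off-path
  stack <- array(1, c(30, 30, 20))
  for (k in 3:17) stack[15, 15, k] <- 120
  on <- extract_profile(stack, cbind(rep(14, 2), rep(14, 2), c(2, 16)) *
                          c(0.2, 0.2, 1)[col(matrix(0, 2, 3))],
                        voxel_size_um = c(0.2, 0.2, 1))
  off <- extract_profile(stack, cbind(rep(5, 2), rep(5, 2), c(2, 16)) *
                           c(0.2, 0.2, 1)[col(matrix(0, 2, 3))],
                         voxel_size_um = c(0.2, 0.2, 1))
  expect_gt(max(on$intensity), 100 * max(off$intensity))

  expect_error(extract_profile(cube, cbind(c(1, 1), c(1, 1), c(2, 2)),
                               voxel_size_um = c(1, 1, 1)),
               class = "axq_invalid_parameter")  # zero length
  expect_error(extract_profile(cube, cbind(c(1, 50), c(1, 1), c(2, 8)),
                               voxel_size_um = c(1, 1, 1)),
               class = "axq_out_of_bounds")
})

test_that("bouton counts match the exhaustive point-to-segment oracle", {
  none <- count_boutons(cbind(0, 0, c(0, -20)),
                        data.frame(x_um = numeric(), y_um = numeric(),
                                   z_um = numeric()))
  expect_equal(none$count, 0L)
  expect_equal(none$density_per_um, 0)

  # varicosity exactly at the overlap distance is included
  verts <- cbind(0, 0, c(0, -10))
  at_d <- count_boutons(verts, data.frame(id = 1, x_um = 0.5, y_um = 0,
                                          z_um = -5))
  expect_equal(at_d$count, 1L)

  for (s in 1:8) {
    out <- make_chc_field(sim_config(seed = s), n_ais = 40,
                          contacted_fraction = 0.6, n_background = 60)
    f <- out$field
    for (i in seq(1, 40, by = 7)) {
      got <- count_boutons(f$ais_records[[i]]$verts, f$varicosities)
      expect_equal(got$count,
                   oracle_bouton_count(f$ais_records[[i]]$verts,
                                       f$varicosities, 0.5))
    }
  }
  expect_error(count_boutons(cbind(c(0, 0), c(0, 0), c(0, 0)),
                             data.frame(x_um = 1, y_um = 1, z_um = 1)),
               class = "axq_undefined_density")
})

test_that("bouton density uses the detected extent length", {
  x <- seq(0, 40, by = 0.5)
  y <- pmax(0, 100 * (1 - abs(x - 20) / 20))
  e <- detect_ais_extent(fluorescence_profile(x, y))
  verts <- cbind(0, 0, seq(0, -40, length.out = 9))  # arclength = profile axis
  vdf <- data.frame(id = 1:3, x_um = c(0, 0, 0.2), y_um = 0,
                    z_um = c(-2, -20, -35))  # first lies outside the extent
  got <- count_boutons(verts, vdf, extent = e)
  expect_equal(got$count, 2L)
  expect_equal(got$density_per_um, 2 / e$length_um)
})

test_that("cartridge grouping equals all-pairs single linkage plus axis rule", {
  one <- group_cartridges(data.frame(id = 1, x_um = 0, y_um = 0, z_um = 0))
  expect_length(one$cartridges, 0)

  pair <- group_cartridges(data.frame(id = 1:2, x_um = 0, y_um = 0,
                                      z_um = c(0, 3)))
  expect_length(pair$cartridges, 1)
  expect_equal(pair$sizes, 2L)

  # pair perpendicular to the AIS axis is rejected
  perp <- group_cartridges(data.frame(id = 1:2, x_um = c(0, 3), y_um = 0,
                                      z_um = 0))
  expect_length(perp$cartridges, 0)

  for (s in 1:10) {
    set.seed(s)
    n <- 60
    pts <- data.frame(id = seq_len(n),
                      x_um = runif(n, 0, 40), y_um = runif(n, 0, 40),
                      z_um = runif(n, 0, 40))
    cs <- group_cartridges(pts, link_dist_um = 5, axis_cos_min = 0)
    ocl <- oracle_single_linkage(as.matrix(pts[, 2:4]), 5)
    # same partition restricted to clusters of size >= 2 (axis filter off)
    osets <- Filter(function(m) length(m) >= 2,
                    split(pts$id, ocl))
    norm <- function(l) sort(vapply(l, function(v) paste(sort(v), collapse = ","),
                                    character(1)))
    expect_equal(norm(cs$cartridges), norm(unname(osets)))
  }
})

test_that("connection probability matches truth and is seed-reproducible", {
  full <- make_chc_field(sim_config(seed = 4), n_ais = 30,
                         contacted_fraction = 1)
  expect_equal(connection_probability(full$field, seed = 1)$probability, 1)
  none <- make_chc_field(sim_config(seed = 4), n_ais = 30,
                         contacted_fraction = 0)
  expect_equal(connection_probability(none$field, seed = 1)$probability, 0)

  half <- make_chc_field(sim_config(seed = 6), n_ais = 80,
                         contacted_fraction = 0.5)
  exhaustive <- connection_probability(half$field, n_sample = 80, seed = 9)
  expect_equal(exhaustive$probability, half$truth$contact_fraction)

  a <- connection_probability(half$field, n_sample = 30, seed = 42)
  b <- connection_probability(half$field, n_sample = 30, seed = 42)
  expect_identical(a, b)

  # expectation over seeds approaches the eligible-set contact fraction
  ps <- vapply(1:60, function(s)
    connection_probability(half$field, n_sample = 30, seed = s)$probability,
    numeric(1))
  p0 <- half$truth$contact_fraction
  tol <- 3 * sqrt(p0 * (1 - p0) / 30) / sqrt(60)
  expect_lt(abs(mean(ps) - p0), max(tol, 0.02))

  far <- half$field
  far$chc_soma <- c(1e4, 1e4, 0)
  expect_error(connection_probability(far, seed = 1),
               class = "axq_no_eligible_ais")
})
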