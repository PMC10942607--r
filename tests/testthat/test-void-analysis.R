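test_that("void maps equal the all-pairs brute force voxel by voxel", {
  g <- tiny_geometry()
  grid <- voxel_grid(g, voxel_size = 0.6)
  expect_true(all(grid$dims <= 33))
  set.seed(4)
  for (nb in c(0, 1, 50)) {
    frame <- data.frame(x = runif(nb, -4, 4), y = runif(nb, -4, 4),
                        z = runif(nb, -6, 6),
                        radius = runif(nb, 0.2, 0.6))
    vm <- void_map(frame, probe_radius = 1.1, grid)
    oracle <- brute_force_void(frame, 1.1, grid)
    expect_identical(as.vector(unclass(vm)), as.vector(oracle))
  }
})

test_that("empty-pore axis voxels are available, oversized probes are not", {
  g <- tiny_geometry()
  grid <- voxel_grid(g, 0.6)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0))
  vm <- void_map(empty, probe_radius = 2, grid)
  k_mid <- which.min(abs(grid$z))
  i_mid <- which.min(abs(grid$x))
  expect_true(vm[i_mid, which.min(abs(grid$y)), k_mid])
  vm_big <- void_map(empty, probe_radius = g$pore_diameter / 2 + 0.1, grid)
  expect_false(any(vm_big[, , grid$in_membrane]))
})

test_that("nested probes give nested availability", {
  g <- tiny_geometry()
  grid <- voxel_grid(g, 0.6)
  set.seed(8)
  frame <- data.frame(x = runif(30, -4, 4), y = runif(30, -4, 4),
                      z = runif(30, -8, 8), radius = 0.4)
  v1 <- void_map(frame, 0.8, grid)
  v2 <- void_map(frame, 1.6, grid)
  expect_true(all(v1[!v2] | !v2[!v2]))  # available(r2) subset of available(r1)
  expect_true(all(!v2 | v1))
})

test_that("open-pore occupancy matches the annulus formula", {
  g <- pore_geometry(40, membrane_thickness = 30, bulk_margin = 15,
                     lateral_margin = 5)
  tr <- gen_brush(g, brush_config(grafting_density = 0, n_frames = 1,
                                  seed = 1))
  prof <- occupancy_profile(tr, probe_radius = 3)
  memb <- prof$z > g$membrane_z_lo + 1 & prof$z < g$membrane_z_hi - 1
  expect_true(all(abs(prof$occupancy[memb] - (17 / 20)^2) < 0.02))
  bulk <- abs(prof$z) > g$membrane_z_hi + 5
  expect_true(all(prof$occupancy[bulk] >= 0.99))
})

test_that("denser brushes have lower occupancy at every slice", {
  g <- pore_geometry(24, membrane_thickness = 18, bulk_margin = 9,
                     lateral_margin = 5)
  grid <- voxel_grid(g, 0.6)
  sparse <- gen_brush(g, brush_config(grafting_density = 1 / 200,
                                      chain_length = 40, seed = 5))
  dense_cfg <- brush_config(grafting_density = 1 / 100, chain_length = 40,
                            seed = 5)
  dense <- gen_brush(g, dense_cfg)
  # nested configurations: dense = sparse beads plus additional chains
  extra <- dense$frames[[1]]
  combined <- npcmimic:::new_bead_trajectory(
    list(rbind(sparse$frames[[1]], extra)), g, 0.3)
  p_sparse <- occupancy_profile(sparse, 2, grid)
  p_dense <- occupancy_profile(combined, 2, grid)
  expect_true(all(p_dense$occupancy <= p_sparse$occupancy + 1e-12))
})

test_that("Boltzmann inversion has the closed-form properties", {
  z <- seq(-50, 50, by = 1)
  occ <- rep(0.8, length(z))
  occ[50] <- 0.4
  prof <- as_occupancy_profile(z, occ, area = 100,
                               membrane_span = c(-20, 20))
  pmf <- pmf_from_occupancy(prof, reference = "bulk_mean")
  expect_equal(pmf$energy[10], 0, tolerance = 1e-12)
  expect_equal(pmf$energy[50], log(2), tolerance = 1e-12)
  # halving occupancy shifts energies uniformly by log 2
  pmf2 <- pmf_from_occupancy(as_occupancy_profile(z, occ / 2, area = 100,
                                                  membrane_span = c(-20, 20)),
                             reference = "explicit", ref_area = 80)
  expect_equal(pmf2$energy - pmf$energy, rep(log(2), length(z)),
               tolerance = 1e-12)
  # zero occupancy flagged infinite
  occ0 <- occ; occ0[60] <- 0
  pmf0 <- pmf_from_occupancy(as_occupancy_profile(z, occ0, area = 100,
                                                  membrane_span = c(-20, 20)))
  expect_true(is.infinite(pmf0$energy[60]))
  expect_error(pmf_from_occupancy(prof, reference = "explicit",
                                  ref_area = 0), "ref_area")
})

test_that("barrier averaging handles constants, ramps and infinities", {
  z <- seq(-45, 45, by = 1)
  flat <- as_occupancy_profile(z, rep(exp(-2), length(z)), area = 1,
                               membrane_span = c(-45, 45))
  # occupancy exp(-2) against reference area 1 => E = 2 everywhere
  pmf <- pmf_from_occupancy(flat, reference = "explicit", ref_area = 1)
  expect_equal(barrier_energy(pmf, z_range = c(-15, 15)), 2,
               tolerance = 1e-9)
  ramp_occ <- exp(-(z - min(z)) / 45 * 1)  # E rises linearly 0 -> 2
  pmf_r <- pmf_from_occupancy(as_occupancy_profile(z, ramp_occ / max(ramp_occ),
                                                   membrane_span = c(-45, 45)),
                              reference = "explicit", ref_area = 1)
  expect_equal(barrier_energy(pmf_r, z_range = range(z)), 1, tolerance = 0.05)
  inf_occ <- rep(0.5, length(z)); inf_occ[46] <- 0
  pmf_i <- pmf_from_occupancy(as_occupancy_profile(z, inf_occ,
                                                   membrane_span = c(-45, 45)),
                              reference = "explicit", ref_area = 0.5)
  expect_warning(e <- barrier_energy(pmf_i, z_range = c(-5, 5)), "infinite")
  expect_identical(e, Inf)
  expect_error(barrier_energy(pmf, z_range = c(100, 110)), "no PMF slices")
})

test_that("Arrhenius rates and k0 calibration are consistent", {
  expect_equal(arrhenius_rate(0, 4), 4)
  expect_equal(arrhenius_rate(1, 1), exp(-1))
  dE <- seq(0, 5, 0.5)
  expect_true(all(diff(arrhenius_rate(dE, 2)) < 0))
  expect_equal(arrhenius_rate(Inf, 2), 0)
  expect_equal(calibrate_k0(1, 4)$k0, 4)
  expect_equal(calibrate_k0(c(1, 1, 1), c(1, 2, 3))$k0, 2)
  set.seed(2)
  pred <- exp(-runif(6, 0, 2))
  meas <- 0.08 * pred
  expect_lt(abs(calibrate_k0(pred, meas)$k0 - 0.08), 1e-6 * 0.08)
  expect_error(calibrate_k0(numeric(0), numeric(0)), "no open pores")
})

test_that("axi-radial density conserves mass and captures uniform beads", {
  g <- pore_geometry(40, membrane_thickness = 30, bulk_margin = 10,
                     lateral_margin = 10)
  set.seed(6)
  n <- 1e5
  rr <- sqrt(runif(n)) * 15
  th <- runif(n, 0, 2 * pi)
  frame <- data.frame(x = rr * cos(th), y = rr * sin(th),
                      z = runif(n, -10, 10), radius = 0.3)
  tr <- npcmimic:::new_bead_trajectory(list(frame), g, 0.3)
  m <- axiradial_density(tr, residue_mass = 100, r_bin = 3, z_bin = 5)
  # mass conservation: sum(density * volume) = total bead mass
  vol <- outer(pi * diff(m$r_breaks^2), diff(m$z_breaks))
  total <- sum(m$value * vol) / 1.66053906660
  expect_equal(total, n * 100, tolerance = 1e-6)
  # interior bins of the uniform cylinder match N m / V
  expected <- n * 100 * 1.66053906660 / (pi * 15^2 * 20)
  interior <- m$value[m$r < 12, m$z > -8 & m$z < 8]
  expect_true(all(abs(interior - expected) / expected < 0.05))
  empty <- npcmimic:::new_bead_trajectory(
    list(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    radius = numeric(0))), g, 0.3)
  expect_true(all(axiradial_density(empty)$value == 0))
})

test_that("axi-radial void maps are probabilities with sensible structure", {
  g <- tiny_geometry()
  grid <- voxel_grid(g, 0.6)
  empty <- npcmimic:::new_bead_trajectory(
    list(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    radius = numeric(0))), g, 0.3)
  av <- axiradial_void(empty, probe_radius = 1, grid = grid)
  expect_true(all(av$value >= 0 & av$value <= 1, na.rm = TRUE))
  k_mid <- which.min(abs(av$z))
  expect_equal(av$value[1, k_mid], 1)      # axis inside the pore
  expect_equal(av$value[nrow(av$value), k_mid], 0)  # metal slab
  # larger probes are never more available
  set.seed(9)
  frame <- data.frame(x = runif(25, -4, 4), y = runif(25, -4, 4),
                      z = runif(25, -7, 7), radius = 0.4)
  tr <- npcmimic:::new_bead_trajectory(list(frame), g, 0.4)
  a1 <- axiradial_void(tr, 0.8, grid = grid)
  a2 <- axiradial_void(tr, 1.5, grid = grid)
  expect_true(all(a2$value <= a1$value + 1e-12, na.rm = TRUE))
})

test_that("Debye screening constant matches the stated conditions", {
  expect_equal(round(debye_kappa(0.15, 294, 80), 2), 1.27)
  expect_equal(debye_kappa(0, 294, 80), 0)
  expect_equal(debye_kappa(0.4, 300, 80) / debye_kappa(0.1, 300, 80), 2,
               tolerance = 1e-12)
})
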