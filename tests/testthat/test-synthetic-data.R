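test_that("background-only photon counts follow Poisson statistics", {
  cfg <- photon_sim_config(duration = 10, background_rate_per_channel = 1000,
                           event_rate = 0, seed = 42)
  st <- gen_photon_stream(cfg)
  n_red <- sum(st$channels == "red")
  expect_lt(abs(n_red - 1e4), 4 * sqrt(1e4))
  expect_lt(abs(sum(st$channels == "blue") - 1e4), 4 * sqrt(1e4))
  expect_identical(nrow(attr(st, "truth")), 0L)
  expect_true(all(diff(st$ticks) > 0))
  expect_true(all(st$macrotimes >= 0 & st$macrotimes <= st$duration + 1e-6))
  expect_true(all(st$microtimes >= 0 & st$microtimes < cfg$tcspc_window))
})

test_that("ground-truth burst count follows the event-rate Poisson law", {
  cfg <- photon_sim_config(duration = 100, background_rate_per_channel = 100,
                           event_rate = 2, seed = 11)
  st <- gen_photon_stream(cfg)
  expect_lt(abs(nrow(attr(st, "truth")) - 200), 4 * sqrt(200))
})

test_that("photon streams are reproducible from the seed", {
  cfg <- photon_sim_config(duration = 5, seed = 99)
  s1 <- gen_photon_stream(cfg)
  s2 <- gen_photon_stream(cfg)
  expect_identical(s1$ticks, s2$ticks)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$microtimes, s2$microtimes)
  expect_identical(attr(s1, "truth"), attr(s2, "truth"))
})

test_that("burst-free inter-photon times are exponential (KS)", {
  pass <- vapply(1:20, function(s) {
    cfg <- photon_sim_config(duration = 10,
                             background_rate_per_channel = 1000,
                             event_rate = 0, seed = s)
    st <- gen_photon_stream(cfg)
    gaps <- diff(st$macrotimes[st$channels == "red"])
    # macrotimes are clock ticks, so quantization ties are expected
    suppressWarnings(
      stats::ks.test(gaps, "pexp", rate = 1 / mean(gaps))$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("decay microtimes have the configured lifetime and offset", {
  mt <- gen_decay_microtimes(1e5, lifetime = 2.30, irf_offset = 1,
                             window = 25, seed = 5)
  m <- mean(mt - 1)
  expect_gt(m, 2.27)
  expect_lt(m, 2.33)
  expect_gte(gen_decay_microtimes(1, 2.3, irf_offset = 1, seed = 1), 1)
  expect_identical(gen_decay_microtimes(100, 2.3, seed = 7),
                   gen_decay_microtimes(100, 2.3, seed = 7))
  expect_error(gen_decay_microtimes(10, lifetime = -1), "lifetime")
})

test_that("brush chain count matches wall area times grafting density", {
  g <- pore_geometry(50, membrane_thickness = 90)
  cfg <- brush_config(grafting_density = 1 / 300, chain_length = 20, seed = 1)
  tr <- gen_brush(g, cfg)
  expect_equal(nrow(tr$frames[[1]]) / cfg$chain_length,
               round(2 * pi * 25 * 90 / 300))  # 47 chains
  empty <- gen_brush(g, brush_config(grafting_density = 0, seed = 1))
  expect_identical(nrow(empty$frames[[1]]), 0L)
})

test_that("brush bonds have fixed length and beads respect the scaffold", {
  g <- pore_geometry(30, membrane_thickness = 30, bulk_margin = 10)
  cfg <- brush_config(grafting_density = 1 / 100, chain_length = 40,
                      n_frames = 2, seed = 3)
  tr <- gen_brush(g, cfg)
  anchors <- attr(tr, "anchors")
  for (f in tr$frames) {
    coords <- as.matrix(f[, c("x", "y", "z")])
    for (ci in seq_len(nrow(anchors))) {
      idx <- (ci - 1) * cfg$chain_length + seq_len(cfg$chain_length)
      chain <- rbind(as.numeric(anchors[ci, ]), coords[idx, ])
      bl <- sqrt(rowSums(diff(chain)^2))
      expect_true(all(abs(bl - cfg$bond_length) < 1e-9))
    }
    # no bead center within bead_radius of the lumen wall inside the membrane
    inside <- f$z >= g$membrane_z_lo & f$z <= g$membrane_z_hi
    rr <- sqrt(f$x^2 + f$y^2)
    expect_true(all(rr[inside] <= g$pore_diameter / 2 - cfg$bead_radius + 1e-9))
    expect_true(all(abs(f$x) <= g$box_x / 2 & abs(f$y) <= g$box_y / 2 &
                    abs(f$z) <= g$box_z / 2))
  }
  expect_error(gen_brush(g, brush_config(grafting_density = 10, seed = 1)),
               "density too high")
})

test_that("perturbed frames keep constraints while differing from frame 1", {
  g <- pore_geometry(30, membrane_thickness = 30, bulk_margin = 10)
  cfg <- brush_config(grafting_density = 1 / 150, chain_length = 30,
                      n_frames = 3, resample_mode = "perturbed", seed = 8)
  tr <- gen_brush(g, cfg)
  expect_false(identical(tr$frames[[1]], tr$frames[[2]]))
  f <- tr$frames[[3]]
  inside <- f$z >= g$membrane_z_lo & f$z <= g$membrane_z_hi
  expect_true(all(sqrt(f$x^2 + f$y^2)[inside] <=
                    g$pore_diameter / 2 - cfg$bead_radius + 1e-9))
})

test_that("synthetic power profiles decay exponentially and stay ordered", {
  z <- seq(-60, 30, by = 1)
  pp <- gen_power_profiles(z, decay_length = 15, loss_fraction_profile = 0.3,
                           asymmetry_profile = 0.6,
                           total_power_profile = 2)
  i_entrance <- pp$iex[pp$z == 0]
  i_inside <- pp$iex[pp$z == -15]
  expect_equal(i_inside / i_entrance, exp(-1), tolerance = 1e-6)
  expect_true(all(pp$pr_h >= pp$pff_h & pp$pff_h >= pp$pffdet_h &
                  pp$pffdet_h >= 0))
  noloss <- gen_power_profiles(z, 15, loss_fraction_profile = 0)
  expect_equal(noloss$pff_h, noloss$pr_h)
  sym <- gen_power_profiles(z, 15, asymmetry_profile = 0.5)
  expect_equal(sym$pffdet_h, sym$pff_h / 2)
  expect_error(gen_power_profiles(z, 15, loss_fraction_profile = -0.1),
               "loss_fraction")
  expect_error(gen_power_profiles(z, 15, loss_fraction_profile = 1.2),
               "loss_fraction")
})

test_that("rate tables realize the quadratic truth and refit exactly", {
  truth <- rate_model_truth(alpha = 1e-3, r_prot = 4, offset_b = 0,
                            noise_cv = 0, diameters = c(50, 60, 80))
  tb <- gen_rate_dataset(truth, seed = 1)
  expect_equal(tb$normalized_rate[tb$diameter == 50], 1e-3 * 21^2)
  fit <- fit_quadratic(tb, r_prot = 4)
  expect_equal(fit$alpha, 1e-3, tolerance = 1e-12)
  t2 <- gen_rate_dataset(truth, seed = 5)
  t3 <- gen_rate_dataset(truth, seed = 5)
  expect_identical(t2, t3)
  expect_error(rate_model_truth(1e-3, 4, 0, 0, diameters = numeric(0)),
               "empty")
  expect_error(rate_model_truth(1e-3, 4, 22, 0, diameters = c(50)),
               "exceed")
})
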