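test_that("normalization divides by concentration, labeling and fraction", {
  er <- event_rate(100, 10)  # 10 Hz
  cond <- measurement_condition(conc_bsa = 500, conc_kap = 100,
                                dol_bsa = 1, dol_kap = 0.7)
  expect_equal(normalize_event_rate(er, cond, "Kap95")$k, 10 / (100 * 0.7),
               tolerance = 1e-12)
  cond2 <- measurement_condition(conc_bsa = 500, labeled_fraction = 0.2)
  expect_equal(normalize_event_rate(er, cond2, "BSA")$k, 0.1)
  expect_equal(normalize_event_rate(event_rate(0, 10), cond, "BSA")$k, 0)
  expect_error(normalize_event_rate(er, measurement_condition(), "Kap95"),
               "zero")
  # 5% flow reduction correction scales rate and error alike
  nr <- normalize_event_rate(er, cond, "Kap95", flow_correction = 1 / 0.95)
  expect_equal(nr$k / normalize_event_rate(er, cond, "Kap95")$k, 1 / 0.95)
})

test_that("per-pore aggregation and selectivity propagate errors", {
  ag <- aggregate_pore(c(1, 2, 3))
  expect_equal(ag$mean, 2)
  expect_equal(ag$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(aggregate_pore(5)$sem, 0)
  expect_equal(aggregate_pore(c(2, 2, 2))$sem, 0)
  s <- selectivity_ratio(2, 4, 0.2, 0.4)
  expect_equal(s$ratio, 0.5)
  expect_equal(s$err, 0.5 * sqrt(0.01 + 0.01), tolerance = 1e-9)
  expect_equal(selectivity_ratio(3, 3)$err, 0)
  expect_equal(selectivity_ratio(6.3 * 0.1, 0.1)$ratio, 6.3)
  expect_error(selectivity_ratio(1, 0), "BSA")
})

test_that("error propagation matches a Monte Carlo oracle", {
  # 3-condition fixture: ratio of two means with independent Gaussian errors
  set.seed(77)
  k_kap <- 0.12; e_kap <- 0.008
  k_bsa <- 0.030; e_bsa <- 0.002
  prop <- selectivity_ratio(k_kap, k_bsa, e_kap, e_bsa)$err
  sims <- rnorm(1e4, k_kap, e_kap) / rnorm(1e4, k_bsa, e_bsa)
  expect_lt(abs(prop - sd(sims)) / sd(sims), 0.1)
  # kap-dependence ratio errors against the same oracle
  tab <- data.frame(pore_id = "p1", diameter = 100, k_bsa_0 = 0.05,
                    k_bsa_100 = 0.06, k_bsa_1000 = 0.08,
                    sem_0 = 0.004, sem_100 = 0.005, sem_1000 = 0.006)
  kd <- kap_dependence(tab)
  sims2 <- rnorm(1e4, 0.08, 0.006) / rnorm(1e4, 0.05, 0.004)
  expect_lt(abs(kd$per_pore$ratio_1000_err - sd(sims2)) / sd(sims2), 0.1)
})

test_that("Fick rates scale with area and reproduce the worked value", {
  k <- fick_rate(D = 1e-10, r = 25e-9, L = 90e-9,
                 delta_c = nM_to_per_m3(100))
  expect_equal(k, 131.4, tolerance = 2e-3)
  expect_equal(fick_rate(1e-10, 0, 90e-9, 1), 0)
  expect_equal(fick_rate(1e-10, 50e-9, 90e-9, 1) /
                 fick_rate(1e-10, 25e-9, 90e-9, 1), 4)
  expect_error(fick_rate(-1, 1, 1, 1), "D")
})

test_that("quadratic fit recovers alpha exactly and from single points", {
  truth <- rate_model_truth(1e-3, 4, 0, 0, diameters = seq(30, 100, 10))
  fit <- fit_quadratic(gen_rate_dataset(truth), r_prot = 4)
  expect_equal(fit$alpha, 1e-3, tolerance = 1e-12)
  one <- data.frame(radius = 5, normalized_rate = 1, sem = 0)
  expect_equal(fit_quadratic(one, r_prot = 4)$alpha, 1)
  expect_error(fit_quadratic(data.frame(radius = 2, normalized_rate = 1,
                                        sem = 0), r_prot = 4), "r_prot")
})

test_that("offset quadratic fit is exact on noiseless data and nests", {
  truth <- rate_model_truth(1e-3, 4, 11.5, 0, diameters = seq(40, 150, 10))
  fit <- fit_offset_quadratic(gen_rate_dataset(truth), r_prot = 4)
  expect_lt(abs(fit$alpha - 1e-3) / 1e-3, 1e-6)
  expect_lt(abs(fit$offset_b - 11.5) / 11.5, 1e-6)
  # b = 0 data reduce exactly to the plain quadratic fit
  t0 <- rate_model_truth(2e-3, 4, 0, 0, diameters = seq(30, 100, 10))
  tb <- gen_rate_dataset(t0)
  f0 <- fit_offset_quadratic(tb, r_prot = 4)
  fq <- fit_quadratic(tb, r_prot = 4)
  expect_equal(f0$offset_b, 0)
  expect_lt(abs(f0$alpha - fq$alpha), 1e-9)
})

test_that("offset fit recovers noisy parameters within stated errors", {
  hits <- vapply(1:50, function(s) {
    truth <- rate_model_truth(1e-3, 4, 10, noise_cv = 0.15,
                              diameters = seq(40, 150, length.out = 20))
    fit <- fit_offset_quadratic(gen_rate_dataset(truth, seed = s),
                                r_prot = 4)
    abs(fit$offset_b - 10) <= 3 * fit$offset_b_sd
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Kap95-dependence ratios and class averages behave", {
  tab <- data.frame(pore_id = c("a", "b", "c", "d"),
                    diameter = c(40, 45, 70, 90),
                    k_bsa_0 = c(1, 1, 1, 1),
                    k_bsa_100 = c(1, 1, 1, 1),
                    k_bsa_1000 = c(1, 1, 1.6, 1.6))
  kd <- kap_dependence(tab)
  expect_equal(kd$per_pore$ratio_1000[3], 1.6)
  expect_equal(kd$per_pore$ratio_100, rep(1, 4))
  large <- kd$by_class[kd$by_class$class == "large", ]
  expect_equal(large$ratio_1000, 1.6)
  expect_error(kap_dependence(tab[, -3]), "missing columns")
  # injected 1.6x increase above 60 nm recovered within 2 SE on noisy data
  set.seed(12)
  nz <- data.frame(pore_id = sprintf("p%d", 1:12),
                   diameter = rep(c(40, 80), each = 6))
  base <- runif(12, 0.5, 1.5)
  nz$k_bsa_0 <- base * (1 + 0.05 * rnorm(12))
  nz$k_bsa_100 <- base * (1 + 0.05 * rnorm(12))
  nz$k_bsa_1000 <- base * ifelse(nz$diameter >= 60, 1.6, 1) *
    (1 + 0.05 * rnorm(12))
  kd2 <- kap_dependence(nz)
  lg <- kd2$by_class[kd2$by_class$class == "large", ]
  expect_lt(abs(lg$ratio_1000 - 1.6), 2 * lg$ratio_1000_sem + 0.05)
})

test_that("selective-area model has the stated limits and monotonicity", {
  expect_equal(selective_area_fraction(12, 6), 1)
  expect_equal(selective_area_fraction(10, 0), 0)
  expect_equal(selective_area_fraction(24, 6), 0.5)
  expect_equal(apparent_selectivity(1, 6, 0.7), 6)
  expect_equal(apparent_selectivity(0, 6, 0.7), 0.7)
  expect_equal(apparent_selectivity(0.5, 6, 0.7),
               1 / (0.5 / 6 + 0.5 / 0.7), tolerance = 1e-9)
  f <- seq(0, 1, 0.05)
  s <- apparent_selectivity(f, 6, 0.7)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0.7 & s <= 6))
  s_arith <- apparent_selectivity(0.5, 6, 0.7, mixing = "arithmetic")
  expect_equal(s_arith, 3.35)
})

test_that("sigma_v is recovered from synthetic selectivity curves", {
  d <- seq(60, 160, by = 10)
  s_true <- apparent_selectivity(selective_area_fraction(d / 2, 6), 6, 0.7)
  fit <- fit_sigmaV(d, s_true, s_sel = 6, s_open = 0.7)
  expect_lt(abs(fit$sigma_v - 6) / 6, 1e-6)
  expect_warning(
    flat <- fit_sigmaV(d, rep(0.7, length(d)), s_sel = 6, s_open = 0.7),
    "degenerate")
  expect_equal(flat$sigma_v, 0)
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    d10 <- seq(60, 150, length.out = 10)
    s_t <- apparent_selectivity(selective_area_fraction(d10 / 2, 12), 6, 0.7)
    obs <- s_t * (1 + 0.2 * rnorm(10))
    f <- fit_sigmaV(d10, obs, err = 0.2 * s_t, s_sel = 6, s_open = 0.7)
    abs(f$sigma_v - 12) <= 3 * f$sigma_v_sd
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("open-pore selectivity rises monotonically toward the D ratio", {
  r <- seq(10, 500, by = 5)
  s <- fick_selectivity(r)
  expect_true(all(diff(s) > 0))
  expect_lt(abs(tail(s, 1) - 3.4 / 4.5), 0.01)
  expect_true(all(s < 3.4 / 4.5))
})
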