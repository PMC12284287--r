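test_that("flat noisy followers are not called connected", {
  set.seed(21)
  tt <- seq(0, 600, by = 0.05)
  spk <- 100 + (0:7) * 50
  for (i in 1:5) {
    sw <- new_sweep(tt, -70 + rnorm(length(tt), 0, 0.2 / sqrt(20)),
                    rep(0, length(tt)), 20000)
    expect_false(detect_connection(sw, spk)$connected)
  }
})

test_that("injected IPSPs are detected with amplitude and latency", {
  k <- list(A1 = 2, tau_rise = 1.5, tau1 = 15, tau2 = 60, w2 = 0.25)
  d <- list(U = 1, tau_rec = 0)  # flat train of 2 mV IPSPs
  sim <- simulate_ipsp_train(k, d, noise_sd = 0.1, n_sweeps = 20,
                             rng_seed = 12)
  # driver spikes 1 ms before each pulse: ground-truth latency 1 ms
  r <- detect_connection(sim$sweep, sim$ground_truth$pulse_times - 1)
  expect_true(r$connected)
  expect_equal(r$amplitude_mV, 2, tolerance = 0.1)
  expect_lt(abs(r$latency_ms - 1), 1)
})

test_that("acausal deflections are rejected by the latency gate", {
  k <- list(A1 = 2, tau_rise = 1.5, tau1 = 15, tau2 = 60, w2 = 0.25)
  sim <- simulate_ipsp_train(k, list(U = 0.5, tau_rec = 200), noise_sd = 0)
  # pretend the driver fired 4 ms after each IPSP onset
  r <- detect_connection(sim$sweep, sim$ground_truth$pulse_times + 4)
  expect_false(r$connected)
})

test_that("gap junction coefficient is the steady-state deflection ratio", {
  # pure arithmetic: driver -15 mV, follower -0.75 mV
  drv <- flat_step_sweep(-150, -15, duration_ms = 500, pre_ms = 200,
                         post_ms = 100)
  fol <- flat_step_sweep(0, 0, duration_ms = 500, pre_ms = 200, post_ms = 100)
  fol$voltage <- -70 + ifelse(drv$current != 0, -0.75, 0)
  g <- gap_junction_test(drv, fol)
  expect_equal(g$coupling_coefficient, 0.05, tolerance = 1e-9)
  # flat follower: not coupled
  fol0 <- flat_step_sweep(0, 0, duration_ms = 500, pre_ms = 200,
                          post_ms = 100)
  set.seed(4)
  fol0$voltage <- fol0$voltage + rnorm(length(fol0$voltage), 0, 0.02)
  g0 <- gap_junction_test(drv, fol0)
  expect_false(g0$coupled)
  expect_lt(g0$coupling_coefficient, 0.005)
  # driver deflection under 1 mV invalidates the test
  weak <- flat_step_sweep(-150, -0.5, duration_ms = 500, pre_ms = 200,
                          post_ms = 100)
  expect_false(gap_junction_test(weak, fol)$valid)
})

test_that("a resistively coupled pair is recovered within 10%", {
  set.seed(9)
  g_c <- 0.45  # nS; theoretical cc ~ 0.051 with R2 = 120 MOhm
  pair <- simulate_coupled_pair(g_c = g_c, noise_sd = 0.2)
  cc_true <- coupled_pair_cc(120, 120, g_c)
  g <- gap_junction_test(pair$driver, pair$follower)
  expect_true(g$valid)
  expect_true(g$coupled)
  expect_equal(g$coupling_coefficient, cc_true, tolerance = 0.1 * cc_true)
})

test_that("connectivity tallies reproduce the recorded pair arithmetic", {
  pairs <- data.frame(
    category = c(rep("pv_pv", 166), rep("nkx_nkx", 182)),
    connected = c(rep(TRUE, 1), rep(FALSE, 165), rep(TRUE, 3),
                  rep(FALSE, 179)))
  s <- connectivity_summary(pairs)
  proto <- s[s$category == "prototypic_pooled", ]
  expect_equal(proto$n_pairs, 348)
  expect_equal(proto$n_connected, 4)
  expect_equal(proto$percent_2dp, 1.15)
  pv <- s[s$category == "pv_pv", ]
  expect_equal(pv$percent_1dp, 0.6)
  # conservation: category counts sum to the total
  cats <- s[s$category %in% c("pv_pv", "nkx_nkx", "foxp2_foxp2", "mixed",
                              "electrical"), ]
  expect_equal(sum(cats$n_pairs), s$n_pairs[s$category == "total"])
  # recomputing percentages from counts reproduces them exactly
  expect_equal(proto$percent, 100 * proto$n_connected / proto$n_pairs)
})

test_that("empty input produces zero counts with undefined percentages", {
  s <- connectivity_summary(data.frame(category = character(0),
                                       connected = logical(0)))
  expect_true(all(s$n_pairs == 0))
  expect_true(all(is.na(s$percent)))
  expect_error(connectivity_summary(data.frame(category = "x",
                                               connected = TRUE)),
               "unknown pair categories")
})

test_that("cohort pair draws follow the Bernoulli design", {
  # p_connect = 0: no connections anywhere downstream
  co0 <- generate_cohort(c(prototypic_PV = 8, arkypallidal = 8),
                         p_connect = list(proto_proto = 0, other = 0),
                         rng_seed = 2, make_morphology = FALSE,
                         protocols = character(0))
  pt0 <- cohort_pair_tests(co0)
  expect_false(any(pt0$connected))
  expect_false(any(pt0$coupled))
  # p = 1: every prototypic pair flagged connected on low-noise sweeps
  co1 <- generate_cohort(c(prototypic_PV = 6),
                         p_connect = list(proto_proto = 1, other = 0),
                         rng_seed = 3, noise_sd = 0.1,
                         make_morphology = FALSE, protocols = character(0))
  pt1 <- cohort_pair_tests(co1)
  expect_true(all(pt1$connected))
  expect_true(all(pt1$latency_ms < 3))
})
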