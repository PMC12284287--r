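test_that("AP detection finds pasted spikes and nothing on flat traces", {
  flat <- flat_step_sweep(0, 0)
  expect_length(detect_aps(flat), 0)

  p <- fixed_cell(spont_rate = 12)
  sim <- simulate_sweep(p, stim_zero(1000), noise_sd = 0, rng_seed = 4)
  peaks <- detect_aps(sim$sweep)
  gt <- sim$ground_truth$spike_times
  expect_equal(length(peaks), length(gt))
  expect_true(all(abs(sim$sweep$time[peaks] - gt) <= 0.2))
})

test_that("detections within the refractory window merge into one", {
  # two rectangular depolarizations 1 ms apart
  sw <- pulse_train_sweep(c(100, 101), 300, width_ms = 0.5)
  expect_length(detect_aps(sw), 1)
  # 5 ms apart: two distinct spikes
  sw2 <- pulse_train_sweep(c(100, 105), 300, width_ms = 0.5)
  expect_length(detect_aps(sw2), 2)
})

test_that("ramp threshold recovers the generator threshold", {
  p <- fixed_cell(g_h = 0)
  rh <- (p$V_T + 70) * 1000 / p$R_in
  ramp <- simulate_sweep(p, stim_ramp(2 * rh / 1000, 1000), noise_sd = 0)$sweep
  thr <- threshold_from_ramp(ramp)
  expect_equal(as.numeric(thr), p$V_T, tolerance = 0.5)
  # subthreshold ramp: flagged missing
  sub <- simulate_sweep(p, stim_ramp(0.3 * rh / 1000, 1000), noise_sd = 0)$sweep
  expect_true(is.na(threshold_from_ramp(sub)))
  expect_identical(attr(threshold_from_ramp(sub), "flag"), "no_ap")
  # a stricter criterion can only move the threshold up
  expect_gte(as.numeric(threshold_from_ramp(ramp, 20)), as.numeric(thr))
})

test_that("rheobase is the smallest spiking step", {
  p <- fixed_cell(g_h = 0)
  rh <- (p$V_T + 70) * 1000 / p$R_in   # analytic, long-step limit
  amps <- seq(round(rh) - 60, round(rh) + 60, by = 20)
  sweeps <- lapply(amps, function(a)
    simulate_sweep(p, stim_step(a, 1000), noise_sd = 0)$sweep)
  est <- rheobase_from_steps(sweeps)
  expect_lte(abs(est - rh), 20)  # within one step increment
  # all subthreshold: missing
  subs <- lapply(c(-50, 20, 60), function(a)
    simulate_sweep(p, stim_step(a, 1000), noise_sd = 0)$sweep)
  expect_true(is.na(rheobase_from_steps(subs)))
})

test_that("input resistance comes from the steady-state I-V slope", {
  p <- fixed_cell(g_h = 0)
  amps <- c(-150, -100, -50, 50, 100)
  sweeps <- lapply(amps, function(a)
    simulate_sweep(p, stim_step(a, 1000), noise_sd = 0)$sweep)
  ir <- input_resistance(sweeps)
  expect_equal(ir$R_in_MOhm, p$R_in, tolerance = 0.001)
  expect_equal(ir$r_squared, 1, tolerance = 1e-9)
  # noisy recovery within 5%
  noisy <- lapply(c(-150, -100, -75, -50, -25, 25, 50), function(a)
    simulate_sweep(p, stim_step(a, 1000), noise_sd = 0.5, rng_seed = a + 200)$sweep)
  expect_equal(input_resistance(noisy)$R_in_MOhm, p$R_in, tolerance = 0.05)
  # spiking sweeps are excluded, not contaminating
  spiking <- simulate_sweep(p, stim_step(600, 1000), noise_sd = 0)$sweep
  ir2 <- input_resistance(c(sweeps, list(spiking)))
  expect_equal(ir2$R_in_MOhm, ir$R_in_MOhm)
  expect_equal(ir2$n_used, length(sweeps))
})

test_that("rectification index is 1 for ohmic cells and < 1 with sag", {
  p <- fixed_cell(g_h = 0)
  amps <- c(-200, -150, -50, 50)
  sweeps <- lapply(amps, function(a)
    simulate_sweep(p, stim_step(a, 1000), noise_sd = 0)$sweep)
  expect_equal(rectification_index(sweeps), 1, tolerance = 1e-6)
  # order invariance
  expect_equal(rectification_index(rev(sweeps)), rectification_index(sweeps))
  ph <- fixed_cell("arkypallidal", seed = 2, g_h = 4)
  sw <- lapply(amps, function(a)
    simulate_sweep(ph, stim_step(a, 1000), noise_sd = 0)$sweep)
  expect_lt(rectification_index(sw), 1)
  expect_true(is.na(rectification_index(sweeps[1:2])))
})

test_that("capacitance is tau over R", {
  p <- fixed_cell(g_h = 0)   # C_m 100 pF, R_in 120 MOhm
  sweeps <- lapply(c(-40, -25), function(a)
    simulate_sweep(p, stim_step(a, 1000), noise_sd = 0)$sweep)
  expect_equal(capacitance(sweeps), p$C_m, tolerance = 0.02)
  # pure arithmetic: synthetic exponential relaxation, R = 100, tau = 10
  tt <- seq(0, 1300, by = 0.05)
  on <- tt >= 200 & tt < 1200
  v <- rep(-70, length(tt))
  v[on] <- -70 - 5 * (1 - exp(-(tt[on] - 200) / 10))  # -50 pA * 100 MOhm
  sw <- new_sweep(tt, v, ifelse(on, -50, 0), 20000, protocol_id = "step",
                  stim = list(kind = "step", amplitude_pA = -50,
                              onset_ms = 200, offset_ms = 1200))
  expect_equal(capacitance(list(sw)), 100, tolerance = 0.01)
  # heavy sag: documented bias, but still positive
  ph <- fixed_cell("arkypallidal", seed = 2, g_h = 6)
  swh <- lapply(c(-40, -25), function(a)
    simulate_sweep(ph, stim_step(a, 1000), noise_sd = 0)$sweep)
  expect_gt(capacitance(swh), 0)
})

test_that("AP waveform metrics match piecewise-linear geometry exactly", {
  # triangle AP: threshold -40, peak +20, 1 ms rise, 2 ms fall
  dt <- 0.05
  tt <- seq(0, 60, by = dt)
  v <- rep(-70, length(tt))
  ramp_up <- tt >= 10 & tt < 20          # slow approach to threshold
  v[ramp_up] <- -70 + 3 * (tt[ramp_up] - 10)
  rise <- tt >= 20 & tt <= 21
  v[rise] <- -40 + 60 * (tt[rise] - 20)
  fall <- tt > 21 & tt <= 23
  v[fall] <- 20 - 30 * (tt[fall] - 21)
  v[tt > 23] <- -40
  sw <- new_sweep(tt, v, rep(0, length(tt)), 1000 / dt)
  pk <- detect_aps(sw)
  expect_length(pk, 1)
  wf <- ap_waveform(sw, pk)
  expect_equal(wf$threshold, -40, tolerance = 0.2)
  expect_equal(wf$amplitude, 60, tolerance = 0.3)
  expect_equal(wf$rise_time, 1, tolerance = dt)
  expect_equal(wf$fall_time, 2, tolerance = dt)
  expect_equal(wf$duration, 3, tolerance = 2 * dt)
  expect_equal(wf$half_width, 2, tolerance = 2 * dt)
  expect_equal(wf$rise_rate, 60, tolerance = 2)
  expect_equal(wf$fall_rate, 30, tolerance = 1)
  expect_equal(wf$fAHP_amplitude, 0, tolerance = 0.01)
})

test_that("waveform features recover the generator template within 3%", {
  for (g in gpe_groups()) {
    p <- fixed_cell(g, seed = 3, g_h = 0)
    rh <- (p$V_T + 70) * 1000 / p$R_in
    sw <- simulate_sweep(p, stim_step(round(1.4 * rh), 1000), noise_sd = 0)$sweep
    pk <- detect_aps(sw)
    expect_gt(length(pk), 1)
    wf <- ap_waveform(sw, pk[1], next_spike_idx = pk[2])
    ap <- p$ap_shape
    expect_equal(wf$amplitude, ap$V_peak - p$V_T, tolerance = 0.03 * wf$amplitude)
    expect_equal(wf$rise_time, ap$t_rise, tolerance = 0.03 * ap$t_rise + 1e-9)
    expect_equal(wf$fall_time, ap$t_fall, tolerance = 0.03 * ap$t_fall)
    expect_equal(wf$fAHP_amplitude, ap$fAHP_depth,
                 tolerance = 0.03 * ap$fAHP_depth)
    expect_equal(wf$fAHP_time, ap$t_fAHP, tolerance = 0.03 * ap$t_fAHP + 0.05)
    # definitional identities, per spike
    expect_equal(wf$duration, wf$rise_time + wf$fall_time, tolerance = 1e-9)
    expect_equal(wf$rise_rate * wf$rise_time, wf$amplitude, tolerance = 1e-9)
    expect_equal(wf$fall_rate * wf$fall_time, wf$amplitude, tolerance = 1e-9)
    expect_lte(wf$half_width, wf$duration)
  }
})

test_that("sag metrics follow the stated arithmetic", {
  # constructed: V_min -110 early, V_steady -95
  sw <- flat_step_sweep(-200, -25, duration_ms = 500, pre_ms = 200,
                        post_ms = 100, v_early_min = -110)
  s <- sag_metrics(sw)
  expect_equal(s$V_min, -110)
  expect_equal(s$V_steady, -95)
  expect_equal(s$sag_amplitude, 15)
  expect_equal(s$sag_ratio, 110 / 95, tolerance = 1e-12)
  expect_true(is.na(sag_metrics(flat_step_sweep(0, 0))$sag_ratio))
})

test_that("spontaneous rate is total spikes over total duration", {
  sweeps <- lapply(1:3, function(k)
    pulse_train_sweep(seq(500, 29500, length.out = 15), 30000))
  sp <- spontaneous_rate(sweeps)
  expect_equal(sp$rate_hz, 45 / 90)
  expect_true(sp$is_firing)
  silent <- list(pulse_train_sweep(numeric(0), 30000))
  sp0 <- spontaneous_rate(silent)
  expect_equal(sp0$rate_hz, 0)
  expect_false(sp0$is_firing)
})

test_that("discharge frequency and f-I slope follow their definitions", {
  mk <- function(n_ap, amp, dur = 1000) {
    sw <- pulse_train_sweep(if (n_ap > 0) seq(250, 150 + dur,
                                              length.out = n_ap)
                            else numeric(0), dur + 400)
    sw$stim <- list(kind = "step", amplitude_pA = amp, onset_ms = 200,
                    offset_ms = 200 + dur)
    sw
  }
  # 10 APs in a 500 ms top step -> 20 Hz
  fi <- discharge_frequencies(list(mk(10, 300, dur = 500)))
  expect_equal(fi$highest_hz, 20)
  # exact regression over the spiking steps: {0,5,10,15} Hz at 1 s steps
  sweeps <- Map(function(f, a) mk(f, a), c(0, 5, 10, 15),
                c(100, 150, 200, 250))
  fi2 <- discharge_frequencies(sweeps)
  expect_equal(fi2$fI_slope_hz_per_pA, 0.1, tolerance = 1e-9)
  expect_equal(fi2$highest_hz, 15)
  # highest frequency non-decreasing in top step amplitude (generator)
  p <- fixed_cell(g_h = 0)
  rh <- (p$V_T + 70) * 1000 / p$R_in
  tops <- c(1.5, 2, 2.5, 3) * rh
  freqs <- vapply(tops, function(a) {
    sw <- simulate_sweep(p, stim_step(a, 1000), noise_sd = 0)$sweep
    discharge_frequencies(list(sw))$highest_hz
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("phase plots pair V with its derivative without resampling", {
  dt <- 0.05
  tt <- seq(0, 50, by = dt)
  sw <- new_sweep(tt, -70 + 2 * tt, rep(0, length(tt)), 1000 / dt,
                  holding_mV = NA_real_)
  pp <- phase_plot(sw)
  expect_equal(nrow(pp), length(tt))
  expect_true(all(abs(pp$dVdt_mV_per_ms - 2) < 1e-9))
  # an AP traces a loop with positive area
  p <- fixed_cell()
  s <- simulate_sweep(p, stim_step(600, 400), noise_sd = 0)$sweep
  pp2 <- phase_plot(s)
  pk <- detect_aps(s)[1]
  i <- (pk - 40):(pk + 80)
  loop <- pp2[i, ]
  area <- sum(diff(loop$V_mV) * (loop$dVdt_mV_per_ms[-1] +
                                   loop$dVdt_mV_per_ms[-nrow(loop)]) / 2)
  expect_gt(abs(area), 0)
})

test_that("sweep tables round-trip through CSV plus JSON sidecar", {
  p <- fixed_cell()
  sw <- simulate_sweep(p, stim_step(-100, 300), noise_sd = 0.2,
                       rng_seed = 1)$sweep
  path <- file.path(tempfile(fileext = ".csv"))
  write_sweep(sw, path)
  back <- read_sweep(path)
  expect_equal(back$voltage, sw$voltage, tolerance = 1e-9)
  expect_equal(back$sampling_rate, sw$sampling_rate)
  expect_equal(back$stim$amplitude_pA, sw$stim$amplitude_pA)
  expect_identical(back$protocol_id, sw$protocol_id)
  # invariants of the sweep container
  expect_warning(new_sweep(0:10, rep(0, 11), rep(0, 11), 5000), "sampling rate")
  expect_error(new_sweep(c(0, 1, 1), rep(0, 3), rep(0, 3), 20000),
               "strictly increasing")
  expect_error(new_sweep(0:2, rep(0, 2), rep(0, 3), 20000), "equal length")
})
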