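# Independent oracles and fixture builders used across the suite.  These are
# deliberately written without reusing the package's internal code paths.

# Brute-force Sholl: densely resample every dendritic segment at 0.1 um and
# count sign changes of (distance-to-center - r), with distance == r resolved
# to the outer side (same tie rule as the analytic implementation).
sholl_bruteforce <- function(m, step = 10) {
  nd <- m$nodes
  soma <- nd[nd$type == 1, ]
  w <- soma$radius / sum(soma$radius)
  ctr <- c(sum(soma$x * w), sum(soma$y * w), sum(soma$z * w))
  pidx <- match(nd$parent, nd$id)
  child <- which(nd$type == 3 & nd$parent != -1)
  seglist <- list()
  maxd <- 0
  for (ci in child) {
    p <- pidx[ci]
    a <- c(nd$x[p], nd$y[p], nd$z[p]) - ctr
    b <- c(nd$x[ci], nd$y[ci], nd$z[ci]) - ctr
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len / 0.1) + 1))
    d <- sqrt(colSums((outer(a, rep(1, length(ts))) + outer(b - a, ts))^2))
    seglist[[length(seglist) + 1]] <- d
    maxd <- max(maxd, d)
  }
  radii <- seq(step, ceiling(maxd / step) * step, by = step)
  ints <- vapply(radii, function(r) {
    sum(vapply(seglist, function(d) {
      s <- d < r
      sum(s[-length(s)] != s[-1])
    }, numeric(1)))
  }, numeric(1))
  data.frame(radius = radii, intersections = as.integer(ints))
}

# Two-compartment resistively coupled pair (explicit Euler), independent of
# the package's compiled integrator.  Returns driver/follower sweeps for a
# current step injected into cell 1.
simulate_coupled_pair <- function(R1 = 120, C1 = 100, R2 = 120, C2 = 100,
                                  g_c = 0, I_step = -150, dur = 500,
                                  pre = 200, post = 200, dt = 0.05,
                                  EL = -70, noise_sd = 0, n_avg = 20) {
  n <- round((pre + dur + post) / dt)
  tt <- (seq_len(n) - 1) * dt
  I <- ifelse(tt >= pre & tt < pre + dur, I_step, 0)
  v1 <- v2 <- numeric(n)
  v1[1] <- v2[1] <- EL
  for (i in 2:n) {
    ic <- g_c * (v2[i - 1] - v1[i - 1])  # nS * mV = pA
    v1[i] <- v1[i - 1] + dt * (-(v1[i - 1] - EL) * 1000 / R1 + ic +
                                 I[i - 1]) / C1
    v2[i] <- v2[i - 1] + dt * (-(v2[i - 1] - EL) * 1000 / R2 - ic) / C2
  }
  if (noise_sd > 0) {
    v1 <- v1 + stats::rnorm(n, 0, noise_sd / sqrt(n_avg))
    v2 <- v2 + stats::rnorm(n, 0, noise_sd / sqrt(n_avg))
  }
  stim <- list(kind = "gap_step", amplitude_pA = I_step, onset_ms = pre,
               offset_ms = pre + dur)
  list(driver = new_sweep(tt, v1, I, 1000 / dt, protocol_id = "gap_step",
                          stim = stim),
       follower = new_sweep(tt, v2, rep(0, n), 1000 / dt,
                            protocol_id = "gap_follower"))
}

# theoretical steady-state coupling coefficient of the two-compartment pair
coupled_pair_cc <- function(R1, R2, g_c) {
  g1 <- 1000 / R1; g2 <- 1000 / R2  # nS
  g_c / (g2 + g_c) * 1  # V2/V1 at steady state from the follower node balance
}

# a deterministic low-dispersion cell for recovery tests
fixed_cell <- function(group = "prototypic_PV", seed = 1, ...) {
  sample_cell(group, rng_seed = seed,
              overrides = utils::modifyList(
                list(sdlog = 1e-9, v_sd = 1e-9, silent_frac = 0), list(...)))
}

# baseline trace with brief rectangular spikes (to +25 mV) at given times;
# enough structure for detect_aps without the full simulator
pulse_train_sweep <- function(spike_times_ms, duration_ms, dt = 0.05,
                              baseline = -70, width_ms = 1) {
  n <- round(duration_ms / dt)
  tt <- (seq_len(n) - 1) * dt
  v <- rep(baseline, n)
  for (s in spike_times_ms) {
    i <- which(tt >= s & tt < s + width_ms)
    v[i] <- 25
  }
  new_sweep(tt, v, rep(0, n), 1000 / dt, holding_mV = NA_real_,
            protocol_id = "zero_current",
            stim = list(kind = "zero_current", amplitude_pA = 0,
                        onset_ms = 0, offset_ms = duration_ms))
}

# step sweep with a prescribed constant deflection (instant settling), for
# definition-level tests of steady-state measures
flat_step_sweep <- function(amplitude_pA, deflection_mV, duration_ms = 1000,
                            pre_ms = 200, post_ms = 100, baseline = -70,
                            dt = 0.05, v_early_min = NULL) {
  n <- round((pre_ms + duration_ms + post_ms) / dt)
  tt <- (seq_len(n) - 1) * dt
  on <- tt >= pre_ms & tt < pre_ms + duration_ms
  v <- rep(baseline, n)
  v[on] <- baseline + deflection_mV
  if (!is.null(v_early_min)) {
    early <- tt >= pre_ms + 20 & tt <= pre_ms + 60
    v[early] <- v_early_min
  }
  I <- ifelse(on, amplitude_pA, 0)
  new_sweep(tt, v, I, 1000 / dt, protocol_id = "step",
            stim = list(kind = "step", amplitude_pA = amplitude_pA,
                        onset_ms = pre_ms, offset_ms = pre_ms + duration_ms))
}
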