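# Sweep simulator: single-compartment membrane with a hyperpolarization-
# activated sag conductance, integrated with a fixed explicit step (0.05 ms),
# plus template-pasted action potentials so waveform ground truth is exact.

# Piecewise-linear AP template anchored at the threshold crossing:
# V_T -> V_peak over t_rise, back to V_T over t_fall, then down to
# V_T - fAHP_depth over t_fAHP.  Integration resumes from the template end.
ap_template <- function(V_T, ap_shape, dt) {
  tr <- ap_shape$t_rise; tf <- ap_shape$t_fall; ta <- ap_shape$t_fAHP
  tt <- (0:ceiling((tr + tf + ta) / dt - 1e-9)) * dt
  v <- numeric(length(tt))
  rise <- tt <= tr
  v[rise] <- V_T + (ap_shape$V_peak - V_T) * tt[rise] / tr
  fall <- tt > tr & tt <= tr + tf
  v[fall] <- ap_shape$V_peak - (ap_shape$V_peak - V_T) * (tt[fall] - tr) / tf
  ahp <- tt > tr + tf
  v[ahp] <- V_T - ap_shape$fAHP_depth * pmin(1, (tt[ahp] - tr - tf) / ta)
  v
}

# holding current that clamps the resting membrane at V_hold given the sag
# conductance at its steady-state activation
holding_current <- function(params, V_hold) {
  m <- 1 / (1 + exp((V_hold + 80) / 6))
  (V_hold - params$E_L) * 1000 / params$R_in +
    params$g_h * m * (V_hold - params$E_h)
}

#' Simulate a current-clamp sweep with ground truth
#'
#' Integrates the single-compartment equation
#' \deqn{C_m dV/dt = -(V - E_L)/R_{in} - g_h m (V - E_h) + I(t)}
#' with first-order sag activation \eqn{\tau_h dm/dt = m_\infty(V) - m},
#' where \eqn{m_\infty} is a decreasing sigmoid of V (half-activation -80 mV,
#' slope 6 mV), using a fixed explicit step.  When V crosses the threshold
#' \eqn{V_T}, an action-potential template parameterised by the cell's
#' \code{ap_shape} is pasted and V resumes from the fAHP depth.  At zero
#' injected current, spontaneous firing is realised as a jittered periodic
#' spike train (5\% CV) at the cell's \code{spont_rate}.  Gaussian recording
#' noise of SD \code{noise_sd} is added to the voltage after integration, so
#' ground truth stays exact and averaging over sweeps behaves as in the
#' experiment.
#'
#' The cell is held at \code{holding_mV} by a computed holding current except
#' for zero-current protocols, where the holding is released.
#'
#' @param params a \code{cell_params} object.
#' @param stimulus a \code{stimulus_protocol}.
#' @param noise_sd recording noise SD in mV.
#' @param rng_seed optional integer seed.
#' @param dt integration step in ms; must be <= 0.1 (accuracy contract).
#' @param holding_mV holding potential (default -70 mV).
#' @return list with elements \code{sweep} (a \code{\link{new_sweep}} object)
#'   and \code{ground_truth} (template parameters, threshold-crossing and
#'   peak times in ms, the analytic steady-state voltage reached for constant
#'   steps when \code{g_h = 0}).
#' @export
simulate_sweep <- function(params, stimulus, noise_sd = 0, rng_seed = NULL,
                           dt = 0.05, holding_mV = -70) {
  stopifnot(inherits(params, "cell_params"),
            inherits(stimulus, "stimulus_protocol"))
  if (dt > 0.1)
    stopf("integration step %.3f ms exceeds the 0.1 ms accuracy contract", dt)
  with_seed(rng_seed, {
    sc <- stim_current(stimulus, dt)
    n <- length(sc$current)
    zero_protocol <- identical(stimulus$kind, "zero_current")
    I <- sc$current
    V0 <- holding_mV
    if (zero_protocol) {
      V0 <- params$E_L
      hold <- NA_real_
    } else {
      hold <- holding_current(params, holding_mV)
      I <- I + hold
    }
    tmpl <- ap_template(params$V_T, params$ap_shape, dt)
    forced <- integer(0)
    if (zero_protocol && params$spont_rate > 0) {
      period <- 1000 / params$spont_rate
      t_spk <- stats::runif(1, 0, period)
      times <- numeric(0)
      total_ms <- n * dt
      while (t_spk < total_ms) {
        times <- c(times, t_spk)
        t_spk <- t_spk + stats::rnorm(1, period, 0.05 * period)
      }
      forced <- sort(unique(pmax(0L, as.integer(round(times / dt)))))
      forced <- forced[forced < n]
    }
    res <- .integrate_membrane(I, dt, params$E_L, params$R_in, params$C_m,
                               params$g_h, params$tau_h, params$E_h,
                               params$V_T, tmpl, forced, V0,
                               allow_spikes = !zero_protocol)
    v <- res$voltage
    if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
    time <- (seq_len(n) - 1) * dt
    thr_idx <- res$threshold_idx + 1L  # to 1-based
    peak_idx <- thr_idx + round(params$ap_shape$t_rise / dt)
    peak_idx <- peak_idx[peak_idx <= n]
    sweep <- new_sweep(time, v, I, sampling_rate = 1000 / dt,
                       holding_mV = if (zero_protocol) NA_real_ else holding_mV,
                       protocol_id = stimulus$kind, stim = sc$meta,
                       group = params$group)
    gt <- list(cell_params = params,
               spike_threshold_times = time[thr_idx],
               spike_times = time[peak_idx],
               holding_current_pA = hold,
               template = tmpl, dt = dt)
    list(sweep = sweep, ground_truth = gt)
  })
}

# ---- IPSP trains ------------------------------------------------------------

#' Per-pulse amplitudes under the depleting-resource depression rule
#'
#' Resource recursion: \eqn{R_1 = 1}, \eqn{a_n = A_1 U R_n},
#' \eqn{R_{n+1} = 1 - (1 - R_n (1 - U)) \exp(-\Delta t_n / \tau_{rec})}.
#' \code{pulse_times} may be irregular; with \code{U = 1} and
#' \code{tau_rec = Inf} the train fully depletes after the first pulse, and
#' with \code{tau_rec = 0} all amplitudes are equal.
#'
#' @param A1 first-pulse amplitude (mV).
#' @param U release fraction in (0, 1].
#' @param tau_rec recovery time constant (ms); may be \code{Inf} or 0.
#' @param pulse_times pulse times in ms.
#' @return numeric vector of per-pulse amplitudes.
#' @export
ipsp_depletion_amplitudes <- function(A1, U, tau_rec, pulse_times) {
  if (U <= 0 || U > 1) stopf("U must lie in (0, 1]")
  if (tau_rec < 0) stopf("tau_rec must be >= 0")
  np <- length(pulse_times)
  R <- numeric(np)
  R[1] <- 1
  if (np > 1) for (i in seq_len(np - 1)) {
    dtp <- pulse_times[i + 1] - pulse_times[i]
    decay <- if (tau_rec == 0) 0 else exp(-dtp / tau_rec)
    R[i + 1] <- 1 - (1 - R[i] * (1 - U)) * decay
  }
  A1 * U * R
}

# unit-peak synaptic kernel: rise exponential times two-component decay
ipsp_kernel <- function(kernel, t) {
  raw <- function(x) (1 - exp(-x / kernel$tau_rise)) *
    ((1 - kernel$w2) * exp(-x / kernel$tau1) + kernel$w2 * exp(-x / kernel$tau2))
  fine <- seq(0, 10 * kernel$tau_rise + 3 * max(kernel$tau1, kernel$tau2),
              length.out = 4096)
  pk <- max(raw(fine))
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- raw(t[pos]) / pk
  out
}

# time at which the unit kernel peaks (ms after onset)
ipsp_kernel_peak_time <- function(kernel) {
  fine <- seq(0, 10 * kernel$tau_rise + 3 * max(kernel$tau1, kernel$tau2),
              length.out = 4096)
  v <- ipsp_kernel(kernel, fine)
  fine[which.max(v)]
}

#' Simulate a 20 Hz IPSP train with short-term depression
#'
#' Generates the averaged postsynaptic trace of a pulse train: each event is
#' a rise-exponential times a double-exponential decay (unit peak, scaled to
#' the per-pulse amplitude from \code{\link{ipsp_depletion_amplitudes}});
#' events superpose linearly on the holding potential.  With the high-chloride
#' internal solution used in the recordings, IPSPs are depolarising at
#' -70 mV, so amplitudes are positive deflections.  Noise emulates an
#' \code{n_sweeps}-sweep average (SD \code{noise_sd / sqrt(n_sweeps)}).
#'
#' @param kernel list \code{A1} (mV), \code{tau_rise}, \code{tau1},
#'   \code{tau2} (ms), \code{w2} (weight of the slow decay, in [0,1]).
#' @param depression list \code{U} (release fraction), \code{tau_rec} (ms).
#' @param n_pulses,rate number and rate (Hz) of pulses (defaults 8 at 20 Hz).
#' @param noise_sd single-sweep recording noise SD (mV).
#' @param n_sweeps number of sweeps averaged.
#' @param rng_seed optional seed.
#' @param dt sample interval, ms.
#' @param pre_ms,post_ms baseline before the first and after the last pulse.
#' @param holding_mV baseline potential.
#' @return list with \code{sweep} and \code{ground_truth} (pulse times and
#'   exact per-pulse amplitudes).
#' @export
simulate_ipsp_train <- function(kernel, depression, n_pulses = 8, rate = 20,
                                noise_sd = 0, n_sweeps = 1, rng_seed = NULL,
                                dt = 0.05, pre_ms = 100, post_ms = 150,
                                holding_mV = -70) {
  stopifnot(kernel$tau_rise > 0, kernel$tau1 > 0, kernel$tau2 > 0,
            kernel$w2 >= 0, kernel$w2 <= 1, rate > 0, n_pulses >= 1)
  with_seed(rng_seed, {
    pulse_times <- pre_ms + (seq_len(n_pulses) - 1) * 1000 / rate
    amps <- ipsp_depletion_amplitudes(kernel$A1, depression$U,
                                      depression$tau_rec, pulse_times)
    total <- pre_ms + (n_pulses - 1) * 1000 / rate + post_ms
    time <- seq(0, total, by = dt)
    v <- rep(holding_mV, length(time))
    for (i in seq_len(n_pulses))
      v <- v + amps[i] * ipsp_kernel(kernel, time - pulse_times[i])
    if (noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, noise_sd / sqrt(n_sweeps))
    sweep <- new_sweep(time, v, rep(0, length(time)),
                       sampling_rate = 1000 / dt, holding_mV = holding_mV,
                       protocol_id = "ipsp_train",
                       stim = list(kind = "ipsp_train",
                                   pulse_times_ms = pulse_times))
    list(sweep = sweep,
         ground_truth = list(pulse_times = pulse_times, amplitudes = amps,
                             kernel = kernel, depression = depression))
  })
}
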