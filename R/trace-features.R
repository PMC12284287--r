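# Intrinsic electrophysiological feature extraction from current-clamp
# sweeps: AP detection, ramp threshold, rheobase, input resistance,
# rectification, capacitance, AP waveform metrics, sag, spontaneous rate,
# discharge frequency / f-I slope, and phase plots.
#
# Missing-value policy: a feature that cannot be computed is returned as NA
# (often with a "flag" attribute), never silently imputed; downstream
# population analysis drops incomplete rows explicitly.

# centered-difference derivative, one-sided at the boundaries (mV/ms)
raw_derivative <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

# 5-point local-quadratic (Savitzky-Golay) smoothing of the derivative,
# used wherever a noise-robust dV/dt criterion crossing is needed
smoothed_derivative <- function(v, dt) {
  d <- raw_derivative(v, dt)
  k <- c(-3, 12, 17, 12, -3) / 35
  s <- as.numeric(stats::filter(d, k, sides = 2))
  s[is.na(s)] <- d[is.na(s)]
  s
}

#' Detect action potentials in a sweep
#'
#' A spike is an upward crossing of the dV/dt criterion followed by a voltage
#' maximum above 0 mV within 5 ms; detections closer than the 2 ms refractory
#' merge window are merged (first kept).
#'
#' @param sweep a \code{sweep}.
#' @param dvdt_criterion detection criterion in mV/ms (default 10).
#' @return integer vector of AP peak indices (possibly empty), with attribute
#'   \code{onset_idx} giving the criterion-crossing sample of each spike.
#' @export
detect_aps <- function(sweep, dvdt_criterion = 10) {
  dt <- sweep_dt(sweep)
  res <- .detect_peaks(sweep$voltage, dt, dvdt_criterion,
                       win = max(1L, as.integer(round(5 / dt))),
                       merge_win = as.integer(round(2 / dt)))
  structure(res$peaks + 1L, onset_idx = res$onsets + 1L)
}

#' AP threshold from a current ramp
#'
#' The cell's threshold feature: the voltage at the sample where the 5-point
#' smoothed dV/dt crosses the criterion and stays above it up to the first AP
#' peak.
#'
#' @inheritParams detect_aps
#' @return threshold in mV, or NA (flag \code{"no_ap"}) if the ramp stays
#'   subthreshold.
#' @export
threshold_from_ramp <- function(sweep, dvdt_criterion = 10) {
  peaks <- detect_aps(sweep, dvdt_criterion)
  if (!length(peaks))
    return(structure(NA_real_, flag = "no_ap"))
  p <- peaks[1]
  dt <- sweep_dt(sweep)
  s <- smoothed_derivative(sweep$voltage, dt)
  below <- which(s[seq_len(p - 1)] < dvdt_criterion)
  if (!length(below)) return(structure(NA_real_, flag = "no_crossing"))
  j <- max(below) + 1L  # last crossing that stays above criterion until peak
  structure(sweep$voltage[j], idx = j)
}

step_amplitude <- function(sweep) {
  if (is.null(sweep$stim) || is.null(sweep$stim$amplitude_pA))
    stopf("sweep lacks step stimulus metadata")
  sweep$stim$amplitude_pA
}

#' Rheobase from an ascending step family
#'
#' The smallest step amplitude whose sweep contains at least one detected AP.
#'
#' @param step_sweeps list of step \code{sweep}s.
#' @param dvdt_criterion AP detection criterion (mV/ms).
#' @return rheobase in pA, or NA (flag \code{"no_spiking_step"}).
#' @export
rheobase_from_steps <- function(step_sweeps, dvdt_criterion = 10) {
  amps <- vapply(step_sweeps, step_amplitude, numeric(1))
  spikes <- vapply(step_sweeps,
                   function(s) length(detect_aps(s, dvdt_criterion)) > 0,
                   logical(1))
  if (!any(spikes)) return(structure(NA_real_, flag = "no_spiking_step"))
  min(amps[spikes])
}

steady_state_window <- function(sweep) {
  st <- sweep$stim
  dur <- st$offset_ms - st$onset_ms
  if (dur >= 900) c(st$onset_ms + 800, st$onset_ms + 900)
  else c(st$offset_ms - 0.1 * dur, st$offset_ms)
}

mean_in_window <- function(sweep, w) {
  i <- sweep$time >= w[1] & sweep$time < w[2]
  mean(sweep$voltage[i])
}

#' Input resistance from subthreshold steps
#'
#' Least-squares slope of the steady-state membrane potential (averaged over
#' 0.8--0.9 s of the step for steps of at least 0.9 s, otherwise over the
#' final 10\% of the step) against injected current.  Sweeps containing APs
#' are excluded.
#'
#' @param step_sweeps list of step \code{sweep}s spanning several amplitudes.
#' @param dvdt_criterion AP detection criterion used for the exclusion rule.
#' @return list with \code{R_in_MOhm}, \code{r_squared}, \code{n_used}; NA
#'   fields (flag \code{"insufficient_sweeps"}) with fewer than 3 usable
#'   sweeps.
#' @export
input_resistance <- function(step_sweeps, dvdt_criterion = 10) {
  usable <- Filter(function(s) length(detect_aps(s, dvdt_criterion)) == 0,
                   step_sweeps)
  if (length(usable) < 3)
    return(structure(list(R_in_MOhm = NA_real_, r_squared = NA_real_,
                          n_used = length(usable)),
                     flag = "insufficient_sweeps"))
  I <- vapply(usable, step_amplitude, numeric(1))
  V <- vapply(usable, function(s) mean_in_window(s, steady_state_window(s)),
              numeric(1))
  fit <- stats::lm(V ~ I)
  slope <- unname(stats::coef(fit)[2])      # mV per pA = GOhm
  r2 <- summary(fit)$r.squared
  list(R_in_MOhm = slope * 1000, r_squared = r2, n_used = length(usable))
}

#' Rectification index
#'
#' Ratio of the I-V slope over the two most hyperpolarizing steps to the
#' slope over the two steps bracketing 0 pA (input resistance at
#' hyperpolarized potentials relative to the holding potential); 1 for an
#' ohmic cell, < 1 with inward rectification.
#'
#' @inheritParams input_resistance
#' @return dimensionless index, or NA (flag \code{"insufficient_steps"}).
#' @export
rectification_index <- function(step_sweeps, dvdt_criterion = 10) {
  usable <- Filter(function(s) length(detect_aps(s, dvdt_criterion)) == 0,
                   step_sweeps)
  I <- vapply(usable, step_amplitude, numeric(1))
  o <- order(I)
  usable <- usable[o]; I <- I[o]
  if (length(I) < 4 || sum(I < 0) < 2 || !any(I > 0))
    return(structure(NA_real_, flag = "insufficient_steps"))
  V <- vapply(usable, function(s) mean_in_window(s, steady_state_window(s)),
              numeric(1))
  slope_hyper <- (V[2] - V[1]) / (I[2] - I[1])
  i_neg <- max(which(I < 0)); i_pos <- min(which(I > 0))
  slope_hold <- (V[i_pos] - V[i_neg]) / (I[i_pos] - I[i_neg])
  slope_hyper / slope_hold
}

#' Membrane capacitance from a small step relaxation
#'
#' Fits a single exponential to the voltage relaxation 2--100 ms after the
#' onset of a small (|I| <= 50 pA) AP-free step and reports
#' \eqn{C_m = 1000 \tau_m / R_{in}} (pF, with tau in ms and R in MOhm); R is
#' taken from the same step's steady-state deflection.  Results are averaged
#' over qualifying sweeps.  A large sag conductance biases the fit; the value
#' is still returned.
#'
#' @inheritParams input_resistance
#' @return capacitance in pF, or NA (flag \code{"no_fit"}).
#' @export
capacitance <- function(step_sweeps, dvdt_criterion = 10) {
  small <- Filter(function(s) {
    a <- step_amplitude(s)
    abs(a) <= 50 && a != 0 && length(detect_aps(s, dvdt_criterion)) == 0
  }, step_sweeps)
  if (!length(small)) return(structure(NA_real_, flag = "no_small_step"))
  vals <- numeric(0)
  for (s in small) {
    st <- s$stim
    base <- mean(s$voltage[s$time >= st$onset_ms - 50 & s$time < st$onset_ms])
    vss <- mean_in_window(s, steady_state_window(s))
    R <- (vss - base) / step_amplitude(s) * 1000
    i <- s$time >= st$onset_ms + 2 & s$time <= st$onset_ms + 100
    df <- data.frame(t = s$time[i] - st$onset_ms, v = s$voltage[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vinf + (v0 - vinf) * exp(-t / tau), data = df,
                        start = list(vinf = vss, v0 = base, tau = 20),
                        lower = c(-Inf, -Inf, 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || R <= 0) next
    tau <- stats::coef(fit)[["tau"]]
    vals <- c(vals, 1000 * tau / R)
  }
  if (!length(vals)) return(structure(NA_real_, flag = "no_fit"))
  mean(vals)
}

# linear interpolation of the first downward crossing of `level` after index
# i0; returns the crossing time or NA
first_decay_crossing <- function(time, v, i0, level, i_max = length(v)) {
  idx <- seq(i0, i_max)
  below <- which(v[idx] <= level)
  if (!length(below)) return(NA_real_)
  j <- idx[below[1]]
  if (j == i0) return(time[j])
  t0 <- time[j - 1]; t1 <- time[j]
  v0 <- v[j - 1]; v1 <- v[j]
  if (v1 == v0) return(t1)
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

#' AP waveform features of one spike
#'
#' Implements the waveform definitions used throughout: amplitude = threshold
#' to peak; rise time = threshold to peak time; fall time = peak to the decay
#' recrossing of the threshold voltage; duration = rise + fall; half-width =
#' threshold time to the decay crossing of threshold + amplitude/2 (note this
#' convention differs from the usual width-at-half-maximum); rise/fall rates
#' = amplitude over the respective times; fAHP amplitude = depth of the
#' post-fall voltage minimum below threshold (positive number, minimum taken
#' within 10 ms of the fall point) with fAHP time measured from the fall
#' point; AHP time uses a 50 ms search window.  Crossings are linearly
#' interpolated between samples.
#'
#' @param sweep a \code{sweep}.
#' @param spike_idx AP peak index from \code{\link{detect_aps}}.
#' @param threshold threshold voltage in mV; if NULL, determined locally as
#'   the last upward dV/dt-criterion crossing before the peak.
#' @param dvdt_criterion criterion for the local threshold (mV/ms).
#' @param next_spike_idx peak index of the following spike, if any, to bound
#'   the decay search.
#' @return list of class \code{ap_features}; fields NA with
#'   \code{truncated = TRUE} when the decay never recrosses threshold.
#' @export
ap_waveform <- function(sweep, spike_idx, threshold = NULL,
                        dvdt_criterion = 10, next_spike_idx = NULL) {
  v <- sweep$voltage; time <- sweep$time
  dt <- sweep_dt(sweep)
  n <- length(v)
  i_max <- min(n, spike_idx + round(60 / dt))  # 60 ms decay/AHP horizon
  if (!is.null(next_spike_idx))
    i_max <- min(i_max, max(spike_idx + 1L, next_spike_idx - round(1 / dt)))
  if (is.null(threshold)) {
    lo <- max(1L, spike_idx - round(10 / dt))
    idx <- lo:(spike_idx - 1L)
    d <- (v[idx + 1L] - v[idx]) / dt
    cross <- d >= dvdt_criterion & c(-Inf, d[-length(d)]) < dvdt_criterion
    if (!any(cross)) return(structure(list(), class = "ap_features",
                                      truncated = TRUE))
    j <- idx[max(which(cross))]
    threshold <- v[j]
    t_thr <- time[j]
  } else {
    # first sample before the peak at or above the supplied threshold
    j <- spike_idx
    while (j > 1 && v[j - 1] >= threshold) j <- j - 1
    t_thr <- time[j]
  }
  v_peak <- v[spike_idx]
  t_peak <- time[spike_idx]
  amplitude <- v_peak - threshold
  rise_time <- t_peak - t_thr
  t_fall_x <- first_decay_crossing(time, v, spike_idx, threshold, i_max)
  truncated <- is.na(t_fall_x)
  fall_time <- if (truncated) NA_real_ else t_fall_x - t_peak
  duration <- rise_time + fall_time
  t_half_x <- first_decay_crossing(time, v, spike_idx,
                                   threshold + amplitude / 2, i_max)
  half_width <- if (is.na(t_half_x)) NA_real_ else t_half_x - t_thr
  fahp_amplitude <- fahp_time <- ahp_time <- NA_real_
  if (!truncated) {
    i_fall <- min(i_max, spike_idx + max(0L, ceiling((t_fall_x - t_peak) / dt)))
    in_win <- function(w) {
      i <- seq(i_fall, min(i_max, i_fall + round(w / dt)))
      i <- i[time[i] > t_fall_x & time[i] <= t_fall_x + w]
      if (!length(i)) return(c(NA_real_, NA_real_))
      k <- i[which.min(v[i])]
      c(threshold - v[k], time[k] - t_fall_x)
    }
    f10 <- in_win(10); f50 <- in_win(50)
    fahp_amplitude <- f10[1]; fahp_time <- f10[2]; ahp_time <- f50[2]
  }
  structure(list(threshold = threshold, amplitude = amplitude,
                 duration = duration, half_width = half_width,
                 rise_time = rise_time, fall_time = fall_time,
                 rise_rate = amplitude / rise_time,
                 fall_rate = if (truncated) NA_real_ else amplitude / fall_time,
                 fAHP_amplitude = fahp_amplitude, fAHP_time = fahp_time,
                 AHP_time = ahp_time),
            class = "ap_features", truncated = truncated)
}

#' Sag amplitude and sag ratio from the -200 pA step
#'
#' \code{sag_amplitude} is the steady-state voltage (mean over the final
#' 100 ms of the step) minus the voltage minimum over the first 150 ms of the
#' step (positive when a sag is present).  \code{sag_ratio} is the minimum
#' divided by the steady state on absolute membrane potentials, so with both
#' negative the ratio is >= 1 and equals 1 without a sag conductance (up to
#' the settling of the passive transient).
#'
#' @param sweep the sag-step \code{sweep} (nominally -200 pA, >= 500 ms).
#' @return list \code{sag_amplitude} (mV), \code{sag_ratio}, \code{V_min},
#'   \code{V_steady}; NA (flag \code{"no_step"}) when the sweep carries no
#'   step metadata.
#' @export
sag_metrics <- function(sweep) {
  st <- sweep$stim
  if (is.null(st) || is.null(st$amplitude_pA) || st$amplitude_pA >= 0)
    return(structure(list(sag_amplitude = NA_real_, sag_ratio = NA_real_),
                     flag = "no_step"))
  i_early <- sweep$time >= st$onset_ms & sweep$time <= st$onset_ms + 150
  v_min <- min(sweep$voltage[i_early])
  v_steady <- mean(sweep$voltage[sweep$time >= st$offset_ms - 100 &
                                   sweep$time < st$offset_ms])
  list(sag_amplitude = v_steady - v_min, sag_ratio = v_min / v_steady,
       V_min = v_min, V_steady = v_steady)
}

#' Spontaneous firing rate from zero-current sweeps
#'
#' Total detected APs divided by total recording duration (the acquisition
#' takes three 30 s sweeps; any set of zero-current sweeps is accepted).
#'
#' @param zero_sweeps list of \code{sweep}s at 0 pA.
#' @param dvdt_criterion AP detection criterion.
#' @return list \code{rate_hz}, \code{is_firing}.
#' @export
spontaneous_rate <- function(zero_sweeps, dvdt_criterion = 10) {
  n_ap <- sum(vapply(zero_sweeps,
                     function(s) length(detect_aps(s, dvdt_criterion)),
                     numeric(1)))
  dur_s <- sum(vapply(zero_sweeps,
                      function(s) length(s$time) / s$sampling_rate,
                      numeric(1)))
  rate <- n_ap / dur_s
  list(rate_hz = rate, is_firing = rate > 0)
}

#' Discharge frequency and f-I slope from suprathreshold steps
#'
#' Per-step discharge frequency is the AP count divided by the step duration;
#' the highest discharge frequency is the frequency at the largest injected
#' step, and the f-I slope is the least-squares slope of frequency versus
#' current over the spiking steps.
#'
#' @inheritParams input_resistance
#' @return list \code{highest_hz}, \code{fI_slope_hz_per_pA},
#'   \code{frequencies} (data.frame); NA fields (flag \code{"no_spiking"})
#'   without any spiking step.
#' @export
discharge_frequencies <- function(step_sweeps, dvdt_criterion = 10) {
  amps <- vapply(step_sweeps, step_amplitude, numeric(1))
  freq <- vapply(step_sweeps, function(s) {
    dur_s <- (s$stim$offset_ms - s$stim$onset_ms) / 1000
    length(detect_aps(s, dvdt_criterion)) / dur_s
  }, numeric(1))
  df <- data.frame(current_pA = amps, frequency_hz = freq)[order(amps), ]
  spk <- df$frequency_hz > 0
  if (!any(spk))
    return(structure(list(highest_hz = NA_real_,
                          fI_slope_hz_per_pA = NA_real_, frequencies = df),
                     flag = "no_spiking"))
  highest <- df$frequency_hz[nrow(df)]
  slope <- if (sum(spk) >= 2)
    unname(stats::coef(stats::lm(frequency_hz ~ current_pA,
                                 data = df[spk, ]))[2])
  else NA_real_
  list(highest_hz = highest, fI_slope_hz_per_pA = slope, frequencies = df)
}

#' Phase plot of a sweep
#'
#' Pairs the membrane potential with its centered-difference derivative
#' (one-sided at the boundaries, no resampling); output length equals input
#' length.
#'
#' @param sweep a \code{sweep}.
#' @return data.frame with columns \code{V_mV}, \code{dVdt_mV_per_ms}.
#' @export
phase_plot <- function(sweep) {
  data.frame(V_mV = sweep$voltage,
             dVdt_mV_per_ms = raw_derivative(sweep$voltage, sweep_dt(sweep)))
}
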