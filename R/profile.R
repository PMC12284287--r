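# Assembly of the per-cell intrinsic profile: the 15 features entering the
# population analysis plus the auxiliary properties (capacitance, sag,
# spontaneous rate).

#' The 15 features of the population analysis
#'
#' Column names, in the documented stable order, of the feature matrix:
#' AP amplitude, duration, half-width, rise time, fall time, AHP time, rise
#' rate, fall rate, fAHP, rectification index, threshold, input resistance,
#' rheobase, maximum discharge frequency, f-I slope.
#'
#' @return character vector of 15 feature names.
#' @export
gpe_feature_names <- function() {
  c("ap_amplitude", "ap_duration", "ap_half_width", "ap_rise_time",
    "ap_fall_time", "ahp_time", "ap_rise_rate", "ap_fall_rate",
    "fahp_amplitude", "rectification_index", "threshold",
    "input_resistance", "rheobase", "max_discharge_freq", "fi_slope")
}

#' Extract the intrinsic profile of one cell
#'
#' Runs the full feature battery on a cell's sweep set: ramp threshold, step
#' rheobase / input resistance / rectification / capacitance / f-I, AP
#' waveform means over the spikes of the lowest suprathreshold step
#' (per-spike local thresholds), sag metrics from the -200 pA step, and the
#' spontaneous rate from zero-current sweeps.
#'
#' @param ramp_sweep ramp \code{sweep} (threshold / rheobase context).
#' @param step_sweeps list of step \code{sweep}s (sub- and suprathreshold).
#' @param sag_sweep the -200 pA sag \code{sweep}, or NULL.
#' @param zero_sweeps list of zero-current \code{sweep}s, or NULL.
#' @param cell_id,group labels copied into the row.
#' @param dvdt_criterion AP detection / threshold criterion (mV/ms).
#' @return one-row data.frame with the 15 features of
#'   \code{\link{gpe_feature_names}} plus \code{cell_id}, \code{group},
#'   \code{C_m}, \code{R_in_r2}, \code{sag_amplitude}, \code{sag_ratio},
#'   \code{spont_rate}, \code{is_firing}, \code{fahp_time}.
#' @export
intrinsic_profile <- function(ramp_sweep, step_sweeps, sag_sweep = NULL,
                              zero_sweeps = NULL, cell_id = NA_character_,
                              group = NA_character_, dvdt_criterion = 10) {
  thr <- threshold_from_ramp(ramp_sweep, dvdt_criterion)
  rheo <- rheobase_from_steps(step_sweeps, dvdt_criterion)
  ir <- input_resistance(step_sweeps, dvdt_criterion)
  rect <- rectification_index(step_sweeps, dvdt_criterion)
  cm <- capacitance(step_sweeps, dvdt_criterion)
  fi <- discharge_frequencies(step_sweeps, dvdt_criterion)

  # waveform: spikes of the lowest suprathreshold step
  wf_means <- rep(NA_real_, 9)
  names(wf_means) <- c("amplitude", "duration", "half_width", "rise_time",
                       "fall_time", "ahp_time", "rise_rate", "fall_rate",
                       "fahp_amplitude")
  fahp_time <- NA_real_
  amps <- vapply(step_sweeps, step_amplitude, numeric(1))
  spiking <- which(vapply(step_sweeps, function(s)
    length(detect_aps(s, dvdt_criterion)) > 0, logical(1)))
  if (length(spiking)) {
    s <- step_sweeps[[spiking[which.min(amps[spiking])]]]
    peaks <- detect_aps(s, dvdt_criterion)
    n_wf <- min(length(peaks), 10L)  # average the first spikes of the step
    feats <- lapply(seq_len(n_wf), function(k) {
      ap_waveform(s, peaks[k], dvdt_criterion = dvdt_criterion,
                  next_spike_idx = if (k < length(peaks)) peaks[k + 1] else NULL)
    })
    feats <- Filter(function(f) length(f) && !isTRUE(attr(f, "truncated")),
                    feats)
    if (length(feats)) {
      g <- function(fld) mean(vapply(feats, function(f) f[[fld]], numeric(1)),
                              na.rm = TRUE)
      wf_means <- c(amplitude = g("amplitude"), duration = g("duration"),
                    half_width = g("half_width"), rise_time = g("rise_time"),
                    fall_time = g("fall_time"), ahp_time = g("AHP_time"),
                    rise_rate = g("rise_rate"), fall_rate = g("fall_rate"),
                    fahp_amplitude = g("fAHP_amplitude"))
      fahp_time <- g("fAHP_time")
    }
  }
  sag <- if (is.null(sag_sweep)) list(sag_amplitude = NA_real_,
                                      sag_ratio = NA_real_)
         else sag_metrics(sag_sweep)
  sp <- if (is.null(zero_sweeps) || !length(zero_sweeps))
    list(rate_hz = NA_real_, is_firing = NA)
  else spontaneous_rate(zero_sweeps, dvdt_criterion)

  data.frame(
    cell_id = cell_id, group = group,
    ap_amplitude = wf_means[["amplitude"]],
    ap_duration = wf_means[["duration"]],
    ap_half_width = wf_means[["half_width"]],
    ap_rise_time = wf_means[["rise_time"]],
    ap_fall_time = wf_means[["fall_time"]],
    ahp_time = wf_means[["ahp_time"]],
    ap_rise_rate = wf_means[["rise_rate"]],
    ap_fall_rate = wf_means[["fall_rate"]],
    fahp_amplitude = wf_means[["fahp_amplitude"]],
    rectification_index = as.numeric(rect),
    threshold = as.numeric(thr),
    input_resistance = ir$R_in_MOhm,
    rheobase = as.numeric(rheo),
    max_discharge_freq = fi$highest_hz,
    fi_slope = fi$fI_slope_hz_per_pA,
    C_m = as.numeric(cm),
    R_in_r2 = ir$r_squared,
    sag_amplitude = sag$sag_amplitude,
    sag_ratio = sag$sag_ratio,
    spont_rate = sp$rate_hz,
    is_firing = sp$is_firing,
    fahp_time = fahp_time,
    stringsAsFactors = FALSE
  )
}
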