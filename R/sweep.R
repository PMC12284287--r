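# Sweep container and stimulus protocols.
#
# A sweep is one current-clamp trace: time (ms), membrane potential (mV) and
# injected current (pA) on a common grid, with acquisition metadata.  The
# on-disk dialect is a CSV (time_ms, voltage_mV, current_pA) plus a JSON
# sidecar carrying the metadata.

#' Construct a current-clamp sweep
#'
#' @param time time base in ms, strictly increasing, equally spaced.
#' @param voltage membrane potential in mV.
#' @param current injected current in pA.
#' @param sampling_rate Hz; a warning is raised outside the 10--20 kHz range
#'   typical of the acquisition.
#' @param holding_mV nominal holding potential (a deviation > 5 mV from
#'   -70 mV warns).
#' @param protocol_id label of the stimulus protocol.
#' @param stim optional list describing the step/ramp timing (used by the
#'   feature extractors): fields \code{kind}, \code{amplitude_pA},
#'   \code{onset_ms}, \code{offset_ms}, and protocol-specific extras.
#' @param cell_id,group optional provenance labels.
#' @return an object of class \code{sweep}.
#' @export
new_sweep <- function(time, voltage, current, sampling_rate,
                      holding_mV = -70, protocol_id = "unknown",
                      stim = NULL, cell_id = NA_character_,
                      group = NA_character_) {
  n <- length(time)
  if (length(voltage) != n || length(current) != n)
    stopf("time, voltage and current must have equal length")
  if (n > 1 && any(diff(time) <= 0))
    stopf("time must be strictly increasing")
  if (sampling_rate < 10000 || sampling_rate > 20000)
    warnf("sampling rate %.0f Hz outside the 10-20 kHz acquisition range",
          sampling_rate)
  if (is.finite(holding_mV) && abs(holding_mV - (-70)) > 5)
    warnf("holding potential %.1f mV deviates > 5 mV from -70 mV", holding_mV)
  structure(list(time = as.numeric(time), voltage = as.numeric(voltage),
                 current = as.numeric(current),
                 sampling_rate = sampling_rate, holding_mV = holding_mV,
                 protocol_id = protocol_id, stim = stim,
                 cell_id = cell_id, group = group),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s: %.0f ms at %.0f kHz, V in [%.1f, %.1f] mV\n",
              x$protocol_id, max(x$time), x$sampling_rate / 1000,
              min(x$voltage), max(x$voltage)))
  invisible(x)
}

sweep_dt <- function(sweep) 1000 / sweep$sampling_rate

# ---- stimulus protocols ----------------------------------------------------

#' Stimulus protocol constructors
#'
#' Build the standard current-clamp protocols: current steps (including the
#' -200 pA/500 ms sag step and the -150 pA/500 ms gap-junction step), ramps,
#' zero-current recordings, and 20 Hz suprathreshold pulse trains used to
#' drive presynaptic APs in paired recordings.
#'
#' @param amplitude_pA step amplitude in pA.
#' @param duration_ms step (or ramp / recording) duration in ms.
#' @param pre_ms,post_ms baseline before and after the step, ms.
#' @param slope_pA_per_ms ramp slope.
#' @param pulse_pA,pulse_ms,rate_hz,n_pulses train parameters (defaults: 2 nA,
#'   30 ms pulses at 20 Hz, 8 pulses).
#' @return a list of class \code{stimulus_protocol}.
#' @name stimulus
NULL

#' @rdname stimulus
#' @export
stim_step <- function(amplitude_pA, duration_ms, pre_ms = 200, post_ms = 100) {
  structure(list(kind = "step", amplitude_pA = amplitude_pA,
                 duration_ms = duration_ms, pre_ms = pre_ms, post_ms = post_ms),
            class = "stimulus_protocol")
}

#' @rdname stimulus
#' @export
stim_sag_step <- function(amplitude_pA = -200, duration_ms = 500,
                          pre_ms = 200, post_ms = 300) {
  out <- stim_step(amplitude_pA, duration_ms, pre_ms, post_ms)
  out$kind <- "sag_step"
  out
}

#' @rdname stimulus
#' @export
stim_gap_step <- function(amplitude_pA = -150, duration_ms = 500,
                          pre_ms = 200, post_ms = 300) {
  out <- stim_step(amplitude_pA, duration_ms, pre_ms, post_ms)
  out$kind <- "gap_step"
  out
}

#' @rdname stimulus
#' @export
stim_ramp <- function(slope_pA_per_ms, duration_ms, pre_ms = 100,
                      post_ms = 50) {
  structure(list(kind = "ramp", slope_pA_per_ms = slope_pA_per_ms,
                 duration_ms = duration_ms, pre_ms = pre_ms, post_ms = post_ms),
            class = "stimulus_protocol")
}

#' @rdname stimulus
#' @export
stim_zero <- function(duration_ms = 30000) {
  structure(list(kind = "zero_current", duration_ms = duration_ms),
            class = "stimulus_protocol")
}

#' @rdname stimulus
#' @export
stim_ap_train <- function(pulse_pA = 2000, pulse_ms = 30, rate_hz = 20,
                          n_pulses = 8, pre_ms = 200, post_ms = 300) {
  structure(list(kind = "ap_train", pulse_pA = pulse_pA, pulse_ms = pulse_ms,
                 rate_hz = rate_hz, n_pulses = n_pulses, pre_ms = pre_ms,
                 post_ms = post_ms),
            class = "stimulus_protocol")
}

# current waveform on the simulation grid, plus stim metadata for the sweep
stim_current <- function(protocol, dt) {
  k <- protocol$kind
  if (k %in% c("step", "sag_step", "gap_step")) {
    n_pre <- round(protocol$pre_ms / dt)
    n_on <- round(protocol$duration_ms / dt)
    n_post <- round(protocol$post_ms / dt)
    I <- c(rep(0, n_pre), rep(protocol$amplitude_pA, n_on), rep(0, n_post))
    meta <- list(kind = k, amplitude_pA = protocol$amplitude_pA,
                 onset_ms = n_pre * dt, offset_ms = (n_pre + n_on) * dt)
  } else if (k == "ramp") {
    n_pre <- round(protocol$pre_ms / dt)
    n_on <- round(protocol$duration_ms / dt)
    n_post <- round(protocol$post_ms / dt)
    I <- c(rep(0, n_pre), protocol$slope_pA_per_ms * dt * seq_len(n_on),
           rep(0, n_post))
    meta <- list(kind = k, slope_pA_per_ms = protocol$slope_pA_per_ms,
                 onset_ms = n_pre * dt, offset_ms = (n_pre + n_on) * dt)
  } else if (k == "zero_current") {
    n <- round(protocol$duration_ms / dt)
    I <- rep(0, n)
    meta <- list(kind = k, amplitude_pA = 0, onset_ms = 0,
                 offset_ms = protocol$duration_ms)
  } else if (k == "ap_train") {
    period <- 1000 / protocol$rate_hz
    total <- protocol$pre_ms + (protocol$n_pulses - 1) * period +
      protocol$pulse_ms + protocol$post_ms
    n <- round(total / dt)
    I <- rep(0, n)
    starts <- protocol$pre_ms + (seq_len(protocol$n_pulses) - 1) * period
    for (s in starts) {
      i0 <- round(s / dt) + 1
      i1 <- min(n, round((s + protocol$pulse_ms) / dt))
      I[i0:i1] <- protocol$pulse_pA
    }
    meta <- list(kind = k, amplitude_pA = protocol$pulse_pA,
                 onset_ms = starts[1],
                 offset_ms = starts[length(starts)] + protocol$pulse_ms,
                 pulse_starts_ms = starts, pulse_ms = protocol$pulse_ms)
  } else stopf("unknown stimulus kind '%s'", k)
  list(current = I, meta = meta)
}

# ---- sweep table I/O -------------------------------------------------------

#' Read and write sweep tables
#'
#' Sweeps are stored as a CSV with columns \code{time_ms}, \code{voltage_mV},
#' \code{current_pA} and a JSON sidecar (same path with extension
#' \code{.json}) holding \code{sampling_rate_hz}, \code{protocol},
#' \code{holding_mV}, \code{cell_id}, \code{group} and the stimulus timing.
#'
#' @param sweep a \code{sweep} object.
#' @param path CSV path; the sidecar path is derived by swapping the
#'   extension.
#' @return \code{read_sweep} returns a \code{sweep}; \code{write_sweep}
#'   returns \code{path} invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep"))
  df <- data.frame(time_ms = sweep$time, voltage_mV = sweep$voltage,
                   current_pA = sweep$current)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(sampling_rate_hz = sweep$sampling_rate,
               protocol = sweep$protocol_id,
               holding_mV = sweep$holding_mV,
               cell_id = sweep$cell_id, group = sweep$group,
               stim = sweep$stim)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ms", "voltage_mV", "current_pA")
  if (!all(need %in% names(df)))
    stopf("sweep table must have columns %s", paste(need, collapse = ", "))
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  new_sweep(df$time_ms, df$voltage_mV, df$current_pA,
            sampling_rate = side$sampling_rate_hz,
            holding_mV = side$holding_mV %||% -70,
            protocol_id = side$protocol %||% "unknown",
            stim = side$stim,
            cell_id = side$cell_id %||% NA_character_,
            group = side$group %||% NA_character_)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)
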