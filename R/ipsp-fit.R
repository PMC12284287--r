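# IPSP train quantification: double-exponential decay fitting with
# subtraction of preceding decays, per-pulse amplitudes, and the steady-state
# depression index.

double_exp <- function(t, A, tau1, tau2, w) {
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- A * ((1 - w) * exp(-t[pos] / tau1) + w * exp(-t[pos] / tau2))
  out
}

# light boxcar smoothing for peak picking on noisy residuals (width in ms)
boxcar <- function(v, dt, width_ms) {
  k <- max(1L, round(width_ms / dt))
  if (k <= 1L) return(v)
  s <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- v[is.na(s)]
  s
}

#' Decompose an IPSP train by double-exponential subtraction
#'
#' For each pulse, the fitted decays of all preceding IPSPs are extrapolated
#' into the pulse's window and subtracted; the pulse amplitude is the
#' post-subtraction peak (2--25 ms after the pulse, lightly smoothed) minus
#' the post-subtraction pre-pulse baseline.  Decaying phases are fitted by
#' nonlinear least squares to \eqn{A [(1-w) e^{-t/\tau_1} + w e^{-t/\tau_2}]};
#' the two time constants and the weight are shared across the pulses of a
#' train (fitted on the first IPSP, per-pulse scale refitted linearly), which
#' stabilises the late, small pulses.  On non-convergence the fit falls back
#' to a single exponential and the train is flagged; negative amplitudes are
#' floored at 0 and flagged.
#'
#' @param avg_trace averaged \code{sweep} (the recordings average 5--20
#'   sweeps before quantification).
#' @param pulse_times stimulus pulse times in ms (default taken from the
#'   sweep's stimulus metadata).
#' @param peak_window c(min, max) ms after each pulse searched for the peak.
#' @param baseline_ms span of the pre-pulse baseline window.
#' @param smooth_ms boxcar width for peak picking.
#' @return object of class \code{ipsp_train}: \code{pulse_times},
#'   \code{raw_amplitudes}, \code{normalized_amplitudes}, \code{fit} (tau1,
#'   tau2, w, per-pulse scales and baselines), \code{rmse_mV}, \code{flags}.
#' @export
fit_ipsp_train <- function(avg_trace, pulse_times = NULL,
                           peak_window = c(2, 25), baseline_ms = 2,
                           smooth_ms = 1) {
  stopifnot(inherits(avg_trace, "sweep"))
  if (is.null(pulse_times)) pulse_times <- avg_trace$stim$pulse_times_ms
  if (is.null(pulse_times)) stopf("pulse times are required")
  pulse_times <- sort(as.numeric(pulse_times))
  time <- avg_trace$time; v <- avg_trace$voltage
  dt <- sweep_dt(avg_trace)
  np <- length(pulse_times)
  flags <- character(0)

  pre <- time < pulse_times[1]
  baseline <- if (any(pre)) mean(v[pre]) else v[1]
  resid <- v - baseline
  model <- numeric(length(time))

  amps <- numeric(np); bases <- numeric(np); scales <- numeric(np)
  peak_t <- numeric(np)
  tau1 <- tau2 <- w <- NA_real_

  for (n in seq_len(np)) {
    r <- resid - model
    tn <- pulse_times[n]
    i_base <- time >= tn - baseline_ms & time < tn
    bases[n] <- if (any(i_base)) mean(r[i_base]) else 0
    i_win <- which(time >= tn + peak_window[1] & time <= tn + peak_window[2])
    rs <- boxcar(r, dt, smooth_ms)
    k <- i_win[which.max(rs[i_win])]
    peak_t[n] <- time[k]
    a <- rs[k] - bases[n]
    if (a < 0) {
      a <- 0
      flags <- c(flags, sprintf("negative_amplitude_pulse_%d", n))
    }
    amps[n] <- a

    # decay fit window: just after the peak up to the next pulse (or +45 ms)
    t_end <- if (n < np) pulse_times[n + 1] - 0.5 else tn + 45
    i_fit <- which(time >= peak_t[n] + 3 & time <= t_end)
    if (length(i_fit) < 10 || a <= 0) {
      scales[n] <- 0
      next
    }
    df <- data.frame(t = time[i_fit] - peak_t[n], y = r[i_fit] - bases[n])
    if (n == 1 || is.na(tau1)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * ((1 - w) * exp(-t / tau1) +
                                     w * exp(-t / tau2)),
                          data = df,
                          start = list(A = a, tau1 = 10, tau2 = 80, w = 0.3),
                          lower = c(0, 0.5, 1, 0), upper = c(Inf, 500, 2000, 1),
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) {
        flags <- c(flags, "single_exponential_fallback")
        fit <- tryCatch(
          minpack.lm::nlsLM(y ~ A * exp(-t / tau1), data = df,
                            start = list(A = a, tau1 = 20),
                            lower = c(0, 0.5),
                            control = minpack.lm::nls.lm.control(maxiter = 300)),
          error = function(e) NULL)
        if (is.null(fit)) { scales[n] <- 0; next }
        cf <- stats::coef(fit)
        tau1 <- cf[["tau1"]]; tau2 <- cf[["tau1"]]; w <- 0
        scales[n] <- cf[["A"]]
      } else {
        cf <- stats::coef(fit)
        tau1 <- cf[["tau1"]]; tau2 <- cf[["tau2"]]; w <- cf[["w"]]
        scales[n] <- cf[["A"]]
      }
    } else {
      shape <- (1 - w) * exp(-df$t / tau1) + w * exp(-df$t / tau2)
      scales[n] <- max(0, sum(df$y * shape) / sum(shape^2))
    }
    model <- model + double_exp(time - peak_t[n], scales[n], tau1, tau2, w)
  }

  normalized <- if (amps[1] > 0) amps / amps[1] else {
    flags <- c(flags, "zero_first_amplitude")
    rep(NA_real_, np)
  }
  rmse <- sqrt(mean((resid - model)[time >= pulse_times[1]]^2))
  structure(list(pulse_times = pulse_times, raw_amplitudes = amps,
                 normalized_amplitudes = normalized,
                 fit = list(tau1 = tau1, tau2 = tau2, w = w,
                            scales = scales, baselines = bases,
                            peak_times = peak_t, global_baseline = baseline),
                 rmse_mV = rmse, flags = unique(flags)),
            class = "ipsp_train")
}

#' @export
print.ipsp_train <- function(x, ...) {
  cat(sprintf("<ipsp_train> %d pulses, a1 = %.2f mV, depression index %.2f\n",
              length(x$pulse_times), x$raw_amplitudes[1],
              tryCatch(depression_index(x), error = function(e) NA)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Steady-state depression index of a train
#'
#' Mean of the normalized amplitudes over the final three pulses: 1 for a
#' flat train, 0 after complete depletion.
#'
#' @param train an \code{ipsp_train} (or any list with
#'   \code{normalized_amplitudes} and \code{raw_amplitudes}).
#' @return fraction in [0, ...]; NA (flag \code{"zero_first"}) when the first
#'   amplitude is zero.
#' @export
depression_index <- function(train) {
  norm <- train$normalized_amplitudes
  if (length(train$raw_amplitudes) < 2)
    stopf("depression index needs at least 2 pulses")
  if (is.na(norm[1]) || train$raw_amplitudes[1] <= 0)
    return(structure(NA_real_, flag = "zero_first"))
  np <- length(norm)
  mean(norm[seq(max(1, np - 2), np)])
}
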