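# Paired-recording connectivity: spike-triggered detection of chemical
# connections, gap-junction (electrical coupling) testing, and the
# category-wise connectivity tally.
#
# Detection thresholds (3 x baseline SD of the averaged trace, 0.2 mV floor,
# 1-6 ms post-spike window, causal 10%-rise latency) are configuration, set
# well below the smallest IPSP reported in these recordings (1.2 mV).

#' Detect a chemical connection from a follower's averaged trace
#'
#' Aligns the follower trace on the driver's AP times, averages the aligned
#' deflections (relative to the 2 ms pre-spike baseline of each AP), and
#' declares a connection when the average deflection peaks within 1--6 ms
#' after the APs, exceeds 3 x the baseline noise SD of the averaged trace AND
#' an absolute floor of 0.2 mV, and rises causally (the 10\%-of-peak point
#' falls after the AP).  With the high-chloride internal, IPSPs are
#' depolarizing, so the deflection searched for is positive.
#'
#' @param follower_avg averaged \code{sweep} of the candidate postsynaptic
#'   cell.
#' @param driver_spike_times driver AP times, ms.
#' @param noise_window c(min, max) ms of the pre-stimulus span used for the
#'   baseline SD estimate (default: up to 10 ms before the first AP).
#' @param sd_mult,floor_mV,latency_window detection configuration.
#' @return list \code{connected}, \code{amplitude_mV} (first-pulse amplitude
#'   via \code{\link{fit_ipsp_train}} when connected), \code{latency_ms},
#'   \code{sta_peak_mV}, \code{noise_sd_mV}, \code{reason}.
#' @export
detect_connection <- function(follower_avg, driver_spike_times,
                              noise_window = NULL, sd_mult = 3,
                              floor_mV = 0.2, latency_window = c(1, 6)) {
  stopifnot(inherits(follower_avg, "sweep"), length(driver_spike_times) >= 1)
  time <- follower_avg$time; v <- follower_avg$voltage
  dt <- sweep_dt(follower_avg)
  t0 <- min(driver_spike_times)
  if (is.null(noise_window)) noise_window <- c(0, max(dt, t0 - 10))
  i_noise <- time >= noise_window[1] & time <= noise_window[2]
  noise_sd <- stats::sd(v[i_noise])
  if (!is.finite(noise_sd)) noise_sd <- 0

  # spike-triggered average over a [-6, +6] ms window
  lag <- seq(-6, 6, by = dt)
  segs <- vapply(driver_spike_times, function(s) {
    idx <- round((s + lag) / dt) + 1L
    ok <- idx >= 1 & idx <= length(v)
    seg <- rep(NA_real_, length(lag))
    seg[ok] <- v[idx[ok]]
    base <- mean(v[time >= s - 2 & time < s], na.rm = TRUE)
    seg - base
  }, numeric(length(lag)))
  sta <- rowMeans(segs, na.rm = TRUE)
  sta <- boxcar(sta, dt, 0.5)  # light smoothing stabilises the latency gate

  i_post <- which(lag >= latency_window[1] & lag <= latency_window[2])
  k_peak <- i_post[which.max(sta[i_post])]
  peak <- sta[k_peak]
  result <- function(connected, reason, amplitude = NA_real_,
                     latency = NA_real_) {
    list(connected = connected, amplitude_mV = amplitude,
         latency_ms = latency, sta_peak_mV = peak, noise_sd_mV = noise_sd,
         reason = reason)
  }
  if (!(peak >= sd_mult * noise_sd && peak >= floor_mV))
    return(result(FALSE, "below_threshold"))
  # causality: the 10%-of-peak rise must occur after the AP.  Scan backward
  # from the peak for the last sample still below 10% of the peak.
  pre_peak <- which(lag >= 0 & seq_along(lag) <= k_peak)
  below <- pre_peak[sta[pre_peak] < 0.1 * peak]
  if (!length(below)) return(result(FALSE, "acausal"))
  latency <- lag[max(below) + 1L]
  if (latency <= 0.2 || any(sta[lag < 0] >= peak))
    return(result(FALSE, "acausal"))
  fit <- tryCatch(fit_ipsp_train(follower_avg,
                                 pulse_times = driver_spike_times),
                  error = function(e) NULL)
  amp <- if (!is.null(fit)) fit$raw_amplitudes[1] else peak
  result(TRUE, "connected", amplitude = amp, latency = latency)
}

#' Test for electrical coupling between a recorded pair
#'
#' Applies the gap-junction criterion to simultaneously recorded averaged
#' sweeps: a -150 pA / 500 ms step in the driver, the coupling coefficient is
#' the follower's steady-state deflection (final 100 ms of the step minus the
#' pre-step baseline) divided by the driver's.  The pair is called coupled
#' when the coefficient is at least 0.01 AND the follower deflection is
#' hyperpolarizing and exceeds 3 x its baseline SD.  A driver deflection
#' under 1 mV invalidates the test.
#'
#' @param driver_sweep,follower_sweep simultaneous averaged \code{sweep}s;
#'   the driver carries the step stimulus metadata.
#' @param sd_mult,cc_min criterion configuration.
#' @return list \code{coupling_coefficient}, \code{coupled}, \code{valid},
#'   \code{dV_driver_mV}, \code{dV_follower_mV}.
#' @export
gap_junction_test <- function(driver_sweep, follower_sweep, sd_mult = 3,
                              cc_min = 0.01) {
  st <- driver_sweep$stim
  if (is.null(st) || is.null(st$onset_ms)) stopf("driver sweep lacks step metadata")
  defl <- function(s) {
    base <- mean(s$voltage[s$time >= st$onset_ms - 100 & s$time < st$onset_ms])
    ss <- mean(s$voltage[s$time >= st$offset_ms - 100 & s$time <= st$offset_ms])
    c(ss - base, stats::sd(s$voltage[s$time < st$onset_ms]))
  }
  dd <- defl(driver_sweep); df <- defl(follower_sweep)
  if (abs(dd[1]) < 1)
    return(list(coupling_coefficient = NA_real_, coupled = FALSE,
                valid = FALSE, dV_driver_mV = dd[1], dV_follower_mV = df[1]))
  cc <- df[1] / dd[1]
  coupled <- is.finite(cc) && cc >= cc_min && df[1] < 0 &&
    abs(df[1]) >= sd_mult * df[2]
  list(coupling_coefficient = max(0, cc), coupled = coupled, valid = TRUE,
       dV_driver_mV = dd[1], dV_follower_mV = df[1])
}

#' Tally connectivity over a set of pair tests
#'
#' Counts tested pairs and connections per category and pooled over the
#' prototypic-prototypic categories, with percentages retained unrounded and
#' rounded to 1 and 2 decimals.  Categories follow the recording design:
#' \code{pv_pv}, \code{nkx_nkx}, \code{foxp2_foxp2}, \code{mixed} (prototypic
#' with arkypallidal), and \code{electrical} (gap-junction tests).
#'
#' @param pair_tests data.frame with columns \code{category} and
#'   \code{connected} (logical), one row per tested pair.
#' @return object of class \code{connectivity_summary}: data.frame with
#'   \code{category}, \code{n_pairs}, \code{n_connected}, \code{percent},
#'   \code{percent_1dp}, \code{percent_2dp}, including pooled
#'   \code{prototypic_pooled} and \code{total} rows.  Percentages of empty
#'   categories are NA.
#' @export
connectivity_summary <- function(pair_tests) {
  cats <- c("pv_pv", "nkx_nkx", "foxp2_foxp2", "mixed", "electrical")
  if (nrow(pair_tests) == 0) {
    tab <- data.frame(category = c(cats, "prototypic_pooled", "total"),
                      n_pairs = 0L, n_connected = 0L, percent = NA_real_,
                      percent_1dp = NA_real_, percent_2dp = NA_real_)
    return(structure(tab, class = c("connectivity_summary", "data.frame")))
  }
  stopifnot(all(c("category", "connected") %in% names(pair_tests)))
  unknown <- setdiff(unique(pair_tests$category), cats)
  if (length(unknown))
    stopf("unknown pair categories: %s", paste(unknown, collapse = ", "))
  count <- function(sel) {
    n <- sum(sel); k <- sum(pair_tests$connected[sel])
    pct <- if (n > 0) 100 * k / n else NA_real_
    data.frame(n_pairs = n, n_connected = k, percent = pct,
               percent_1dp = round(pct, 1), percent_2dp = round(pct, 2))
  }
  rows <- lapply(cats, function(cc) cbind(category = cc,
                                          count(pair_tests$category == cc)))
  proto <- cbind(category = "prototypic_pooled",
                 count(pair_tests$category %in% c("pv_pv", "nkx_nkx")))
  tot <- cbind(category = "total", count(rep(TRUE, nrow(pair_tests))))
  tab <- do.call(rbind, c(rows, list(proto, tot)))
  rownames(tab) <- NULL
  structure(tab, class = c("connectivity_summary", "data.frame"))
}

#' @export
print.connectivity_summary <- function(x, ...) {
  cat("Connectivity summary (pairs tested / connected / %):\n")
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-18s %4d / %2d / %s\n", df$category[i], df$n_pairs[i],
                df$n_connected[i],
                ifelse(is.na(df$percent_2dp[i]), "-",
                       sprintf("%.2f%%", df$percent_2dp[i]))))
  invisible(x)
}

#' Annotate a pharmacological block
#'
#' Compares IPSP amplitudes before and after a GABA-A antagonist
#' application: the response is flagged abolished when the post amplitude is
#' below 10\% of the pre amplitude.
#'
#' @param pre_amplitude,post_amplitude first-pulse IPSP amplitudes (mV).
#' @return list \code{blocked} (logical), \code{ratio}.
#' @export
block_annotation <- function(pre_amplitude, post_amplitude) {
  ratio <- post_amplitude / pre_amplitude
  list(blocked = is.finite(ratio) && ratio < 0.1, ratio = ratio)
}
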