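# Cohort generator: ground-truth-labeled cells, their protocol sweeps, pair
# tests (sparse Bernoulli connectivity), and SWC morphologies, emulating the
# study design: three molecularly identified groups recorded in slices of up
# to four simultaneously patched neighbours, prototypic-prototypic chemical
# connectivity ~1.15%, no arkypallidal or mixed connections, and no
# electrical coupling unless overridden.

#' Default synaptic kernel and depression parameters
#'
#' The IPSP kernel (first-pulse amplitude 2 mV, 1.5 ms rise, double
#' exponential decay of 15 and 60 ms with 25\% slow weight) and depression
#' (release fraction 0.5, 200 ms recovery) used for connected pairs in
#' synthetic cohorts; within the range reported for GPe collaterals.
#'
#' @return named list of kernel / depression parameters.
#' @export
default_ipsp_kernel <- function() {
  list(A1 = 2, tau_rise = 1.5, tau1 = 15, tau2 = 60, w2 = 0.25)
}

#' @rdname default_ipsp_kernel
#' @export
default_depression <- function() list(U = 0.5, tau_rec = 200)

# synthesize a follower trace: baseline + depressing IPSPs at the driver's
# spike times (+ synaptic delay), noise scaled for an n_sweeps average
synth_follower <- function(time, spike_times, kernel, depression,
                           delay_ms = 1, noise_sd = 0, n_sweeps = 20,
                           holding_mV = -70, sampling_rate = 20000) {
  v <- rep(holding_mV, length(time))
  amps <- numeric(0)
  if (length(spike_times)) {
    ev <- spike_times + delay_ms
    amps <- ipsp_depletion_amplitudes(kernel$A1, depression$U,
                                      depression$tau_rec, ev)
    for (i in seq_along(ev)) v <- v + amps[i] * ipsp_kernel(kernel, time - ev[i])
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd / sqrt(n_sweeps))
  list(sweep = new_sweep(time, v, rep(0, length(time)), sampling_rate,
                         holding_mV = holding_mV, protocol_id = "pair_follower"),
       amplitudes = amps)
}

#' Generate a labeled synthetic cohort
#'
#' Samples cells per group, simulates their protocol sweeps (ramp, step
#' family scaled to the cell's rheobase, -200 pA sag step, zero-current
#' spontaneous sweeps), generates SWC morphologies, partitions cells into
#' recording slices of up to \code{slice_size} same-group neighbours, and
#' draws chemical connectivity per pair as a Bernoulli variable
#' (\code{p_connect$proto_proto} within the two prototypic groups,
#' \code{p_connect$other} elsewhere).  Connected pairs get driver AP-train
#' sweeps and follower IPSP responses; all pairs get gap-junction test
#' sweeps with coupling coefficient \code{coupling_cc} (0 by default,
#' emulating the observed absence of electrical coupling).
#'
#' @param n_per_group named integer vector over \code{gpe_groups()} (groups
#'   may be omitted); every requested group needs n >= 1.
#' @param p_connect list with \code{proto_proto} (default 0.0115) and
#'   \code{other} (default 0).
#' @param rng_seed optional seed for the whole cohort.
#' @param noise_sd single-sweep recording noise (mV).
#' @param protocols subset of \code{c("ramp", "steps", "sag", "zero")} to
#'   simulate per cell.
#' @param make_sweeps,make_morphology stage toggles (pair outcomes are drawn
#'   regardless, so large connectivity-only cohorts stay cheap).
#' @param spont_duration_s,spont_sweeps zero-current recording layout.
#' @param slice_size cells per simulated slice (pairs are formed within
#'   slices).
#' @param pair_pulse_ms driver stimulation pulse width; the default 3 ms
#'   (2 nA at 20 Hz, 8 pulses) triggers exactly one AP per pulse.
#' @param kernel,depression IPSP kernel and depression parameters of
#'   connected pairs.
#' @param coupling_cc ground-truth gap-junction coupling coefficient.
#' @param n_avg_sweeps sweeps averaged in pair tests (noise scaling).
#' @param overrides passed to \code{\link{sample_cell}} (e.g.
#'   \code{list(g_h = 0)}).
#' @return object of class \code{gpe_cohort}: \code{cells} (list of
#'   \code{cell_params}), \code{cell_table}, \code{sweeps} (per cell),
#'   \code{morphologies}, \code{pairs} (data.frame incl. ground truth),
#'   \code{pair_sweeps}.
#' @export
generate_cohort <- function(n_per_group = c(arkypallidal = 10,
                                            prototypic_PV = 10,
                                            prototypic_Nkx = 10),
                            p_connect = list(proto_proto = 0.0115, other = 0),
                            rng_seed = NULL, noise_sd = 0.3,
                            protocols = c("ramp", "steps", "sag", "zero"),
                            make_sweeps = TRUE, make_morphology = TRUE,
                            spont_duration_s = 5, spont_sweeps = 3,
                            slice_size = 4, pair_pulse_ms = 3,
                            kernel = default_ipsp_kernel(),
                            depression = default_depression(),
                            coupling_cc = 0, n_avg_sweeps = 20,
                            overrides = list()) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% gpe_groups()))
    stopf("n_per_group must be named with labels from gpe_groups()")
  if (any(n_per_group < 1)) stopf("each requested group needs n >= 1")
  with_seed(rng_seed, {
    tags <- c(arkypallidal = "foxp2", prototypic_PV = "pv",
              prototypic_Nkx = "nkx")
    cells <- list()
    for (g in names(n_per_group)) {
      for (i in seq_len(n_per_group[[g]])) {
        p <- sample_cell(g, overrides = overrides)
        attr(p, "cell_id") <- sprintf("%s_%03d", tags[[g]], i)
        cells[[attr(p, "cell_id")]] <- p
      }
    }
    cell_table <- do.call(rbind, lapply(cells, function(p) data.frame(
      cell_id = attr(p, "cell_id"), group = p$group, R_in = p$R_in,
      C_m = p$C_m, V_T = p$V_T, g_h = p$g_h, spont_rate = p$spont_rate,
      soma_radius = p$soma_radius, stringsAsFactors = FALSE)))
    rownames(cell_table) <- NULL

    sweeps <- list()
    if (make_sweeps) {
      for (id in names(cells)) {
        p <- cells[[id]]
        I_rh0 <- (p$V_T + 70) * 1000 / p$R_in
        out <- list()
        if ("ramp" %in% protocols)
          out$ramp <- simulate_sweep(p, stim_ramp(2.5 * I_rh0 / 1200, 1200),
                                     noise_sd = noise_sd)
        if ("steps" %in% protocols) {
          small <- min(40, round(0.2 * I_rh0))  # capacitance-grade step
          amps <- unique(c(round(I_rh0 * c(-0.8, -0.6, -0.4)), -small, small,
                           round(I_rh0 * c(0.4, 1.3, 1.8, 2.4))))
          out$steps <- lapply(amps, function(a)
            simulate_sweep(p, stim_step(a, 1000), noise_sd = noise_sd))
        }
        if ("sag" %in% protocols)
          out$sag <- simulate_sweep(p, stim_sag_step(), noise_sd = noise_sd)
        if ("zero" %in% protocols)
          out$zero <- lapply(seq_len(spont_sweeps), function(k)
            simulate_sweep(p, stim_zero(spont_duration_s * 1000),
                           noise_sd = noise_sd))
        sweeps[[id]] <- out
      }
    }

    morphologies <- list()
    if (make_morphology)
      for (id in names(cells)) morphologies[[id]] <- generate_swc(cells[[id]])

    # pairs within same-group slices
    pair_rows <- list()
    pair_sweeps <- list()
    proto <- c("prototypic_PV", "prototypic_Nkx")
    for (g in names(n_per_group)) {
      ids <- names(cells)[vapply(cells, function(p) p$group == g,
                                 logical(1))]
      ids <- sample(ids)
      slices <- split(ids, ceiling(seq_along(ids) / slice_size))
      for (si in seq_along(slices)) {
        sl <- slices[[si]]
        if (length(sl) < 2) next
        cmb <- utils::combn(sl, 2)
        for (k in seq_len(ncol(cmb))) {
          a <- cmb[1, k]; b <- cmb[2, k]
          category <- switch(g, prototypic_PV = "pv_pv",
                             prototypic_Nkx = "nkx_nkx",
                             arkypallidal = "foxp2_foxp2")
          p_c <- if (g %in% proto) p_connect$proto_proto else p_connect$other
          connected <- stats::runif(1) < p_c
          dist <- min(186, max(15, stats::rnorm(1, 80, 30)))
          pid <- sprintf("%s__%s", a, b)
          pair_rows[[pid]] <- data.frame(
            pair_id = pid, driver_id = a, follower_id = b,
            category = category, distance_um = dist,
            connected_gt = connected, coupling_cc_gt = coupling_cc,
            slice = sprintf("%s_s%02d", tags[[g]], si),
            orientation = "sagittal", stringsAsFactors = FALSE)
          if (make_sweeps) {
            drv <- simulate_sweep(cells[[a]],
                                  stim_ap_train(pulse_ms = pair_pulse_ms),
                                  noise_sd = noise_sd)
            spk <- drv$ground_truth$spike_threshold_times
            fol <- synth_follower(drv$sweep$time,
                                  if (connected) spk else numeric(0),
                                  kernel, depression, noise_sd = noise_sd,
                                  n_sweeps = n_avg_sweeps)
            gap_d <- simulate_sweep(cells[[a]], stim_gap_step(),
                                    noise_sd = noise_sd)
            base_d <- mean(gap_d$sweep$voltage[gap_d$sweep$time <
                                                 gap_d$sweep$stim$onset_ms])
            vf <- -70 + coupling_cc * (gap_d$sweep$voltage - base_d)
            if (noise_sd > 0)
              vf <- vf + stats::rnorm(length(vf),
                                      0, noise_sd / sqrt(n_avg_sweeps))
            gap_f <- new_sweep(gap_d$sweep$time, vf,
                               rep(0, length(vf)),
                               gap_d$sweep$sampling_rate,
                               protocol_id = "gap_follower")
            pair_sweeps[[pid]] <- list(
              driver = drv$sweep, driver_spike_times = spk,
              follower = fol$sweep, ipsp_amplitudes_gt = fol$amplitudes,
              gap_driver = gap_d$sweep, gap_follower = gap_f)
          }
        }
      }
    }
    pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(pair_id = character(0), driver_id = character(0),
                 follower_id = character(0), category = character(0),
                 distance_um = numeric(0), connected_gt = logical(0),
                 coupling_cc_gt = numeric(0), slice = character(0),
                 orientation = character(0))
    rownames(pairs) <- NULL
    structure(list(cells = cells, cell_table = cell_table, sweeps = sweeps,
                   morphologies = morphologies, pairs = pairs,
                   pair_sweeps = pair_sweeps,
                   config = list(n_per_group = n_per_group,
                                 p_connect = p_connect, noise_sd = noise_sd,
                                 kernel = kernel, depression = depression,
                                 coupling_cc = coupling_cc)),
              class = "gpe_cohort")
  })
}

#' @export
print.gpe_cohort <- function(x, ...) {
  cat(sprintf("<gpe_cohort> %d cells (%s), %d pairs (%d connected)\n",
              length(x$cells),
              paste(sprintf("%s: %d", names(table(x$cell_table$group)),
                            table(x$cell_table$group)), collapse = ", "),
              nrow(x$pairs), sum(x$pairs$connected_gt)))
  invisible(x)
}

#' Extract intrinsic profiles for every cell of a cohort
#'
#' @param cohort a \code{gpe_cohort} with sweeps.
#' @param dvdt_criterion AP detection criterion.
#' @return data.frame of \code{\link{intrinsic_profile}} rows.
#' @export
cohort_profiles <- function(cohort, dvdt_criterion = 10) {
  stopifnot(inherits(cohort, "gpe_cohort"), length(cohort$sweeps) > 0)
  rows <- lapply(names(cohort$sweeps), function(id) {
    sw <- cohort$sweeps[[id]]
    intrinsic_profile(
      ramp_sweep = sw$ramp$sweep,
      step_sweeps = lapply(sw$steps, `[[`, "sweep"),
      sag_sweep = if (!is.null(sw$sag)) sw$sag$sweep else NULL,
      zero_sweeps = if (!is.null(sw$zero)) lapply(sw$zero, `[[`, "sweep")
                    else NULL,
      cell_id = id, group = cohort$cells[[id]]$group,
      dvdt_criterion = dvdt_criterion)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the connection and coupling detectors on a cohort's pairs
#'
#' @param cohort a \code{gpe_cohort} with pair sweeps.
#' @return data.frame: the cohort's \code{pairs} plus detector columns
#'   \code{connected}, \code{ipsp_amplitude_mV}, \code{latency_ms},
#'   \code{coupling_coefficient}, \code{coupled}.
#' @export
cohort_pair_tests <- function(cohort) {
  stopifnot(inherits(cohort, "gpe_cohort"))
  pairs <- cohort$pairs
  if (nrow(pairs) == 0 || length(cohort$pair_sweeps) == 0) {
    pairs$connected <- pairs$connected_gt
    pairs$ipsp_amplitude_mV <- NA_real_
    pairs$latency_ms <- NA_real_
    pairs$coupling_coefficient <- NA_real_
    pairs$coupled <- FALSE
    return(pairs)
  }
  det <- lapply(pairs$pair_id, function(pid) {
    ps <- cohort$pair_sweeps[[pid]]
    chem <- detect_connection(ps$follower, ps$driver_spike_times)
    gap <- gap_junction_test(ps$gap_driver, ps$gap_follower)
    data.frame(connected = chem$connected,
               ipsp_amplitude_mV = chem$amplitude_mV,
               latency_ms = chem$latency_ms,
               coupling_coefficient = gap$coupling_coefficient,
               coupled = gap$coupled)
  })
  cbind(pairs, do.call(rbind, det))
}
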