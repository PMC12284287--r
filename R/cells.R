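# Synthetic cell parameter generator for the three GPe populations.
#
# The defaults encode the qualitative orderings reported for the two GPe
# classes: arkypallidal (FoxP2+) neurons have higher input resistance, a more
# hyperpolarized spike threshold (hence lower rheobase), slower and larger
# action potentials, a deeper sag, lower spontaneous rates with a larger
# silent fraction, and smaller somata with narrower dendrites than the two
# prototypic groups (PV+ and Nkx2.1+), which differ from each other only in
# small AP-waveform details.  Exact population means are not published
# (violin plots only), so the means below are field-realistic choices; all
# are overridable.

#' Group labels recognised by the generator
#' @return character vector of the three group labels.
#' @export
gpe_groups <- function() c("arkypallidal", "prototypic_PV", "prototypic_Nkx")

#' Default generator parameters for a GPe cell group
#'
#' Mean parameters of the group-specific sampling distributions used by
#' \code{\link{sample_cell}}.  Units: resistances MOhm, capacitances pF,
#' voltages mV, times ms, conductances nS, rates Hz, lengths um.
#'
#' @param group one of \code{gpe_groups()}.
#' @return named list of mean parameters plus dispersion settings.
#' @export
group_defaults <- function(group) {
  group <- match.arg(group, gpe_groups())
  base <- list(
    E_L = -70, E_h = -30, tau_h = 80,
    sdlog = 0.12,        # log-normal dispersion of positive-scale parameters
    v_sd = 1.5,          # SD of threshold draw (mV)
    dendrite_geometry = list(n_primary = 4, mean_segment_len = 40,
                             taper = 0.004, base_diameter = 1.8,
                             bifurcation_prob = 0.45)
  )
  per <- switch(group,
    arkypallidal = list(
      R_in = 350, C_m = 60, V_T = -45, g_h = 4,
      ap_shape = list(t_rise = 0.45, t_fall = 1.40, V_peak = 15,
                      fAHP_depth = 12, t_fAHP = 2.0),
      spont_rate = 2, silent_frac = 0.40, soma_radius = 5,
      base_diameter = 1.2),
    prototypic_PV = list(
      R_in = 120, C_m = 100, V_T = -40, g_h = 1,
      ap_shape = list(t_rise = 0.25, t_fall = 0.70, V_peak = 10,
                      fAHP_depth = 18, t_fAHP = 1.0),
      spont_rate = 15, silent_frac = 0.05, soma_radius = 7,
      base_diameter = 1.8),
    prototypic_Nkx = list(
      R_in = 120, C_m = 100, V_T = -40, g_h = 1,
      ap_shape = list(t_rise = 0.22, t_fall = 0.70, V_peak = 12,
                      fAHP_depth = 16, t_fAHP = 1.0),
      spont_rate = 15, silent_frac = 0.05, soma_radius = 7,
      base_diameter = 1.8)
  )
  out <- utils::modifyList(base, per)
  out$dendrite_geometry$base_diameter <- out$base_diameter
  out$base_diameter <- NULL
  out$group <- group
  out
}

#' Sample ground-truth parameters for one synthetic GPe cell
#'
#' Draws a parameter set from the group-specific distributions: log-normal
#' around the group mean for positive-scale quantities (input resistance,
#' capacitance, conductances, AP kinetics, geometry), normal for the spike
#' threshold.  A Bernoulli draw with the group's silent fraction can set the
#' spontaneous rate to zero.
#'
#' @param group one of \code{gpe_groups()}.
#' @param rng_seed optional integer; fixes the draw.
#' @param overrides named list merged over the group defaults before sampling
#'   (e.g. \code{list(g_h = 0)} for an ohmic cell).
#' @return an object of class \code{cell_params}.
#' @export
sample_cell <- function(group, rng_seed = NULL, overrides = list()) {
  if (!is.character(group) || length(group) != 1L || !group %in% gpe_groups())
    stopf("unknown group label '%s'; expected one of: %s",
          as.character(group)[1], paste(gpe_groups(), collapse = ", "))
  def <- utils::modifyList(group_defaults(group), overrides)
  with_seed(rng_seed, {
    ln <- function(mu) if (mu <= 0) mu else
      stats::rlnorm(1, meanlog = log(mu) - def$sdlog^2 / 2, sdlog = def$sdlog)
    ap <- def$ap_shape
    V_T <- stats::rnorm(1, def$V_T, def$v_sd)
    silent <- stats::runif(1) < def$silent_frac
    dg <- def$dendrite_geometry
    params <- list(
      group = group,
      R_in = ln(def$R_in),
      C_m = ln(def$C_m),
      E_L = def$E_L,
      V_T = V_T,
      g_h = if (def$g_h > 0) ln(def$g_h) else 0,
      tau_h = def$tau_h,
      E_h = def$E_h,
      # AP segment times snap to the 0.05 ms integration grid so the pasted
      # template realises the recorded shape exactly (ground truth stays
      # recoverable to machine precision from noiseless sweeps)
      ap_shape = list(
        t_rise = snap_ms(ln(ap$t_rise)),
        t_fall = snap_ms(ln(ap$t_fall)),
        V_peak = max(stats::rnorm(1, ap$V_peak, 1.3 * def$v_sd), V_T + 20),
        fAHP_depth = ln(ap$fAHP_depth),
        t_fAHP = snap_ms(ln(ap$t_fAHP))
      ),
      spont_rate = if (silent) 0 else ln(def$spont_rate),
      soma_radius = ln(def$soma_radius),
      dendrite_geometry = list(
        n_primary = max(2L, stats::rpois(1, dg$n_primary)),
        mean_segment_len = ln(dg$mean_segment_len),
        taper = dg$taper,
        base_diameter = ln(dg$base_diameter),
        bifurcation_prob = dg$bifurcation_prob
      )
    )
    class(params) <- "cell_params"
    validate_cell_params(params)
    params
  })
}

# snap a duration to the 0.05 ms simulation grid (never below one step)
snap_ms <- function(x, dt = 0.05) max(dt, round(x / dt) * dt)

validate_cell_params <- function(p) {
  stopifnot(inherits(p, "cell_params"))
  if (p$R_in <= 0 || p$C_m <= 0) stopf("R_in and C_m must be positive")
  ap <- p$ap_shape
  if (ap$t_rise <= 0 || ap$t_fall <= 0) stopf("AP rise/fall times must be positive")
  if (ap$V_peak <= p$V_T) stopf("V_peak must exceed the spike threshold")
  if (p$spont_rate < 0) stopf("spont_rate must be >= 0")
  bp <- p$dendrite_geometry$bifurcation_prob
  if (bp < 0 || bp > 1) stopf("bifurcation_prob must lie in [0, 1]")
  invisible(p)
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("<cell_params> %s: R_in %.0f MOhm, C_m %.0f pF, V_T %.1f mV, g_h %.1f nS, spont %.1f Hz\n",
              x$group, x$R_in, x$C_m, x$V_T, x$g_h, x$spont_rate))
  invisible(x)
}
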