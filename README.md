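# gpephys

Analysis toolkit for *ex vivo* current-clamp characterisation of external
globus pallidus (GPe) neurons — the prototypic (PV+ / Nkx2.1+) and
arkypallidal (FoxP2+) populations — for cellular electrophysiologists who
need the full chain from raw sweeps to population statements:

* **Intrinsic features** from sweep recordings: input resistance (steady-state
  I–V regression), rectification index, membrane capacitance (τ/R), ramp
  threshold (dV/dt criterion), rheobase, AP waveform metrics (amplitude,
  rise/fall times and rates, duration, half-width, fAHP), sag amplitude and
  sag ratio from the −200 pA step, spontaneous rate, discharge frequency and
  f–I slope, phase plots.
* **Synaptic analysis**: IPSP train decomposition by double-exponential decay
  fitting with subtraction of preceding decays (per-pulse amplitudes under
  20 Hz stimulation, short-term depression index), spike-triggered connection
  detection for paired recordings, and gap-junction testing via the
  steady-state coupling coefficient (follower ΔV / driver ΔV).
* **Morphometry** from standard SWC reconstructions: dendritic lengths,
  bifurcation/termination counts, soma and total surface areas, Sholl
  profiles, branch-order diameters.
* **Population analysis**: z-scored 15-feature matrix, correlation-matrix PCA
  (eigenvalue > 1 retention), Ward hierarchical clustering on squared
  Euclidean distances, and a normality-gated dispatcher (Shapiro–Wilk →
  one-way ANOVA + Tukey, else Kruskal–Wallis + Dunn/Bonferroni).
* **A synthetic-data generator** — a single-compartment membrane with a sag
  conductance, template-pasted APs, depressing IPSP trains
  (depleting-resource recursion R₁ = 1, aₙ = A₁·U·Rₙ,
  Rₙ₊₁ = 1 − (1 − Rₙ(1−U))·e^(−Δt/τ_rec)), Bernoulli pair connectivity, and
  SWC tree growth — so every stage is testable against ground truth without
  the original recordings.

The sweep model is C·dV/dt = −(V−E_L)/R_in − g_h·m·(V−E_h) + I(t) with
first-order sag activation (m_∞ half-activation −80 mV, slope 6 mV),
integrated at 0.05 ms. See `vignettes/gpephys-methods.Rmd` for the science,
conventions and design decisions.

## Worked example

```r
library(gpephys)

# one synthetic prototypic cell, its step family, and feature extraction
p <- sample_cell("prototypic_PV", rng_seed = 1,
                 overrides = list(g_h = 0, sdlog = 1e-9, v_sd = 1e-9))
rheo <- (p$V_T + 70) * 1000 / p$R_in                      # analytic, 250 pA
steps <- lapply(c(-150, -100, -50, 50, 325, 450), function(a)
  simulate_sweep(p, stim_step(a, 1000), noise_sd = 0)$sweep)
input_resistance(steps)[c("R_in_MOhm", "r_squared")]
#> $R_in_MOhm
#> [1] 120.0002
#> $r_squared
#> [1] 1

sw <- steps[[5]]                                          # lowest suprathreshold
pk <- detect_aps(sw)
wf <- ap_waveform(sw, pk[1], next_spike_idx = pk[2])
unlist(wf[c("amplitude", "rise_time", "fall_time", "half_width")])
#>  amplitude  rise_time  fall_time half_width
#>      50.00       0.25       0.70       0.60
```

The extracted input resistance equals the generator's 120 MΩ with a perfect
linear fit, and the AP waveform metrics reproduce the cell's template (50 mV
threshold-to-peak amplitude, 0.25 ms rise, 0.70 ms fall; the 0.60 ms
half-width is rise + fall/2 under the threshold-referenced half-width
convention).

Connectivity tallies use the recorded pair counts directly:

```r
pairs <- data.frame(category = c(rep("pv_pv", 166), rep("nkx_nkx", 182)),
                    connected = c(TRUE, rep(FALSE, 165), rep(TRUE, 3),
                                  rep(FALSE, 179)))
connectivity_summary(pairs)
#>   pv_pv                166 /  1 / 0.60%
#>   nkx_nkx              182 /  3 / 1.65%
#>   ...
#>   prototypic_pooled    348 /  4 / 1.15%
```

Pooling 1/166 PV+ and 3/182 Nkx2.1+ connections gives the 1.15%
prototypic–prototypic connectivity rate (0.6% among PV+ pairs).

An end-to-end run (simulate → features → connectivity → morphometry →
clustering, with a hashed manifest for byte-identical reruns):

```r
run <- run_pipeline(list(seed = 1, output_dir = "gpe_demo"))
run$clustering$purity
```

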