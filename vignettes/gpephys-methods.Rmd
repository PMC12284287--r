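---
title: "Models and methods behind gpephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpephys)
```

# Scope

`gpephys` implements the analysis chain used to characterise the two main
neuron classes of the external globus pallidus (GPe) — prototypic (PV+ and
Nkx2.1+) and arkypallidal (FoxP2+) neurons — from *ex vivo* current-clamp
recordings: intrinsic membrane-property extraction, IPSP train decomposition
with short-term depression, paired-recording connectivity and gap-junction
testing, SWC morphometry with Sholl analysis, and PCA + Ward clustering of
the feature matrix.  Because the original recordings are not publicly
deposited, the package ships a synthetic-data generator that emulates the two
populations with known ground truth; every analysis stage is validated by
recovering that ground truth.

# The membrane model of the sweep simulator

Sweeps are integrated from a single-compartment equation with a
hyperpolarization-activated (sag) conductance:

$$C_m \frac{dV}{dt} = -\frac{V - E_L}{R_{in}} - g_h\, m\, (V - E_h) + I(t),
\qquad \tau_h \frac{dm}{dt} = m_\infty(V) - m,$$

with $m_\infty(V) = 1/(1 + e^{(V + 80)/6})$ (half-activation −80 mV, slope
6 mV).  Units are mV, ms, pA, MΩ, pF and nS throughout.  Integration is a
fixed-step explicit scheme at 0.05 ms; the simulator refuses steps above
0.1 ms.  A holding current computed from the model keeps cells at −70 mV
(as in the recordings) except during zero-current protocols.

Action potentials are not conductance-generated.  When $V$ crosses the
threshold $V_T$, a piecewise-linear template (rise to $V_{peak}$ over
$t_{rise}$, fall back to $V_T$ over $t_{fall}$, descent to the fAHP depth
over $t_{fAHP}$) is pasted and integration resumes from the fAHP.  This
makes the waveform ground truth exact, which is what the acceptance story
requires — parameter recovery, not biophysical realism.  For the same
reason the template segment durations snap to the 0.05 ms integration grid
when a cell is sampled: the pasted trace then realises the recorded shape to
machine precision, so extraction errors measure the extractor, not the
discretisation.  Recording noise is Gaussian, added to the voltage *after*
integration (measurement noise): ground truth stays exact and averaging over
sweeps reduces noise as it does at the rig.

Spontaneous activity at 0 pA is modelled as a jittered periodic spike train
(5% CV) at the cell's rate rather than by a pacemaker current — the simplest
ground truth for rate-recovery tests.  A group-specific fraction of
arkypallidal cells is silent.

## Generator populations

Exact population means are not published (the study reports violin plots),
so the group defaults are field-realistic values chosen once to reproduce
the reported orderings: arkypallidal cells have higher input resistance
(350 vs 120 MΩ), lower capacitance (60 vs 100 pF), a more hyperpolarized
threshold (−45 vs −40 mV, hence much lower rheobase), slower and larger APs
(rise 0.45 vs ≈0.25 ms, fall 1.4 vs 0.7 ms), a larger sag conductance, lower
spontaneous rates (2 vs 15 Hz, with 40% vs 5% silent), and smaller somata
with narrower dendrites.  The two prototypic groups share all passive
parameters and differ only slightly in AP shape, which is why they form a
mixed cluster downstream.  Positive-scale parameters vary log-normally
(σ_log = 0.12), voltages normally (SD 1.5 mV); everything is overridable via
`sample_cell(..., overrides = )`.

On the abstract-versus-results discrepancy in the source material about the
direction of the threshold difference, the generator follows the results
(arkypallidal thresholds more hyperpolarized, consistent with their lower
rheobase and higher input resistance).

What the generator does **not** emulate: channel noise and pacemaker
dynamics, AP shape accommodation during trains, dendritic filtering,
electrode/access artefacts, bridge imbalance, and liquid-junction offsets
(not corrected in the recordings either).  Passing recovery tests therefore
demonstrates correctness of the extraction arithmetic on well-posed traces,
not robustness to every pathology of real recordings.

# Feature extraction choices

* **AP detection**: an upward dV/dt crossing of the criterion followed by a
  voltage maximum above 0 mV within 5 ms; detections merge within a 2 ms
  refractory window.
* **Threshold criterion**: default 10 mV/ms, exposed as configuration.  The
  source prints 10 mV·s⁻¹, which any suprathreshold ramp exceeds throughout;
  we treat that as a unit slip and use the field-standard 10 mV/ms.
* **Ramp threshold** uses a 5-point local-quadratic (Savitzky–Golay)
  smoothed derivative and takes the last criterion crossing that stays above
  the criterion until the AP peak.  Per-spike thresholds for waveform
  metrics apply the same criterion locally on the raw forward difference
  (noise-robustness matters less within 10 ms of a spike, and the raw
  derivative localises the template foot exactly).  Phase plots use the raw
  centered difference, unsmoothed.
* **Waveform conventions** follow the study's definitions, including its
  non-standard half-width: time from *threshold* to the decay crossing of
  threshold + amplitude/2 (not the full width at half maximum).  Fall time
  ends at the decay's recrossing of the threshold voltage; crossings are
  linearly interpolated between samples.  fAHP amplitude is reported as a
  positive depth below threshold; its time is measured from the fall point
  (10 ms search window; the slower AHP time uses 50 ms).
* **Input resistance**: regression slope of steady-state voltage (0.8–0.9 s
  into the step; for steps shorter than 0.9 s, the final 10% of the step)
  against current, over AP-free sweeps only.  With a nonzero sag
  conductance the measured slope is the *effective* resistance, which is
  smaller than the passive $R_{in}$ parameter — recovery is therefore
  asserted on ohmic ($g_h = 0$) cells, and sag cells are covered by the
  rectification and sag metrics instead.
* **Capacitance**: the procedure is referenced but not described in the
  source; we fit a single exponential to the relaxation 2–100 ms after the
  onset of a small (≤50 pA) AP-free step and report $C_m = 1000\,\tau/R$
  with $R$ from the same step.  A strong sag biases $\tau$ downward; the
  value is returned regardless and documented as such.
* **Sag**: minimum over the first 150 ms of the −200 pA step versus the mean
  of the final 100 ms; the ratio is taken on absolute potentials, so it is
  ≥ 1 when a sag is present and 1 without one, up to the passive settling
  of the 150 ms minimum window (a relative term exp(−150/τ_m)·|ΔV|/|V_ss|,
  about 10⁻³ for the slowest cells).  With the stated activation
  kinetics the ratio increases with $g_h$ through the physiological range
  used by the generator (≤ 4 nS) and saturates beyond it — the monotonicity
  property is asserted on that range.
* **Missing values** are returned as `NA` with a flag attribute and never
  imputed; the population stage drops incomplete rows and logs the ids.

# IPSP trains and connectivity

Synthetic trains use a depleting-resource rule — $R_1 = 1$,
$a_n = A_1 U R_n$, $R_{n+1} = 1 - (1 - R_n(1-U))\,e^{-\Delta t/\tau_{rec}}$ —
and each event is a rise exponential times a double-exponential decay,
superposed linearly.  The decomposition mirrors the study's procedure: fit
the decaying phases with a double exponential, extrapolate and subtract the
preceding decays, and measure each amplitude as post-subtraction peak minus
the post-subtraction pre-pulse baseline.  The two time constants and the
weight are shared across a train's pulses (fitted on the first IPSP,
per-pulse scale refitted linearly) because independent fits on the late,
small pulses are unstable.  Peaks are picked on a 1 ms boxcar-smoothed
residual so window maxima are not inflated by noise; fits that fail to
converge fall back to a single exponential with a flag, and negative
amplitudes floor at 0 with a flag.

Connection detection aligns the follower's averaged trace on the driver's
AP times, averages the baseline-referenced deflections, and requires the
peak within 1–6 ms to exceed both 3× the baseline SD of the averaged trace
and an absolute 0.2 mV floor, with a causal 10%-of-peak rise (the
spike-triggered average is lightly smoothed, 0.5 ms, before the latency
gate).  These thresholds are configuration, not published values; they sit
well below the smallest IPSP reported in the recordings (1.2 mV).  With the
high-chloride internal solution of the experiments, IPSPs are depolarizing
at −70 mV, so positive deflections are searched.  Electrical coupling uses
the −150 pA / 500 ms step: the coupling coefficient is the ratio of
steady-state deflections, a pair counts as coupled at coefficient ≥ 0.01
with a hyperpolarizing follower deflection above 3× its baseline SD, and a
driver deflection under 1 mV voids the test.  The 0.01 cut-off is below
coupling coefficients reported in other regions; since the study reports an
absence of coupling, the operative surface is specificity.

The cohort generator draws chemical connections per within-slice pair as a
Bernoulli variable with probability 0.0115 for prototypic–prototypic pairs
and 0 elsewhere, matching the study's tallies (4 of 348 prototypic pairs;
no arkypallidal, mixed, or electrically coupled pairs).  Driver stimulation
in synthetic pair tests uses 2 nA pulses at 20 Hz; the default pulse width
in cohorts is 3 ms so each pulse triggers exactly one AP (the 30 ms pulses
of the experimental protocol make real prototypic neurons burst, which is
irrelevant to the detector's contract and would entangle the depression
ground truth).

# Morphometry

SWC trees are validated structurally (single root, parents precede children,
positive radii); axon nodes (type 2) are ignored because long-range axons
were severed in the slices and not quantified.  Conventions the source
leaves unstated are package choices: soma area is the projected disc
$\pi r^2$ on the largest soma radius; total surface is the soma sphere
$4\pi r^2$ plus dendritic frustum lateral areas (a `soma_surface = "disc"`
switch exists); the Sholl centre is the radius-weighted soma centroid and
the default step is 10 µm.  Sholl crossings are counted analytically: the
squared distance to the centre along a straight segment is a convex
quadratic, so each segment crosses a sphere 0, 1 or 2 times; a node exactly
on a sphere resolves to the outer side.  The test suite pins this against a
brute-force oracle that resamples every segment at 0.1 µm.  Nodes with three
or more children count as multiple bifurcations so the Euler identity
(terminations = bifurcations + primaries) generalises.  Branch-order
diameters are length-weighted means of 2× the child-node radius per order
class (1, 2, >2), with order incrementing at each bifurcation.

The tree generator is a truncated binary branching process (bifurcation
probability per section end, at most 6 orders) with radially biased growth
and linear radius taper; its expected bifurcation count has the closed form
implemented in `expected_bifurcations()`, which the tests compare against
Monte-Carlo counts.

# Population analysis

The 15-feature matrix (AP amplitude, duration, half-width, rise/fall times,
AHP time, rise/fall rates, fAHP, rectification index, threshold, input
resistance, rheobase, maximum discharge frequency, f–I slope) is z-scored;
rows with any missing value are dropped and logged.  PCA is the
eigendecomposition of the correlation matrix, so eigenvalues sum to the
feature count; the operative retention rule is eigenvalue > 1 (the scree
elbow is advisory output only).  Clustering is agglomerative Ward linkage on
*squared* Euclidean distances (`hclust(dist(x)^2, method = "ward.D")`),
matching the stated metric/linkage combination.  Whether the published
dendrogram was computed on raw features, z-scores, or retained PC scores is
unstated; clustering operates on the z-scored features here (the
conservative reading — no information is discarded), and the separation
property is robust to either choice.

The group-comparison dispatcher tests each group with Shapiro–Wilk
(α = 0.05; the source says only "tested for Gaussian distribution"); all
normal → one-way ANOVA with Tukey's HSD, otherwise Kruskal–Wallis with
Dunn's test.  No installed package provides Dunn's test, so the standard
rank-sum z statistic with tie correction is implemented directly and
Bonferroni-adjusted (the source names Dunn but not the adjustment); the
tests pin the two-group case against the Kruskal–Wallis statistic, to which
it is analytically equal.  Constant groups force the non-parametric branch
with a flag.

# Reproducibility and problem sizes

Every stochastic entry point takes a seed; `run_pipeline()` validates its
configuration by name, derives all stage seeds from one mandatory seed, and
writes a manifest with the MD5 of every output, so identical configuration
and seed give byte-identical outputs.

The validation suite uses problem sizes chosen to estimate each property
stably while staying quick on one CPU: 200 synthetic trees for the Sholl
oracle and Euler identity, 1,000 simulated pairs each for the detector's
false-positive rate and power, 10,000 Bernoulli pairs for the connectivity
rate, and twenty 120-cell cohorts (60 arkypallidal, 30 + 30 prototypic) for
the clustering property — the arkypallidal-versus-prototypic purity is
asserted at ≥ 0.95 while the PV-versus-Nkx2.1 purity within the prototypic
subset stays near chance, the computational analogue of the published
dendrogram with its single arkypallidal cluster and mixed prototypic
cluster.

# Known limitations

* With $g_h > 0$ the extracted input resistance is the effective (chord)
  resistance, not the passive parameter; this mirrors real measurements but
  means "recovery" is only defined for ohmic cells.
* The sag ratio is non-monotone in $g_h$ far above the generator's range
  (the early minimum itself is lifted once the conductance saturates).
* The capacitance estimate inherits the arbitrariness of its unpublished
  definition; alternative conventions (e.g., current-clamp charge methods)
  would scale differently.
* The IPSP decomposition assumes one kinetic class per connection; mixed
  fast/slow connections would need per-pulse kinetics.
* Synthetic cohorts cannot validate immunohistochemical identification,
  slice-orientation effects, or distance-dependent connectivity — the
  distance field is pass-through data.
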