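---
title: "Quantifying axo-axonic plasticity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axo-axonic plasticity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Chandelier cells (ChCs) are GABAergic interneurons whose axons form
vertical "cartridges" of boutons exclusively onto the axon initial
segments (AIS) of pyramidal neurons. Measuring how this axo-axonic
microcircuit assembles and remodels requires a chain of small,
rule-based quantifications: where an AIS starts and ends in a
fluorescence image, how many boutons sit on it, whether a ChC "contacts"
a given AIS, how many perisomatic synapses a basket cell makes, whether
a cell is active (cfos), what the postsynaptic currents and spike
thresholds look like in patch clamp, and what polarity a GABAergic
response has in a voltage-imaging movie. `axoquant` implements that
chain as testable functions, together with seeded synthetic-data
generators that embed ground truth for every input class, so every rule
can be validated by parameter recovery rather than by eye.

# AIS morphometry

The AIS marker signal (e.g. AnkyrinG) is brightest near the middle of
the segment and fades toward both ends, so "length" needs a rule. The
rule used here is fractional: the AIS extends over the contiguous region
around the brightest point where intensity stays above 20% of the
profile maximum; the two crossings of the 20% level, located by linear
interpolation between samples, are the start and end points
(`detect_ais_extent()`, `fraction = 0.2`).

Two practical choices deserve note:

* **Multiple crossings.** A noisy profile crosses any threshold many
  times. We take the super-threshold run containing the global argmax,
  which matches the idea of a single bright segment and is robust to
  dim distal blobs.
* **Pre-smoothing.** The raw rule terminates the super-threshold run at
  the *first* sub-threshold sample, so a single noise dip inside the
  AIS truncates it. A moving-average option (`smooth_width`, default
  off) exists for noisy profiles; with it engaged the detector recovers
  true extents with median error well below one sampling step at
  SNR 10. It is off by default so that the published rule is applied
  verbatim to clean data.

`extract_profile()` replaces the manual profile-reading step: it
resamples a traced 3-D path at equal arclength steps and reads the stack
by trilinear interpolation (0-based voxel convention, micrometers
everywhere).

Bouton counting follows the overlap rule: every ChC varicosity whose
distance to the AIS polyline (restricted to the detected extent) is at
most `overlap_dist_um` counts, and density is count per micrometer of
detected length. The published analysis judged "overlap" by eye; we had
to pick a number, and use 0.5 µm, boundary-inclusive, configurable, and
echoed in every output. Cartridges — collections of two or more boutons
projecting along the AIS axis — are likewise a verbal rule
operationalized as single-linkage clustering at 5 µm with a principal
axis within |cos| ≥ 0.9 of the AIS axis; both cut-offs are parameters.

Connection probability uses the sampling geometry of the original
measurements: AISs are eligible if they fall inside a 90 µm radius ×
100 µm height cylinder centered on the ChC soma (height centered on the
soma depth), 30 of them are sampled blindly (seeded, without
replacement), and a contact is at least one overlapping varicosity.

# Perisomatic synapses and cfos

Somata (NeuN) and synaptic puncta (VGAT) are segmented from single
planes; thresholds default to Otsu with a per-image manual override,
and the value used is recorded in the outputs because per-image
adjustment is part of the procedure. Touching puncta are split by a
distance-transform watershed (EBImage). A punctum is perisomatic when
its centroid lies within 1 µm of the segmented soma *region* — distance
zero inside the polygon, distance to the boundary outside,
boundary-inclusive — and density divides the count by the soma
perimeter. Perimeters are measured on a lightly resampled boundary
polygon, which removes the systematic length over-estimate of raw
8-connected pixel chains (a digitized disk's chain-code perimeter runs
~5–8% long; the resampled polygon is within a fraction of a percent).

cfos classification applies two class-specific thresholds against a
background estimate (mean and SD over user-supplied ROIs): pyramidal
cells are positive above 1.2× the background mean, chandelier cells
above the background mean plus 2 SD. The direction of the inequality at
exactly the threshold is not specified by the rule's wording; we use
strict `>`, so a cell at threshold is negative. Boundary cases are
measure-zero in practice; the choice is documented and tested.

# Patch-clamp measurements

Input–output curves report AP frequency per current step (spike count
over the 500 ms step) against both injected current (pA) and current
density (pA/pF), the latter normalizing for cell size via capacitance.
Spikes are upward 0 mV crossings with a 1 ms refractory.

**Voltage threshold** is the voltage at the time of the first peak of
the jerk — the third time-derivative of voltage. Raw third differences
amplify noise catastrophically, so the trace is smoothed with a
Savitzky–Golay filter and the third derivative taken from the same
filter. Numerical choices, each configurable:

* a two-stage search: a 0.7 ms window (order 6) localizes the first
  qualifying jerk peak, then a 0.4 ms window re-estimates it locally —
  the wide window alone shifts the sharply asymmetric onset lobe a few
  hundred microseconds early, which reads several mV low;
* a prominence floor of 20% of the window's jerk maximum *and* 4.5
  robust (MAD) SDs of the pre-onset jerk noise, so baseline noise
  wiggles are never accepted;
* parabolic interpolation of the peak for sub-sample timing;
* a per-cell summary, `cell_voltage_threshold()`, that takes the median
  over all APs in a sweep — single-AP estimates at realistic noise
  occasionally lock onto a noise peak, and the median is what a
  threshold measurement reports anyway.

On the synthetic APs (below) this recovers the true threshold with
|bias| < 1 mV and SD < 1 mV across 50 seeded cells at 0.5 mV RMS noise.

**Evoked PSCs** are baseline-subtracted per sweep, averaged over the
first 15 sweeps, and the extremum of the mean trace in the
post-stimulus window is the amplitude (inward currents negative;
magnitudes carry the sign in metadata). **Failures** are sweeps without
a detectable response: the trace is smoothed at the PSC rise-time scale
(5 ms default), and a sweep succeeds when its post-stimulus deflection
exceeds k = 3 baseline SDs, with the SD pooled across sweeps — a
per-sweep SD of smoothed, correlated noise has too few effective
degrees of freedom and misclassifies marginal sweeps. Cells with fewer
than two successes are excluded rather than scored. The success
criterion's k, window (stimulus + 50 ms) and smoothing are parameters;
none is prescribed by the original rule beyond "absence of a response".

**Spontaneous PSCs** are detected by scaled-template matching
(Clements–Bekkers): at every lag the template — difference of
exponentials, rise 1 ms, decay 20 ms, 1 ms zero-baseline, 40 ms total —
is fitted by least squares in scale and offset, and the detection
criterion is scale over the fit's standard error. The criterion
threshold is not part of the published kernel parameters; we default to
3 (field convention) and log it. Super-threshold runs collapse to their
best lag, and events closer than the decay time merge, which prevents a
noise dip inside one event from splitting it in two.

# Voltage imaging

The genetically encoded voltage indicator dims on depolarization, so a
*drop* in fluorescence is a depolarizing response. Processing follows
the acquisition structure: dark frames flank the LED-on span, so camera
noise is the mean of a 10-frame dark window, subtracted per repeat.
Photobleaching is fitted per repeat as a double exponential
`A1 exp(-t/τ1) + A2 exp(-t/τ2)` on LED-on frames *excluding* the
expected response window — otherwise the response itself bends the
envelope (a paired-fit regression test asserts exactly this).
Initialization is a deterministic multi-start (τ pairs from {0.1, 1,
10} × duration, amplitudes by linear least squares at fixed τ; no RNG in
fitting), with τ bounded to [2 frames, 100 × duration]. No constant
offset term is included: the camera offset is removed beforehand, and a
constant would trade off against the slow exponential on these short
traces.

ΔF/F uses F = the mean bleach-corrected fluorescence of the last 10
frames before the evoked event. The correction form is a choice the
procedure leaves open: we default to the ratio form (raw/fit), which is
invariant to multiplicative gain, and also provide the subtractive form
(raw − fit + mean fit) behind a flag. Repeats are averaged frame-wise
and smoothed with a centered 3-frame moving average whose window
shrinks at the edges (no padding is invented).

Event detection Z-scores the averaged trace against all pre-stimulus
LED-on frames and calls a time-locked event when |Z| > 3 for at least
2 consecutive frames inside the response window (stimulus span plus
50 ms for GABAergic decay). The 2-frame persistence is ours: a
single-frame rule at 120 Hz is noise-fragile. Response polarity maps
negative events to depolarizing, positive to hyperpolarizing, and no
event to non-responsive (presumed shunting). For amplitude readouts,
`response_amplitude()` reports the response-window mean (unbiased for a
sustained response) alongside the extremum, because the extremum of a
noisy trace is biased outward. For recordings whose responses are too
long to leave a fittable baseline, `bleach_correct_by_reference()`
trains the envelope on non-stimulation repeats of the same cell and
transfers its shape.

One caveat the synthetic experiments make visible: frames inside the
exclusion window are *extrapolated* by the bleach model, so their
variance exceeds the baseline's. At high noise this inflates the
false-positive rate of the 3 SD rule above the naive Gaussian
expectation for cells with no response; the iid-noise false-positive
calibration in the test suite therefore uses unsmoothed traces, and the
population script reports the confusion table honestly.

# Group statistics and the developmental sigmoid

Connection probability across age is summarized with a four-parameter
logistic (lower and upper asymptote clamped to [0, 1], midpoint in
days, slope per day), fitted by bounded Levenberg–Marquardt with a
deterministic multi-start over midpoint and slope sign; the fit is
reported in the canonical orientation (lower ≤ upper), exploiting the
4PL's mirror symmetry. All-equal probabilities return a flagged
degenerate fit instead of an error.

Group comparisons are reporting plumbing over standard routines:
normality per group by the D'Agostino–Pearson K² omnibus test (written
in-package from the standard skewness and kurtosis transforms because
no installed package provides it; validated against independently
computed reference values), then t test / one-way ANOVA + Tukey when
all groups pass, otherwise Mann–Whitney / Kruskal–Wallis with pairwise
Wilcoxon and Holm correction as the post hoc. Groups smaller than 8 fall
back to Shapiro–Wilk for the screening step. Significance is read at
α = 0.05.

# What the generators emulate — and what they do not

Every generator is deterministic under its `sim_config(seed)` and
attaches a truth record that analysis code never reads.

* **AIS profiles** (`make_ais_profile()`) place triangular, plateau or
  Gaussian intensity shapes whose analytic 20% crossings are the truth;
  with zero noise the sampled profile equals its analytic form to
  machine precision.
* **ChC fields** (`make_chc_field()`) draw AIS polylines (roughly
  vertical, ≥ 8 µm apart, as neighboring somata dictate) inside and
  outside the cylinder; a deterministic fraction receives on-path
  varicosities, background varicosities keep 4× the overlap distance
  clear of every AIS, so the contact map is exact by construction and
  recomputable by brute-force distance scans.
* **Soma images** (`make_soma_image()`) are disks plus Gaussian puncta
  at controlled boundary offsets.
* **Patch sweeps** (`make_patch_sweeps()`) build APs as a sum of two
  logistic sigmoids. For a logistic, the first local maximum of the
  third derivative falls where the curve sits at s₁ = ½ − √6/6
  (≈ 9.18%) of its amplitude; the spike amplitude is solved so that the
  voltage at the *exact* first jerk peak of the full kernel equals the
  requested threshold, making "first peak of the jerk" an analytic
  ground truth rather than an empirical byproduct. Up- and down-stroke
  amplitudes are equal so stacked APs do not drift the baseline.
  Membrane noise is Gaussian band-limited to ~1 kHz — white noise at
  the full 25 kHz Nyquist band is unphysical in current clamp and its
  genuine third derivative would exceed any AP's onset jerk. PSCs are
  differences of exponentials at the template's own kinetics (the
  detector's design point), with seeded Bernoulli failures.
* **Repeat series** (`make_repeat_series()`) compose camera offset +
  double-exponential bleach × (1 + boxcar response) + Gaussian read
  noise, with ≥ 10 dark frames at both ends and depolarizations
  *decreasing* fluorescence.

They do not emulate: optics or point-spread functions, motion,
biophysically detailed conductances, correlated camera noise, or
instrument-calibrated noise levels (no noise statistics are published
for the original recordings; defaults were chosen once at what the
recovery task plausibly faces — e.g. single-repeat SNR ≈ 0.3 for
voltage imaging, 0.5 mV RMS membrane noise — and the acceptance suite
runs at those conditions). Passing tests therefore demonstrate that the
*rules* are implemented correctly and recover known truth under
realistic synthetic conditions, not that any specific biological result
reproduces.

# Problem sizes

The validation suites run at fixed, modest sizes chosen for the
package's test turnaround: 50-cell recovery sets for the jerk threshold,
100 runs (20 seeds × 5 amplitudes) for ΔF/F recovery at 45 repeats,
fields of ≤ 200 varicosities for the exhaustive counting oracles,
25-second spontaneous traces at 10 kHz for template matching, and
100-window noise sets for false-positive calibration.

# Known limitations

* The overlap distance (0.5 µm), cartridge link/axis cut-offs, template
  criterion threshold, and failure-criterion k are explicit stand-ins
  for manual judgements; all are parameters and all are logged.
* The extent rule without smoothing is noise-fragile by construction;
  engage `smooth_width` for noisy profiles.
* Per-repeat bleach extrapolation across the response window carries
  irreducible variance at low SNR; amplitude estimates should be read
  per condition (pooled), not per cell.
* `summarize_groups()` uses pairwise Wilcoxon + Holm as its rank-based
  post hoc; Dunn's exact procedure is not implemented.
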