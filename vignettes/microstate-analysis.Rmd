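---
title: "Resting-state EEG microstate analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
microstate model and the assumptions behind each stage, the parameters that
matter and their defaults, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the classical
workflow leaves the details open.

## The microstate model

Average-referenced multichannel EEG can be viewed, frame by frame, as a
scalp topography $x(t) \in \mathbb{R}^C$. The microstate description
asserts that resting-state topographies do not drift continuously but
linger in one of a few quasi-stable configurations for tens of
milliseconds before switching abruptly:

$$x(t) \approx a(t)\, m_{s(t)} + \varepsilon(t),$$

with $K$ unit-norm, zero-mean prototype maps $m_1 \dots m_K$ (classically
four, labeled A--D), a piecewise-constant state sequence $s(t)$ with dwell
times of roughly 50--100 ms, and an amplitude $a(t)$ whose sign is
irrelevant: the generators are oscillatory, so $m$ and $-m$ are the same
brain state. Every comparison of topographies in this package is therefore
*polarity-invariant*: the spatial Pearson correlation across channels is
taken in absolute value.

Two quantities organize the whole analysis:

* **GFP** (global field power), the spatial standard deviation of the
  average-referenced topography at one frame. We use the population
  (divide-by-$C$) convention, the dominant one in the microstate
  literature; for centered data GFP equals the RMS over channels. GFP
  peaks are the moments of highest topographic signal-to-noise and supply
  the samples for clustering.
* **GEV** (global explained variance) of a labeling with maps:
  $\mathrm{GEV} = \sum_t \big(\mathrm{GFP}_t\, r_t\big)^2 \big/ \sum_t
  \mathrm{GFP}_t^2$, where $r_t$ is the spatial correlation between frame
  $t$ and its assigned map and unassigned frames contribute only to the
  denominator.

## Pipeline stages and their parameters

### Signal conditioning

* Bandpass 1--40 Hz, Butterworth order 2 (−12 dB/octave per edge), applied
  forward and backward for zero phase. Edge transients are suppressed by
  odd-symmetric reflection padding of three low-frequency periods; the
  passband gain error this leaves is below 2% of signal RMS on 10 s
  segments.
* Downsampling to 250 Hz after a zero-phase 4th-order low-pass at 90% of
  the target Nyquist; integer ratios decimate, non-integer ratios resample
  by linear interpolation.
* Bad channels are rebuilt by spherical-spline interpolation (order
  $m = 4$, 7-term Legendre expansion, ridge $10^{-5}$ on the spline
  system — the standard Perrin parameters, all configurable). Fields that
  lie exactly in the spline basis are reproduced to machine precision when
  the ridge is disabled.
* Independent-component artifact correction is deliberately *not*
  implemented: the pipeline accepts already-cleaned input, and the
  preprocessing functions are the hook where an external ICA step slots
  in. Likewise the choice of which neck/cheek channels to exclude is an
  explicit user-supplied list, not a heuristic.

### Clustering (modified k-means)

Subject-level clustering runs on the topographies at GFP peaks only.
Assignment is winner-takes-all by $|r|$; samples whose best $|r|$ falls
below `minAssignCorr = 0.5` remain unassigned and are excluded from
centroid updates (we read the threshold as "strictly below 0.5 ⇒
unassigned"). The centroid update is the first principal direction of the
assigned topographies — the natural polarity-invariant mean — computed by
warm-started power iteration; a sign-aligned weighted mean is available as
a cheaper alternative (`centroid = "meansign"`). Each run iterates until
the relative GEV improvement drops below $10^{-6}$ (cap 300 iterations);
the best of `nRestarts` random initializations (defaults: 100 subject
level, 200 group level) by GEV is kept, which makes runs deterministic
under a fixed seed. Empty clusters are reseeded from the worst-fitting
assigned topography. On small instances this procedure attains the
exhaustive-search optimum of the GEV objective, which the test suite
verifies by enumerating all assignments (the per-cluster optimal centroid
under the GEV objective is the leading eigenvector of the GFP²-weighted
scatter of normalized topographies — the same eigenvector the k-means
update uses).

### Choosing the number of maps

The optimal $k$ (subject level 1--12, group level 1--15) is chosen by a
**meta-criterion**: the median vote of three standard model-order criteria
computed on the per-$k$ solutions — the Krzanowski–Lai index on the
GFP²-weighted unexplained dispersion $W(k)$, the predictive-residual
(cross-validation) criterion, and the maximum-distance elbow of the $W$
curve. The meta-criterion used by the Cartool toolbox is unpublished; this
three-criterion vote is our documented approximation, and the full per-$k$
diagnostic table with each criterion's vote is always returned. On
synthetic recordings with four well-separated planted maps, all three
criteria typically vote 4.

The group stage pools *all retained subject maps* from every participant
into a single clustering — one analysis across groups, because clustering
each subgroup separately inflates false-positive rates. "Most dominant
topographies" is read as each subject's full optimal-$k$ map set, the
common usage. Group maps are canonically ordered by best match to
idealized A--D template fields built from the sensor positions
(right-frontal→left-posterior, left-frontal→right-posterior,
frontal→occipital, frontocentral); unmatched maps append in decreasing
explained-variance order.

### Backfitting

The group maps are fit back onto **every frame** of each subject's
recording (not only GFP peaks): argmax $|r|$, threshold 0.5. Temporal
smoothing uses windowed-vote rescoring: each assigned frame's score for
state $s$ is the evidence $(\mathrm{GFP}_t r_s(t))^2$ plus
`smoothnessWeight = 15` times the count of $s$-labels within the 11-frame
window (half-width 5); sweeps run left-to-right until no label changes
(cap 50; a frame whose window is unanimous can never flip). The exact cost
function behind the classical "window 11, smoothness 15" settings is not
published; this rescoring is our documented interpretation, with both
parameters exposed. Unassigned frames never gain a label.

Segments of ≤ 5 frames (20 ms at 250 Hz) are rejected: split in half,
first $\lfloor n/2\rfloor$ frames to the preceding segment, the rest to
the following one — a deterministic tie-break for odd lengths. A short
segment at a boundary, or flanked by an unassigned gap, is absorbed
entirely by its single labeled neighbor (or becomes unassigned when it has
none). Because absorption can merge two runs of the same state and create
a new short run, the rule is re-applied to a fixed point; each pass
strictly reduces the number of labeled runs, so termination is guaranteed
and the pass count is reported.

### Temporal parameters

Per subject and state: mean **duration** (ms), **occurrence** (segments
per second of labeled time), **coverage** (% of labeled time) and **GEV**
(%). Unassigned frames are excluded from every denominator *except* GEV's,
which spans the total GFP² of all frames — the "fraction of the data
explained by the group maps" reading; the alternative (labeled-frames
denominator) would overstate the explained fraction whenever frames are
unassigned. Durations of states that never occur are reported as missing
rather than zero, to avoid biasing group means; their occurrence, coverage
and GEV are zero. The exact identity
$\text{coverage} = \text{duration} \times \text{occurrence} / 10$
(%, ms, s⁻¹) holds by construction and is asserted in the tests.

### Source imaging

The paper-scale head model (template-MRI, LSMAC, ~7000 gray-matter points)
is out of scope; the package substitutes a fully synthetic spherical model
that preserves every algorithmic step. The forward model is the analytic
quasi-static potential of a current dipole in a homogeneous unit
conducting sphere (Legendre series, 40 terms), evaluated on a quasi-uniform
grid of solution points (default 800, radius ≤ 0.85) for the montage
sensors. The inverse is a Laplacian-weighted minimum norm (LORETA-style):
$J = W^{-1}G^\top (G W^{-1} G^\top + \lambda c I)^{-1} x$ with $W$ the
squared k-nearest-neighbor graph Laplacian applied per orientation, and
$\lambda$ scale-free via $c$ = mean diagonal of $GW^{-1}G^\top$. The
default $\lambda = 1/9$ follows the fixed-SNR heuristic $1/\mathrm{SNR}^2$
at SNR 3 (no regularization value is standard; it is exposed in config).
Orientations are free; point activity is the Euclidean norm over the three
components. Each point's time series is then standardized (z-scored)
across time to remove depth-dependent activation bias — we keep the signed
z-scores rather than re-rectifying, so the per-point time mean is exactly
zero — and the per-state source map averages the standardized densities
over frames labeled with that state whose winning correlation exceeds
0.9.

Known behavior, verified in the tests: noiseless cortical-shell point
sources (radius ≳ 0.5, within sensor coverage) are localized within two
grid steps, localization improves with sensor count, and deep or
below-coverage sources blur toward neighboring shells — the classical
low-resolution character of this inverse. Depth weighting was evaluated
and rejected: combined with the Laplacian prior it pushed all estimates
toward the center on this model.

### Statistics

One-way ANOVA compares the three groups per parameter and state; the
summary-statistics form
$F = \frac{\sum n_i(\bar m_i - \bar m)^2/(k{-}1)}{\sum (n_i{-}1)s_i^2/(N{-}k)}$
reproduces F statistics exactly from printed group means/SDs/sizes and is
verified against the raw-data ANOVA algebraically. Post-hoc pairwise tests
are pooled-variance t tests (Welch by flag), corrected with
Benjamini–Hochberg FDR at $\alpha = 0.05$ within the family of the three
pairwise tests of one parameter × state cell — matching figure-panel-wise
reporting; a global family is available. Cohen's d uses the
$(n_i-1)$-weighted pooled SD, with the first-minus-second sign convention.
Questionnaire scoring sums ten fixed triplets of the thirty 1--5 Likert
items into domain scores in $[3, 15]$; the item→domain map ships as an
editable configuration because published item orderings vary.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is validated.

* **Maps**: random combinations of low-order polynomial (solid-harmonic)
  fields of the sensor positions — spatially smooth by construction —
  redrawn until all pairs satisfy $|r| \le 0.6$.
* **State sequence**: semi-Markov, not first-order Markov — dwell times
  are gamma (shape 2) with the planted per-state means (defaults 55, 65,
  75, 60 ms, within the empirical 50--80 ms range), successors drawn from
  a zero-diagonal transition matrix. Geometric dwell times would
  misrepresent microstate duration distributions and make mean durations
  awkward to plant.
* **Signal**: $x(t) = A\,a(t)\,m_{s(t)} + \text{noise}$ with $a(t)$ a
  rectified 10 Hz sinusoid (GFP waxing/waning at alpha rate, giving ~20
  GFP peaks/s), $A = 30\,\mu V$, and spatially correlated noise
  (neighbor-averaged white noise) scaled to the requested signal-to-noise
  ratio (default SNR 5). Every frame is average-referenced.
* **Cohorts**: the default design mirrors a three-group clinical study
  (30/60/60 subjects): group effects are planted as multipliers on the
  *generator* dwell-time means (default: one state reduced ×0.85 in the
  first two groups, another increased ×1.15 in the first), never on
  extracted metrics, so recovery exercises the entire pipeline.
  Between-subject variability is log-normal (σ_log = 0.08) on the
  dwell-time means. Ground-truth temporal parameters are computed from the
  generated label sequence with independent arithmetic (no code shared
  with the metrics module) and must agree exactly.
* **Questionnaire**: a designated domain's latent score mixes the z-scored
  true occurrence of a designated state with noise at a target correlation
  (default 0.3), then is split into three items, discretized to 1--5 and
  re-summed — mimicking 3-item Likert domains and the attenuation
  discretization causes.

What it does **not** emulate: 1/f background spectra, eye-blink/ECG
artifacts, volume-conducted inter-subject topography differences, or
electrode digitization error. Passing recovery tests therefore shows the
pipeline is *internally correct and calibrated* — unbiased under the
model's own assumptions — not that those assumptions hold for any given
real recording.

## Validation experiment sizes

The test suite and the acceptance script run the recovery experiments at
sizes chosen to make the Monte-Carlo answer clear while keeping a full run
in minutes: map-recovery cohorts of 12 subjects × 60 s at 32 channels and
SNR 5 (subject k-range 2--6 with 15--20 restarts, group 2--8 with 30--40);
effect-recovery cohorts of 5/10/10 subjects × 40 s at 24 channels with a
0.75 duration multiplier; null calibration over 200 effect-free cohorts
using the generator's sequence-only fast path; exhaustive-search
comparisons on ≤ 10 topographies over 6 channels; and a 220-point,
48-sensor head model for the inverse. Under these conditions the planted
k = 4 is recovered by the meta-criterion, group maps match planted
templates with $|r| > 0.99$, the planted duration decrease is recovered in
direction with FDR-significant pairwise tests, and the null rejection rate
sits at the nominal α within Monte-Carlo error.

## Known limitations

* The meta-criterion and the smoothing cost are documented approximations
  of unpublished toolbox internals; their parameters are exposed rather
  than claimed canonical.
* Backfitting smoothing and short-segment rejection compress group
  differences in mean duration (a planted ratio of 0.75 is recovered
  around 0.8--0.9): direction and significance are preserved, absolute
  effect sizes are attenuated. This bias is shared across groups.
* The spherical head model supports algorithm-level claims only; no
  anatomical labeling of sources is possible or attempted.
* Durations are quantized to frames (4 ms at 250 Hz); planted means are
  recovered to within sampling error plus a sub-frame rounding bias.

```{r example, eval = FALSE}
# A complete run, driven by one config:
library(microstates)
res <- runPipeline(list(
  seed = 1, out = "run1",
  simulation = list(nChannels = 32, durationS = 60, K = 4, snr = 5),
  cohort = list(groupSizes = c(4, 4, 4)),
  clustering = list(subjectKRange = 2:6, groupKRange = 2:8),
  sources = list(enabled = TRUE, nPoints = 200, states = 3)))
res$stats
```
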