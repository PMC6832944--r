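---
title: "Portable activity clustering: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Portable activity clustering: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristclust)
```

## The problem and the modelling idea

Wrist-worn accelerometers record raw triaxial acceleration in g at 80–100 Hz
for days at a time. Supervised activity classifiers need labelled training
data, which is costly and ties the classifier to the labelled protocol. The
approach implemented here is unsupervised: summarise the signal into
window-level features, let *k*-means find structure, and make the model
*portable* — every quantity needed to reproduce an assignment (feature list,
normalisation parameters, centroids) is stored in a plain-text JSON file and
reapplied blind to new recordings. Identical centroids across studies mean
cluster "C" denotes the same region of feature space everywhere, so cluster
occupancy can be compared between populations that were never jointly
modelled.

Over-clustering is deliberate: with nine expected activity types we fit
K = 10, so that a heterogeneous behaviour (e.g. household activity) can
occupy several clusters rather than contaminate one. Interpretation happens
afterwards, by collapsing clusters into broad behaviour categories and
checking, against labelled ground truth, what fraction of each activity's
windows each category captures.

## Signal model and features

A recording is a uniformly sampled series $(x_t, y_t, z_t)$ in g. Within
each non-overlapping 10-s window we compute 47 candidate features:

* **Magnitude statistics** per axis: max, min, mean, median, 10th/75th/90th
  percentile, standard deviation, variance (units: g).
* **ENMO** per sample, $\max(0, \sqrt{x^2+y^2+z^2} - 1)$ (g): its window
  mean, max and median. ENMO removes the 1 g gravity offset; flattening
  negatives to zero makes a resting device read exactly 0.
* **Orientation angles** per sample and axis,
  $\theta_a = \arctan\!\big(a / \sqrt{b^2+c^2}\big)\cdot 180/\pi \in
  [-90^\circ, 90^\circ]$: window min, max, mean, median and SD per axis.
  At rest these estimate wrist posture; their dispersions index postural
  variability and are insensitive to the wrist of wear.
* **Frequency features**: dominant frequency (Hz) and its power from the
  periodogram of the window's ENMO series.

The canonical model uses a fixed 24-feature subset of these (one frequency,
eleven magnitude, twelve angle features), originally chosen by requiring
|Pearson r| ≥ 0.12 between feature and integer-encoded activity class on a
development sample. The subset ships as data
(`canonical_feature_spec()`) rather than being recomputed, because the
selection depends on the encoding of the class vector and on the
development data; `select_features()` re-runs the procedure when users want
their own selection, with the class encoding an explicit, user-suppliable
ordered label list (default: nine laboratory activities ranked by typical
intensity, coded 0–8).

### Numerical conventions

Decisions the feature definitions do not themselves fix:

* **SD/variance** use the population convention (divide by $n$). A 10-s
  window at 100 Hz has $n = 1000$, so the distinction is negligible there,
  but the convention is applied uniformly and the tests assume it.
* **Percentiles** interpolate linearly between order statistics
  (`quantile` type 7, R's default).
* **Degenerate angle denominators** (acceleration entirely along one axis)
  resolve to ±90° via the two-argument arctangent; the all-zero vector is a
  hard error.
* **Periodogram**: plain (untapered) $|{\rm FFT}|^2/n$ on the ENMO series,
  DC bin excluded, resolution $1/\text{window width}$ = 0.1 Hz. ENMO is
  used rather than the raw magnitude because the 1 g offset otherwise
  dominates the low-frequency bins. A constant window reports (0, 0) by
  convention. Power is reported as the raw bin value; note it scales with
  the number of samples in the window, one reason it is not among the
  canonical 24 features.
* **MinMax normalisation** maps each feature through
  $(x - \min)/(\max - \min)$ with training-set parameters; a constant
  training column maps to 0; new data are *not* clipped to [0, 1], because
  clipping would distort distances to the stored centroids.

## The clustering model

`activity_kmeans()` is Lloyd's algorithm: assign each window to the nearest
centroid by squared Euclidean distance, update each centroid to its members'
mean, stop when assignments stabilise (or after `max_iter = 300`
iterations). Initialisation is k-means++ (D² sampling); the best of
`n_restarts = 10` runs by total within-cluster sum of squares is kept; the
whole fit is a deterministic function of the seed. Three further choices the
algorithm statement leaves open:

* **Ties** in assignment go to the lowest cluster index.
* **Empty clusters** are reseeded to the point farthest from its current
  centroid, which cannot increase the objective.
* **Cluster letters**: clusters are renamed A, B, … in ascending order of
  their members' mean ENMO, ties kept in original index order. The letters
  are an analyst-facing convention that makes purity matrices comparable
  across runs; nothing downstream depends on it semantically.

The model file is JSON with full-precision decimal floats and no
timestamps, so refitting with the same inputs and seed reproduces the file
byte for byte, and reapplying a file produced elsewhere gives identical
assignments. We chose a self-describing text format over binary
serialisation precisely because portability is the method's point.

## Evaluation statistics

With $n_{ij}$ the number of windows of class $j$ in cluster $i$, cluster
totals $n_{ci}$, class totals $n_{ej}$ and grand total $N$:

$$\mathrm{ACP} = \frac{1}{N}\sum_i \sum_j \frac{n_{ij}^2}{n_{ci}}, \qquad
  \mathrm{AEP} = \frac{1}{N}\sum_j \sum_i \frac{n_{ij}^2}{n_{ej}}.$$

Both lie in (0, 1]; ACP is 1 iff every cluster is single-class, AEP is 1
iff every class is single-cluster. For the combination ACEP two conventions
coexist: the literal product $\mathrm{ACP}\times\mathrm{AEP}$ and the
geometric mean $\sqrt{\mathrm{ACP}\times\mathrm{AEP}}$ used in the speaker
diarization literature these statistics descend from. `acep()` defaults to
the product and offers `method = "geometric"`; the discrepancy is
documented rather than resolved. The purity matrix reports, for each class,
the percentage of its windows per cluster (rows sum to 100); report output
is rendered at one decimal while internal computation is full precision.
Classes absent from a dataset are simply omitted rows. Bland–Altman
agreement of daily minutes reports the mean paired difference and the
1.96·SD (sample SD, $n-1$) half-width as a single limits-of-agreement
number per category.

Reference purity matrices and a daily-minutes agreement summary for one
published development/validation study of this method ship under
`inst/extdata/` so the collapsing arithmetic can be exercised against known
totals; `reference_purity()` and `reference_daily_minutes()` load them.

## The synthetic-data generator

`simulate_recording()` emulates a laboratory protocol as a schedule of
archetypes. Static postures hold a fixed gravity orientation, perturbed by
a slow (0.05 Hz) wobble sinusoid with a per-bout random offset
(SD = wobble/2) and white Gaussian noise per axis. Ambulation adds three
cadence-locked components: an orientation oscillation (tilt amplitude
min(30°, 40·amplitude)), a magnitude modulation along gravity (the
"bounce", which is what places the cadence into the ENMO spectrum), and a
smaller perpendicular sway in quadrature. The three components share one
random phase per bout: arm swing and step impact are phase-locked in real
gait, and an earlier variant with independent phases made arm-swing
features artificially inconsistent between simulated studies. Left-wrist
wear mirrors the X and Z axes, matching the device's axis layout.

Default archetypes: lying, seated and standing (distinct gravity
orientations, noise 0.01–0.02 g), household (no cadence, large wobble,
noise 0.08 g), three walking speeds (amplitude 0.15–0.25 g, cadence
1.6–1.9 Hz), brisk walking (0.45 g, 2.2 Hz), stairs (0.40 g, 1.4 Hz) and
running (0.80 g, 2.8 Hz). The default protocol runs each archetype once,
3–5 min per bout (41 min, 246 windows at 100 Hz) — large enough for a
K = 10 fit with every cluster populated, small enough that the full test
suite completes in well under a minute.

**Intensity collapsing.** To interpret a fit without labels, clusters are
mapped to four categories by their mean member ENMO with fixed cuts at
0.04, 0.12 and 0.20 g: 40 mg is the standard sedentary boundary for wrist
ENMO, and the upper cuts fall between the mean rectified-sine ENMO levels
of the simulated walking (≈ amplitude/π ≈ 0.05–0.08 g), brisk
walking/stairs (≈ 0.13 g) and running (≈ 0.26 g) archetypes. These cuts
are part of the generator's study conditions, fixed once.

**What the simulator does not model** — and hence what passing tests do
not show about real data: gait harmonics beyond the fundamental,
device-specific noise spectra, temperature drift, non-wear, free-living
behaviour mixtures, and between-subject anthropometric variation. One
consequence is that simulated activities separate more cleanly than real
ones: purity indices near 0.75–0.85 and capture percentages near 100% on
synthetic protocols say the pipeline is implemented correctly, not that
real wrist data would cluster that well. Conversely, because each archetype
appears as a single bout with one random posture offset per study,
cross-study feature-profile drift for a cluster is estimated from one bout
against one bout; it is typically below 0.1 normalised units but can reach
≈ 0.12 for the high-intensity cluster under unlucky posture draws — a
limitation of the one-bout protocol, not of the stored-model mechanism.

## Windowing and labelling rules

Windows are tumbling (non-overlapping), `round(width · fs)` samples each,
with the trailing partial window dropped. Thirty seconds are discarded from
each end of every labelled bout before labelling; a window is labelled only
if it lies entirely inside one trimmed bout, which prevents mixed-label
windows at activity boundaries. Sample ranges are 0-based and half-open;
time is seconds from recording start. Non-uniform timestamps (beyond half a
sample interval) are a hard error rather than being resampled, and signal
values are assumed already calibrated to g.

## Known limitations

* K is fixed by the user; no internal K-selection diagnostics are provided.
* k-means presumes roughly spherical clusters in normalised feature space;
  behaviours with strongly non-convex signatures will split or merge.
* The canonical feature list is tied to the 10-s window and the wrist wear
  site; other epochs or sites need re-selection.
* The evaluation module quantifies cluster content; it never auto-assigns
  semantic labels to clusters — category maps are explicit user input.
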