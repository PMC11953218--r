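---
title: "Microstate and peak analysis of TMS-evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate and peak analysis of TMS-evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepstates)
```

## The problem

A transcranial magnetic stimulation (TMS) pulse over primary motor cortex
evokes a stereotyped EEG response — the TMS-evoked potential (TEP) — whose
components (N15, P30, N45, P60, N100, P180) index the recruitment of
distinct cortico-cortical circuits. Two stimulation parameters change which
circuits are recruited: the pulse waveform (monophasic vs. biphasic) and the
induced current direction (posterior–anterior PA, anterior–posterior AP,
latero-medial LM), giving a 2 × 3 within-subject design.

`tepstates` implements the two complementary analyses of such data:

1. **Component peaks** — amplitude and latency of each canonical TEP
   component, extracted as the signed extremum of a four-electrode
   region-of-interest (ROI) average within a fixed, non-overlapping time of
   interest (TOI).
2. **Microstates** — periods of quasi-stable scalp topography, obtained by
   GFP-normalized modified k-means clustering of the grand-average
   topographies, with a randomization test for topographic consistency,
   cross-validated selection of the number of maps, per-subject backfitting,
   and feature extraction (AUC, duration, onset).

An inferential layer (repeated-measures ANOVA with sphericity handling,
Tukey post-hocs, robust trimmed-means rmANOVA, ANCOVA with stimulation
intensity, and a gamma/identity mixed model for onset order) connects both
to the experimental design. A synthetic TEP generator with known ground
truth makes every stage testable without recorded data.

## Data model and conventions

* **Time** is in milliseconds relative to the TMS pulse. Analysis windows
  are half-open `[start, end)`; the default is **5–400 ms** (the early bound
  avoids residual pulse artifacts). Component TOIs are *closed* intervals so
  that printed tables with touching decimals (e.g. 24.9 / 25) partition
  time exactly as written. Some analyses of full epochs use 0–400 ms; the
  window is a configuration value, not a constant.
* **GFP** (global field power) at a timepoint is the spatial standard
  deviation of the average-referenced map — a reference-free response
  strength.
* Evoked records are channels × time matrices in µV at a common sampling
  rate (recordings preprocessed at 4800 Hz are decimated by the integer
  factor 5 to **960 Hz** before microstate analysis).
* The montage is a 74-channel 10-10 layout. Positions are reconstructed
  from nominal 10-10 arc angles on a unit sphere — an idealized geometry,
  sufficient because positions only parametrize the spatial smoothness of
  synthetic maps and plotting, never the analysis itself.

## Peak extraction

For each component the ROI trace is the unweighted mean of four electrodes
(built-in table, user-overridable). The amplitude is the **signed extremum**
within the TOI — minimum for N components, maximum for P components — and
the latency its time. A strict local-peak rule is deliberately not used:
individual subjects may lack a component or show inverted polarity, and the
TOIs are already defined to be non-overlapping, so boundary extrema are
eligible. Ties resolve to the earliest sample (determinism).

Group screening flags a subject for a component when amplitude **or**
latency in any condition deviates from that cell's mean by strictly more
than 2.5 SD (single pass; exclusion applies to that component in all
conditions). Normality repair follows a fixed ladder — none, √, log10,
inverse, each shifted into positivity when needed — scored by Shapiro–Wilk
W; if no candidate reaches p > .05 the variable is routed to the robust
(trimmed-means) analysis instead.

## Microstate pipeline

**Normalization.** Each subject's record is divided by its mean GFP over
the analysis window (mean GFP becomes exactly 1). This removes amplitude
differences between subjects while preserving topography and the relative
GFP time course. Normalization by the *mean* GFP — not timepoint-wise — is
the default because timepoint-wise division would flatten the GFP weighting
that the clustering and GEV statistics rely on.

**Topographic consistency test (TCT).** Per condition and timepoint the
observed statistic is the GFP of the across-subject mean map. The null is
built by independently shuffling each subject's channel order (random
topographies, amplitudes intact), re-averaging and recomputing the GFP,
5000 times by default. p-values use the add-one rule
`(1 + #{null ≥ obs}) / (1 + n_perm)`, never zero. The permutation core is
compiled (RcppArmadillo) and draws from R's RNG, so runs are seed-exact.

**Segmentation.** Condition grand-averages over the window are
concatenated and clustered by modified k-means: templates seeded from
observed timepoints, each timepoint labelled with the template of maximal
**signed** spatial correlation (evoked convention — polarity carries
information; an ignore-polarity option exists for resting-state-style use),
templates re-estimated as the normalized mean of their members. Global
explained variance,

GEV = Σₜ GFP(t)² r(t)² / Σₜ GFP(t)²,

is evaluated after every template update, and the best matched
configuration across all restarts (default 250) is retained. An empty class
is reseeded from the worst-fit timepoint. Restart seeding is
k-means++-style: the first seed is drawn with probability ∝ GFP², later
seeds ∝ GFP² × (1 − best r² so far). This markedly improves the quality of
few-restart fits (important inside cross-validation) while remaining a
draw from observed timepoints. Template sign is indeterminate (flipping a
template and its members' polarity leaves GEV unchanged); recovery is
therefore always assessed via |correlation| after optimal class matching.

**Choosing K.** For each K in 3–12, subjects are repeatedly (50×) split
into random halves; templates fit on the learning half's grand-averages
are backfit to the test half's, and the mean test GEV per K forms the
curve. The selected K is the smallest one within 1% of the curve's maximum
("first K on the plateau"). Inside the loop each fit uses 3 ++-seeded
restarts (max 20 iterations) — with the improved seeding this matches
many-restart fits on data of this size at a fraction of the cost. When the
curve maximum stays below 0.5 the selection is flagged unreliable.

**Backfitting and features.** Group templates are backfit to every
subject × condition record (max signed correlation; ties to the lowest
class; the fraction of timepoints with max |r| < 0.5 is reported as
low-confidence). Per class: AUC = Σ GFP·Δt over labelled samples (ms·µV),
duration = #samples·Δt (ms), onset = first labelled time (absent if the
class never occurs). Durations sum to the labelled span and AUCs to the
total GFP area exactly — these conservation laws are asserted in tests.

**Subject screening.** Each subject is represented by their concatenated
condition-average maps, PCA-reduced to ≥ 90% variance (at most n − 2
dimensions), and scored by Mahalanobis distance to the group centroid;
subjects beyond the χ²(0.99) quantile are flagged. The exact feature space
of the original graphical tool is not published; this PCA construction is
the package's documented choice.

## Statistical layer

* **rmANOVA (2 × 3)** from balanced sums of squares, each effect tested
  against its own subject-interaction error; Mauchly's test per
  multi-level effect, Greenhouse–Geisser correction when Mauchly p < .05
  (the two-level waveform factor is exempt); ηp² = SSₑ/(SSₑ+SS_err).
  Cross-checked in the tests against `aov()` and `mauchly.test()`.
* **Tukey post-hocs**: paired t statistics for all cell pairs, adjusted via
  the studentized range with the number of cells as the number of means;
  paired Cohen's d = mean difference / SD of differences.
* **Robust rmANOVA**: Wilcox-style trimmed-means test (default 20% trim):
  between-level mean square of trimmed means over the effective sample
  size h, against an error term from the winsorized covariance matrix,
  with Huynh–Feldt-type ε̃ degrees of freedom estimated from that matrix.
  At trim = 0 it reduces *exactly* to the classical one-way rm-F (oracle
  test). Contrast estimates ψ use winsorized-variance SEs on h − 1 df.
* **ANCOVA**: direction effect per waveform adjusted for TMS intensity via
  `lmer(value ~ direction + intensity + (1 | subject))` with Satterthwaite
  df.
* **Onset model**: `glmer(onset ~ class * condition + (1 | subject),
  Gamma(identity))` on strictly positive onsets (absent onsets dropped
  listwise and counted). Fixed effects get Wald type-III χ² on sum-to-zero
  contrasts. Post-hoc family: the 15 class pairs within each of the 6
  conditions — 90 contrasts — Benjamini–Hochberg adjusted over that
  declared family (missing members count as p = 1 via the family-size
  denominator). Pairs with significant opposite-signed contrasts in
  different conditions are reported as **order swaps**. Fitting uses
  `nAGQ = 0` (fast PIRLS-only estimation; with one scalar random effect
  its estimates are indistinguishable from the default here, and it keeps
  Monte-Carlo calibration studies tractable); a zero-variance (singular)
  subject effect is legitimate and not treated as a failure, while a true
  non-convergence triggers a flagged log-link refit. The Wald covariance
  is scaled to the **Pearson** estimate of the gamma dispersion — the
  moment estimator `summary.glm` uses for gamma models — because the
  ML/deviance-based estimate makes the χ² tests conservative (size ≈ 0.02
  instead of ≈ 0.04 at nominal .05 in our calibration).

## The synthetic generator

Ground truth consists of K unit-norm, zero-mean, spatially smooth random
maps (Gaussian fields smoothed over electrode geometry — clustering only
ever sees topography vectors, so dipole-level realism is unnecessary),
a per-condition plan of contiguous class segments, and a GFP envelope of
Gaussian bumps at the component latencies 15/30/45/60/100/180 ms plus a
broad low-amplitude late slow wave (300 ms, width 60 ms, 2 µV): recorded
TEPs do not decay to zero field late in the epoch, and without that bump
the late microstate segment would be pure noise by construction.

Each record is `envelope(t) · scaleₛ · √n_ch · map_class(t)` inside
segments plus white sensor noise, so the noiseless GFP equals the envelope
times the subject scale exactly. Between-subject variation: lognormal
amplitude scale (σ_log = 0.2), independent boundary jitter (default
N(0, 3 ms), order-preserving), and 10% spatial perturbation of each
subject's maps. Sensor SNR is defined as mean in-window noiseless GFP over
noise SD; the clean fixture uses SNR 5. Everything is reproducible
bit-exactly from one seed.

Bundled fixtures: `clean6` (27 subjects, 6 maps, shared segment order),
`swapAB` (classes 1 and 2 exchange their slots — 60 ms onset gap — between
monophasic and biphasic conditions; jitter 10 ms), `swapnull` (same
geometry, no swap), `deviant1` (clean6 with one channel-scrambled
subject), `nullflat` (pure noise, for TCT calibration).

What the generator does **not** emulate: volume-conducted component
overlap (segments are pure single-class), pulse and muscle artifact
residues, oscillatory background EEG (noise is white), or electrode-level
artifacts. Passing tests therefore demonstrate correctness of the
algorithms under their own assumptions, not robustness to every pathology
of recorded TMS-EEG.

## Validation design and problem sizes

The test suite validates, among others: template recovery on `clean6`
(all six maps at |r| ≥ 0.95, GEV ≥ 0.90, 250 restarts); exactness on
noiseless data (GEV = 1 within 1e-9, onsets within one sample,
conservation within 1e-9); map-count selection (50-iteration CV on twenty
12-subject datasets); TCT size and power (5000 permutations; null fraction
of significant timepoints within [0.03, 0.07] over 1000 samples, ≥ 95%
significant at SNR 2); equality of small-instance segmentation with the
brute-force optimum over all 2⁸ labelings (100 instances, exact by
exhaustive labeling-seeded restarts); swap detection on `swapAB` (20
simulations) with null size of the interaction Wald test measured on 600
model-consistent gamma draws; peak exactness at every component; oracle
equivalence of the ANOVA/BH/trimmed statistics; and Mahalanobis ranking
(100 deviant datasets). Monte-Carlo sizes are fixed seeds and are chosen
to keep the whole suite desk-scale.

The null calibration of the onset model deserves a note: with *additive*
onset jitter (constant variance), the gamma model's variance-∝-µ²
assumption makes the Wald test markedly conservative — a property of the
model, not a bug; the calibration study therefore draws onsets from the
model's own family (gamma, CV ≈ 0.17, subject intercepts), which is the
correct check that the test implementation holds its nominal size.

## Numerical choices and edge cases

* Permutation p-values use the add-one rule; they can never be zero.
* Labeling ties resolve to the lowest class index; equal extrema in peak
  extraction to the earliest sample.
* An empty k-means class reseeds from the worst-fit timepoint.
* Flat (zero-GFP) maps get zero correlation with every template rather
  than NaN.
* Degenerate inputs error loudly: zero mean GFP in normalization, constant
  transform input, constant ANCOVA covariate, incomplete designs (the
  offending subjects are named), non-positive onsets in the gamma model.
* `downsample_evoked()` refuses to upsample; non-integer ratios go through
  polyphase resampling (`signal`), the 4800→960 path is pure decimation.

## Known limitations

* The robust trimmed-means statistic implements the Wilcox formulation
  directly (see the trim → 0 oracle); other software may differ in its ε̃
  details at heavy trimming.
* Wald χ² tests at `nAGQ = 0` with Pearson dispersion are near-nominal but
  mildly conservative in our calibration; likelihood-ratio tests would
  need much slower fits.
* The Mahalanobis screen's χ² threshold is conservative when the retained
  dimension approaches the subject count (distances saturate); ranking is
  the more robust output, and the threshold, dimension and distances are
  all reported.
* Group-level label sequences (from the segmentation) and subject-level
  backfits are both produced; figures of the former should not be read as
  subject consensus.
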