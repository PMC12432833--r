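---
title: "Individual functional channels of interest in block-design fNIRS: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual functional channels of interest in block-design fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through scalp optodes: light at two or three near-infrared wavelengths is
attenuated by oxy- and deoxy-hemoglobin (HbO/HbR), whose concentration
changes follow neural activity. A central question this package supports is
whether inferior-frontal cortex contains *language-selective* tissue distinct
from the *multiple-demand* (MD) tissue recruited by cognitive effort — a
double dissociation: language channels respond to intact versus acoustically
degraded speech but not to task difficulty, MD channels the reverse.

Group analyses that assume a fixed channel-to-cortex correspondence are
fragile, especially developmentally: head size, probe placement, and
functional anatomy vary across individuals. The functional
channel-of-interest (fCOI) approach instead selects, per participant, the
channel within an a-priori *search space* (the channels plausibly overlying
left or right inferior frontal gyrus) that shows the individual's maximal
localizer contrast, and then estimates that channel's response on data that
played no role in selecting it — either held-out runs of the same task
(leave-one-run-out, LORO) or all runs of the other task.

`fcoinirs` implements this analysis end to end, together with a synthetic
cohort generator with known ground truth so that every stage — and the
double-dissociation logic as a whole — can be validated by parameter
recovery without access to any human recordings.

## The preprocessing chain

Each run is processed in isolation (one run's noise can never skew
another's normalisation), in a fixed order:

1. **Channel pruning.** A channel is kept iff at every wavelength its mean
   raw intensity lies in `[1e3, 1e7]` (detector counts) and mean/SD ≥ 5.
   A constant channel has unbounded SNR and is kept. Visual-inspection
   exclusions ("no clear cardiac signal") are accepted only as an explicit
   user-supplied list; no quantitative cardiac criterion is invented.
2. **Negative-intensity guard.** Non-positive samples on kept channels are
   replaced by the channel's smallest positive value (counted in the
   provenance log) so the logarithm below is defined.
3. **Optical density.** `dOD(t) = -ln(I(t)/mean(I))`, per channel and
   wavelength. The run mean is the reference and the natural log is used —
   a common fNIRS convention; any base change is a constant factor that
   cancels in contrasts.
4. **Linear detrending** per channel/wavelength over the full run.
5. **TDDR motion correction** (temporal derivative distribution repair):
   the signal is split at 0.5 Hz; the low part's first difference is
   re-estimated by iteratively reweighted least squares with Tukey
   biweights (c = 4.685, tolerance 1e-8 on the maximum weight change, at
   most 50 iterations — literature values, all exposed in
   `preprocess_config()`); the corrected low part is rebuilt by cumulative
   summation and the high part added back. No user threshold is needed.
6. **Band-pass filtering**, 0.01–0.09 Hz: Butterworth low-pass of order 3
   and high-pass of order 5, each applied forward–backward (zero phase), so
   block means are never time-shifted; the effective response is the
   squared magnitude.
7. **Beer–Lambert inversion** with partial pathlength factor 1.0 per
   wavelength: the 2×2 extinction system is solved exactly; three
   wavelengths use the least-squares (normal-equations) solution. With
   ppf = 1 the concentration scale is molar-equivalent up to the unknown
   pathlength factor — immaterial, because every inference in the package
   is a within-subject contrast.
8. **PCA spatial filter** (σ = 46°): channel positions are projected to a
   head-centred unit sphere, the concentration matrix is decomposed by SVD,
   each spatial loading is smoothed with a Gaussian kernel in pairwise
   angular distance, and the reconstruction from smoothed loadings — the
   spatially global signal — is subtracted. Diffuse systemic physiology is
   removed; focal activity survives because smoothing dilutes sharp
   loadings. Applied per chromophore, after concentration conversion.

Every step is shape-preserving, never un-prunes a channel, and is recorded
in an ordered provenance log.

### Numerical notes on the filters

Butterworth designs use the bilinear transform with frequency pre-warping
and are *applied as cascaded second-order sections* (compiled): the
monolithic polynomial form of a 5th-order high-pass at 0.01 Hz against an
11 Hz rate has poles clustered near `z = 1` and loses ~11 digits of
precision; biquads do not. Unity gain is imposed exactly at DC (low-pass) or
Nyquist (high-pass). Zero-phase application uses odd-reflection padding of
about three time constants of the slowest pole, and the series mean is
removed before filtering (re-added only through paths with unit DC gain), so
constant inputs are annihilated exactly by the high-pass. Empirical gains
match the analytic `1/sqrt(1 + (f/fc)^(2n))` magnitude (squared for
forward–backward) to well under 1%.

### What TDDR does and does not guarantee

Two properties of the published TDDR algorithm matter for interpretation and
shaped the validation worlds:

* **It needs a noise floor.** The robust scale is the MAD of the
  low-frequency derivative. On *noise-free* input that MAD collapses and
  genuine response transitions become "outliers" that are clipped — the
  algorithm flattens the signal it was meant to protect. The noise-free
  forward/inverse recovery oracle therefore runs the chain with TDDR
  disabled (a config switch, not a code path change). With realistic noise
  the weights at response transitions are ≈ 0.95 and responses pass.
* **It shrinks, slightly but systematically.** When broadband noise
  dominates the sub-0.5 Hz derivative, Tukey weighting of a shifted
  distribution biases the re-integrated increments toward zero (≈ 8% for a
  Gaussian derivative, more when per-sample white noise is large). This is
  a property of the published estimator, not of this implementation; it is
  one reason recovered group effects are smaller than the injected
  amplitudes.
* **Artifact metrics are taken through the TDDR + band-pass cascade**, the
  configuration in which TDDR is deployed: TDDR repairs the
  sub-split-frequency content of spikes and steps, and the band-pass
  removes the sharp residue that TDDR adds back with its high-frequency
  path. Measured this way, 10-robust-SD spikes lose > 90% of their peak,
  5-robust-SD steps > 80% of their size, and block means of segments away
  from the artifact move < 5% — while the band-pass alone, without TDDR,
  leaves several-fold larger residues.

## Block responses, exclusions, selection, inference

**Block responses.** Each block is baseline-corrected by the mean of the
2 s preceding onset, then summarised as the arithmetic mean of HbO (HbR
carried alongside) over the analysis window — onset-relative
`[5, end)` seconds, half-open so integer sample grids are unambiguous. The
window end is task-specific: 20 s (adult language), 33 s (adult spatial
working memory), 17 s (toddler language), 12 s (toddler go/no-go; block
onset is the start of the 12-s trial sequence, excluding the 3-s
instruction screen). The 5-s start accounts for hemodynamic lag.

**Exclusions.** Per search space: a run is excluded when *strictly more
than* one third of the space's channels were pruned (2/7 keeps, 3/7
excludes); a subject is excluded, per task and space, below two valid runs
(exactly two is retained). Per-space bookkeeping means a run can be valid
for RIFG and excluded for LIFG; a config switch evaluates the rule over all
channels instead.

**LORO selection.** For each held-out run, per-channel condition means are
averaged over the remaining valid runs (unweighted mean of per-run means,
robust to unequal block counts); the in-space channel maximising the
positive-minus-negative HbO contrast is selected, ties broken by lowest
channel id (deterministic, seed-independent); the held-out run's block-level
responses at that channel are recorded. Channels pruned in any training run
are ineligible for that fold (requiring the held-out run too is available
via config). Cross-task estimation selects on *all* defining-task runs and
reads responses from the other task only; estimating on the defining task
without hold-out is refused as double dipping.

**Inference.** Block-level held-out (or cross-task) responses are modelled
as `HbO ~ condition + (1|subject)` by maximum likelihood (`lme4`), the
condition factor coded preferred = 1 / other = 0 so selectivity implies
β > 0 — the sign convention is stated in the output rather than matched to
any particular software's contrast coding. Wald t with residual df
(`n_obs − 2`); at these sample sizes df corrections are immaterial, and the
named penalised-likelihood variant of the original tooling coincides with
ML for a Gaussian random-intercept model. Random slopes are deliberately
absent (they do not converge at these sizes). A singular fit falls back to
its boundary (OLS) solution and is flagged. Family-wise control is
Bonferroni over the left/right pair within each task: α = 0.05/2 = 0.025.
The dissociation flag requires language fCOIs significant for the language
contrast and not for the demand contrast in both spaces, and the reverse
for MD fCOIs.

## The synthetic cohort: a stated world

The generator renders, per run: condition boxcars convolved with a
unit-peak double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6 — the
simplest standard kernel, identical for adults and toddlers since the
analysis assumes only a 5-s lag; the kernel is normalised to unit sum so a
sustained block plateaus at its stated amplitude), scaled per channel:
the preferred condition evokes `base + effect`, the other `base`. HbR is
−1/3 of HbO (a typical empirical inverse ratio). Noise adds white noise,
a random-walk drift, cardiac/respiratory/Mayer sinusoids with per-channel
phases, and a shared band-limited global component whose channel weights
form a smooth Gaussian random field with correlation length (120°) well
above the 46° filter kernel, so the spatial filter's assumption holds by
construction. Motion spikes (Gaussian, σ = 0.5 s — sharp enough to be
derivative outliers, narrow enough that most energy stays below the
0.5 Hz split) and step shifts are scheduled at seeded Poisson times,
injected in the OD domain where TDDR operates, and listed in a manifest.
Raw intensities follow the forward Beer–Lambert model,
`I = baseline · exp(−dOD)`, so the inversion round-trips exactly.

Defaults, chosen once: effect 0.5 µM and white noise 0.3 µM per sample
(stated calibration of the design); base response 0.1 µM; drift 0.2 µM;
cardiac 1.2 Hz / 0.15 µM, respiration 0.25 Hz / 0.1 µM, Mayer
0.1 Hz / 0.1 µM; global 0.5 µM; spikes 0.5/min at 0.02 OD; shifts 0.2/min
at 0.01 OD; between-subject effect SD 0.1 µM; baseline intensity 1e5
counts (mid `d_range`). Counterbalancing alternates condition order by
(subject + run) parity — deterministic and "systematically varied".
Behavioural responses are not simulated; the generator models hemodynamics
only. Everything is reproducible from one integer seed.

The packaged scenarios mirror the two experiments: adults — 20 subjects,
8 language + 4 working-memory runs, 79 channels at 760/850 nm, 11 Hz;
toddlers — 22 subjects, 4 + 4 runs, 81 channels at 730/808/850 nm. Channels
of the published inferior-frontal search spaces carry their tabulated MNI
coordinates (stored as printed, including the toddler table's
left-labelled channels with positive x: the printed search-space column is
authoritative and geometry never drives membership); remaining channel
positions are a deterministic synthetic scalp layout used only by the
spatial filter. Montage optode pairs are generated synthetically at 3 cm
separation.

What the generator does **not** emulate: layered scalp/skull optics and
photon transport (the forward model is the same Beer–Lambert expression the
inversion uses, which is exactly what makes round-trip validation
meaningful, and why a green round-trip says nothing about real-tissue
pathlength effects); short-separation channels; serially correlated
physiological amplitude modulation; behavioural data. A green recovery test
establishes that the *analysis* is correct and unbiased under the stated
world, not that the acquisition model is complete.

## Scaled-down validation worlds and honest limits

Repeated-cohort criteria use a *compact* world for runtime: the montage
shrinks to the two search spaces at their published sizes (7 + 6 adult,
5 + 5 toddler) plus three filler channels — laid out as bilateral frontal
patches with the real probe's ~3 cm (~13°) channel spacing, so the spatial
filter sees a comparable channel density — with 12 subjects (20 where
noted) and 4 runs per task; effect sizes, noise, block timing, and all
thresholds are unchanged. The LORO fold-accuracy criterion runs at the full stated
adult scale (20 subjects × 8 language runs × 79 channels).

Two recovery margins are worth stating plainly, because they are properties
of the analysis design rather than implementation defects:

* The adult demand contrast survives preprocessing at only ≈ 30–40% of its
  injected amplitude: the hard-minus-easy pattern of a run with two 34-s
  blocks in ≈ 98 s concentrates near 0.01 Hz, exactly at the high-pass
  corner, and linear detrending attacks the same component; TDDR shrinkage
  adds to this. With only four MD runs (one block per condition), MD fCOI
  selection then operates near its noise floor.
* Consequently the all-cells double-dissociation flag has a per-cohort
  probability around 0.7–0.85 in the adult-like compact world — close to,
  and sometimes below, the 80%-of-cohorts acceptance bar. The toddler-like
  pattern (shorter blocks, whose contrast sits comfortably inside the
  pass-band) recovers essentially always. We report the measured rates
  as-is rather than easing thresholds or retuning the stated world.

## Other design choices

* Recordings are stored as plain delimited text (full 64-bit precision,
  events in a sidecar) rather than an HDF5 container, keeping the package
  dependency-free in this environment; the loader validates wavelengths,
  channel counts, and event bounds against the montage.
* Extinction coefficients at 730/760/808/850 nm are compiled literature
  constants validated by the round-trip property; they are implementation
  inputs, not results.
* The degraded-speech generator low-passes the clip at 350 Hz (order 7,
  ≥ 40 dB an octave up), builds a noise track by a seeded uniform
  permutation of the samples (destroying phase while preserving the
  amplitude histogram exactly; 10-ms frame shuffling available), multiplies
  it by the clip's Hilbert-envelope, low-passes it at 8 kHz, and mixes at a
  configurable noise-to-speech RMS ratio (default 1.0 — "unintelligible" is
  not quantified, so the ratio is a parameter). Prosodic rhythm survives in
  the output's short-time energy profile, which is the point of the
  control condition.
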