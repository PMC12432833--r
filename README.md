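# fcoinirs

Individual functional channel-of-interest (fCOI) analysis for block-design
fNIRS experiments, with a fully seeded synthetic-cohort generator for
validation by parameter recovery.

## The problem

fNIRS estimates cortical HbO/HbR concentration changes from scalp-measured
attenuation of near-infrared light. A recurring question — here framed
around inferior-frontal cortex — is whether *language-selective* tissue
(responding to intact versus acoustically degraded speech, indifferent to
task difficulty) is dissociable from *multiple-demand* tissue (the
reverse). Because channel-to-cortex correspondence varies across heads and
caps, the fCOI approach selects, per participant, the channel within an
anatomical *search space* (left/right IFG channel sets) showing the
individual's maximal localizer contrast, and estimates its response only on
independent data: held-out runs (leave-one-run-out, LORO) within task, or
all runs of the other task across tasks.

The package implements, as tested units:

* **Preprocessing** (per run, in order): channel pruning (intensity range
  `[1e3, 1e7]`, SNR ≥ 5), negative-intensity guard, optical-density
  conversion `−ln(I/mean I)`, linear detrending, TDDR motion correction
  (Tukey-biweight reweighting of the sub-0.5 Hz derivative), zero-phase
  Butterworth band-pass 0.01–0.09 Hz (orders 3/5, run as compiled
  second-order sections), modified Beer–Lambert inversion (ppf = 1), and a
  PCA spatial filter with a 46° Gaussian kernel that removes spatially
  global systemic signals while keeping focal activity.
* **Block responses**: 2-s pre-onset baseline correction; windowed means
  over `[5, end)` s post-onset (end = 20/33 s adult, 17/12 s toddler);
  exclusion rules — a run is dropped when > 1/3 of a search space's
  channels are pruned, a subject when fewer than 2 valid runs remain.
* **fCOI selection**: LORO with deterministic tie-breaking and strict
  train/test separation; cross-task estimation; selection histograms.
* **Group inference**: `HbO ~ condition + (1|subject)` by maximum
  likelihood (`lme4`), preferred condition coded +1 so selectivity ⇒
  β > 0; Wald t, Bonferroni family threshold 0.05/2 = 0.025 over the
  hemisphere pair; an 8-cell dissociation report with a double-dissociation
  flag.
* **Synthetic cohorts**: boxcar ⊗ double-gamma HRF responses with
  channel-level ground truth, physiological oscillations, drifts, a smooth
  global component, seeded motion spikes/steps in OD, rendered to raw
  intensities via the forward Beer–Lambert model. Defaults: effect 0.5 µM,
  white noise 0.3 µM/sample; adult scenario 20 subjects × (8 language +
  4 working-memory) runs × 79 channels; toddler 22 × (4 + 4) × 81.
* **Degraded-speech stimuli**: 350 Hz low-passed speech plus an
  envelope-modulated, seeded sample-permutation noise track (8 kHz
  low-passed), WAV in/out.

## Worked example

Simulate and analyse a compact cohort (published search-space sizes, 20
subjects, 4 runs per task) with known ground truth:

```r
library(fcoinirs)
scn <- scenario("adult", compact = TRUE, n_subjects = 20, seed = 42)
res <- analyze_scenario(scn)
print(res$dissociation)
#> <dissociation_report> threshold 0.025, double dissociation: TRUE
#>   search_space fcoi_type data_task          beta          t            p significant
#> 1         LIFG  language  language  2.384761e-07 10.5295826 1.932500e-22        TRUE
#> 2         LIFG  language        md -3.237477e-08 -1.1823679 2.388361e-01       FALSE
#> 3         LIFG        md        md  1.696582e-07  4.7535238 4.466443e-06        TRUE
#> 4         LIFG        md  language -2.184905e-08 -1.0342848 3.017889e-01       FALSE
#> 5         RIFG  language  language  2.568608e-07 11.4100744 1.655895e-25        TRUE
#> 6         RIFG  language        md -7.276328e-08 -2.5021883 1.336046e-02       FALSE
#> 7         RIFG        md        md  9.051199e-08  2.6827430 8.079125e-03        TRUE
#> 8         RIFG        md  language -1.903330e-08 -0.9095512 3.637481e-01       FALSE
```

Reading the table: each row is one mixed-model fit (β in molar units, with
preferred condition coded +1). Language fCOIs in both hemispheres are
strongly selective for intact speech (rows 1, 5) and silent on the demand
contrast (rows 2, 6); MD fCOIs show the reverse (rows 3, 7 versus 4, 8), so
the double-dissociation flag is `TRUE`. The MD cells are systematically the
weakest (β recovered at ~0.1–0.17 µM of the injected 0.5 µM): the demand
contrast of 34-s blocks loses most of its amplitude to the 0.01 Hz
high-pass, detrending, and TDDR, and in a fair share of cohorts one MD cell
misses the corrected threshold — `scripts/acceptance.R` reports the honest
flag rate over 25 seeded cohorts (see the methods vignette for the
analysis). Selection itself is accurate:

```r
scn$truth$language_channels
#> [1] 2 9
print(res$histograms$LIFG.language)
#>   channel_id count
#> 1          2    71
#> 2          3     2
#> 3          4     1
#> 4          5     1
#> 5          6     1
#> 6          7     4
```

71 of 80 LORO folds pick the true LIFG language channel (channel 2). At the
full stated adult scale (8 language runs, 79 channels) fold accuracy is
about 95% with the modal channel equal to ground truth.

## Command line

```sh
Rscript inst/cli/fcoi-nirs.R simulate   --config scenario.json --seed 7 --out runs/
Rscript inst/cli/fcoi-nirs.R preprocess --in runs/ --out conc/
Rscript inst/cli/fcoi-nirs.R analyze    --config scenario.json --seed 7 --out results/
Rscript inst/cli/fcoi-nirs.R degrade    --in clip.wav --out clip_degraded.wav --seed 1
```

The scenario config is a JSON object of `scenario()` arguments, e.g.
`{"population": "adult", "compact": true, "n_subjects": 12}`.
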