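# attnmod

Attentional modulation analysis of decoded visual features, with a
synthetic encoding simulator for end-to-end validation by parameter
recovery.

## What this is for

When two images are superimposed at equal contrast and an observer covertly
attends one of them, the neural representation of the scene is biased
toward the attended image. A quantitative way to measure that bias is
**feature decoding**: train one linear regression per unit of a
hierarchical image-feature space that predicts the unit's activation from a
multivoxel response pattern (training on passively viewed single images),
then apply the decoders to the attention trials and compare the decoded
feature pattern against patterns of physically realizable stimuli.

`attnmod` implements the full analysis for researchers working with
trial-level response matrices (simulated or real):

* **Decoder training** — per-unit ordinary least squares on the voxels with
  the highest `|r|` against that unit's training feature values (capped,
  default 500), with z-score normalization of all patterns by training-set
  unit statistics, and a variance-matching correction for
  reconstruction-type consumers.
* **Weighted-contrast peak modeling** — correlate the decoded pattern of an
  attention trial with feature patterns of superpositions
  `S_w = (w/100)·A + (1−w/100)·B` over a 0–100% grid (5% steps); the
  argmax weight (*peak contrast*) is the stimulus-contrast equivalent of
  attentional modulation (50 = none). Per-pair means over both attention
  conditions give 45 data points; Cohen's *d* of `(peak − 50)` across pairs
  with a one-sided *t* test quantifies the shift.
* **Pair-wise identification** — the decoded pattern identifies the
  attended image between the two candidates by the larger Pearson
  correlation (chance 50%); single-image trials are identified against all
  nine false candidates.
* **Feature-set amplitude modulation** — per image, the top 10% of units by
  mean decoded value in single-image trials form its *feature set*; in
  attention trials, mean amplitudes over the attended, unattended and
  "other" sets measure unit-level modulation.
* **Statistics** — Cohen's *d*, one-sided *t*, Bonferroni, *t*-based 95%
  CIs, exact/Monte-Carlo permutation tests for correlations, post-hoc power
  (noncentral *t*), Lilliefors-style normality checks.
* **Synthetic studies** — a deterministic hierarchical feature bank, toy
  stimuli, and a sparse linear encoding model with layer-tuned areas
  (V1…HVC analogs) and a ground-truth attentional weight `alpha_true`, so
  the estimate the pipeline produces can be checked against the value the
  generator injected.

## A worked example

```r
library(attnmod)

# a complete synthetic study: 60 training images x 2 repeats, 10 test
# images, 45 pairs x 2 attention conditions x 8 trials, moderate noise,
# ground-truth attentional weight 0.65
config <- study_config(alpha_true = 0.65, noise_sd = 0.5, seed = 202)
report <- run_recovery_experiment(config)
report
#> <recovery_report> alpha_true = 0.65 (contrast mode), area VC
#>   decoding accuracy : 0.885 0.884 0.879 0.885 0.908
#>   mean peak contrast: 65.0 65.2 65.1 65.5 65.4 (overall 65.22, truth 65)
#>   identification    : 99.3 98.2 96.1 94.2 93.5 %
#>   amplitude d       : 2.81 2.55 2.41 2.21 2.10
```

Reading the output: decoded patterns correlate ~0.88 with the true feature
patterns of held-out single-image trials; the per-pair mean peak contrast
recovers the injected weight (65%) to within a fraction of a grid step in
every layer; the attended image is identified from the decoded pattern in
93–99% of attention trials; and the attended-vs-unattended amplitude
difference across the 45 pairs has a large effect size in all layers.
Per-layer inference is available in the report, e.g.:

```r
report$peak_effects$layer3
#> <effect_size_result> mean 65.076 (baseline 50), d = 9.291,
#>   one-sided p = 7.27e-45 (adj 3.63e-44, m = 5),
#>   95% CI [64.589, 65.564], n = 45
```

A staged command-line interface (`simulate`, `train`, `decode`, `analyze`,
`report`) over the same functions lives at
`system.file("cli", "attnmod.R", package = "attnmod")`; see `?run_cli`.
User-supplied data enter through the same seams the simulator uses: a
response matrix with voxel area labels, a trial table (TSV), and stimulus
images (PNG).

The methods vignette (`vignettes/attention-decoding.Rmd`) documents the
model, the conventions (SD definitions, tie-breaking, error-trial
handling), the simulator's assumptions, and what the validation does and
does not establish.

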