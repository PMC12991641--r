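# fearrsa

Representational similarity analysis (RSA) of a four-phase fear-conditioning
fMRI paradigm — fear acquisition, reversal, and two test phases — driven by a
synthetic-data generator that plants known representational structure in
BOLD-like volumes, so every stage of the analysis can be verified against
ground truth without any data download.

## Who this is for

Researchers who analyze event-related fMRI with trial-wise pattern
similarity and want a fully tested, self-contained implementation of the
standard stack — least-squares-separate (LSS) beta series, Fisher-z
representational similarity matrices, cubic searchlights, nonparametric
cluster-level FWE, and mixed-effects group models — plus a generator for
validating that stack end to end.

## The paradigm and the metrics

Eight cues in four CS types (two items each), named by their US pairing in
acquisition/reversal: CS++ (paired/paired), CS+- (paired/unpaired), CS-+
(unpaired/paired), CS-- (never paired). Each of four phases has 128 trials;
US-paired cues are reinforced on 50% of presentations; context videos (sets
A/B/C of 4/4/8) are orthogonal to CS type by construction.

With `z(i,j) = atanh(r)` the Fisher-z Pearson correlation between the LSS
beta patterns of trials `i` and `j` (unreinforced trials only), the package
computes the field's standard masked-mean metrics:

- **item stability** — mean `z` over pairs of presentations of the same item;
- **cue generalization** — mean `z` over pairs of *different* items of the
  same CS type;
- **context specificity** — mean within-context `z` minus mean
  between-context `z` (context-model betas);
- **item / generalized reinstatement** — cross-phase mean `z` over same-item
  / same-type-different-item pairs.

Searchlight maps (cubic neighborhood, 5 mm radius, centers with at least 50%
of the box in-mask) feed a one-sample group t map; cluster-level FWE is
assessed by sign-flip permutation of participant maps (cluster-forming
p < 0.001, max-cluster-size null, Bonferroni-adjusted alpha across the
contrasts of a phase), clusters of at least 1500 mm^3 become ROIs, and
mixed-effects models (REML, Satterthwaite df) link ROI metrics — including
the model `reinstatement ~ context specificity x CS type + (1 |
participant)`.

## Worked example

Simulate one participant's acquisition phase, estimate trial-wise betas,
and compute cue generalization:

```r
library(fearrsa)
geom <- volume_geometry(c(12, 12, 8))          # 2.5 mm voxels, TR 2.53 s
bank <- make_pattern_bank(geom, seed = 7)       # latent voxel patterns
spec <- assign_counterbalancing(participant_index = 0)
design <- build_phase_design(spec, "acquisition", seed = 42)
ds <- synthesize_bold(design, bank, geom, effect_spec(), seed = 42)
cue_betas <- estimate_lss_betas(ds, model_kind = "cue")
gen <- cue_generalization(build_rsm(cue_betas))
print(gen, digits = 3)
```

```
  cs_type n_pairs  value
1    CS--     256 0.0461
2    CS-+     256 0.0397
3    CS+-      64 0.0633
4    CS++      64 0.0487
```

The values are Fisher-z similarities between different items of one CS
type. The generator planted a stronger shared "threat" pattern for the
US-paired cues (CS++ and CS+-), and that is what comes back out: their
generalization (0.0487, 0.0633) exceeds that of the safe cues (0.0397,
0.0461); the CS+ minus CS- contrast is +0.0131 for this participant. CS+
cues have 64 usable pairs rather than 256 because only unreinforced trials
(8 of 16 presentations per US-paired cue) enter the statistics. The same
session's context-model betas give an acquisition context specificity of
0.0299, and a full cohort is one call:

```r
res <- run_study(default_study_config())   # simulate -> LSS -> RSA ->
res$report                                 # searchlight -> FWE -> LMEs
```

which writes events/ratings/confound tables, searchlight maps, cluster and
ROI tables, mixed-model results, a ground-truth recovery report, and a
checksummed run manifest.

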