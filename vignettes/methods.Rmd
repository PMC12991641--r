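---
title: "Representational similarity analysis of simulated fear learning: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational similarity analysis of simulated fear learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In a fear-reversal paradigm, initially neutral cues (here, images of
household appliances) acquire or lose threat value as their pairing with an
aversive unconditioned stimulus (US, a mild electric shock) changes across
experimental phases. The question this pipeline addresses is *how the brain
represents* those cues and the contexts they appear in: do repeated
presentations of one item evoke a stable voxel pattern (**item stability**)?
Do different items that share a threat value come to evoke similar patterns
(**cue generalization**)? Are contexts represented distinctly
(**context specificity** = within-context minus between-context pattern
similarity)? And do memory traces formed in one phase reappear in a later
test (**item** and **generalized reinstatement**)?

Group-level statistics from a real cohort cannot be reproduced on a desk,
so the package inverts the problem: a synthetic-data generator plants known
item, valence-category, and context components in BOLD-like volumes, and
every analysis stage is then validated by (a) oracle equivalence against
brute-force reimplementations and (b) recovery of the planted effects'
signs at the group level.

## The paradigm and its simulation

Four phases — acquisition, reversal, test in new contexts (`test_new`), and
test in old contexts (`test_old`) — of 128 trials each. Eight cues fall
into four CS types of two items each, named by their US pairing in
acquisition/reversal: CS++ (paired/paired), CS+- (paired/unpaired), CS-+
(unpaired/paired), CS-- (never paired). US-paired cues are reinforced on
exactly half of their 16 presentations per phase. Context videos come in
sets A (4, acquisition), B (4, reversal), and C (8, `test_new`);
`test_old` reuses A and B. Every cue-context combination occurs equally
often (4 times with 4 contexts, 2 times with 8), so CS type and context are
orthogonal by construction. A trial is: context video 2 s, cue 1 s
embedded in the context, a 2.5 s 4-point US-expectancy rating window, the
US (if any) at the rating-window offset — a trace-conditioning gap after
cue offset — and a 7-9 s jittered fixation ITI.

Where the public description of the paradigm leaves a detail open we chose
once and kept it:

* **Pseudorandomization** is a constrained shuffle with rejection sampling:
  reshuffle until the first and last trials are unreinforced and no cue
  occurs more than twice in a row. No stronger run-length constraints are
  imposed.
* **Counterbalancing** is a Latin-square style rotation: cue `c` of
  participant `p` occupies slot `(c - p) mod 8`, consecutive slot pairs map
  to the four CS types, so across any 8 consecutive participants each cue
  serves each CS type exactly twice. The A/B context sets swap with
  participant parity.
* **US onset** is placed at the rating-window offset (cue onset + 3.5 s),
  respecting the trial's event order and the trace gap.
* **ITI jitter** is continuous uniform on [7, 9] s.

## The generative model for BOLD data

Each simulated participant has a `pattern_bank`: orthogonalized,
unit-variance Gaussian voxel patterns for a baseline, each cue (one
persistent pattern plus one per phase), the two valence categories
(threat/safe), each of 16 contexts, and the US. The true pattern of a cue
trial is

```
baseline + w_item_shared * P_cue + w_item_phase * P_cue,phase
         + w_threat * P_threat + w_safe * P_safe
         + w_ctx * P_context + trial noise
```

and of a context epoch `baseline + w_ctx * P_context + noise`. The
weights (`effect_spec()`) are the ground truth every analysis is judged
against: within-phase item stability grows with
`w_item_shared^2 + w_item_phase^2`, cue generalization with the squared
category weight, cross-phase item reinstatement with the product of
`w_item_shared` across phases, and generalized reinstatement with the
product of category weights. Keeping separate persistent and phase-private
item patterns lets the generator plant item stability with or without
reinstatement.

Voxel time series are the planted patterns times HRF-convolved event
regressors (canonical double-gamma, peak about 5-6 s, undershoot around
16 s, no derivatives), plus US responses, confound contributions (six
motion random walks, AR(1) white-matter and CSF signals, each with its own
random spatial loading pattern), a per-voxel linear drift, and stationary
AR(1) Gaussian scan noise (default lag-1 correlation 0.3) — the
autocorrelation that motivates trial-wise LSS estimation in the first
place.

### Default weights and why

Defaults are in per-voxel noise-SD units and mirror the qualitative
structure the pipeline is asked to recover: threat-category weight 0.7 vs
safe 0.25 during acquisition and reversal (threat cues generalize more);
phase-private item weight 0.8 for the valence-changing cues CS-+/CS+-
during reversal vs 0.4 elsewhere (contingency change raises item
stability); context weight 0.8 in reversal vs 0.4 in the other phases
(reversal contexts are more specific); weak residual category traces (0.1
to 0.3) during the tests, with the `test_old` traces of the
contingency-changing cues coupled across participants to reversal context
specificity (`participant_effect_spec()`), which plants the
specificity-by-cue-type reinstatement interaction. Trial noise SD 0.5,
scan noise SD 1.0. The baseline (shared mean pattern) amplitude is kept
small (0.5): a large shared component would push every pattern correlation
toward 1 and compress all similarity contrasts; real RSA pipelines face
the same issue and often remove the mean pattern explicitly.

These are desk-scale, single-session amplitudes chosen so that planted
effects sit in the regime real studies report — single-trial pattern
correlations of roughly 0.05-0.4 after estimation noise — while remaining
recoverable in sign by a 12-participant cohort.

### What the generator does and does not emulate

It emulates trial-level pattern structure, HRF convolution and overlap,
nuisance structure (motion/WM/CSF loadings, drift), and temporally
autocorrelated noise. It does **not** emulate spatial noise correlations,
physiological noise, susceptibility distortion, image-space head motion, or
inter-regional heterogeneity: passing tests show the *estimation and
inference machinery* is correct and calibrated, not that effects of this
size are detectable in any particular real dataset.

## Estimation: LSS beta series

Trial-wise responses are estimated least-squares-separate: one GLM per
trial with the target trial's regressor, one shared column summing all
other same-kind trials, US-onset impulses (no-interest, only where USs
occur), six motion parameters, WM and CSF signals, a cosine high-pass
drift basis (128 s cutoff), and an intercept; ordinary least squares, no
prewhitening (beta patterns feed correlations, where shared whitening
largely cancels). Cue models use 1 s cue boxcars and contain no context
regressors; context models use the video-onset-to-cue-onset epoch and
contain no cue regressors — the two event streams are deliberately kept in
separate model families and their temporal adjacency is tolerated, since
CS type and context are orthogonal by design. Rating periods are not
modeled.

Numerical notes: each per-trial solve uses the Cholesky factor of the
normal equations; a rank-deficient design raises an error naming the
collinear columns. The betas match an explicit pseudoinverse solution to
1e-8 on every tested instance. Noiseless recovery of planted amplitudes
is *exact* exactly when the one-column "others" model can represent the
data (all same-kind trials sharing the target's amplitude pattern, however
much they overlap); with heterogeneous per-trial amplitudes a small
residual leaks through the global regressors and recovery is near-perfect
but not exact — the familiar LSS approximation.

## RSA metrics

All similarities are Fisher r-to-z transformed Pearson correlations across
voxels between trial betas. Within-phase RSMs exclude self-pairs;
zero-variance patterns yield undefined entries that are dropped from every
mask (not imputed). Only unreinforced trials enter the statistics — a US
would otherwise contaminate the cue pattern — and, by default, the same
exclusion is applied to the context models (configurable, since the
original rule is stated for cues). All non-self pairs are averaged,
including temporally adjacent ones; a minimum-separation exclusion is easy
to add but is off by default to match the stated averaging rule. Metrics:

* **item stability** — mean over same-item pairs, per cue, averaged to CS
  types;
* **cue generalization** — mean over same-CS-type different-item pairs;
* **context stability / generalization / specificity** — within-context
  mean, between-context mean, and their difference (the decomposition
  `specificity = stability - generalization` is exact by construction);
* **item / generalized reinstatement** — cross-phase same-item /
  same-type-different-item means, per CS type.

Every metric is the mean of RSM entries under a boolean pair mask, which is
what makes the pair-enumeration oracle in the tests possible.

## Searchlight and group inference

The searchlight is a cubic box ("square" neighborhood) of half-width
`round(radius / voxel size)` voxels — 125 voxels at the default 5 mm
radius and 2.5 mm voxels — centered on every gray-matter voxel; a center is
kept only if at least 50% of its full ideal box (out-of-bounds positions
counted in the denominator, the strictest reading) is in the mask. At each
center the RSM is rebuilt from the member voxels and the metric contrast
evaluated; masks are cached across centers since they depend only on trial
metadata.

Group inference is a one-sample t test over participant contrast maps with
nonparametric cluster-level FWE: clusters form at the one-sided voxelwise
threshold corresponding to p < 0.001, the null distribution of the maximum
cluster size is built by random sign flipping of whole participant maps
(10,000 permutations by default), and cluster
`p_fwe = (1 + #{null max >= observed}) / (1 + n_perm)` — the +1 correction
keeps p-values valid. Cluster labeling uses 26-connectivity by default (6
available). When several contrasts share a phase the alpha threshold is
Bonferroni-divided (`0.05 / 2 = 0.025`, `0.05 / 4 = 0.0125`). Significant
clusters become ROIs if they reach 1500 mm^3 (96 voxels at 2.5 mm); when
ROIs from different source maps overlap only the larger (by voxel count)
is kept, and each application of that rule is logged.

## Mixed-effects linkage

ROI metric tables are modeled with `lme4`/`lmerTest`: REML fits with
Satterthwaite denominator degrees of freedom, random participant
intercepts. Behavioral US-expectancy ratings use
`mean_rating ~ cs_type * phase + (1 | participant)` on the four averaged
ratings per phase per participant, with paired Wilcoxon signed-rank
post-hocs Bonferroni-corrected within two families (the 6 CS-type pairs
within each phase; the 6 phase pairs) — the test is reported as the
signed-rank statistic even though some reports print t-like letters.
Reinstatement is modeled with phase and CS type as fixed effects;
the specificity linkage uses
`reinstatement ~ specificity * cs_type + (1 | participant)` over the
contingency-changing cues (CS-+, CS+-), with Benjamini-Hochberg FDR within
each item/generalized pair per ROI. Singular or failed random-effect fits
fall back to ordinary fixed-effects F tests and are flagged in the output
rather than silently accepted.

## Calibration and problem sizes

The package's own studies run at sizes a laptop handles in minutes, chosen
once as the simulation's study conditions:

* recovery: 20 cohorts of 12 participants on an 18x18x12 grid at 2.5 mm
  (about 2,000 in-mask voxels in an ellipsoidal mask), all four planted
  contrasts expected positive in at least 95% of cohorts;
* cluster-FWE error control: 200 null cohorts on a 12x12x8 grid with 500
  sign-flip permutations each; null participant maps are smoothed Gaussian
  noise (SD 1.5 voxels) because searchlight maps are spatially smooth by
  construction — with unsmoothed maps the maximum-cluster-size statistic is
  too discrete near the 0.001 forming threshold and the test becomes
  visibly conservative;
* behavioral and linkage type-I error: 200 replicates each, rejection
  rates checked against the binomial 95% interval around 0.05.

`run_study()` executes the whole pipeline (design, behavior, synthesis,
LSS, metrics, searchlight, cluster inference, ROIs, linkage, report) for
one cohort and writes a manifest with seeds, a config hash, and per-file
checksums; identical configurations and seeds reproduce byte-identical
metric tables. Voxel indices are 0-free R conventions internally (1-based,
column-major); world coordinates exist only through the NIfTI affine,
which is a scaled identity for synthetic geometries.

## Known limitations

* The LSS approximation biases betas when neighboring trials carry
  different amplitudes; the generator reproduces this honestly rather than
  hiding it, so planted contrasts shrink between truth and estimate.
* Pattern correlations are computed over few voxels in small searchlights;
  Fisher z values are then noisy, which the group stage absorbs.
* The sign-flip null assumes symmetric participant effects under the null;
  heavy asymmetry would miscalibrate the cluster test.
* The behavioral generator is a rounded latent-Gaussian model; it
  reproduces cell-mean orderings and interaction calibration, not reaction
  times or trial-by-trial learning curves.
* Real-data mode accepts preprocessed volumes, events, and confounds; the
  package performs no image preprocessing.
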