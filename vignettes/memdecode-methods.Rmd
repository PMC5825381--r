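---
title: "Decoding individual memories from multivoxel patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding individual memories from multivoxel patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdecode)
```

## The scientific problem

When a person vividly recalls a specific autobiographical memory in the
scanner, the recall period evokes a spatial pattern of BOLD activity across
voxels that is partly specific to that memory. Multivoxel pattern analysis
(MVPA) asks whether a classifier can tell, from a region of interest's
voxel pattern alone, *which* of several trained memories was being
recalled. In a longitudinal two-study design — the same participants and
the same memories scanned roughly two years apart — the interesting
quantities are (i) per-region decoding accuracy for each memory set
("recent", "remote", and a recall-frequency "control" set), (ii) how those
accuracies change with memory age and across studies, and (iii) whether the
*locations* carrying memory information (information maps) overlap between
memory sets or between timepoints, probed with the Dice coefficient against
a permutation null. Systems-level consolidation predicts exactly such
regional and spatial reorganisation.

`memdecode` implements the full analysis pipeline and, because the original
scanner data are not publicly deposited, a synthetic-data module that
generates complete two-study experiments with planted, known ground truth.
Every downstream claim the package makes is therefore testable.

## The simulated world

One simulated subject is a phantom voxel grid (1.5 mm isotropic) carrying
named, disjoint ROI masks — by default a hippocampus-like ellipsoid
elongated 3:1 along a designated long axis, and a spherical vmPFC-like
region, sized to the study's mean ROI voxel counts (928 and 1169 voxels at
full scale). The trial design is fixed by the protocol: 9 memories (3 per
condition) recalled 14 times each, 126 trials split into two 63-trial
sessions, each trial a 3 s cue, 12 s eyes-closed recall, 1.5 s tone, two
self-paced ratings (up to 3 s each) and 4 s rest (26.5 s per trial, TR
3.5 s). Orders are pseudo-random with no memory repeated back-to-back.

Each memory has, per ROI, a sparse *support* (default 40% of ROI voxels)
with standard-normal weights. The forward model is linear: a recall-period
boxcar per trial, convolved with the canonical double-gamma HRF sampled at
the TR, scales the memory's weight map by a per-(ROI, condition) amplitude;
linear scanner drift (0.05 signal units/volume, restarting each session)
and i.i.d. Gaussian noise (SD 1) are added. With amplitude 0 the data are
pure noise plus drift — the null world used for calibration.

Key generator parameters, their units and defaults:

| parameter | default | meaning |
|---|---|---|
| `repetitions` | 14 | recall trials per memory |
| `tr_s` | 3.5 s | volume sampling interval |
| `retention_prob` | 0.79 | P(trial passes the vividness/consistency filter), matching ~11 of 14 trials retained |
| `support_frac` | 0.40 | fraction of ROI voxels in a memory's support |
| `support_overlap` | `NULL` | cross-condition shared-support fraction; `NULL` = unconstrained |
| `timepoint_overlap` | 1 | fraction of a memory's support retained at study two |
| `noise_sd` | 1 | Gaussian noise SD (signal units) |
| `drift_slope` | 0.05 | drift per volume (signal units) |

Ratings are drawn independently on 1..5 with `P(rating >= 4) =
sqrt(retention_prob)` per scale, so the joint "both >= 4" filter retains
`retention_prob` of trials in expectation. The simulator deliberately does
*not* model any relationship between ratings and signal quality — nothing
in the protocol pins that relationship down — so the filter only thins
trials.

When `support_overlap` is specified, condition supports are structured:
a shared core of `round(support_overlap * support_size)` voxels is common
to all conditions, and the remainder is drawn from disjoint per-condition
pools laid out as contiguous slabs along the ROI's long axis. The slab
layout mirrors the long-axis separation seen in hippocampal information
maps, and it makes overlap exactly controllable: two memories from
different conditions share exactly the core, to within rounding.
Feasibility constrains the parameters: disjoint pools for three conditions
require `support_frac * (1 - support_overlap) * 3 <= 1`, so fully disjoint
(`support_overlap = 0`) supports need `support_frac <= ~0.25`; the
generator raises an error otherwise rather than silently overlapping.

What the generator does **not** emulate: physiological (cardiac,
respiratory, 1/f) noise, head motion, susceptibility distortion,
spatially correlated noise, anatomical variability, and any coupling
between phenomenology and signal. A green test on this world therefore
establishes that the *pipeline machinery* behaves as specified (no
leakage, correct nulls, recoverable planted effects at the stated SNR) —
not that the original biological effects are real.

## The preprocessing model

Fixed order: Gaussian smoothing (3 mm FWHM, converted to voxels via the
voxel size) → per-session linear detrend (slope removed, session mean
retained) → convolution of the data with the canonical HRF (unit-sum
kernel sampled at the TR, restarted per session) → onset shift → trial
extraction → rating filter. Convolving already-haemodynamic data with the
HRF doubles the effective BOLD delay to ~12 s; onsets are accordingly
shifted forward by `round(12 / 3.5) = 3` volumes, and each trial
contributes the `ceil(12 / 3.5) = 4` volumes of its shifted recall window.

The 4 volumes are averaged into one pattern per trial by default. One
pattern per trial keeps cross-validation folds honest: individual volumes
of the same trial are strongly autocorrelated and would leak across folds
if treated as independent samples. `volumes_as_samples = TRUE` exposes the
alternative.

A consequence of HRF-convolving the data that the package documents rather
than hides: the kernel's undershoot anti-correlates noise at lags near the
trial spacing (~26.5 s). Because the schedule forbids immediate repeats,
temporal neighbours are always *different* memories, so that
anti-correlation carries a little label information. Held-out accuracy in
the null world stays at chance (0.334 ± 0.011 over 60 null subjects), but
*random* inner cross-validation folds during feature scoring inflate every
sphere's score by a few points. Sphere scoring therefore uses temporally
blocked inner folds (contiguous trial blocks), which removes the
inflation; this is the standard fMRI practice of respecting temporal
autocorrelation in fold construction.

## Decoding

Per condition, decoding the 3 memories is a 3-class problem (chance 33%).
The decoder is a 10-fold stratified cross-validation. Within each fold:

1. **Searchlight feature selection, training data only.** Every ROI voxel
   centres a sphere of radius 3 voxels, truncated at the ROI border. Each
   sphere is scored by inner 5-fold (temporally blocked) cross-validated
   ECOC-SVM accuracy on the training trials. The *single best-scoring*
   sphere is selected — the voxel set carrying the greatest decoding
   information — with ties going to the lowest index. If even the best
   sphere fails to beat chance the selection is flagged but still used, so
   the classifier always has features. All per-sphere scores are retained.
   Selecting one winning sphere per fold, rather than the union of all
   above-chance spheres, is deliberate: with ~30 training trials the
   per-sphere score quantum is ~0.03, so roughly a third of pure-noise
   spheres exceed chance by luck, and a union rule selects nearly the whole
   ROI on every fold (and saturates the information maps; the union over
   10 folds of any rule with false-positive rate above ~25% covers
   everything). The union of the per-fold winners across 10 folds lands at
   a few distinct sphere positions — a few hundred voxels at full ROI
   scale, the magnitude such pipelines report.
2. **ECOC classification.** The 3-class problem becomes three one-vs-rest
   dichotomies with codewords (1,0,0), (0,1,0), (0,0,1) (minimum pairwise
   Hamming distance 2). One linear soft-margin SVM (C = 1) is fit per
   dichotomy on the selected voxels, z-scored with training-split
   statistics; a test pattern's binary output vector is decoded to the
   class with minimum Hamming distance, ties to the lowest class index.

No SVM solver is available in the target environment, so the package ships
its own: dual coordinate descent on the L1-hinge dual (the standard
linear-SVM algorithm), bias handled by an augmented constant feature,
stopping at projected-gradient tolerance 1e-4 or an epoch cap (400 for
classification; 100 during sphere scoring, where thousands of small fits
only need to *rank* spheres). The test suite cross-checks the solver
against an exact quadratic-programming solution of the same dual and
checks ECOC predictions against an exhaustive plain-R oracle.

Set-level generalisation asks a different question: can a binary classifier
told only the *condition* generalise to memories it never saw? Training
leaves out one memory per condition and tests on the held-out memories'
trials, averaged over all held-out pairs (chance 1/2). Above-chance
generalisation requires a shared condition-level component, which the
generator can plant via the structured support core.

Cross-study comparisons never transfer classifiers between studies: each
study is decoded independently and the accuracies and maps are compared.
This avoids assuming that the same voxel pattern persists across years.

## Information maps and Dice permutation testing

A condition's information map is the union, over cross-validation folds, of
each fold's selected voxel set, counting only folds whose held-out
accuracy beat chance. Map overlap between two conditions (or timepoints) is
summarised by Dice, `2|A∩B|/(|A|+|B|)`. The null hypothesis — overlap is
what two arbitrary voxel sets of these sizes would show — is simulated by
re-drawing both maps as uniformly random ROI subsets with the observed
cardinalities (1000 draws by default). Uniform re-drawing, rather than
rigid translation, is used because translation is ill-defined in an
irregular ROI and the Dice null depends only on the two cardinalities and
the ROI size (its expectation is `2ab/(N(a+b))`, the hypergeometric mean,
which the tests verify by brute force).

The group statistic is a two-tailed one-sample t-test across subjects of
(observed − subject's null mean) against zero, with the direction (below
or above the null) reported; a per-subject permutation p is also returned.
The group construction is the default because the headline claims are
group-level; both views are exposed.

## Group statistics

Accuracies are compared to chance with one-tailed one-sample t-tests (only
above-chance decoding is of interest), conditions with two-tailed paired
t-tests following a one-way repeated-measures ANOVA, and study × condition
effects with the 2×2 within-subject interaction F (computed as the squared
t of the difference-of-differences, df (1, n−1)). No sphericity or
multiple-testing correction is applied — the analysis family is small and
fixed, a p < 0.05 threshold is used throughout, and the report records how
many tests it ran. Left/right hemisphere accuracies, when masks are split,
are averaged before testing.

## Numerical and reproducibility choices

* All randomness flows from one integer master seed through
  `substream_seed(master, tags...)`, a polynomial hash modulo 2^31 − 1;
  every stage (geometry, schedule, patterns, noise, folds, permutations)
  draws from its own substream, so any report regenerates bit-identically.
* Rounding: the onset shift rounds half away from zero; the long-axis
  split uses round-half-up on occupied slices (the anterior block always
  keeps at least one slice on each side); support sizes round to the
  nearest voxel.
* Degenerate inputs error loudly: empty masks, single-slice masks, ROI
  requests exceeding grid capacity, sessions under 3 volumes, trial
  windows past the run end (naming the trials), classes with fewer than 2
  trials, both-empty Dice masks, zero-variance t-tests.
* If rating exclusion leaves the smallest class with fewer trials than the
  fold count, `k` is reduced to that count with a message.
* Z-scoring uses training-split statistics only; zero-variance columns are
  centred but not scaled.

## Desk-scale testing

The packaged tests and the acceptance script run phantoms with 50–100
voxel ROIs instead of the ~900–1200 voxel originals to stay within
single-CPU time budgets; trial structure, TR, timing grid and fold counts
stay at the protocol values. Chance levels and test calibration do not
depend on ROI size. Two desk-scale consequences are handled explicitly:
the parameter-recovery runs scale the searchlight radius to 1.5 voxels so
the sphere/ROI volume ratio matches full-scale geometry (a radius-3 sphere
would cover half of a 100-voxel ROI), and they use `support_frac = 0.2`
because fully disjoint three-condition supports are geometrically
infeasible above ~0.25. Recovery amplitudes come from a power-calibration
sweep: hippocampal amplitude 0.55 decodes at ~75%, giving within-slab
sphere selection that is stable enough for interpretable maps with five
subjects; the vmPFC contrast plants 0.25 vs 0.55 (~40% vs ~75% accuracy).

## Known limitations

* The linear forward model and white noise understate real fMRI noise
  structure; calibration results transfer to real data only to the extent
  that detrending and blocked folds absorb the extra structure.
* The best-sphere selection rule makes per-fold feature sets exactly one
  sphere; regions with several disjoint informative clusters would be
  summarised by whichever cluster wins each fold.
* The Dice null conditions on map cardinalities; it does not model spatial
  smoothness of maps, which inflates observed overlap and null overlap
  alike but is not separately accounted for.
* `read_nifti`/`write_nifti` implement the minimal NIfTI-1 subset the
  pipeline needs (little-endian, identity orientation); they are not a
  general neuroimaging I/O layer.
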