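---
title: "Modelling multistep anticipation with asymmetric-Gaussian pattern similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multistep anticipation with asymmetric-Gaussian pattern similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When people hold a learned sequence in mind, the brain may pre-activate the
states that lie ahead (and behind) the current one. seqhorizon analyses a
paradigm designed to expose that structure: participants learn circular
sequences of eight virtual environments, where each "map" of eight
environments carries two different cyclic orders (a green and a blue path).
During an anticipation task they see one environment plus a path cue and must
anticipate environments one to four steps ahead; a separate localizer task
yields a multivoxel activity template for each environment.

The core quantity is a *cue-centered similarity profile*: the correlation
between a trial's cue-phase activity pattern and each same-map environment
template, arranged by signed step distance from the cue along the cued path
(-4 ... +4, the antipode of an 8-cycle being shared between the two
directions and therefore duplicated at both ends). A graded, bidirectional
representation of the sequence shows up as a bump around step 0 that decays
smoothly with distance.

## The model

Profiles are fit with an asymmetric Gaussian

$$ y(s) \;=\; c + (A - c)\, e^{-s^2 / (2\sigma_{dir}^2)},
   \qquad \sigma_{dir} = \begin{cases}\sigma_b & s < 0\\
                                      \sigma_f & s \ge 0\end{cases} $$

with four parameters:

* **amplitude** $A = y(0)$, similarity units — evidence for the on-screen
  cue environment;
* **asymptote** $c$ — the far-step plateau; when $c$ falls below the
  *different-map baseline* (the correlation between a cue pattern and the
  voxelwise mean template of the irrelevant map's eight environments) it
  indicates relative suppression of distant environments;
* **backward / forward widths** $\sigma_b, \sigma_f$ in steps — how far
  graded similarity extends into past and future positions.

The fit minimizes the L2-regularized squared error
$\sum_s (v_s - y(s))^2 + \lambda (A^2 + c^2)$ over the 9 profile positions
(8 with the cue excluded), with $\lambda = 0.01$ and widths constrained to
$(0.05, 10]$ steps. The duplicated antipode contributes two residuals, one
per direction, exactly as arranged.

### Numerical strategy

For fixed widths the curve is *linear* in $(A, c)$: with
$g_s = e^{-s^2/(2\sigma_{dir}^2)}$, $y = A g + c (1-g)$. The penalized
least-squares solution for $(A, c)$ is therefore a closed-form ridge
solution, and the whole objective reduces to a quadratic form in the data
for each width pair. seqhorizon exploits this by scoring a deterministic
log-spaced $15 \times 15$ grid over $(\sigma_b, \sigma_f) \in [0.05, 10]^2$
— which can be evaluated for thousands of profiles at once as matrix
products — and then refining the best grid point with bounded quasi-Newton
(`optim(method = "L-BFGS-B")` on $\log \sigma$). Ties are broken toward the
smaller total width, which also pins down the reported widths for degenerate
flat profiles (both at the 0.05-step lower guard). This replaces the more
conventional 4-parameter multi-start optimizer: it is deterministic,
immune to poor starts, and fast enough to sit inside permutation loops.

The σ lower bound 0.05 is purely a numerical guard (a Gaussian narrower
than a twentieth of a step is indistinguishable from a delta on integer
positions); the upper bound 10 matches the analysis convention for this
paradigm.

## Inference

**Group error.** The group-level statistic is a leave-one-participant-out
generalization error: fit the curve to the positionwise mean profile of
$n-1$ participants, evaluate the SSE on the held-out participant, average
over folds. Fitting the mean profile is equivalent to pooled least squares
on balanced data and keeps the procedure deterministic.

**Permutation null.** Each of (by default) 10,000 shuffles independently
reassigns, per participant, the unique profile values to unique positions —
8 slots including the cue, 7 excluding it, with the antipode value
re-duplicated after shuffling — and recomputes the same leave-one-out error.
$p$ is the add-one-smoothed fraction of shuffles with error at most the
observed ($p \ge 1/(n_{perm}+1)$, never exactly zero), and
$R^2 = 1 - \mathrm{err}_{obs}/\overline{\mathrm{err}}_{null}$. Inside
permutation loops the width optimizer runs in grid-only mode, *identically*
for observed and shuffled data, so the comparison stays exchangeable; the
user-facing per-participant fits refine by default. Shuffles are drawn
independently per participant within each permutation — the strongest
exchangeability null for this design.

**Cue exclusion.** Running the test with and without the step-0 value
separates two claims: a region may carry the cue environment only (fit
survives with the cue, dies without it) or genuinely graded neighbor
structure (fit survives both ways). The cued-vs-uncued comparison re-uses
the same machinery on the difference of leave-one-out errors between the
two orderings, cue excluded from both since the cue is shared.

**Parameter tests.** One-sample t-tests compare per-participant amplitudes
(above) and asymptotes (below) to the per-participant different-map
baseline; backward vs forward widths are compared with a two-sided Wilcoxon
signed-rank test. Amplitude is defined as the fitted value at step 0
(not peak-minus-asymptote), which makes it directly comparable to the
baseline in those tests.

## Voxel selection and topography

**Reliability.** For each voxel, each participant's 16-element environment
beta vector is correlated with the mean vector of the remaining
participants; the reliability score is the raw mean of the Pearson r values
over held-out choices (no Fisher transform — the plain average is the
convention this analysis follows). Voxels with any zero-variance fold are
flagged undefined rather than zeroed. Selection keeps voxels with
$r \ge 0.1$ in face-connected (6-neighborhood) clusters of at least 10
voxels; connectivity is a package choice, as is averaging folds with equal
weight and excluding undefined voxels.

**Searchlight.** Cubes of side 7 voxels move with step 2 from the lattice
origin; partial boundary cubes are kept when they still contain at least 64
reliable voxels. Each qualifying cube repeats the full profile-and-fit
analysis on its reliable voxels; a per-cube goodness score
$g = 1 - SSE_{correct}/\overline{SSE}_{perm}$ uses a reduced default of 100
per-cube shuffles (configurable; the full 10,000 of the profile-level test
is unnecessary for a score that is subsequently averaged and tested across
participants). Cube results are written to every cube voxel and averaged
over overlapping cubes; uncovered voxels stay missing.

**Group maps.** Voxelwise group inference on $g > 0$ uses one-sample t
statistics with familywise error controlled by the max-statistic
distribution over random participant sign flips (exhaustive when $2^n$ is
small). This replaces threshold-free cluster enhancement: the sign-flip
max-statistic procedure is exact under sign symmetry, has no tuning
parameters, and is appropriate at the problem sizes the package targets; a
caller can still plug any voxelwise map into an external TFCE tool.

**Gradients.** Within a region, each participant contributes the Spearman
correlation between the mean of the two widths and the voxel y-coordinate
(the second lattice axis; an anterior-axis override applies for real data
with a meaningful affine), with an optional partial variant: Pearson
correlation of rank-transformed width and y after linear residualization on
rank-transformed amplitude. Across regions, mean widths are ranked along a
supplied hierarchy (e.g. V1 < V2 < V3 < V4 < PPA). Group significance is a
one-sample t-test of the participant correlations; ties use average ranks,
and participants with undefined correlations are excluded with a logged
count.

## The synthetic generator

The generator produces data with exactly the statistical structure the
analysis assumes, plus known ground truth:

* **Templates.** Group environment templates are drawn per voxel within a
  signal region (default: a centered box spanning half of each lattice
  dimension), then mean-centered, orthogonalized across environments and
  rescaled to per-voxel RMS `template_sd`. Orthogonal zero-mean templates
  make profile values exactly proportional to the generating mixture
  weights in the noise-free limit, which the tests exploit. A
  non-orthogonalized option exists for realism. Participant templates add
  independent noise (`participant_template_sd`), which is what makes
  across-participant reliability less than 1.
* **Anticipation patterns.** Each trial type's signal pattern is the
  weighted mixture of the participant's templates at each step from the cue
  along the *cued* path, with weights following the same asymmetric
  Gaussian the model fits (the shared antipode weight is the mean of the
  two directional evaluations, since the duplication makes them
  indistinguishable). Suppression is a negative additive weight on far
  templates. Measurement noise is added everywhere; non-signal voxels are
  pure noise. A configured width gradient makes σ a linear function of the
  voxel y-coordinate, computed per y-slab.
* **Behavior.** Response times are `rt_base + slope_i * steps` plus noise;
  per-participant slopes are drawn so their correlation with the
  participant's true asymptote approaches `coupling` (Gaussian coupling on
  standardized values — negative coupling means deeper suppression goes
  with steeper response-time costs). Accuracy follows a logistic model of
  steps; a zero logit gives an exact 50% chance responder.

Defaults mirror the study conditions the pipeline targets: 32 participants,
16 environments in two maps of 8, profile (A = 0.09, c = -0.014,
σ_b = 0.712, σ_f = 0.634), between-participant SDs 0.029 / 0.009 for
amplitude and asymptote, rt slope 0.126 s/step, accuracy ≈ 87%, coupling
-0.362. Noise SDs (template 1, participant 0.3, measurement 1) were chosen
so that per-participant amplitude variability and voxel-selection behavior
are realistic for across-participant template analyses of this kind.

What the generator deliberately does *not* emulate: spatially correlated
noise, hemodynamic autocorrelation (a minimal forward model exists only to
exercise the GLM stage), motion or physiological artifacts, and
heterogeneous anatomies. Passing tests therefore demonstrate that the
*statistics* behave as claimed under the assumed generative structure, not
that any particular real dataset satisfies those assumptions.

## Design choices in the sequence module

The two path orders of a map are required to be "as distinct as possible"
in their ±2-step neighborhoods. Full set-disjointness of the combined
4-element neighborhoods is impossible on an 8-cycle — a blue neighborhood
would need four distinct environments among the three that are not green
neighbors; exhaustive enumeration shows the minimum achievable overlap is
2. The default validator therefore checks the strongest achievable
criterion: predecessors disjoint from predecessors, successors from
successors, and combined overlap at most 2. This accepts valid random and
fixed shuffles, and rejects both identical and reversed orders. A weaker
positionwise-inequality mode is available for comparison. Both construction
modes exist because the provenance of the original design's fixed shuffle
is unknown: `method = "search"` samples blue orders until valid;
`method = "fixed"` applies one pre-validated position shuffle to every
green order.

Schedule timing draws all jitter on a 0.5 s grid (ITI uniform 3-8 s,
anticipation blank 5-9 s); the granularity is a package choice. Probe
phases are recorded in the schedule but only cue-phase patterns are
analyzed downstream.

## Profile-stage choices

Profiles average all 32 trial types (both maps, both paths) before fitting
— one profile per participant, ROI and ordering; a per-map/path fit is the
natural extension but participant-level averaging is the granularity at
which the group statistics operate. The different-map baseline
averages the other map's templates voxelwise *then* correlates
(average-then-correlate). Correlations are plain Pearson on ROI-restricted
values with no spatial z-scoring.

## Simulation sizes used by the test suite

The statistical acceptance tests run, as the package's own study sizes:
parameter recovery on 100 default-condition datasets (n = 32) plus 60
symmetric-width datasets; permutation calibration on 500 exchangeable-noise
profile sets (n = 12, 200 shuffles); context specificity on 100 datasets
(n = 16); gradient recovery and its flat-σ null on 100 searchlight
simulations each (n = 12, 8×14×4 lattice); behavior coupling on 200
replicates (n = 32). Under these conditions recovery errors run well under
the 15% acceptance bound, permutation rejection rates sit at the nominal
5%, and gradient and coupling recovery are near-ceiling.

## Known limitations

* Real-data ingestion expects beta images already estimated (or the
  package's simple OLS GLM); fMRIPrep-style preprocessing and nuisance
  estimation are out of scope, and mixed-effects group models are replaced
  by per-participant estimates with one-sample/paired tests.
* TFCE-based cluster inference is not reimplemented (see above).
* Anatomical/probabilistic atlases are consumed as prepared binary masks,
  never derived.
* The amplitude definition ($A = y(0)$) and the reading of "intercept" as
  the asymptote in the regularizer are documented conventions; analyses
  that require peak-minus-asymptote amplitudes can compute $A - c$ from the
  returned fits.
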