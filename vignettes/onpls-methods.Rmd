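---
title: "Multi-block integration of omics data with OnPLS: models, parameters and design choices"
author: "onpls package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block integration of omics data with OnPLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onpls)
```

## The problem and the model

Transcript, protein and metabolite levels measured on the same biological
samples are linked by flows of information, but each platform also carries
systematic variation of its own (platform effects, block-specific biology)
plus noise. Treating the blocks jointly therefore needs a model that
*separates* what is shared from what is not. This package implements the
OnPLS family of latent-variable decompositions: every block
$X_i \in \mathbb{R}^{M \times N_i}$ (samples by variables) is split into

$$X_i = \underbrace{\textstyle\sum_a t_a p_{i,a}'}_{\text{globally joint}}
      + \underbrace{\textstyle\sum_b t_b p_{i,b}'}_{\text{locally joint}}
      + \underbrace{\textstyle\sum_c t_c p_{i,c}'}_{\text{unique}}
      + E_i,$$

where globally joint components share score vectors across *all* blocks,
locally joint components across a proper subset, and unique components live
in one block only. O2PLS is the two-block special case ($X = X_J + X_U +
E$). The method is symmetric: no block is an outcome, and the result does
not depend on the order in which blocks are supplied.

### The consensus extraction

One globally joint component is found by maximising the sum of pairwise
score covariances
$$J = \sum_{i < j} (X_i w_i)'(X_j w_j), \qquad \lVert w_i \rVert = 1,$$
with cyclic alternating least squares: each weight update
$w_i \gets \mathrm{normalise}\!\big(X_i' \sum_{j \neq i} X_j w_j\big)$ is the
exact maximiser given the others, so $J$ is non-decreasing and the
trajectory is logged and asserted in the test suite. Weights are
initialised from the leading left singular vector of the concatenated
cross-covariances $[X_i' X_j]_{j \neq i}$, computed through the small
$M \times M$ Gram matrix of the other blocks so that the initialisation
costs $O(M^2 \sum N_i)$ rather than an SVD of an $N_i \times \sum N_j$
matrix. For two blocks the update is a power iteration on
$X_1'X_2$, so the converged pair equals the top singular pair of the
cross-covariance -- the package's own two-block oracle test.

After each component, every block is deflated by $t p'$ with
$p = X't/(t't)$. Deflation makes successive scores within a block exactly
orthogonal, which in turn makes the variance ledger additive: the squared
Frobenius norms of all parts plus the residual reproduce the preprocessed
block norm to machine precision, and the per-block $R^2$ fractions sum
to one.

### Staging, local components, unique components

Fitting proceeds in three stages. Global components are extracted across
all blocks, with optional interleaved orthogonal filtering (below). Local
components are then extracted from proper block subsets, visiting larger
subsets first; among equal-size subsets the one whose converged objective
$J$ is largest wins the next extraction (ties break on the sorted subset
key), and only the subset's blocks are deflated. Unique components are the
leading principal components of each block's remaining residual -- either a
requested count or, under `"auto"`, as long as each captures at least
`auto_var_ratio` of the block's preprocessed variance.

All internal loops run in sorted block-name order and local counts are
keyed by sorted block names, which is why permuting the input blocks
reproduces the model bit for bit.

### Orthogonal filtering

O2PLS-style filtering looks for within-block structured variation that is
orthogonal to the joint variation: the candidate weight is the part of a
joint loading not contained in the block's joint weight space,
$w_o = p - Q Q' p$ with $Q$ an orthonormal basis of all global weights.
Orthogonalising against the whole space rather than one direction matters:
two global components of comparable strength only pin down a 2-D subspace,
their individual loadings rotate freely within it, and a filter that only
knows one direction would read the other global direction as "orthogonal
structure" and strip it. The global stage therefore extracts all global
components tentatively, judges candidates against the full weight space,
deflates accepted candidates and repeats until none passes, and only then
commits the global components. A candidate is accepted only if **both** of
the following hold, governed by a single parameter `ortho_var_ratio`
(default 0.05):

1. the orthogonal share of the loading, $\lVert w_o\rVert^2 / \lVert
   p\rVert^2$, is at least the threshold -- genuine orthogonal structure
   makes the loading point visibly away from the weight, whereas mere
   estimation noise misaligns them by a fraction of a degree;
2. the candidate's captured variance is at least that fraction of the
   block's *preprocessed* squared norm.

The second gate alone cannot work in the short-fat regime typical of
omics: with $M = 9$ samples, *any* unit direction "captures" roughly
$1/(M-1) \approx 12\%$ of a block, because regressing 243 columns on an
arbitrary 9-vector always explains something. A variance-only gate
therefore accepts noise candidates indefinitely and strips real joint
signal into the unique part; the loading-share gate is what makes the
filter selective. Setting `filter_orthogonal = FALSE` turns the filter off
entirely, in which case orthogonal within-block structure is picked up
later by the unique stage.

## Preprocessing

The preprocessing chain mirrors common two-colour-array practice followed
by reference standardisation:

* `log2_transform` (optionally with an offset), state `raw` to `log2`;
* `censor_low`: intensities below `censor_threshold` (default 7, on the
  log2 scale) are raised to the threshold, damping non-expressed genes.
  The operation is idempotent;
* `combine_dye_swap`: technical (dye-swap) replicate rows are averaged per
  variable, ignoring missing values, so a value observed in one replicate
  only is kept as is; a variable missing in all replicates stays missing;
* `center_per_sample`: each row is centred at its observed mean;
* `wt_reference_scale`: every variable is standardised by the mean and the
  $n-1$ standard deviation of the *reference-genotype* samples, so the
  wild type becomes the common origin of all platforms. All rows,
  reference included, are scaled by the same statistics so that the model
  operates in one coherent space and reference samples legitimately carry
  scores. Variables whose reference spread is numerically zero (below
  `min_reference_sd`, default 1e-12) or observed in fewer than two
  reference samples cannot be standardised and are dropped, with the ids
  and reasons attached to the result.

Proteomic and metabolomic matrices normally arrive already summarised, so
only the reference scaling is applied to them; the log2/censor/dye-swap
steps are meant for the transcript block. Whether per-sample centering runs
before or after replicate combination is not fixed by the chain; the
package combines first and centres second, and both operations are exposed
separately so the order can be swapped.

Missing measurements are a first-class marker (`NA`), distinct from zero,
through the whole chain; the decomposition itself requires complete
matrices, so `impute_missing` (variable-mean or drop-variable) is provided
as the last step before fitting.

## Variable selection

**VIP.** Variable importance in projection is adapted to the unsupervised
multi-block setting: for the globally joint components of one block,
$$\mathrm{VIP}_k = \sqrt{\,N \cdot \frac{\sum_a SS_a\, w_{a,k}^2}{\sum_a SS_a}\,},
\qquad SS_a = \lVert t_a p_a' \rVert_F^2 .$$
There being no outcome block, each component is weighted by the joint
variance it captures in the block itself. Unit-norm weights make
$\mathrm{mean}(\mathrm{VIP}^2) = 1$ exactly, and a single component
collapses to $\sqrt{N}\,|w_k|$. A variable passes the VIP gate when its
VIP strictly exceeds the threshold (default 0.5).

**Jackknife.** Leave-one-sample-out refits (the biological plant is the
resampling unit) attach a standard error to each variable's loading on its
dominant global component:
$\mathrm{var} = \frac{M-1}{M} \sum_m (\theta_{(-m)} - \bar\theta)^2$, with
the confidence interval $\hat\theta \pm t_{0.975,\,M-1}\,\mathrm{SE}$.
Before the loadings are read off, each resample's global components are
aligned to the full model by an orthogonal Procrustes rotation of the
loading matrix. With one component this reduces to a sign flip; with
several components of comparable strength it removes the rotational
indeterminacy of the joint subspace -- resampled fits are rotated copies of
the same subspace, and without the alignment that arbitrary rotation would
masquerade as loading variance and inflate every interval.

How preprocessing behaves inside a resample is a genuine modelling choice,
exposed as `resample_preprocess`:

* `"reference"` recomputes the reference scaling on the remaining
  reference samples. With three reference samples this leaves two, and a
  standard deviation estimated from two values is so noisy that the
  resulting intervals mostly measure scaling uncertainty;
* `"center"` recentres columns per resample (for models fitted on centred
  matrices, e.g. the synthetic benchmark);
* `"none"` conditions on the training preprocessing and refits on the row
  subset as is -- the convention of the PLS jackknife literature and the
  default of the bundled pipeline.

A variable is called **significant** when it passes both gates: VIP
strictly above the threshold *and* a confidence interval excluding zero.
No multiple-testing correction is applied, deliberately: the procedure is
a two-gate stability filter, not a calibrated hypothesis test. Direction
arrows then record, per transgenic line, the sign of the line's mean
reference-scaled value (up/down relative to the reference genotype), and
the protein-transcript coregulation fraction counts, over all
(significant protein, line) pairs, the share whose mapped transcript is
significant with the same direction in that line.

## The synthetic generator

`simulate_multiomics()` emulates a three-genotype design: 9 samples (a
reference `WT` plus two transgenic lines, three biological replicates
each) and three blocks of 243, 243 and 61 variables. The genotype effect
lives in two globally joint components with means 0/3/3 (both lines
against the reference) and 0/-2/2 (line against line), jittered by a
within-genotype spread of $\tau = 0.1$; one locally joint component links
the transcript and protein blocks; each block has one unique component;
noise is i.i.d. Gaussian with $\sigma = 0.2$. Joint loadings are sparse
(10% of variables per component, magnitudes at least 0.15 so that every
effect variable has a detectable effect), unique loadings are dense with
standard deviation 0.3 -- chosen once so the globally joint part dominates
each block's variance, as it does in real genotype-contrast panels.

Three structural choices make ground-truth comparisons exact rather than
approximate, and they matter:

* **scores are centred and mutually orthogonalised** across parts, so each
  part's variance contribution is well defined and the recorded fractions
  sum to one with the noise fraction (the recorded denominators are
  $\sum_{\text{parts}} \lVert t p' \rVert^2 + \lVert E \rVert^2$, so
  signal-noise cross terms are excluded by definition);
* **the sparse supports of a block's joint parts are disjoint** and the
  dense unique loading is orthogonalised against them. Without this the
  generated decomposition is not a stationary point of the consensus
  objective -- overlapping supports couple the parts, the optimum mixes
  them, and noiseless recovery could never reach numerical precision. With
  it, the truth is the exact optimum and the noiseless benchmark demands
  recovery to 1e-6;
* **the signal mask** marks the variables with a nonzero loading in at
  least one globally joint component -- the target population of the
  VIP/jackknife machinery, which operates on global components.

The generator emits the exactly-centred matrices plus a reference-scaled
variant. The recovery benchmark fits the centred matrices: at
$\tau = \sigma = 0$ every reference standard deviation is zero, so
reference scaling is undefined there, and the centred space is the one in
which both the noiseless-exactness and the noisy-recovery halves of the
benchmark are well posed. The ground truth also stores reference-centred
score variants ($t - \bar t_{\mathrm{WT}}$), which are the correct
comparison for a model fitted on the scaled variant, since per-column
affine scaling shifts each score direction by its reference mean.
Benchmark sensitivity and specificity are pooled over seeds 0--9 as one
aggregate confusion matrix.

What the generator does **not** emulate: dye bias, batch and run-order
drift, heteroscedastic or structured missingness, platform-specific
intensity distributions, and correlated noise. Passing the recovery
benchmark therefore demonstrates correctness of the decomposition and the
selection machinery under the stated latent-variable model, not robustness
to real-data artefacts.

## Numerical choices

* ALS convergence: maximal weight change below `tol = 1e-9`, at most
  `max_iter = 500` cycles; non-convergence returns the last iterate with a
  warning.
* Sign convention: the largest-magnitude element of the first block's
  weight (sorted block names) is made positive and every other block's
  score is sign-matched to the first; loadings, arrows and exports are
  thereby reproducible.
* Degenerate inputs: an all-zero block residual is a hard error ("no
  extractable variation"); a zero cross-covariance yields a near-zero
  objective and a "no appreciable joint variation" warning; a zero score
  range makes the genotype CV `NaN` with a warning.
* Principal angles are computed with the combined cosine/sine formulation
  (`acos` of the singular values of $Q_a'Q_b$ for large angles, `asin` of
  the singular values of $Q_b - Q_a(Q_a'Q_b)$ for small ones); `acos`
  alone cannot resolve angles below ~1e-8.
* Report percentages are rounded by a largest-remainder scheme so each row
  of the variance report sums to exactly 100.0 at one decimal.
* Determinism: all randomness flows from the single generator seed; model
  fitting is deterministic, and the pipeline's writers use fixed formats,
  so one seed yields byte-identical output files.

Problem sizes used by the bundled checks: the targeted-size generator
(9 samples, 243/243/61 variables) everywhere, ten seeds with nine
leave-one-out refits each for the noisy benchmark, and one fit of the
all-variable-scale preset (14619/271/386) for throughput.

## Component counts and limitations

The number of global components is user-specified (default 2, matching a
reference-plus-two-lines contrast: one direction separating both lines
from the reference, one separating the lines); no cross-validation is
built in, and none is attempted because component-count selection for
multi-block models is an open methodological question. Components removed
by the orthogonal filter are classified as unique even though in a full
OnPLS treatment some could be locally joint; when that distinction
matters, run with `filter_orthogonal = FALSE` and request local components
explicitly. The per-genotype CV formula (within-genotype standard
deviation of the first joint consensus score over the score's full range)
is one of several possible definitions; its values are comparable across
runs of this package but not across differently defined summaries.
Technical metabolite replicates are expected to be averaged before entry
(or collapsed with `combine_dye_swap`, which is platform-agnostic in what
it averages).
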