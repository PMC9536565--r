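---
title: "Measuring letter similarity from reaction times and comparing it to feature models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring letter similarity from reaction times and comparing it to feature models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lettersim)
```

## The problem

How similar is a lowercase `e` to a lowercase `c`? Perceptual similarity
between letters can be measured without asking anyone to introspect, by
timing behavior in which similarity gets in the way. `lettersim`
implements two such assays and the representational-similarity machinery
around them:

* **Odd-one-out visual search.** One target letter appears among five
  identical distractor letters; the participant clicks the odd one out.
  Search is slow when target and distractors look alike, so mean search
  time indexes pairwise similarity.
* **Speeded categorization.** A target letter is held in mind (e.g. "a")
  and single letters are accepted or rejected as quickly as possible.
  The time to *reject* a non-matching letter indexes its similarity to
  the internal representation of the target.

Both experiments produce a **representational dissimilarity matrix**
(RDM): a symmetric items-by-items matrix whose lower triangle is the
behavioral signature of the letter representation. Model feature spaces
(network layer activations, intuitive stroke-feature counts, one-hot
category labels, raw pixels) produce RDMs of the same shape, and models
are scored by the Spearman correlation between their lower triangles and
the behavioral one. That rank correlation is deliberately conservative:
no reweighting of features or dimensions is applied, so a model can fail
either by having the wrong features or by having them in the wrong
proportions.

## Experiment designs

The search design is fully counterbalanced: one session (HIT) per
combination of target position, font, and target-distractor assignment,
and *every* session contains exactly one trial of every unordered letter
pair. With 26 letters that is 325 trials per HIT and, at 6 positions x
20 fonts x 2 assignments, 240 HITs. Because each session sees all pairs,
a generally slow participant slows all pairs equally — session speed is
removed later by within-HIT normalization, not by modeling.

The categorization design cannot show every ordered (target, presented)
pair to every participant: with 26 letters there are 650 ordered pairs.
Each HIT instead runs two blocks with different targets and 13 assigned
non-target letters each, repeating each assigned pair 8 times among an
equal number of target-match trials (416 trials per HIT). Ordered pairs
are distributed over HITs by round-robin over seeded per-target queues;
this keeps the per-pair coverage within a max-min spread of about 2
HITs. (The reference design this emulates reported coverage between 50
and 56 sessions per pair, so near-uniformity rather than exact balance
is the design property that matters.)

`generate_search_designs()` and `generate_categ_designs()` take the
alphabet and font list as parameters, so reduced designs — used
throughout the test-suite — are first-class rather than special cases.

## From reaction times to RDMs

**Search.** Incorrect trials are dropped. RTs are log-transformed
(reaction times are positively skewed; log brings them near symmetry)
and z-scored *within HIT*, which makes fast and slow sessions
commensurable because each session tested all pairs. Trials beyond 3 SD
are excluded. The z-scores are computed in a single pass and not
recomputed after the outlier exclusion: recomputation would change the
exclusion set itself, and a one-pass rule is deterministic and easier to
reason about. The RDM entry for a pair is the negated mean z over all
its retained trials — fast search means dissimilar letters, so negation
puts the matrix on a dissimilarity scale. Pairs with no retained trials
are flagged `NA`, never silently zero-filled; the counterbalanced design
guarantees full coverage in practice.

**Categorization.** Whole sessions below 90% accuracy are dropped, then
incorrect trials, then any (pair, session) cell in which more than half
of the scheduled repetitions were wrong (more than 4 of 8 at the default
design). The remaining non-match RTs are averaged per cell, and the cell
means enter a linear mixed model

```
mean_rt ~ condition + (1 | hit)
```

with a fixed effect per ordered condition (dummy coded) and a random
intercept per session absorbing between-participant speed. The reference
condition's estimate is added back to every effect, the two directions
of each unordered pair are averaged, and the result is negated into the
RDM. The estimate is invariant to which condition is the reference
(asserted by test). REML is the default criterion; `method = "ML"` is
used inside split-half loops where speed matters more than unbiased
variance components. One subtlety: adding a constant to every RT of one
session is absorbed only up to a common shift of all entries (the grand
intercept moves by the mean offset); rank-based comparisons are
unaffected, and zero-sum offsets are absorbed exactly in balanced
designs.

Degenerate inputs are handled explicitly: a session whose correct-trial
log-RTs have zero variance is excluded with a warning (its z-scores are
undefined); a mixed-model design with a single session, or too few
observations to identify the random intercept, degrades to the
fixed-effects fit, whose estimates are the per-condition cell means.

## Noise ceilings

A model cannot be expected to correlate with behavior better than
behavior correlates with itself. Both ceilings are split-half
correlations corrected upward with the Spearman-Brown prophecy formula
`2 * rho / (1 + rho)`:

* **Search** splits sessions by font into two equal halves, correlates
  the half-RDMs, and averages over all `choose(n_fonts, n_fonts/2)`
  splits (184,756 at 20 fonts; enumeration over subsets double-counts
  complementary halves, which leaves the mean unchanged).
* **Categorization** splits each pair's retained measurements into equal
  halves (dropping one measurement at random per odd-count pair per
  split, so halves stay balanced), rebuilds the RDM per half with the
  full mixed-model pipeline, and averages over random splits. The
  default of 20 splits estimates a mean whose split-to-split SD is small
  (the reference procedure used 10,000 splits with the human-scale
  data); the split count is a parameter.

## Model RDM conventions

Feature activations arrive as pooled vectors, one row per image
(`pool_feature_maps()` collapses convolutional maps by spatial
summation: a 13x13 map of ones pools to 169). Two conventions mirror
what each task asks of the observer:

* **Search convention** — distances between letters *within* each font,
  averaged across fonts, because search always compares letters rendered
  in the same font.
* **Categorization convention** — distance from each font-specific
  exemplar to the *template* (mean activation across fonts) of the other
  letter, averaged over fonts, because categorization compares a
  percept to a font-general internal target. The raw exemplar-to-
  template matrix need not be symmetric; the two directions are averaged,
  exactly as the behavioral pipeline averages its two directional
  estimates. The positive self-distance (exemplar spread around its own
  template) is preserved as an attribute rather than in the RDM proper.

Euclidean distance is the default metric; correlation and cosine
distance are available and produce the same qualitative structure.
Baselines include the one-hot categorical RDM (same letter 0, different
letter `sqrt(2)` — any metric monotone in same/different gives identical
rank structure) and hand-coded intuitive stroke features (a synthetic
example rating table ships in `extdata`; the original ratings were
never published, so the file is illustrative, not a reproduction).

Letter-preferring feature subspaces are selected by a per-feature Welch
two-sample t-test on pooled activations to letter images versus object
images, keeping features with higher letter means at p < 0.05. Welch
rather than pooled-variance is the deliberate choice: activation
variances differ wildly between image sets. The sampling unit is the
individual image's pooled activation. Under a null where both groups
share one distribution the directional filter keeps about alpha/2 of
features — a calibration the test-suite checks by Monte Carlo. Control
subspaces are drawn as size-matched random masks from the eligible
non-preferring pool.

## Inference

Model-behavior curves report the per-stage Spearman correlation;
uncertainty comes from bootstrapping the 325 unordered letter pairs with
replacement. Two models are compared either stage-by-stage or by the
stage each model fit best in the original sample (`max_layer`). The
reported `p` is the one-sided proportion of resamples in which the
nominally better model is not better; ties count against rejection
(conservative), and duplicated pairs enter the rank correlation as-is. A
two-sided option doubles the smaller tail. Resamples with degenerate
(constant) ranks are skipped and counted. Per-font comparisons take each
model's maximum correlation per font and use a paired t-test across
fonts (df = n_fonts - 1).

MDS projections (`mds_embed()`: classical scaling, optionally refined by
Sammon stress minimisation — both deterministic) are provided for
visualization only, never for inference.

## The synthetic-data generator

No human or network data ship with the package; a generator produces
data with the statistical structure the pipelines assume, and the
pipelines are validated by parameter recovery against the generator's
known ground truth.

* **Glyphs**: 5x7 dot-matrix letter templates rasterized at 24x24, with
  each "font" a deterministic parametric perturbation (scale 0.75-1,
  slant +/-0.25, stroke dilation, sub-pixel jitter). No font files, no
  binary assets.
* **Latent structure**: the pixelwise RDM of the glyphs (mean of
  within-font pixel distances, normalized to [0, 1]) plays the role of
  the true perceptual similarity.
* **Search RTs**: log RT = baseline + session offset + slope x
  similarity + Gaussian residual, exponentiated to ms. Defaults:
  baseline `log(600)` ms, session-offset SD 0.15, slope 0.7 (the most
  similar pairs run about 2x slower than the most distinct), residual SD
  0.25 (lognormal RTs with ~25% residual variability), 1% lapses
  replaced by far-tail RTs, and error probability rising with similarity
  from 1% (mean accuracy ~97%).
* **Categorization RTs** (ms scale): baseline 600, session-intercept SD
  60, similarity slope 200, residual SD 120, similarity-dependent errors
  as above. Match trials sit at baseline.
* **Feature hierarchies**: cascades of random 3x3 convolutions, ReLU,
  and 2x downsampling over the glyphs — an untrained stand-in with the
  same pooling and RDM conventions as a trained network, used to
  exercise the model pipeline, not to model learning.

These defaults describe what realistic crowdsourced letter-RT data look
like and are *not* tuned to any particular test outcome. What the
generator does not emulate: sequential effects and learning within a
session, non-Gaussian session-speed distributions, letter-specific error
strategies, and real typographic variation. Passing recovery tests
therefore show the pipelines are consistent estimators of the structure
they assume — not that the assumed structure exhausts real data.

## Problem sizes and numerical choices

The test-suite and the acceptance script run a reduced configuration — 6
letters, 6 fonts, 60 sessions per experiment — chosen so the full
design-simulate-estimate-validate loop, including repeated mixed-model
fits inside split-half loops, completes in well under a minute; the
behavioral-scale configuration (26 letters, 20 fonts, 240/664 HITs) is
exercised for the design combinatorics, which are exact counts. At the
reduced scale the pipelines recover the latent structure at Spearman
rho of roughly 0.92 (search) and 0.86-0.95 (categorization), and the
bootstrap comparison's null rejection rate at the 0.05 threshold sits
inside its binomial sampling band.

Other numerical choices: within-HIT z-scores use the sample SD with a
hard error on zero variance; mixed-model fits inside ceiling loops relax
optimizer tolerances (`xtol_abs = ftol_abs = 1e-6`) and ignore singular
fits, which are expected when simulated session variance is small; all
randomized operations draw from local RNG streams seeded per call, so
package functions never perturb (or depend on) the caller's RNG state,
and every seeded operation is bit-reproducible.

## Known limitations

* The mixed model treats cell means as homoscedastic; cells retaining
  fewer correct trials are noisier, and no weighting is applied (the
  reference procedure did not weight either).
* The categorization ceiling rebuilds RDMs on half the measurements,
  which mildly underestimates full-sample reliability structure when
  conditions have very few retained measurements.
* The pixelwise latent RDM is a convenient, monotone-recoverable ground
  truth, not a theory of letter similarity; recovery thresholds are
  statements about pipeline fidelity, not about perception.
* Glyph "fonts" are parametric perturbations of one template set and do
  not span real typographic diversity.
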