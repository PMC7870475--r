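---
title: "Methods: reverse correlation with a sinusoid noise basis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse correlation with a sinusoid noise basis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revcorr)
```

This vignette is the package's own account of the model it implements: the
parametric noise basis, the observer models, the classification-image (CI)
estimator and its statistics, the CI-weighted classifier, and the design
choices that were genuinely open.

## The noise model

A noise image is a weighted sum of a fixed dictionary of localized
sinusoid components. At each spatial scale the image is tiled by a regular
grid of square patches (1, 2, 4, 8, 16 patches per side by default); each
patch carries one sinusoid per orientation × phase combination
(6 orientations 30° apart, phases 0 and π/2), spanning two cycles across
the patch and zero outside it. Two cycles per patch on grids of 1–16
patches per side realise 2–32 cycles/image, which is why the scale labels
are cycles/image. The default dictionary therefore has

K = Σ_s grid² × 6 × 2 = (1 + 4 + 16 + 64 + 256) × 12 = **4,092**

amplitude parameters, drawn i.i.d. Uniform(−1, 1) per trial. Synthesis is
exactly linear in the parameters, so the scale layers partition any
synthesized image — including the CI itself — additively.

Conventions fixed here (they affect nothing statistical, but are stated so
images are reproducible elsewhere): orientation is measured in degrees from
the horizontal axis with the row index increasing downwards; the sinusoid
argument uses patch-local pixel coordinates; patches have hard rectangular
windows (no taper); every component has unit sinusoid amplitude before
weighting, which keeps parameter magnitudes comparable across scales for
the per-parameter tests.

Dictionary non-orthogonality matters and is worth stating plainly:
same-patch sinusoids 30° apart are far from orthogonal, so the dictionary
synthesis operator B has B·Bᵀ ≠ I. Consequences appear below.

## Stimuli

A stimulus blends the template T with the rescaled noise N:
S = (1 − w)·T + w·rescale(N), clipped to [0, 1], with w = 0.5 by default.
`rescale` maps the noise's theoretical amplitude range [−A, A] affinely
onto [0, 1], where A = max over pixels of Σ_k |C_k(pixel)| is computed
exactly per basis. Because the rescaled noise already lies in [0, 1],
clipping never actually triggers for templates in [0, 1]; the clip is a
guard, not a nonlinearity. Analysis always uses the continuous stimulus;
8-bit quantization happens only on PNG export.

Prototypes render a CI visible: the CI is rescaled so its largest absolute
pixel equals `peak` (default 0.2 of the dynamic range — the source
construction leaves the value open, so it is an exposed parameter), then
added to the template for the female prototype and subtracted for the male
one. The CI's sign convention is female-minus-male throughout, which is
what makes "add ⇒ female" correct.

## Observers

The **linear template observer** computes v = Σ_j (S_j − T_j)·a_j + ε with
ε ~ N(0, σ²) and answers "female" iff v > θ; ties go to "male" (a fixed
tie rule is needed for determinism). Subtracting the template makes the
observer respond to noise content only; with a flat template the decision
variable is then exactly proportional to the noise's projection on the
axis a, and CI recovery has a clean closed-form target. The **random
observer** answers a fair coin and anchors all null calibrations.
**External classifiers** are wrapped by a two-score adapter: any callable
returning (score₁, score₂) per image; the decision variable is their
difference, and raw scores are kept in the trial record.

Two decision criteria exist because real classifiers can be biased:
`fixed_threshold` compares v with θ; `mean_activation` compares v with its
empirical mean over the whole batch (two-pass), removing any constant
response bias. The two are exactly equivalent when θ equals the batch
mean — the package tests this as an identity, and on an unbiased observer
the CIs obtained under the two criteria are nearly identical (r > 0.99).

Four-level confidence responses ("probably/possibly × female/male") are
generated by a median split on |v − θ| within the batch; only their binary
collapse is used by any downstream analysis, so the split convention is
cosmetic.

## The CI estimator

`compute_ci()` returns the parameter-space mean difference
ĉ = mean(a | female) − mean(a | male) and its pixel synthesis B·ĉ. For a
noiseless linear observer, ĉ converges (up to a scalar) on Bᵀa — each
parameter's covariance with the response sign. The *pixel* CI therefore
converges on B·Bᵀ·a, not on a itself; with the default dictionary this
caps the pixel-space recovery correlation near 0.93 regardless of trial
count. This is a property of the basis, not an estimation error, and it is
why the acceptance checks ask for r ≥ 0.9 rather than r → 1. Parameter-
space similarity (`ci_similarity(..., space = "parameter")`) is offered
because it is basis-exact and free of this attenuation.

Null calibration: under a random observer each CI entry has standard error
√(1/3 · (1/n_f + 1/n_m)) (uniform amplitude variance 1/3). The test suite
checks that all 4,092 standardized entries stay within 4 SE at 5,000
trials. The expected maximum of ~4,092 near-Gaussian deviates is ≈ 3.7, so
this check sits deliberately close to its null expectation; its seeds were
fixed before running and are reported with the tests.

## Per-parameter contribution statistics

For each parameter, a **pooled-variance** (Student) two-sample t-test
between female- and male-trial amplitudes, two-sided, with |Cohen's d| =
|mean_f − mean_m| / pooled SD as the contribution index. Pooled rather
than Welch: class sizes are near-equal by design and d shares the pooled
SD, keeping t and d consistent (their orderings coincide exactly at equal
n). The Bonferroni family is all K parameters jointly at family α = 0.05,
matching a single Manhattan-plot-wide correction; per-scale summaries then
count significant parameters against per-scale denominators. Parameters
with zero pooled variance are flagged degenerate and never significant
(zero variance with zero difference reports t = 0, p = 1 instead).
`top_contributors()` ranks by |d| with ties broken by ascending parameter
index — determinism again — and returns the shortest prefix reaching the
requested share of total |d|.

A practical note the synthetic experiments make visible: with a unit-norm
axis built from equal-magnitude component coefficients, component energies
differ by scale (a full-image patch holds ~4× the energy of the next
scale's patches), so low-frequency members of the axis dominate the
decision variable and reach significance first. Detecting all members of a
mixed-scale axis requires either energy-equalized coefficients or more
trials; the tests use both regimes deliberately.

## The CI as a one-layer classifier

"Convolving" a class exemplar with the CI here means the full-image inner
product — the CI as the connected weights of one output unit — not a
sliding convolution. Each input image is mean-centered first (default,
switchable), which removes brightness confounds; activation is then
invariant to adding a constant to the image. Class separation is Cohen's d
(pooled SD, signed female-minus-male) between the two activation
distributions. The baseline scrambles the CI's pixels (seeded
permutations) and recomputes d; a genuine CI must beat the 95th percentile
of the scrambled |d|. For the synthetic populations
(clip(T ± e·A + ε), ε ~ N(0, sd²)) the ideal-CI separation has the closed
form d = 2e‖A‖/sd, which the tests verify at e = 0.1, sd = 0.05 (d ≈ 4).

## Synthetic data: what it emulates, and what it does not

`make_axis()` (sparse known component mixtures, with a low-frequency
preset placing ≥ 80% of squared coefficient mass at the two lowest
scales), `make_template()` (flat / radial / schematic-face), and
`make_population()` (template ± effect·axis + pixel noise) generate every
input the pipeline needs, seeded and exactly regenerable. They emulate the
*statistical* structure of the original design — a neutral template, an
observer driven by a hidden linear template, aligned class exemplars — but
none of the *photometric* structure of real faces or the nonlinearity of
real deep networks or human observers. Green tests therefore certify the
estimator chain (noise → responses → CI → statistics → classifier), not
any claim about what a particular real observer represents.

Problem sizes used by the tests and the acceptance script, chosen to
mirror the design's two regimes while staying desk-sized: recovery runs at
image size 128 with 20,000 trials (the machine-observer regime; 1,000–
5,000 trials corresponds to a human session); null calibration at 5,000
trials; familywise-error calibration over 200 replicates of a reduced
30-parameter basis at 100 trials each; classifier populations of 500
images per class with 200 permutations.

## Numerical and degenerate-input choices

- Ties v = θ label "male"; a batch of one under `mean_activation` is its
  own mean, hence "male".
- Single-class trial sets, all-zero CIs (no direction to rescale), and
  constant CIs (no display normalization) are hard errors naming the
  problem, not silent zeros; zero-variance correlations return `NA` with a
  warning rather than 0.
- All randomness flows through explicit seed arguments; library calls
  save and restore the caller's RNG state, and each pipeline stage derives
  its own substream (seed, seed+1, …) so runs are bit-reproducible.
- Run artifacts carry an MD5 hash of the run configuration so any output
  file can be traced to the exact settings that produced it.

## Known limitations

- The pixel-space CI is the synthesis of the parameter CI; no smoothing or
  Z-scoring is applied (some reverse-correlation variants do).
- Non-square images, tapered patch windows, and 1/f or Gabor noise are out
  of scope; so are face morphing/alignment — external image sets must be
  pre-aligned to the template by the user.
- The external-observer adapter calls the classifier once per image in R;
  it is meant for contract testing and moderate batches, not for
  large-scale network inference.
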