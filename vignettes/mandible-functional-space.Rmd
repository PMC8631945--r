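---
title: "Mandibular mechanical advantage, functional spaces, and phylogenetic ordination"
author: "levermorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mandibular mechanical advantage, functional spaces, and phylogenetic ordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levermorph)
```

## The problem

Insect mandibles are third-class levers. The adductor muscle inserts at
a fixed point, the mandible rotates about its joint (a single condyle
in flattened compression fossils, a dicondylar axis in extant
material), and food is engaged somewhere along the toothed gnathal
edge, from the proximal molar region to the distal incisivi. The
*mechanical advantage* (MA) at a bite point is the ratio of the muscle
inlever to the outlever at that point — the fraction of muscle force
transmitted to the item. Because it is a ratio of moment arms, MA is
dimensionless and size-independent, which makes it a usable functional
descriptor for taxa known only from fragmentary fossils: low MA with a
gently exponential decline toward the incisivi is typical of fast-biting
predators, high MA with a near-linear decline of slow, forceful
herbivore biting, and intermediate curves of mixed diets.

`levermorph` turns this observation into a tested pipeline: MA curves
are computed along the whole gnathal edge, summarised as polynomial
coefficients with a common order selected by AIC, and the resulting
functional space is ordinated by PCA and — because related species are
not independent samples — by phylogenetic PCA, with phylogenetic signal
quantified by Blomberg's K and its multivariate extension.

## Lever geometry and MA curves

`lever_geometry_from_landmarks()` consumes a labelled landmark
configuration whose semantic roles identify the joint, the adductor
attachment, and an ordered polyline of edge points (proximal to
distal). `ma_curve()` resamples the edge at `n_points` positions
equally spaced in arc length (default 100) and computes

* **2D**: outlever = Euclidean distance from the resampled point to the
  pivot; inlever = pivot-to-attachment distance;
* **3D**: both moment arms are perpendicular distances to the
  dicondylar axis, as lever mechanics requires — axial components carry
  no moment.

MA values are reported against normalized arc length `s` in [0, 1].
The curve is invariant under translation, rotation, reflection and
uniform scaling of the input coordinates (asserted to 1e-10 in the test
suite), so units and digitization frames are irrelevant. No smoothing
is applied to the raw curve: the polynomial stage is the smoother.
Degenerate inputs — edge points on the joint axis, repeated consecutive
points, an attachment on the axis — are rejected with errors that name
the offending element.

## Alignment and composite fossils

Fragmentary fossil material is handled by aligning several replicates
of the same mandible with generalized Procrustes analysis and using the
mean shape as a single terminal unit (`composite_representation()`).
Design choices:

* **Unit centroid size.** All configurations are rescaled to unit
  centroid size; downstream use is shape-only and MA itself is
  dimensionless, so size preservation would add nothing.
* **No silent reflections.** Left and right mandibles are mirrored
  explicitly with `reflect_to_reference()` before alignment; allowing
  improper rotations inside the superimposition could silently flip the
  chirality of lever geometry.
* **Convergence.** Iteration stops when the summed squared Procrustes
  distance to the mean changes by less than `tol` (default 1e-15, cap
  500 iterations). The objective is quadratic around its optimum, so
  coordinate accuracy is roughly the square root of the objective
  tolerance; the near-machine-precision default is what makes the
  advertised 1e-8 invariance of the output under input transformations
  hold.
* **Canonical orientation.** The Procrustes optimum is unique only up
  to one common rotation. The mean shape is therefore rotated onto its
  principal axes with a fixed sign convention (and determinant +1), so
  results are reproducible regardless of input orientation or order.
* **No missing landmarks.** A composite requires the common complete
  label set across its fragments; imputation is out of scope.

## The polynomial functional space

Each curve is fitted by ordinary least squares on raw powers of `s`
(`fit_polynomial()`). Because `s` is fixed to [0, 1] before fitting,
coefficients are comparable across specimens. The common order is
selected by AIC (`select_order_by_aic()`): per curve, a Gaussian
likelihood with its own maximum-likelihood residual variance; pooled by
summation over curves; parameter count `n_curves * (order + 2)`
(coefficients plus one variance per curve); ties break toward the lower
order. Residual variances are clamped at `.Machine$double.eps^1.5` so
that, for curves fitted exactly, machine-noise differences in residual
sums of squares cannot drive the selection.

The coefficient matrix excludes the intercept by default
(`descriptor_policy = "exclude_intercept"`): on [0, 1] the intercept is
nearly collinear with the level information already carried by the
remaining coefficients, and dropping it leaves exactly `order` shape
descriptors (five at order 5). The alternative policy is available and
reported whenever used. PCA (`functional_pca()`) decomposes the
covariance matrix by default — the descriptors share one dimensionless
unit — with correlation mode as an option; component signs are fixed by
forcing the largest-magnitude loading of each component positive.

## Phylogenetic comparative layer

Shared ancestry enters through the Brownian-motion covariance matrix
`C` of the tree (`phylo_covariance()`, entries = root-to-MRCA shared
path lengths). With the GLS (phylogenetically weighted) mean
`a = (1'C^-1 1)^-1 1'C^-1 x`:

* **Blomberg's K** is the ratio of the observed mean-square
  partitioning `(x-a)'(x-a) / (x-a)'C^-1(x-a)` to its Brownian
  expectation `(tr C - n / 1'C^-1 1) / (n - 1)`; K = 1 under pure
  Brownian motion, exactly 1 on an equal-branch star tree.
* **K_mult** generalises this to a trait matrix by summing numerator
  and denominator over descriptors before taking the ratio; it reduces
  exactly to K for one column. Both the per-descriptor K vector and the
  single K_mult are reported, because a single printed statistic for a
  multivariate descriptor set implies a multivariate formulation
  without fixing its variant.
* **Permutation test**: trait rows are shuffled across tips with the
  tree fixed (default 9999 permutations, seed mandatory), and the
  add-one p-value `(1 + #{K_perm >= K_obs}) / (1 + n_perm)` is
  reported; it can never be exactly zero, and at 9999 permutations its
  resolution is 1e-4.
* **Phylogenetic PCA** eigen-decomposes the evolutionary covariance
  `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` and scores all tips —
  including a grafted fossil — in that single decomposition; there is
  no two-stage projection. A singular `C` (e.g. zero-length terminal
  pairs) is reported with a suggestion to adjust branch lengths.
  Polytomies are retained as hard polytomies.

A composite fossil enters the tree as a stem tip
(`add_fossil_tip()`), attached at the root by default with a terminal
branch equal to the mean root-to-tip depth, so an ultrametric tree
stays ultrametric; both attachment node and branch length are
user-configurable because published topologies rarely fix them.

## What the synthetic generator emulates

`make_study()` builds a complete, seeded study: a pure-birth tree
(unit speciation rate), diet classes assigned to contiguous blocks of
the tree's tip order so that diet itself carries phylogenetic signal,
per-species mandibles whose profile parameters carry Brownian-motion
jitter, and one omnivore-profile fossil fragmented into four distorted
replicates, grafted onto the stem.

Class profile defaults (all configurable): herbivores
`ma(s) = 0.60 (1 - 0.4 s)` (high, near-linear); carnivores
`ma(s) = 0.30 exp(-1.5 s) + 0.1` (low, gently exponential); omnivores
`ma(s) = 0.45 exp(-0.8 s) + 0.1` (intermediate). The exponential floor
is fixed at 0.1. Brownian jitter standard deviations are 0.04 on level
and 0.10 on curvature — visible biological variation that does not
break the class ordering.

`mandible_from_profile()` inverts the lever formula: the pivot sits at
the origin, the adductor at unit distance, and edge vertices are placed
with exactly equal chord steps at radius `1 / ma*(s)` from the pivot,
so arc-length resampling lands on the vertices and the recovered curve
equals the target up to machine precision with zero noise. This
inverse-construction identity is the oracle for the whole MA stage.

Two properties of real material are modelled deliberately:

* **Dental relief.** Real gnathal edges carry teeth. Profiles accept a
  quasi-periodic modulation `ma(s) (1 + a sin(2 pi N s + phase))`
  (study default: amplitude 0.015, 8–12 teeth, random phase per
  species). This small-scale morphology is what polynomial fits
  legitimately treat as residual structure; it is the reason AIC
  settles on a stable low order for study curves instead of chasing
  ever-higher orders on noise-free, infinitely smooth truths.
* **Digitization noise.** Isotropic landmark noise (study default sd
  0.002 on structures with outlever radii of 2–5 units, i.e. well
  under 0.1%) is kept well below the vertex spacing of the digitized
  edge. Larger per-vertex jitter at dense spacing does not behave like
  measurement noise at all: it perturbs cumulative arc length, and the
  resampling stage converts it into autocorrelated, random-walk-like
  curve deviations that mimic smooth shape differences. That pathology
  is a property of arc-length resampling of noisy polylines, not of
  any particular dataset, and is the main reason curve-level residual
  structure is modelled through dental relief instead.

What the generator does **not** emulate: real dental morphology beyond
a sinusoid, allometry, curve heteroscedasticity from foreshortening,
non-Brownian trait evolution, diet classes that are not clade-clustered,
and taphonomic deformation beyond rigid motion + isotropic noise.
Passing tests therefore demonstrate the correctness and calibration of
the computations, not that any empirical dataset satisfies the model.

## Validation scales and numerical choices

The test suite validates each stage against independent oracles at desk
scale, the package's chosen problem sizes: two-shape alignments against
the closed-form orthogonal Procrustes solution (200 random instances);
composite recovery over 100 seeded fragmentations; AIC order recovery
for generating orders 1–4 over 100 replicates each (20 curves of 100
points, noise sd 0.01); Blomberg's K against a brute-force
linear-algebra oracle and an independent implementation; K calibration
under Brownian motion (200 replicates on a 50-tip tree, expecting the
mean in [0.9, 1.1]); permutation p-values checked for
super-uniformity under an i.i.d. null (500 replicates at 199
permutations); phylogenetic PCA against a step-by-step GLS oracle and
its star-tree collapse onto ordinary PCA; and fossil placement between
the herbivore and carnivore centroids on PC1 across 50 replicate
studies at the full 43-species + fossil design scale.

Numerical conventions collected in one place: GPA tolerance 1e-15 on
the objective with canonical orientation; AIC variance clamp
`.Machine$double.eps^1.5` and ties to the lower order; PCA/pPCA sign
convention via the largest-magnitude loading; permutation p-values use
the add-one rule; degenerate geometry, rank-deficient designs,
constant traits and singular tree covariances all raise early,
specimen-naming errors rather than propagating NaNs.

## Limitations

The lever model is static: it ignores muscle force–length dynamics,
bite kinematics and material properties, so MA comparisons are
relative, not absolute bite-force statements. Composite
representations assume fragments differ by rigid motion plus noise;
plastically deformed material violates that. The AIC-selected order is
a property of the dataset at hand — richer real curves can warrant
higher orders than the smooth two-parameter synthetic family does — so
coefficient spaces from different selections are not directly
comparable. Finally, raw-power coefficients at high orders are
ill-conditioned descriptors; if selection runs to the top of the
candidate range, widening the range or reconsidering the residual
structure of the curves is more honest than interpreting the resulting
space.
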