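---
title: "Methods: whole-brain cFos-TRAP quantification and connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain cFos-TRAP quantification and connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapmap)
```

## Overview

trapmap quantifies fluorescently labeled cFos-TRAPed cells in coronal
section images, assigns them to hierarchical atlas regions, and derives
two kinds of statements: per-region activity changes under a 2x2
sleep-deprivation design (condition: ad-libitum sleep vs sleep
deprivation; method: dedicated chamber vs gentle handling), and changes
in inter-regional "functional connectivity" estimated from the
cross-animal correlation structure of the regional activity ratios.
Because raw whole-brain imaging cohorts are rarely shareable, the
package carries a synthetic-data module that generates toy atlases,
rendered section stacks with known ground truth, and count tables with
controllable effects — every downstream stage is validated against those
known truths.

## Detection model

A labeled cell appears as a compact bright spot on a smooth background.
The detection chain is the classic ImageJ-style recipe:

1. **Median filter**, window 3x3 px (odd, configurable). Borders are
   handled by edge replication so the image shape is preserved. The
   filter removes single-pixel noise but also erodes the corners of
   small square plateaus: a 3x3 plateau survives only as its 5-pixel
   "plus" core, which is why the minimum-size filter below operates on
   the *post-filter* footprint.
2. **Rolling-ball background subtraction**, radius 5 px. The background
   is the grayscale opening of the image with a ball-shaped structuring
   element whose height profile is the spherical cap
   `h(dx, dy) = sqrt(r^2 - dx^2 - dy^2)`. Opening (erosion then
   dilation) is anti-extensive, so the background never exceeds the
   image; structures narrower than the ball — the cell spots — are
   excluded from it. We implement the opening exactly rather than with
   the shrink/enlarge approximation used by interactive tools; on
   smooth backgrounds with compact spots the two agree, and the exact
   form is testable against an independent erosion-dilation oracle. At
   image borders the element is truncated to the pixels that exist
   (anti-extensivity survives truncation because the zero offset is
   always present). Subtraction clips at 0.
3. **Threshold**: pixels of the filtered, background-subtracted image
   with intensity >= 20 are foreground. The threshold is applied after
   background subtraction — the reading under which a fixed global
   threshold is meaningful across sections with uneven illumination.
4. **Component labeling** at 8-connectivity by default (4 selectable),
   implemented over the pixel-adjacency graph. Components smaller than
   2 px are excluded.
5. **Centroids** are unweighted means of member-pixel coordinates,
   reported 0-based with pixel centers at integers (x = column,
   y = row).

Two monotonicity properties follow from the construction and are
enforced by tests: raising the intensity threshold or the minimum
component size never increases the number of detections.

## Atlas assignment and exclusion

Registration of sections to an atlas is outside this package; it
consumes the registered per-section label maps (integer region id per
pixel, 0 = outside the brain). A cell takes the label of the nearest
integer pixel to its centroid, with half-pixel ties broken toward the
lower index (`ceiling(v - 0.5)`), a deterministic convention that
matters only for centroids landing exactly on pixel boundaries. Cells
on label 0 are retained but flagged unassigned and excluded from every
denominator — off-atlas cells carry no regional information.

Section series often lose dorsal cortical tissue posteriorly during
preparation, so cells whose leaf region descends from the isocortex,
olfactory areas, hippocampal formation or cortical subplate are removed
when their section's anterior-posterior coordinate lies in the closed
interval [-4.7, -3.2] mm. The interval is treated as closed because no
endpoint convention is standard; the exclusion is idempotent.

## Ratios, fold changes, ANOVA

Counts alone are not comparable across animals (total yield varies), so
two ratio normalizations are used:

* **parent14** — parent-region count / animal's total assigned cells;
* **subdivided** — leaf count / the animal's total in that leaf's
  parent region. Within one animal these sum to 1 over each parent's
  leaves, an identity the tests verify exactly.

A third, **wholebrain** (leaf count / animal total), exists for
sensitivity analyses and the simulation harness (see below).

Fold change for a region and deprivation method is
`mean(SD ratio) / mean(ad-lib ratio)` over the animals of that method,
conventionally reported to 2 decimals. When either group mean is zero
the fold is reported as *not determined* rather than 0 or infinity — a
collapse to or from zero expression carries no meaningful ratio.

Per region, a fixed-effects 2x2 ANOVA `ratio ~ condition * method` is
fit on the per-animal ratios directly. Reproduction defaults: no
variance-stabilizing transform and no multiple-testing correction
(matching how such tables are conventionally reported); an arcsine or
logit transform and `p.adjust` methods are available behind flags. With
a balanced design the classical sequential decomposition is unique, and
the implementation (via `stats::lm`/`anova`) is checked against a
hand-coded cell-means sums-of-squares oracle to 1e-10. Designs with no
residual degrees of freedom are flagged rather than fit.

## Connectivity

Regions with zero counts in every animal of the dataset are removed
first; with the study-scale configuration (348 leaves, 54 silent) this
leaves 294 regions and hence 294 x 293 / 2 = 43,071 unordered pairs.
The 2x2 design collapses into two pooled groups per scheme (sum_ad_lib
vs sum_SD, or sum_chamber vs sum_hand). Within each group, Pearson
correlations of the subdivided ratio across animals are computed for
every region pair; a region with zero variance in a group yields
missing r, excluded from all pools. Correlations over four animals are
extremely noisy — the package warns below 10 animals, and all
calibration simulations run at larger n.

Leaf-pair correlations pool into the symmetric grid of parent-region
pairs. Cell (P, Q) collects every r with one endpoint under P and the
other under Q (the diagonal pools within-parent pairs); four summaries
are computed per cell: mean r, mean of positive r, mean of negative r,
and mean |r|. The signed mean says which sign dominates; the restricted
and absolute means capture strength — both views are reported because a
near-zero mean r can hide strong correlations of both signs.

Groupings are compared per cell with the two-sided two-sample
Kolmogorov-Smirnov test on the raw pooled r values. The p-value is
exact when both pools hold at most 10 values (pool sizes in the
parent-pair grid vary widely and the asymptotic p is unreliable at
single digits), asymptotic otherwise. No correction is applied across
the 105 cells by default.

## Synthetic data: what it emulates, and what not

`render_scene()` emulates the geometry of a full section series — 25
sections spanning AP +1.3 to -5.9 mm at 5 um pixels by default — at a
deliberately toy image size (160 x 120 px default; the full
2592 x 1944 camera frame is configurable). Each section holds an
elliptical "brain" tiled into contiguous leaf-region patches (a Voronoi
tessellation of in-mask seed points; cells of a Voronoi diagram
intersected with an ellipse are convex, hence connected). Cells are
Poisson draws per region and section, placed at least two spot
diameters apart and one spot radius from the border, and rendered as
hard disks of fixed peak intensity on a background of constant offset,
linear illumination gradient, and Gaussian noise. The hard-disk profile
(rather than a Gaussian PSF) makes the threshold and minimum-size
behavior exactly analyzable, which is what turns detection recall into
a sharp test rather than a statistical one.

`simulate_count_tables()` draws per-animal counts as
`Poisson(rate x effect^SD x exp(loading x z))` with a standard-normal
latent factor `z` per animal — a log-normal shared frailty. Default
base rates are heterogeneous (log-normal weights) and scale to an
expected 29,621 cells per animal, the scale of real whole-brain yields;
per-region absolute rates are otherwise unconstrained because published
tables report ratios, not counts.

What the generator does **not** emulate: anatomically realistic region
geometry, registration error, optical blur and overlapping cells,
section-to-section tissue loss, or non-Poisson overdispersion beyond
the shared frailty. Passing tests therefore demonstrate correctness of
the computational chain under its stated model, not robustness to
registration or segmentation failure on real tissue.

### An identifiability caveat

A latent factor loaded *uniformly* on all leaves of a parent multiplies
numerator and denominator of the within-parent ratio equally and
cancels exactly: uniform per-parent loadings are invisible to the
subdivided normalization. The connectivity-recovery simulation
therefore correlates whole-brain-normalized leaf ratios, where the
factor survives as long as the loaded regions are a small share of the
total. The pipeline default for connectivity remains the subdivided
normalization; the caveat matters when interpreting near-zero
within-parent mean r for parents whose subdivisions co-activate as a
block.

## Numerical choices

* Median filter borders: edge replication. Opening borders: element
  truncation. Both choices are frozen in the oracles.
* Centroid-to-pixel lookup: round-half-down per axis.
* Rendered images are rounded to integers and clipped to [0, 65535],
  mimicking camera counts; TIFF I/O scales 16-bit.
* Component labels are numbered by raster order of first appearance,
  making label matrices comparable across implementations.
* Zero-total animals, zero-variance regions, empty pools and zero
  residual df all propagate as missing values with warnings or flags,
  never as errors, except where the input is structurally invalid
  (unknown region ids, groups under 3 animals).

## Calibration and problem sizes

The simulation checks run at sizes chosen for statistical regularity,
not to mirror the two-animals-per-cell study design (which has almost
no power and degenerate correlation estimates):

* ANOVA null calibration: 1000 replicates at 5 animals per cell,
  2 parents x 2 leaves, 2000 expected cells per animal; the condition
  p-value of one target region per replicate is compared to
  Uniform(0, 1) and its rejection rate at 0.05 to the nominal level.
* KS null calibration: 1000 replicate pool pairs of sizes 8 and 10.
  These sizes were chosen from the exact null distribution
  (`stats::psmirnov`): the attainable significance level just below
  0.05 is 0.0499 there, so the discrete exact test is near-regular and
  the rejection rate is interpretable.
* Effect recovery: a 2-fold multiplicative effect on a leaf carrying
  ~1% of its parent, 50 animals per cell — the small share keeps the
  ratio denominator nearly unperturbed so the ratio fold estimates the
  generative effect with ~1% structural bias.
* Connectivity recovery: 100 simulations at 20 animals, loading 0.6 on
  the leaves of two parents whose rates are a small share of the total.

## Limitations

* The rolling-ball opening is exact but O(pixels x element size); at
  the full camera frame it is noticeably slower than approximate
  implementations. The toy default sizes keep full-pipeline runs in
  seconds.
* No watershed splitting: touching cells merge into one component (the
  generator's minimum-separation default avoids this by construction;
  an overlap mode exists for stress tests).
* With two animals per design cell, ANOVA power is low and group
  correlations are estimated from four animals; the package reproduces
  such analyses faithfully but warns, and its own validation runs at
  larger simulated n.
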