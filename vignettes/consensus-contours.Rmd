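---
title: "Consensus LV contours from multiple expert readers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus LV contours from multiple expert readers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvconsensus)
```

## The problem

Left-ventricular (LV) mass and volumes from short-axis cine cardiac MR are
computed from manually drawn endocardial and epicardial contours. Individual
expert readers are highly consistent with themselves, but different
laboratories train their readers to place contours systematically tighter or
looser, so the same images analyzed at different centers yield volumes that
differ by tens of millilitres. `lvconsensus` implements the analysis used to
quantify this situation: it fuses the contours of several readers into a
statistically optimal *consensus* contour per slice, derives LV functional
indices from every source, and measures each reader's agreement with the
panel.

## Consensus estimation: STAPLE

Each reader's contour on one slice (one surface, one cardiac frame) is
converted to a binary decision map $D_{ij} \in \{0,1\}$ (cell $i$ inside
reader $j$'s contour) on a grid supersampled 4x relative to the image pixels,
since hand-placed contours are drawn at sub-pixel resolution. The
Simultaneous Truth and Performance Level Estimation (STAPLE) model treats
the unknown true label $T_i$ as latent, and each reader as a classifier with
sensitivity $p_j = P(D_{ij}=1 \mid T_i=1)$ and specificity
$q_j = P(D_{ij}=0 \mid T_i=0)$. Expectation-maximization alternates:

* **E step** — the consensus probability
  $W_i = a_i / (a_i + b_i)$ with
  $a_i = \pi \prod_j p_j^{D_{ij}}(1-p_j)^{1-D_{ij}}$ and
  $b_i = (1-\pi) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}$,
  accumulated in log space;
* **M step** — $p_j = \sum_i W_i D_{ij} / \sum_i W_i$ and
  $q_j = \sum_i (1-W_i)(1-D_{ij}) / \sum_i (1-W_i)$,
  i.e. the consensus-weighted proportions of agreeing foreground and
  background cells.

Because $p_j$ and $q_j$ act as per-reader weights, the result is not a vote
count: a reader who is erratic is discounted everywhere, which is exactly
what distinguishes the method from pixel voting (the package's 6-plus-outlier
test fixture demonstrates the difference). The voting map initializes $W$,
and a consensus contour is generated for a slice only when at least four
readers contoured it.

### Numerical choices the model itself does not fix

The underlying description leaves the prior, the convergence rule, the
consensus binarization and the computation region open; the package fixes
them as follows (all configurable through `staple_params()`):

* **Region of interest.** EM runs only inside the union of the reader masks
  dilated by 5 mm. With an unbounded background the specificity of every
  reader saturates at 1 and stops discriminating; restricting to a band
  around the contours keeps $q_j$ informative. The dilation uses a separable
  square structuring element — only the amount of included background
  matters, not its shape. Cells outside the ROI get $W = 0$.
* **Prior.** A scalar $\pi$ fixed at the mean of the initial voting map over
  the ROI, not re-estimated during EM. Re-estimating a global mixing weight
  on strongly spatially structured data destabilizes the fit without
  benefit.
* **Convergence.** Mean absolute change in $W$ below $10^{-6}$, or 100
  iterations. The observed-data log-likelihood is tracked per iteration and
  tested to be non-decreasing (tolerance $10^{-9}$), the standard EM
  guarantee.
* **Clamping.** $p_j, q_j$ are clamped to $[10^{-6}, 1-10^{-6}]$ inside the
  E step so perfectly agreeing readers do not produce $\log 0$.
* **Consensus polygonization.** The consensus contour is the 0.5 level set
  of $W$, traced with marching-squares linear interpolation
  (`grDevices::contourLines`) on the zero-padded map; the largest-area
  closed contour is kept, yielding one deterministic polygon per slice.
  On a binary map this tracing is unbiased (the boundary runs midway
  between inside and outside cell centers).

Rasterization uses pixel-center containment with the even-odd rule and a
half-open scanline convention, so boundary-touching cell centers are
resolved deterministically and two polygons sharing an edge never double-count
a cell.

## Volumetrics

Volumes use slice summation: each contoured slice contributes its 2D cavity
area times the center-to-center inter-slice distance (the slice *spacing*,
not the thickness, where the two differ). There is no interpolation or
partial-slice correction for skipped slices — an omitted apical or basal
slice simply lowers the volume, and that bias is part of what the agreement
statistics are meant to expose. Mass is defined at end-diastole as
$\mathrm{LVM} = 1.05 \,\mathrm{g/ml} \times (V_{epi} - \mathrm{EDV})$, and
$\mathrm{EF} = 100 (\mathrm{EDV} - \mathrm{ESV}) / \mathrm{EDV}$. The
end-systolic frame is the one with the smallest endocardial area in a
mid-ventricular slice (ties to the earliest frame); in the pipeline the
frames are pre-labelled ED/ES, and `select_es_frame()` exposes the rule for
area curves.

Reader areas are computed from their polygons (shoelace formula); consensus
areas come from the supersampled raster, either the traced polygon (default)
or the thresholded-map cell count (`backend = "mask"`). The distinction is a
design decision, not something the method dictates: computing *both* sides
from raster areas makes the zero-noise identity of the pipeline exact, which
is how the identity test asserts exact zeros, while the polygon default is
what one would use on real reader polygons.

## Agreement statistics

For each functional index $F$ (EDV, ESV, LVM, EF), with $R$ readers and $N$
cases:

* inter-reader RMSE
  $E_i = \sqrt{\sum_{j\neq i}\sum_k (F_i(k)-F_j(k))^2 / (N(R-1))}$,
* consensus RMSE
  $E_C = \sqrt{\sum_j \sum_k (F_C(k)-F_j(k))^2 / (NR)}$,
* per-reader Bland-Altman bias (mean difference from the consensus),
  precision (sample SD of the differences, denominator $N-1$) and limits of
  agreement at bias $\pm 1.96$ SD,
* per-case consensus standard error
  $SE_k = \sqrt{\sum_j (F_j(k)-F_C(k))^2/R} / \sqrt{R}$.

The $N-1$ precision denominator and the 1.96 multiplier are the standard
Bland-Altman conventions; the $SE_k$ estimator (RMS reader deviation over
$\sqrt{R}$) is one defensible reading of "consensus $\pm$ standard error"
and is isolated in `consensus_se()` so it can be swapped. Complete
reader-by-case coverage is required rather than pairwise deletion.

A consensus is considered functionally acceptable when $E_C < \min_i E_i$
for every index — the consensus agrees with the panel better than any single
member does. When the consensus row is the per-case reader mean this holds
as a theorem ($E_i^2 = \frac{R}{R-1}\,\overline{(F_i-\bar F)^2 + V}$ while
$E_C^2 = \bar V$); for the STAPLE consensus it is an empirical property
verified in distribution on simulated cohorts.

## Reader reports

Per-reader, per-slice discrepancy reports give the distance from each reader
contour point to the consensus polyline (segment-wise, directed — matching
"points on the reader contour far from the consensus", not a symmetric
Hausdorff distance), flags at > 3 mm, and a cross-reader band: the min/max
boundary radius over all readers sampled on 72 equally spaced rays (5°
resolution) from the consensus centroid. The band construction is a
visualization decision; contours here are star-shaped about their centroid,
for which the outermost ray crossing is well defined. Rendered figures are
backed by a CSV of the same numbers so the report is testable without pixel
comparison.

## The synthetic cohort generator

No public multi-reader contour set accompanies the method, so the package
ships a generator whose defaults are the study conditions it emulates:
15 cases read by 7 readers; 10-15 short-axis slices of thickness 8 or 10 mm
(contiguous, so spacing equals thickness; thinner slices come in longer
stacks); square pixels of 1.1-2.1 mm; a 200 mm field of view.

**Truth model.** Each case is a stack of smooth closed curves: the
endocardial radius follows a truncated half-ellipsoid profile from apex to
base (apex radius floored at 3 mm so the cap stays contourable), the
epicardium is offset outward by a constant wall, end-systole contracts the
endocardium radially with slightly stronger contraction toward the apex, and
a case-level low-order angular irregularity (two cosine harmonics, up to 3%)
breaks rotational symmetry. Three phenotypes set the scale — healthy
(endocardial radius 25-29 mm, wall 5.5-7.5 mm, EF emerging in the 50-70%
band), dilated (radius 32-40 mm, thin wall, EF roughly 10-30%, covering the
infarct/heart-failure spectrum), hypertrophic (normal cavity, wall
9.5-12 mm) — and the default 5/8/2 mix puts cohort EDV roughly in the
100-380 ml range and mass roughly in the 70-195 g range, the spread reported
across real pathologies. True LV function is computed from the true contours
by the same slice summation as everything else, so a bias-free reader
reproduces it exactly.

**Reader model.** A reader displaces each true contour radially about its
centroid by a constant per-surface bias plus smooth zero-mean angular noise
(low-order cosine series — hand contouring wobbles coherently, not per
vertex; the two surfaces of a slice share 80% of their noise so the wall
stays positive), and occasionally omits the most apical or most basal slice,
where real readers disagree most. The default panel spreads endocardial
biases over ±2 mm (zero mean) with epicardial biases of the opposite sign
pattern — mimicking labs that draw tight blood pools but generous epicardial
borders and vice versa — 1 mm noise, and an 8% end-slice omission rate. At
typical LV perimeters 1 mm of radial bias moves EDV by roughly 10-16 ml, so
the panel produces volume biases of a few tens of millilitres, the
magnitude observed between real core laboratories. Sensitivity and
specificity are emergent, not dialled in.

**What the generator does not emulate:** pixel intensities and
contrast-dependent ambiguity, papillary and trabecular anatomy, the
outflow-tract region (real basal disagreement is structured, not radial),
long-axis motion of the base at ES, and non-star-shaped contours. Passing
tests therefore validate the statistical machinery — fusion, volumetrics,
agreement — under a controlled observation model; they do not certify
performance on real images.

**Seeds.** One cohort seed deterministically derives every per-case and
per-reader seed (recorded in a manifest), and simulation restores the
caller's RNG state, so cohorts are reproducible and side-effect free.

## Problem sizes used in the checks

The test-suite checks run at the sizes the analysis itself uses: single
slices of 80-180 pixels rasterized at 4x for fixture geometry; EM fixtures
of a few hundred to $10^4$ cells; rater-performance recovery with 7 readers
at sensitivity 0.95 / specificity 0.98 over $10^4$ cells and 10 seeds; and
20 full cohorts (15 cases x 7 readers) for the headline property that the
consensus agrees better with the panel than any reader, which is required to
hold in at least 18 of 20 cohorts. The zero-bias, zero-noise cohort is run
end-to-end and must leave every agreement statistic at exactly zero (with a
common area backend) and reproduce the true LV function bit-for-bit.

## Known limitations

* The consensus polygon is traced at supersampled-cell resolution, so
  consensus areas differ from reader polygon areas by discretization
  (well under 1% for realistic contour sizes at the default 4x factor).
* EM assumes readers are conditionally independent given the truth; real
  core-lab protocols are correlated, which a multi-reader simulation with
  shared biases only partially represents.
* The most-readers rule is the only missing-data mechanism; a slice with
  four readers' contours produces a consensus even if three disagree
  wildly.
* Contours are assumed star-shaped for the radial band display (not for the
  fusion or volumetrics, which are fully general).
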