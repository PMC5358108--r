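---
title: "Quantifying lamination in re-aggregated retinal organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lamination in re-aggregated retinal organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(laminatr)
```

## The measurement problem

Dissociated retinal progenitors re-aggregated in culture can re-form
organoids in which cell types arrange into concentric layers: in the
zebrafish "Spectrum of Fates" reporter system, Crx:gapCFP-positive
photoreceptor/bipolar cells gather at the centre, Ptf1a:cytGFP-positive
amacrine/horizontal cells form a ring around them, and Atoh7:gapRFP marks
a broad population throughout. `laminatr` turns a single multichannel
confocal section of such an aggregate into a scalar *lamination score*
that can be compared across experimental conditions.

The procedure is:

1. **Segmentation.** The aggregate outline is found on the DAPI channel
   with a Chan-Vese active contour followed by morphological clean-up
   (largest component, hole filling, opening), or supplied as a
   hand-drawn mask. The Chan-Vese model is region-based: it separates the
   image into a bright and a dark phase without relying on edges, which
   suits aggregates whose boundary intensity is irregular.
2. **Radial profiling.** Each in-mask pixel is assigned to a concentric
   band of width $w = 5$ px. By default bands are level sets
   (isocontours) of the Euclidean distance to the aggregate outline;
   binning by distance to the centroid ("circular crowns") is available
   as an alternative. The boundary-distance construction is preferred
   because it is robust to non-circular aggregate shapes: a ring of
   signal running parallel to the boundary of an elongated aggregate
   stays sharp in boundary-distance bands but smears across centroid
   bands (this is asserted as a test).
3. **Normalisation.** Band mean intensities per channel are rescaled onto
   a common axis of 0–100 *radial units* (ru; 0 = centre) and divided by
   their trapezoidal integral, giving a fluorescence density that is
   invariant to aggregate size, exposure and gain.
4. **ECDF and score.** The cumulative integral of the density is the
   ECDF curve $F(x)$; a spatially uniform channel gives the diagonal
   $F(x) = x/100$. The score is the trapezoidal area beneath the CFP
   curve minus that beneath the GFP curve: positive when CFP is more
   central than GFP, 0 for indistinguishable distributions, bounded by
   $\pm 100$.
5. **Cohorts.** Profiles are averaged over aggregates on a common
   101-point grid with an SEM (or SD) band, and scores of two conditions
   are compared with a two-tailed Mann–Whitney U test.

## A worked example

```{r example}
cfg <- synth_config(organization = 1, seed = 1)
agg <- simulate_aggregate(cfg)
mask <- segment_aggregate(agg$stack$DAPI)
mask

prof <- radial_profile(agg$stack, mask, w = 5)
ec <- profile_ecdf(normalize_profile(prof))
lamination_score(agg$stack, mask)
```

```{r plots, fig.show = "hold"}
autoplot(ec)
```

## The synthetic-data generator

No imaging data ships with the package, so a seeded generator
(`synth_config()`, `simulate_aggregate()`, `generate_cohort()`) provides
aggregates with known ground truth. It emulates:

- an aggregate whose boundary is a low-order perturbed circle
  ($r(\theta) = R(1 + \sum_{k=2}^{5} a_k \cos(k\theta + \varphi_k)$),
  $\sum_k |a_k|$ = `shape_perturbation`), connected and hole-free by
  construction;
- four reporter classes (CFP, GFP+RFP, RFP-only, CFP+RFP) whose radial
  zones reproduce the central-CFP / GFP-ring / RFP-everywhere order;
  the `organization` parameter $\lambda \in [0,1]$ is the probability a
  cell respects its zone rather than being placed uniformly, so
  $\lambda = 1$ is full lamination and $\lambda = 0$ no lamination;
- cells rendered as Gaussian blobs (sd = `cell_radius`/2) into the
  channels their class expresses, plus DAPI from every cell and a uniform
  in-mask DAPI fill for the unlabelled majority of nuclei;
- optionally a central non-fluorescent, DAPI-positive core mimicking a
  small cluster of pigmented RPE cells, and DAPI-visible debris blobs
  outside the boundary mimicking dead cells;
- Poisson shot noise followed by Gaussian read noise.

Default conditions (512×512 px frame, aggregate radius 120 px, zone radii
0.55/0.85, 60/60/40/60 cells per class, cell radius 6 px, amplitude 100
with ±30% per-cell brightness, background 5, Poisson scale 1, read-noise
sd 2, cohorts of 15) were fixed once to mimic the published geometry —
roughly circular aggregates a few hundred pixels across with one or two
hundred reporter-positive cells per section and per-condition cohorts of
15 — at a resolution where a full two-cohort analysis runs in a couple of
minutes on one CPU. All are overridable.

Per-stage and per-cohort-item seeds are derived from the master seed by a
single MINSTD congruential step, so any stage is individually
reproducible and cohort members are independent yet fully determined by
one integer.

What the generator deliberately does *not* reproduce: subcellular
morphology (membrane vs cytoplasmic label — band means cannot see it),
3D structure, rosettes, and — importantly — the biological
between-aggregate variability of real cohorts. Synthetic cohort members
differ only through sampling noise, giving score SDs of ~1.5 ru, whereas
published per-condition score spreads are visibly much larger. Passing
tests therefore demonstrate the pipeline's mathematics and robustness,
not that real cohorts of 15 would show the same p-values.

One consequence is worth stating plainly: with a non-fluorescent central
core enabled, blanking reporter signal in even a small core (default
0.12 of the aggregate radius, matching a small central RPE cluster)
removes the most central CFP mass and systematically lowers the score by
roughly 2 ru. Against the tight synthetic variance this small shift is
statistically detectable at $n = 15$, while in real data it is swamped
by biological variance. The package reports what it measures; the
corresponding cohort comparison in the test suite documents this
sensitivity rather than hiding it.

## Numerical choices

- **Distance transform**: exact Euclidean (EBImage), verified against an
  all-pairs brute-force oracle in the tests.
- **Band assignment**: `floor(d / w)`; the innermost partial band is
  retained (exact partition of the mask beats equal band purity), and a
  band's representative coordinate is its interval midpoint. Empty bands
  are dropped; downstream interpolation onto a common grid makes the
  gaps benign.
- **Axis direction**: radial coordinates are reported centre → periphery
  (0 = centre) in both modes, so central enrichment shifts curves left.
- **Endpoint extension**: profiles are extended to $x = 0$ and
  $x = 100$ by constant continuation before normalisation — this
  invents no gradients.
- **Averaging**: arithmetic mean per band; per-aggregate curves are
  linearly interpolated onto 0–100 ru at unit resolution for cohort
  means.
- **Mann–Whitney**: exact (full-enumeration distribution) when
  $n_1 + n_2 \le 25$ with no ties, otherwise the tie- and
  continuity-corrected normal approximation; both paths agree to
  < 0.01 at $n_1 = n_2 = 15$ and the exact path is calibrated under the
  null (both verified in tests).
- **Degenerate inputs**: blank or contrast-free images raise "no
  aggregate found"; all-zero channels and single-band profiles are
  rejected with the offending channel named; a band width exceeding the
  mask inradius yields a single-band result with a warning.
- **Score scale**: the area is reported in ru on the 0–100 axis (range
  ±100). Published scores are in arbitrary units, so only relative
  comparisons between conditions are meaningful, and the score is kept
  signed (CFP-central positive) rather than absolute.

## Segmentation parameters

`seg_params()` defaults: 200 iterations (with early stop on
convergence), one 3×3 binary-median smoothing pass per iteration, an
initial centred disk covering 25% of the frame, opening radius 2 px,
minimum area 100 px. The Chan-Vese literature leaves these free; these
values hold mask IoU ≥ 0.99 against ground truth across the documented
noise grid (`default_noise_grid()`: read-noise sd 0–5, shot noise
on/off) and are configuration-overridable. Manual masks (any two-valued
image) bypass the contour entirely and are the supported route for
excluding artefacts such as dead cells attached outside the aggregate;
z-stack handling is out of scope — the package analyses one central 2D
section per aggregate.

## Limitations

- Arbitrary-unit intensities: no background subtraction or flat-field
  correction is applied (profiles normalise units away, but structured
  background would bias curves).
- The synthetic emulation's variance caveat above: effect sizes and
  p-values transfer to real data only qualitatively.
- Single 2D sections; no selection of the central-most section from a
  stack.
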