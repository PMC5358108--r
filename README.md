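# laminatr

Quantifies laminar (layered) organisation in re-aggregated retinal
organoids from multichannel fluorescence micrographs. Re-aggregated
retinal progenitors can self-organise into concentric layers — a central
Crx:gapCFP-positive photoreceptor/bipolar population, a surrounding ring
of Ptf1a:cytGFP-positive amacrine/horizontal cells, and broadly
distributed Atoh7:gapRFP-positive cells. `laminatr` measures how strong
that layering is and compares it across experimental conditions.

## Method

For one aggregate section (channels CFP, GFP, RFP, DAPI):

1. **Mask** the aggregate on the DAPI channel with a Chan-Vese active
   contour plus morphological clean-up (`segment_aggregate()`), or load a
   hand-drawn mask (`load_mask()`).
2. **Profile** each channel as the mean intensity in concentric bands of
   width *w* = 5 px of the Euclidean distance to the aggregate outline
   (`radial_profile()`; centroid-based crowns available via
   `mode = "centroid"`).
3. **Normalise** the profile to unit integral on a 0–100 radial-unit (ru)
   axis (`normalize_profile()`), and accumulate it into an ECDF curve
   *F(x)* (`profile_ecdf()`); a spatially uniform channel gives the
   diagonal *F(x) = x/100*.
4. **Score** lamination as the trapezoidal area beneath the CFP curve
   minus that beneath the GFP curve (`lamination_score()`):

   score = ∫₀¹⁰⁰ F_CFP(x) dx − ∫₀¹⁰⁰ F_GFP(x) dx  (ru, range ±100)

   Positive when the CFP population sits more centrally than the GFP
   population; 0 when their radial distributions coincide.
5. **Compare** conditions: cohort mean profiles with an SEM band
   (`average_profiles()`) and a two-tailed Mann–Whitney U test on scores
   (`mann_whitney()`), exact for small tie-free samples.

A seeded synthetic generator (`synth_config()`, `simulate_aggregate()`,
`generate_cohort()`) produces aggregate images with known ground-truth
organisation (`organization` = λ ∈ [0, 1]) for validation; every stage is
tested against brute-force and closed-form oracles.

## Worked example

```r
library(laminatr)

agg  <- simulate_aggregate(synth_config(organization = 1, seed = 1))
mask <- segment_aggregate(agg$stack$DAPI)
mask
#> <aggregate mask> 512 x 512 px, area 45228 px, provenance: auto

lamination_score(agg$stack, mask)
#> # A tibble: 1 × 5
#>   area_CFP area_GFP area_RFP score mask_provenance
#>      <dbl>    <dbl>    <dbl> <dbl> <chr>
#> 1     69.3     38.7     57.6  30.5 auto
```

The CFP area (69.3 ru) is well above the uniform-distribution reference
of 50 (centrally enriched), the GFP area (38.7 ru) well below
(peripherally enriched), so the score of ~30 ru indicates strong
lamination; a disorganised aggregate (λ = 0) scores near 0. Plot methods
(`autoplot()` on profiles, ECDFs and cohort means) draw the profile and
ECDF figures, the latter with the dotted uniform diagonal.

Two cohorts are compared end to end with `run_pipeline()`:

```r
org <- lapply(generate_cohort(synth_config(organization = 1, seed = 11), 15), `[[`, "stack")
dis <- lapply(generate_cohort(synth_config(organization = 0, seed = 22), 15), `[[`, "stack")
run <- run_pipeline(c(org, dis), pipeline_config(),
                    groups = rep(c("organised", "disorganised"), each = 15))
run$test
#> Mann-Whitney two-tailed test: U = 225 (n1 = 15, n2 = 15), p = 3.392e-06 [normal approximation (tie/continuity corrected)]
```

A thin command-line wrapper with verbs `simulate`, `segment`, `score`,
`run` and `compare` is installed at `inst/cli/laminatr.R`.

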