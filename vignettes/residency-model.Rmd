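---
title: "The cohesin-residency loop model: assumptions, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cohesin-residency loop model: assumptions, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carloops)
```

## The model

`carloops` simulates a single yeast-like mitotic chromosome whose
folding is governed by one latent quantity per cohesin associated
region (CAR): the occupancy probability `p_i`, the chance that CAR *i*
carries stably bound cohesin in a given cell. Per cell, each CAR is
occupied independently with its `p_i`; loop-extruding cohesin halts at
occupied CARs, so a positioned loop forms between every pair of
*consecutive occupied* CARs — a loop spans k CAR intervals iff its two
endpoints are occupied and the k−1 intermediates are not. Under uniform
occupancy p this implies the truncated geometric span law
`P(k) ∝ p(1−p)^(k−1)`, which the test suite verifies both by exhaustive
enumeration of all 2^12 occupancy patterns at 12 CARs and by Monte
Carlo at 200 CARs.

Two loop-formation modes are provided. The default **consecutive** mode
is the endpoint rule above. The **extruder** mode loads a fixed number
of extruders per cell at uniform positions; each grows symmetrically,
each side halts permanently at the first occupied CAR it reaches, and
growth stops when the total extruded length reaches the processivity.
Anchors at occupied CARs are *positioned*; a side that exhausts its
budget leaves an *unpositioned* anchor at the coordinate reached. The
extruder mode exists because the Pds5-depletion phenotype — long loops
emanating from the centromere — requires one-sided, unpositioned
anchors that the endpoint rule cannot produce. Extruders do not collide
and are not impeded by unoccupied CARs; loading is uniform. All three
choices are conventions: the verbal model this package encodes is
silent on them.

Population maps are rendered as
`E(i,j) = background + Σ_loops freq ×
 [focal bell at the anchor pair + uniform boost over the loop interior]`,
with a softened power-law background `(s + s0)^−α` and Poisson count
sampling scaled to a total read count. Focal mass is confined by a
Gaussian of σ = 500 bp, so ~all of a spot sits within ±1 kb of its
anchors, matching the observed 1 kb confinement of anchors at CARs.

## Scenarios

Depletion phenotypes are occupancy transforms (plus one processivity
override), applied by `apply_scenario()`:

| scenario | transform | phenotype emulated |
|---|---|---|
| `WT` | identity | wild type |
| `MCD1` | all `p_i = 0` | cohesin core lost; no positioned loops |
| `BRN1` | identity | condensin lost; loops unaffected |
| `WPL1` | `p_i × 0.5` | cohesin at CARs halved; loops expand |
| `PDS5` | arms (>30 kb from centromere) × 0.05, pericentric × 0.7, centromere kept; extruder processivity × 10 | arm depletion; centromeric stripes |

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `spacing_median` | 8,000 | bp | observed median CAR spacing; spacings are log-normal, clipped to 3–40 kb (right-skewed like the real interval histogram) |
| `occupancy_shape` | 0.9·Beta(2.5,3) + 0.1·Beta(10,2) | — | mean ≈ 0.5 with a *separated* top decile, so high-residency CARs are a qualitatively distinct barrier class; a single Beta leaves the decile continuous with the bulk and washes out barrier/boundary contrasts |
| `peak_width` | 1,000 | bp | ChIP peak FWHM (~1 kb observed) |
| `alpha`, `s0` | 1.0, 1,000 | —, bp | yeast-like decay curve; no exponent is prescribed by the data this emulates, so it is config-exposed |
| `focal_weight`, `domain_weight` | 5,000, 15,000 | background-mass units | free parameters; set so WT adjacent-pair APA is ~4×, WT interval-series enrichment fades ~+5 and WPL1 ~+9/+10 |
| `total_reads` | 1e7 | counts | genome-wide Micro-C depth scaled to one 750 kb chromosome; shallower maps make single-pixel shot noise dominate the caller |
| `n_extruders` | chrom_length/30 kb | per cell | order-of-magnitude choice so WT extruder mode is adjacent-dominated |
| insulation `res`/`window` | 2,000 / 15,000 | bp | canonical kb-scale settings; the window rounds to 8 bins (16 kb) since 15/2 is not an integer |
| caller `min_dist`/`max_dist`/`fdr` | 5 kb / 100 kb / 0.1 | — | mirrors the published calling options and the manual >100 kb removal |

## Numerical and statistical choices

* **ICE balancing** is the symmetric fixed point `b ← b/√(rowsum)`;
  bins below the 2% nonzero-coverage quantile are masked (`NA`
  weights). Convergence is asserted to row-sum CV < 1e−6 in tests.
* **O/E** divides by per-diagonal means; empty diagonals are masked,
  never infinite.
* **Decay curves** report both a mass fraction (`prob`, sums to 1) and
  a probability density over distance (`density`). For matrix input the
  density uses the *per-locus-pair* mean at each distance, which removes
  the finite-chromosome edge effect; slopes are least-squares fits of
  log10 density vs log10 distance in sliding windows.
* **Loop caller**: donut-only local background (Chebyshev ring minus
  the same-row/column strips, summed-area tables for O(1) box sums).
  Significance requires clearing Benjamini–Hochberg at the given FDR on
  *two* Poisson tails — the 3×3 spot footprint and the centre pixel —
  against the donut-adjusted expected count; BH runs over every pixel
  of the distance band, since restricting the pool to
  already-enriched pixels biases the realised FDR (measured: ~70% junk
  calls under that reading). Adjacent significant pixels merge greedily
  to their strongest within `merge_radius`. There is no lower-left/
  horizontal/vertical multi-filter and no lambda-chunking — this is a
  deliberate simplification aimed at planted-truth synthetic maps, and
  its realised call-level precision at FDR 0.1 on noisy maps is ~0.9,
  not the ~1.0 it achieves noise-free.
* **Ties** everywhere (peak merging, high-residency classification)
  break toward the leftmost coordinate; all randomness flows from a
  single seed through fixed per-stage/per-cell offsets, so populations
  and pipelines are bit-reproducible.
* **Degenerate inputs**: empty populations render background-only maps
  (the Mcd1 scenario), flat tracks return empty peak sets, all-zero
  matrices refuse to balance, masked regions cannot host boundaries.

## What the generator emulates — and what it does not

The generator reproduces: CAR spacing and peak-width geometry,
occupancy-proportional ChIP peaks, focal anchor–anchor spots with
loop-domain squares on a distance-decay background, and the four
depletion phenotypes as occupancy transforms. It does **not** emulate
read-level artefacts (ligation orientation, mappability), replication
or sister-chromatid cohesion, extruder collisions, transcription-driven
cohesin-independent domains (CIDs), or real multi-chromosome genomes.
A green test therefore establishes that the *statistics* behave as the
model predicts on maps whose noise is Poisson counting noise — not that
the model fits any particular real dataset.

Two documented properties of the stated model world fall short of
idealised expectations and are left as failing assertions rather than
being tuned away. First, under the Pds5 transform the pericentric CARs
(occupancy × 0.7) intercept most extruders, so ~15% — not ≥90% — of
positioned anchors sit exactly at the centromeric CAR, and the
continuous stripe level in the centromere row is ~1.1–1.3× expected,
not >1.5×: concentrating ≥90% of anchors on a single CAR out of ~90
would require arm occupancies orders of magnitude below the stated
transform. Second, because every CAR blocks extrusion in proportion to
its occupancy, the insulation track dips at essentially every CAR; at
the default prominence threshold (0.1 log2 units) only ~a fifth of
called boundaries fall within 2 kb of a top-decile CAR — a 4–5×
enrichment over chance, in the observed direction, but far from
exclusive. Both analyses are implemented faithfully and the
corresponding tests state the idealised expectation.

## Known limitations

* Dense matrix storage: desk scale by design (a 750 kb chromosome at
  200 bp is a 3750² matrix); whole-genome maps are out of scope.
* The caller's Poisson rate uses the raw-count distance expectation,
  which assumes roughly uniform balancing weights — true for synthetic
  maps, not for real ones.
* `occupancy_from_adjacent_loops()` (√frequency) is exact only under
  locally uniform occupancy; with heterogeneous neighbours it estimates
  the geometric mean of adjacent occupancies.
* One chromosome per simulation; multi-chromosome studies are a loop
  over independent maps.
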