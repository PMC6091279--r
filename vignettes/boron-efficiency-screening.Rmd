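---
title: "Screening for boron-deficiency tolerance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for boron-deficiency tolerance: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boreff)
```

## The screening problem

Boron (B) is an essential micronutrient for vascular plants, and *Brassica
napus* (rapeseed) is among the crops most sensitive to its deficiency: on
low-B soils most genotypes arrest shoot meristem growth at the cotyledon
stage. Identifying the rare B-efficient genotypes — those that keep growing
with trace amounts of B — requires screening large accession panels under
controlled soil-B treatments (deficient B0, adequate B1, surplus B2) and
reducing several phenotyping streams to a small number of decisions:

1. an **efficiency index** per accession from endpoint measurements,
2. **growth dynamics** from daily top-view imaging,
3. **root elongation kinetics** from plate assays, and
4. **root system architecture** (RSA) from traced root scans.

`boreff` implements these analytics plus a seeded synthetic-data generator
that emulates the screen design, so every stage is exercised and validated
without access to the (unreleased) experimental images.

## The boron-efficiency index

For accession $i$, with condition means over at least $n_{\min}$ replicate
plants (default 10; 12 replicates is the default design),

$$\mathrm{BEI}_i \;=\; \frac{\overline{DW}_{B0,i}}{\overline{DW}_{B1,i}}
  \times \frac{\overline{L1}_{B0,i}}{\overline{L1}_{B1,i}},$$

where $DW$ is shoot dry weight and $L1$ the length of the first vegetative
leaf. The index is a **ratio of condition means**, never a mean of
per-plant ratios: the formula is defined on means, and replicates are not
paired across soil conditions. It is dimensionless and invariant to any
common rescaling of all weights or all lengths. An accession is
**B-efficient iff BEI ≥ 0.7** — the threshold is inclusive, following the
explicit classification rule; it is a `threshold` argument everywhere.
Indices above 1 are reported as-is (a deficiency-grown group can exceed
its control by noise); ranking ties are broken by accession id so output
order is deterministic.

## Imaging traits

The extractor starts from *segmented* images (binary masks, optional
RGB rasters); segmentation of raw photographs is out of scope. The default
feature set has 12 features in the three standard categories:

* biomass-related: `projected_area_px` (foreground pixel count — the
  validated biomass proxy) and `border_length_px`;
* architectural: convex-hull area, bounding height/width, and
  compactness = area / hull area ∈ (0, 1];
* colour-related: foreground means of hue, saturation, R, G, B (sRGB) and
  LAB lightness L (D65).

Two conventions deserve note. **Border length** is the count of foreground
pixels with a 4-neighbour in the background, with the image edge counting
as background — a deterministic inner-boundary definition of "pixels at
the border between foreground and background". It is a pixel *count*, not
a geometric perimeter estimate: for grid-aligned shapes it matches the
perimeter closely, while for curved shapes it is a consistently biased
perimeter estimator (≈ 11% low for disks) but scales linearly with shape
size, which is what matters for a biomass-related trait. **Convex hull**
vertices are pixel corners (each pixel is a unit square), so a filled
rectangle has hull area equal to its pixel count and compactness exactly 1.

HSV value is computed but not in the default set: V = max(R, G, B) is
nearly collinear with lightness, and keeping L covers the LAB space
explicitly; the feature set is configurable via the `features` argument of
`assemble_feature_table()`. Hue is averaged arithmetically in degrees,
which is adequate for the narrow hue range of plant foregrounds but would
wrap incorrectly for foregrounds straddling 0°/360° — a documented
limitation.

## Relative growth rate and arrest detection

The two-point RGR on projected area over a window $(t_1, t_2)$ is

$$\mathrm{RGR} = \frac{\ln A(t_2) - \ln A(t_1)}{t_2 - t_1}
  \quad [\mathrm{day}^{-1}],$$

with natural logs, the classical form for windowed growth analysis. The
default windows are early stress (4–7 DAS) and late stress (10–13 DAS).
RGR is computed per plant and then summarised per group (the distribution
across replicates is the object of interest; box-plot style reporting
needs per-plant values). Missing imaging days are linearly interpolated on
log-area for gaps of at most one day — daily imaging with occasional
misses is the design being supported — and longer gaps are errors rather
than silent extrapolations. The log form gives the exact chaining
identity: the RGR over a long window is the duration-weighted mean of the
RGRs over any partition of it, which the tests verify.

Growth arrest is detected as the earliest day $d$ whose forward-window RGR
over $(d, d+3)$ falls below $\varepsilon = 0.02\ \mathrm{day}^{-1}$. Both
constants are free operational choices, configurable and reported in
output: a healthy seedling's windowed RGR in this span is an order of
magnitude above $\varepsilon$, while an arrested plant's is ≈ 0, so the
call is insensitive to the exact value.

## Root cessation kinetics

In the plate assay, primary-root depth is marked at transfer and every
24 h for five days. The analysis is:

1. daily depth gain $g_t = d_t - d_{t-1}$ (cm/day), with a hard
   data-integrity error on decreasing depth;
2. the **slope coefficient**: the ordinary-least-squares slope of gain
   against day offset — the acceleration of root growth. The gain-vs-time
   curve is the "acceleration curve"; its slope is fitted per seedling and
   averaged (default), so unbalanced seedling counts cannot bias an
   accession; a pooled regression is available via `pooling = "pooled"`.
   The day 0→1 gain is included — marks start directly after transfer, and
   the immediate deceleration is part of the phenotype;
3. the cessation call: **cessation iff the deficient-condition slope is
   negative**; zero is assigned to non-cessation because only a negative
   acceleration constitutes cessation. The sufficient-condition slope is
   context only.

Seedlings contributing fewer than three gains are excluded with a log
(a line needs three points); the default design is 3 plates × 5 seedlings
= 15 per accession and condition.

## RSA metrics

From traced polylines (primary root plus first-order laterals — the clean
interchange point downstream of any tracing software), `trace_metrics()`
computes Euclidean arclengths and the five standard traits: PR length,
1LR count, total and average 1LR length, and 1LR density (count per cm
PR). Average lateral length is per-plant total/count and then averaged
across plants — a mean of ratios, which is why a group-level printed mean
need not equal total/count of the other printed means. With no laterals
the average is reported missing (`NA`), never 0. The summary table runs a
per-trait one-way ANOVA of each condition against the control condition
within each cultivar and stars cells with p < 0.05; cells with fewer than
two plants are flagged, never starred.

## Aggregation, PCA and treatment separation

`replicate_mean_matrix()` averages replicates for each cultivar ×
treatment × imaging day and trait. The default keeps day as a row key
(one row per cultivar × treatment × day — e.g. 13 cultivars × 3
treatments × 9 days = 351 rows); a day-expanded wide layout
(`day_handling = "columns"`) is available when one point per cultivar ×
treatment is wanted. PCA (`pca_traits()`) is a column-centred SVD,
z-scored by default because the traits mix pixel counts and colour means
on incommensurate scales; a constant column under standardisation is an
error naming the column. Loading signs follow a fixed convention (largest
magnitude element positive) so outputs are deterministic.

The treatment-separation score quantifies, per cultivar, how cleanly the
B treatments separate in PC space: the RMS spread of treatment centroids
around their grand centroid divided by the pooled within-treatment RMS
spread, on the chosen components (PC1 by default). Inefficient cultivars —
whose deficient plants collapse — score high; efficient cultivars cluster
and score low. The package deliberately does not claim to reproduce the
published variance percentages of the experimental PCA; those depend on
the unreleased images.

## The synthetic generator: what it emulates and what it does not

The generator reproduces the *design* of the screen and the *qualitative
phenotypes*, with recorded ground truth for every object:

* **Panel**: 234 spring + 356 winter accessions by default; hidden
  efficient class drawn per accession with probability 3/590 (the rarity
  observed in the screen), winter types always inefficient; 12 replicates
  per accession × treatment.
* **Endpoints**: multiplicative lognormal noise around class- and
  treatment-dependent means. Measurements are positive and right-skewed,
  so a lognormal keeps every invariant (positivity, DW ≤ FW) true by
  construction, and `noise_cv = 0` reproduces the means exactly — the
  anchor for the generator-oracle tests. Weight traits use
  `noise_cv = 0.15` (a realistic biological CV for shoot dry weight at
  this scale); linear traits use `noise_cv/3`, since mass scales roughly
  with the cube of linear size, making the CV of a length about a third
  that of a weight. The within-accession variance of the real screen is
  not published; these are the package's own defaults, stated once here.
  Class ratio defaults (efficient: DW 0.90, L1 0.95; inefficient: DW
  0.05, L1 0.08) place true BEIs near 0.86 and 0.004, matching the >90%
  biomass collapse of inefficient accessions; `ratio_jitter_sd` spreads
  true ratios across accessions for recovery studies (default 0 so the
  zero-noise limit is exact).
* **Growth series**: logistic area trajectories (rate 0.35/day,
  inflection 10 DAS, span 4–13 DAS); inefficient plants under deficiency
  freeze their area from 9 DAS onward — arrest as *freezing*, matching
  the arrested-meristem phenotype, without inventing senescence dynamics.
  Imaging noise (`area_noise_cv = 0.03`) models repeatability of a pixel
  count, which is far tighter than biological replicate scatter; plant-
  to-plant size differences enter through class/treatment scaling and
  cancel in RGR, as they do for real ratios of areas of the same plant.
* **Root depth**: constant gains under sufficiency; a linear ramp from
  the initial gain to zero by day 4 for inefficient seedlings under
  deficiency (deceleration within a day, complete cessation three days
  later); a small positive trend (+0.05 cm/day²) for efficient seedlings.
  Gains are noised multiplicatively (`gain_noise_cv = 0.10`), so depth is
  nondecreasing by construction.
* **Traces and rasters**: polylines with *exact* arclengths (unit-speed
  construction, rescaled), and analytic shapes rasterised by the
  pixel-centre rule (row-major grid, origin top-left, foreground iff the
  pixel centre is inside the shape) with recorded analytic area and
  perimeter.

What the generator does **not** emulate: soil chemistry and B transport
physiology, element or sugar concentrations (treated as opaque tables),
real leaf shapes and overlapping rosettes, segmentation errors, spatial
greenhouse effects, or genotype structure beyond the two-class model.
Passing the recovery suites therefore demonstrates that the *analytics*
are correct and well-calibrated against known truth at the study's design
sizes — not that the biological effect sizes of any real panel will match.

## Numerical and design choices

* Degenerate inputs fail loudly with classed errors: empty masks, zero
  reference means, decreasing depth marks, windows outside the data,
  constant columns under z-scoring. Nothing is silently zeroed or
  dropped; every exclusion (replication minima, short seedlings, skipped
  windows, dropped matrix rows) is returned alongside the results.
* All randomness flows from explicit seeds; the pipeline derives one
  stream per stage from the single config seed by hashing the stage name,
  so stages are individually reproducible and re-runs produce identical
  file digests (verified in the manifest).
* Compact letter displays for Bonferroni-adjusted pairwise comparisons
  use a small insert–absorb implementation on the pairwise p-value
  matrix.
* Default problem sizes in the recovery suites — 500 accessions for index
  and slope-sign recovery, 200 plants per class for arrest detection —
  are the package's validation scale: large enough that the reported
  rates have small Monte-Carlo error, small enough to run routinely.

## Worked demo

```{r demo, eval = FALSE}
out <- tempfile()
run_pipeline(system.file("extdata", "demo_config.yaml", package = "boreff"),
             out)
list.files(out)
```

## Known limitations

* Hue averaging is non-circular (see above).
* The border-length trait is a pixel count, not an unbiased perimeter
  estimator; comparisons should stay within one imaging setup.
* The arrest detector assumes approximately exponential healthy growth in
  the scanned span; at capacity saturation (beyond ~13 DAS at default
  parameters) the windowed RGR of healthy plants approaches the epsilon
  region and the default epsilon would need revisiting.
* The efficiency classification inherits the screen's endpoint-based
  definition; it does not model developmental-stage interactions.
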