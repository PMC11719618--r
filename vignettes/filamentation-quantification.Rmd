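---
title: "Quantifying whole-colony filamentation and its dose response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-colony filamentation and its dose response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamentr)
```

## The measurement problem

Nutrient-limited yeasts such as *Dekkera* (*Brettanomyces*) switch from
round budding growth to pseudohyphal, filamentous growth — a
density-regulated social behavior with practical consequences for
biofilm formation and beverage spoilage. On low-ammonium agar, a
filamenting colony photographed at low magnification looks like a bright
central mass with thin radial protrusions. The question the package
answers is: *how filamentous is this colony, as a number, and does that
number rise with the dose of a quorum-sensing compound such as
2-phenylethanol or tryptophol?*

The index used is the **f-measure** (in the whole-colony growth sense,
not the precision–recall score). Let `A_inner` be the area enclosed by
the boundary of the central colony mass and `A_outer` the area enclosed
by the boundary spanning every filamentous protrusion. Then

$$ f \;=\; \frac{A_\mathrm{outer} - A_\mathrm{inner}}{A_\mathrm{inner}} \;\ge\; 0 , $$

the relative area excess contributed by filaments: 0 for a perfectly
smooth colony, 2 when the protrusion-spanning boundary encloses three
times the central mass.

## The segmentation chain

`process_image()` composes six deterministic stages; every tunable lives
in `pipeline_config()`.

1. **Standardize** to 2560 × 1920 px (the reference acquisition
   resolution). Scaling preserves aspect ratio and pads with the
   estimated agar level; anisotropic stretch is never applied because it
   would bias the area *ratio* that defines f. Downscaling uses
   area-weighted (box) resampling and upscaling bilinear interpolation,
   so thin filaments are neither aliased away nor ringed.
2. **Grayscale** by the Rec. 601 luminance combination
   0.299 R + 0.587 G + 0.114 B, honoring the recorded channel order
   (BGR camera buffers are common; a silent swap corrupts thresholding).
3. **Gaussian blur** with a 5 × 5 kernel. The kernel's standard
   deviation is not dictated by the acquisition protocol; the default
   σ = 1.1 px is the value implied by common 5 × 5 defaults and is
   exposed as `gaussian_sigma`. Borders replicate edge pixels so mean
   intensity is preserved.
4. **Binarize** at a manual threshold, or automatically by Otsu's
   between-class-variance criterion (`threshold = "auto"`, the default
   so batch runs need no interaction). The chosen value is recorded on
   every record (`threshold_used`) because it is one of the two
   operator-dependent parameters of the original protocol. An empty or
   full-frame foreground raises a *segmentation failure* — the
   programmatic analogue of discarding an unusable photograph.
5. **Fill voids**: enclosed background pockets (filaments overlapping,
   or merging into the central mass) become foreground. Whether the
   original protocol capped the size of removed voids is not stated;
   both behaviors are supported via `max_void_px` (default: unlimited).
6. **Extract contours.** The outer boundary is the filled largest
   foreground component; `a_outer` is its pixel area. The derivation of
   the *inner* (central-mass) boundary from a single binary image is the
   one genuinely open design point; this package uses **morphological
   opening** with a disc of radius `opening_radius_px` (default 8 px at
   the standardized scale), which deterministically removes protrusions
   thinner than about twice the radius and is logged per run. Radius 0
   degenerates to inner = outer, f = 0. If a second component of
   comparable size is present (a neighboring colony), the largest is
   measured and the record is flagged for review.

With a physical pixel pitch (2.2 µm at 2.5× magnification for the
reference setup), areas are also reported in µm² via the squared pitch.

Contours are returned as 0-based (x, y) vertex chains. Their shoelace
areas agree with the filled pixel counts within 2 % at colony scale
(the discrepancy is a half-perimeter boundary term, so the bound holds
for colony-sized, convex-ish masks rather than for arbitrarily small
500-px shapes).

## Synthetic colonies: the validation substrate

No raw colony photographs are publicly deposited, so correctness is
established on rendered colonies with *exact* ground truth.
`colony_spec()` describes a filled disc plus straight radial spokes
(rectangles anchored on the disc boundary); `render_colony()` rasterizes
it with additive Gaussian pixel noise and returns `a_inner_true` (disc
pixel count), `a_outer_true` (filled union pixel count) and `f_true` by
exact pixel counting on the noiseless mask. Enclosed pockets between
spokes count toward the outer area only when fully surrounded by
foreground — deliberately congruent with the pipeline's void-filling
stage, so generator and analyzer share one definition of "outer area".

```{r render, eval = FALSE}
spec <- colony_spec(640, 480, inner_radius = 60,
                    filaments = radial_filaments(16, 80, 9),
                    noise_sd = 6, seed = 1)
rc <- render_colony(spec)
rc$truth$f_true
process_image(rc$image, pipeline_config(resolution = c(640, 480),
                                        opening_radius_px = 6))$f
```

What the generator emulates: bright colony on darker agar, thin radial
protrusions, additive sensor noise, 8-bit grayscale content replicated
into three channels. What it does **not** emulate: curved or branching
filaments, colony texture, uneven illumination, vignetting, focus blur,
agar artifacts, neighboring colonies. Passing the recovery tests
therefore demonstrates that the measurement chain is *internally
correct* (it recovers known geometry through noise, resolution changes
and thresholding), not that it is robust to every real-world artifact —
that is what the flagging/QC-overlay machinery is for.

Default rendering geometry (640 × 480, disc radius 60 px, sixteen 9-px
spokes) is chosen so spoke length can realize f up to ≈ 2.2, the top of
the observed assay range, while keeping per-image cost low enough that
the test suite renders dozens of colonies.

## Simulated f-measure samples

`dose_design()` + `simulate_fmeasures()` draw per-group values
moment-matched to target (mean, SD) pairs. The default family is
**lognormal**: f is nonnegative and, in the reference assays, group SDs
scale with group means — classic multiplicative behavior. Gamma and
left-truncated normal are provided as alternatives; the truncated
normal's attainable coefficient of variation is below 1, and infeasible
targets raise an error naming the group. A zero target SD yields
constant draws under any family. `dekkera_designs()` packages the
published post-exclusion (concentration, n, mean, SD) quadruples for
*D. anomalous* and *D. bruxellensis* under 2-phenylethanol and
tryptophol, so simulated panels carry the statistical structure of the
real assays. An optional contamination mechanism multiplies a fraction
`outlier_rate` of draws by `outlier_scale` to exercise the outlier
screen.

## Outlier screening

Group summaries replicate the robust screening convention: modified
z-scores $M_i = 0.6745\,(x_i - \tilde{x})/\mathrm{MAD}$ with values
$|M_i| > 3.5$ (strict) excluded, applied **per experimental group**
(strain × compound × concentration) in a **single pass**. When the MAD
is zero the scale falls back to $1.253314 \times$ the mean absolute
deviation about the median, the standard substitute that keeps $M$ an
estimate of $(x - \tilde{x})/\sigma$; all-identical groups score 0.
Groups with fewer than three raw values are summarized without
exclusion and flagged.

Single-pass screening is *not* an idempotent operation: removing tail
points shrinks the MAD, so a second pass may flag new points. This is a
property of the rule, not a defect. Simulation shows re-screening is a
no-op in ≈ 99 % of lognormal groups only at low dispersion
(σ_log ≈ 0.1, n = 100) and in only ≈ 65 % at the dispersion typical of
the filamentation assays (cv ≈ 0.6). An iterative mode
(`filter_outliers(..., iterate = TRUE)`) is available and always reaches
a fixed point; the single-pass default matches the published protocol.

## Nonparametric dose-response inference

Group distributions are skewed and unequal in size, so inference is
rank-based throughout, on pooled mid-ranks (ties share the average of
the ranks they span; the rank sum is exactly $N(N+1)/2$).

**Omnibus:** the tie-adjusted Kruskal–Wallis statistic

$$ H = \frac{\frac{12}{N(N+1)} \sum_i n_i\,(\bar R_i - \tfrac{N+1}{2})^2}
           {1 - \sum_t (t^3 - t)/(N^3 - N)} $$

referred to χ² with k − 1 degrees of freedom (df = 4 for the five-dose
0/10/50/100/200 µM design). All pooled values identical is degenerate
and errors. For small samples (N ≤ 10) `kruskal_wallis(exact = TRUE)`
replaces the asymptotic p with the exact permutation p by enumerating
all distinct group assignments.

**Post hoc:** Dunn's pairwise comparisons. For groups i, j:

$$ \mathrm{se}_{ij} = \sqrt{\Bigl(\tfrac{N(N+1)}{12} -
      \tfrac{\sum_t (t^3-t)}{12(N-1)}\Bigr)\Bigl(\tfrac{1}{n_i}+\tfrac{1}{n_j}\Bigr)},
   \qquad z_{ij} = \frac{\bar R_i - \bar R_j}{\mathrm{se}_{ij}} , $$

with two-sided standard-normal p-values and Bonferroni adjustment
$p_\mathrm{adj} = \min(1, m\,p)$, $m = k(k-1)/2 = 10$ for five doses.
Rows are ordered lower concentration first, so a dose that raises the
response produces a negative rank-mean difference. Bonferroni is the
default because it is the convention of the reference tables; Holm is
available (`adjust = "holm"`) for users who find plain Bonferroni too
conservative. On near-continuous f-measures the tie terms vanish below
3-decimal resolution, which is why the no-tie closed form
(`dunn_se()`) reproduces published standard-error columns exactly.

`dose_response_report()` composes the chain — within-group screening,
omnibus test, pairwise table — per strain × compound panel, and the
report layer formats p-values only at output time (full precision is
kept internally; a printed "0.000" is a formatting artifact, not a
stored value).

## Numerical and design choices

| parameter | default | units | rationale |
|---|---|---|---|
| `resolution` | 2560 × 1920 | px | reference acquisition resolution |
| `gaussian_kernel` | 5 | px | protocol-specified kernel size |
| `gaussian_sigma` | 1.1 | px | implied default for a 5 × 5 kernel; exposed |
| `threshold` | `"auto"` (Otsu) | intensity | unattended batch runs; logged per image |
| `max_void_px` | unlimited | px² | protocol does not state a cap; cap supported |
| `opening_radius_px` | 8 | px | removes protrusions < ~16 px wide at standardized scale |
| `pixel_pitch_um` | unset | µm/px | 2.2 for the reference 2.5× setup |
| z threshold | 3.5 (strict) | — | robust-screening convention |
| `adjust` | Bonferroni | — | reference-table convention; Holm optional |

Tie-breaking and degenerate inputs: zero-length filaments add no area;
opening radius 0 gives f = 0 by construction; all-identical statistical
groups are degenerate for ranking and error out; empty/full-frame
masks are segmentation failures; a vanished colony after opening is an
error instructing a smaller radius.

Problem sizes in the shipped tests and acceptance script are chosen as
the package's own validation scale: colonies are rendered at 640 × 480
or smaller (where the full 2560 × 1920 standardization path is still
exercised by upscaling tests), recovery uses 20 colonies spanning
f_true 0.1–2.0, the omnibus calibration uses 1000 null replicates at
the published group sizes, and the qualitative dose-response check uses
100 replicate panel simulations.

## Known limitations

- The inner-mass contour depends on `opening_radius_px`; colonies whose
  central mass is itself thin or highly concave need a manually chosen
  radius, and the exact numeric f is radius-dependent (the dose-response
  *ordering* is much less so).
- Exact reproduction of the original per-colony f values is impossible
  without the raw photographs and the per-plate manual thresholds,
  which were never published; the package instead reproduces every
  closed-form quantity of the published pairwise tables and the
  qualitative dose–response conclusions under simulation.
- The generator's straight spokes do not probe curvature- or
  branching-related failure modes.
- Single-pass outlier screening is order-zero idempotent only at low
  dispersion (see above); this mirrors the published protocol rather
  than a statistical optimum.
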