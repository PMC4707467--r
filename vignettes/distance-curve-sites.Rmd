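---
title: "Predicting ncRNA functional sites from distance-curve extrema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ncRNA functional sites from distance-curve extrema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasites)
```

## The model

Geometric analysis of protein structures found functional residues both at
the surface (far from the centroid) and buried in pockets (unusually close
to it) — in either case, at *extreme points* of a residue-location signal.
This package applies the same idea to noncoding RNAs, with one substitution
that makes it broadly applicable: the nucleotide coordinates come from the
**secondary-structure drawing** rather than the 3D fold. That substitution
is defensible because the two location signals are strongly rank-correlated
across solved RNA structures, and it matters because reliable secondary
structure is obtainable for essentially any RNA while tertiary structure is
not.

Given per-nucleotide coordinates $p_1,\dots,p_n$ the location metrics are

$$\mathrm{NDC}(i) = \lVert p_i - \tfrac1n\textstyle\sum_j p_j\rVert,
\qquad
\mathrm{NDS}(i) = \sum_{j \ne i} \lVert p_i - p_j \rVert .$$

Both are non-negative, rigid-motion invariant, and monotone in "outerness":
the outermost nucleotide of a molecule has the largest value, the innermost
the smallest. NDC is the default; NDS weights the whole mass distribution
and is exposed as an alternative (`metric = "nds"`).

The pipeline is then

1. smooth $D(1..n)$ with a truncated Gaussian kernel,
2. find the local maxima **and** minima of the smoothed curve,
3. chain extrema no more than `merge_gap` nucleotides apart into one
   predicted site interval.

Nucleotides at NDC maxima sit at hairpin-loop apices and chain termini
(exposed, often interaction surfaces — anticodons, acceptor ends);
nucleotides at minima sit at multiloop junctions (buried, often catalytic
cores or protein-clamped regions). Both are reported because both kinds of
location are biologically meaningful, and the published evaluations need
hits on loop apices *and* junction nucleotides.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `sigma` | 2.0 | nt | Smoothing scale of the Gaussian filter. The source method states a Gaussian filter without printing its width; 2 nt suppresses single-nucleotide drawing noise while a tRNA-scale (76 nt) molecule retains ~10 extrema, the granularity at which published site tables operate. |
| `truncation` | 4.0 | sigmas | Kernel half-width `ceiling(truncation * sigma)`; beyond 4σ the weights are < 3.4e-4 of the peak. |
| `boundary` | `"reflect"` | — | Edge handling by index reflection with the edge repeated; `"nearest"` (clamping) is offered. Reflection avoids the spurious edge drift clamping causes on trending curves. |
| `include_endpoints` | `TRUE` | — | Positions 1 and n are eligible one-sided extrema. Published hit tables list position 1 as a predicted site, which is only reachable if curve ends are eligible. |
| `merge_gap` | 2 | nt | Successive extrema ≤ 2 nt apart (compared pairwise, so chains merge) become one site, regardless of RNA length. |
| `backbone_spacing` / `pair_span` | 1 / 2 | drawing units | Radiate-layout bond lengths. Only their ratio matters downstream: the metrics are rigid-motion invariant and the correlation analysis is rank-based, hence scale-free. |
| `tolerance` | 0 | nt | Slack added to known intervals before overlap testing. Zero reproduces the published tables (every printed hit falls strictly inside its interval); footprint-style evaluations may widen it. |
| `representative` | `"mean"` | — | PDB per-residue point: all-heavy-atom mean by default (no atom is named by the method's description); `"c1prime"` for sensitivity analysis. |

## Conventions and numerical choices

**Positions** are 1-based, intervals inclusive at both ends ("13–22"
contains 10 nucleotides).

**Plateaus.** Runs of exactly equal smoothed values are collapsed before
extremum classification; an interior plateau flanked by strictly smaller
(larger) values on both sides is one maximum (minimum), represented by its
midpoint, taking the lower of the two middles for even runs. This is
deterministic and symmetric, so reversing a curve reverses its extrema.

**Extrema alternate** between maxima and minima after plateau collapsing —
a property the test suite asserts on random integer curves, where plateaus
and ties are frequent.

**`sigma = 0`** skips filtering but still marks the curve smoothed, so
running the detector on a raw curve is an explicit user decision, never an
accident of the pipeline.

**Site peaks.** A merged site's `peak_position` is the member whose
smoothed value deviates most from the curve mean (a site can contain a
maximum only, a minimum only, or — after heavy merging — both kinds of
member; deviation from the mean ranks them on a common scale). Ties break
toward the smaller index.

**Undefined ratios.** PPV with zero predictions and sensitivity with zero
known intervals are flagged undefined rather than reported as 0 or 1;
pooling across molecules sums counts (`Σ hits / Σ predictions`), never
averages percentages. Integer percents round half up (6/7 → 86).

**Spearman p-values** use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ degrees of freedom. For
$|\rho| = 1$, and whenever the approximation underflows, the p-value is
floored at the smallest positive double instead of printing a literal 0.

**q-values.** Storey's estimator is reimplemented: $\hat\pi_0(\lambda)$ on
the grid $\lambda = 0.05, \dots, 0.95$, stabilized by a smoothing spline
evaluated at $\lambda = 0.95$ and clipped into $[1/m, 1]$. Batches smaller
than 100 fall back to Benjamini–Hochberg ($\pi_0 = 1$): with few p-values
the $\pi_0$ estimate is dominated by noise, and BH is conservative in the
direction that matters for the coarse thresholds (q < 0.01, q < 1e-5) the
analysis uses.

**Pooled correlation** concatenates raw distances across molecules of
different sizes and units. This is deliberate — it mirrors how the pooled
2D/3D scatter is constructed — but it means the pooled ρ is *not* any
average of per-molecule ρ: two molecules each with ρ = 1 but different
scales pool to ρ < 1 (the suite keeps a counterexample so nobody
"optimizes" this away). A per-molecule z-scored pooling is available
behind `zscore = TRUE`.

## The layout engine

When no drawing coordinates are supplied (the bit-exact path is the
PostScript `/coor` reader), `layout_radiate()` produces them from the
nested pair set:

* the exterior loop runs along the +x axis from the origin, consecutive
  backbone neighbours `backbone_spacing` apart;
* helices are parallel ladders, partners `pair_span` apart, consecutive
  pairs `backbone_spacing` apart, axis continuing the bisector of the
  entering direction;
* every loop is drawn on a circle. The radius solves the inscribed-polygon
  equation $\sum_k 2\arcsin(c_k / 2r) = 2\pi$ where the chords $c_k$ are
  `backbone_spacing` between loop members and `pair_span` across each pair
  (closing and children). Chord lengths are therefore exact wherever the
  polygon can close; for degenerate micro-loops where it cannot, the
  radius is the minimum feasible one and the remaining members get angles
  proportional to their chords. In both cases all loop members — including
  the closing pair's two ends, which keep their helix-assigned positions —
  lie on one circle.

This differs from "equal angular spacing of all members" in that the pair
chords subtend wider angles than backbone chords; the exact-chord variant
was chosen so the backbone step length is a single global constant, which
makes layout properties testable by construction. The engine does not
attempt overlap-free aesthetics (NAVIEW-style untangling) and does not
reproduce any external program's coordinates — downstream quantities are
invariant to rigid motion and, for the correlation analysis, to scale.

**Pseudoknots** (`[] {} <>` families, and any crossing pair) are parsed and
retained but refused by the layout with an explicit error; `predict_sites()`
strips them with a warning. A planar drawing cannot represent crossing
helices faithfully, and known pseudoknotted cases are a documented failure
mode of 2D-derived curves (predicted-structure input can even flip the
2D–3D correlation sign).

## Synthetic data: what it emulates, what it does not

* `make_structure()` produces idealized topologies — hairpins, a 76-nt
  tRNA-like cloverleaf (acceptor stem 7 bp, three arms, variable loop,
  NCCA-length tail), unpaired chains. Real structures have bulges,
  internal loops and non-canonical pairs; none of that changes which code
  paths run, only the drawing's shape.
* `make_planted_curve()` builds a constant baseline plus Gaussian lobes
  with *known* extremum positions. Lobe signs must alternate: two adjacent
  same-sign lobes would mathematically create a third extremum between
  them, making "recovered exactly the planted extrema" unachievable by
  construction rather than by implementation error. Real distance curves
  are not sums of clean Gaussians; the generator tests the
  smoothing/detection/merging chain, not biological realism.
* `make_toy_pdb()` writes one C1' atom per residue along an A-form-like
  helix (radius 9.4 Å, twist 32.7°, rise 2.8 Å), optionally with a second
  chain or hydrogen-only residues to exercise the exclusion filters. It is
  a file-format and filter fixture, not a model of RNA 3D structure.

A green test on these fixtures establishes that the arithmetic chain is
correct and deterministic; it does *not* establish predictive accuracy on
real molecules, which in this package is represented only by the shipped
literature-derived site tables (tRNA(Lys) 6/7 at 86%, Diels-Alder ribozyme
3/3, RNase P 13/17 at 76%).

## Known limitations

* Pseudoknots are excluded from layout; predictions for heavily
  pseudoknotted RNAs reflect the nested sub-structure only.
* Sites carry no significance or score beyond the peak value; ranking,
  conservation features and statistical testing are out of scope.
* The molecule filters replicate the published screening rules (single
  chain, length > 20 nt, complete coordinates, all four bases present);
  "no longer than 20 nt" excludes molecules of exactly 20.
* The full-scale correlation study over public PDB/NDB cohorts requires
  external downloads and is intentionally not part of the package or its
  tests; `run_correlation_batch()` implements the analysis for any batch a
  user assembles (the `correlate` CLI subcommand takes a manifest of
  PostScript/PDB file pairs).
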