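---
title: "Quantifying branching morphogenesis with branchmorph: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying branching morphogenesis with branchmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchmorph)
```

## The problem

Branching epithelia (the embryonic mammary gland is the motivating system)
elongate their terminal branches and split their tips by clefting. Two-colour
nuclear cell-cycle reporters (Fucci-type: green nuclei in S/G2/M, red in
G1/G0) imaged in 3D and in time-lapse make it possible to ask *where* cells
proliferate, *how* they move, and what changes when a tip bifurcates.
`branchmorph` turns such stacks — or tables of detected nuclei — into the
quantities this line of work reports: spatial cell-cycle fractions, distance
profiles, track kinematics and flows, directional statistics, and tip/cleft
morphometrics.

All positions are physical micrometers; times are minutes (frame interval)
and hours (rates). Arrays are `(x, y, z)`-ordered with voxel `(i, j, k)`
centered at `origin + (c(i, j, k) - 0.5) * voxel_size`.

## The analysis model, stage by stage

**Detection.** Nuclei are found with scale-matched Laplacian-of-Gaussian blob
detection: the blob scale is `sigma = diameter / (2 * sqrt(3))`, applied with
per-axis sigmas in voxel units so anisotropic stacks (e.g. 0.7 µm xy, 2 µm z)
need no prior resampling. Local 26-neighbourhood maxima are thresholded —
`"auto"` applies Otsu's criterion to the positive blob-response distribution,
standing in for the interactive per-image thresholds of commercial tools, and
is always overridable — then greedily suppressed at a minimum separation of
`diameter * separation_factor`. The default `separation_factor = 0.75` keeps
spots slightly smaller than nuclei so touching neighbours stay resolved. The
conventional diameters are 6 µm (red/G1-G0) and 7 µm (green/S-G2-M). Where a
green and a red spot claim the same locus, the higher normalized response
wins; exact ties go to green (the rarer class in ducts). This is logged in
the spot table, not silent.

**Geometry.** The epithelial mask is built as the union of balls around
nuclear positions followed by morphological closing; `closing_radius`
defaults to 7 µm (one nuclear diameter) so the mask has no spurious holes
between neighbouring nuclei. Two distance fields anchor all spatial labels:

* surface distance — by default the *exact* Euclidean transform (distance to
  the nearest background voxel center); the `<3,4,5>` chamfer approximation
  is retained as an option to mirror classical morphology toolboxes, with a
  documented maximum relative error of 8%;
* geodesic distance — Dijkstra on the 26-connected voxel graph with
  Euclidean edge weights (6-connectivity is available), seeded at a landmark
  and confined to the mask.

Fields are sampled at cell positions by trilinear interpolation; corners in
background are dropped with weight renormalization so cells hugging the mask
border still get a value. Cells are *basal* when the surface distance is at
most 6 µm (the peak of the nuclear-depth distribution sits at 4–5 µm, so
6 µm captures the outermost layer), *inner* otherwise. Domains pool cells at
landmark-anchored distances: tips within 100 µm of the leading edge, ducts
and branch points within 50–100 µm of their annotated centers (wider for
thicker branches), with precedence tip > branch point > duct. In bifurcating
tips, tip cells split into daughter-tip versus cleft-region by whichever
landmark is nearer; exact ties go to the daughter tip. Landmark placement
(duct centers, cleft, T0) is deliberately an *input*: the source workflow
placed these by eye, and inferring them automatically would silently change
the science.

**Tracking.** Spots are linked frame-to-frame within their cycle class only,
with hard per-class caps on step length — 8 µm (red) and 9.3 µm (green) —
no gap closing, and tracks shorter than 2 h discarded (and counted). The
assignment minimizes the total linked distance, with an unlinked spot
costing one cap; the bipartite candidate graph is decomposed into connected
components, each solved exactly by branch-and-bound (components above
`exact_limit = 12` spots fall back to distance-sorted greedy, and a pure
greedy mode exists for speed). Under the caps this reduces to
near-nearest-neighbour linking, which is what makes the exact solver
affordable. Velocity is path length over duration, net velocity is
displacement over duration, and straightness is their ratio. For
bifurcations, velocity comparisons between the branch point and the daughter
tips are made on the post-T0 segments of the tracks (`metrics_post_t0`),
because whole-track averages dilute a stage-specific slowdown.

**Directional statistics.** Displacement vectors are compared with a
reference vector — the leading-edge displacement for elongating branches,
the neck-to-cleft line for bifurcations — as signed planar angles in
[0, 360) (sign from the cross-product z-component, i.e. left- versus
right-sided movement), optionally folded to [0, 180] with 0 = parallel and
180 = antiparallel. Uniformity is tested with the Rayleigh test using the
small-sample-corrected exponential p approximation; folded (axial) samples
are doubled before testing, the standard axial-data correction (the naive
linear treatment is available for comparison). Homogeneity of two angle
samples uses Watson's two-sample U² from the pooled-rank formulation with
midrank ties; the default p-value is by random-relabeling permutation, which
is preferable to the asymptotic series at the sample sizes tips yield.

**Group comparisons.** `compare_groups()` implements the canonical decision
tree: Shapiro–Wilk on each group (on the differences when paired); any
normality p below the gate (0.05 by default, exposed) routes to Wilcoxon
(signed-rank when paired); otherwise a Levene gate (median-centered by
default, i.e. Brown–Forsythe; the variant is exposed because the source
procedure does not state it) chooses Student's versus Welch's t.
Bonferroni correction multiplies by the declared family size and caps at 1.
Constant samples cannot be Shapiro-tested and are routed nonparametric, with
the decision logged. The decision log is part of the result object: the
chosen test is always re-derivable from it.

**Morphometrics.** Tip and neck widths are maximal chords perpendicular to
the branch axis on 2D maximum projections (the projection axis is
configurable, default z), matching the line-tool measurements the field
uses. Cleft angle is the angle at the cleft landmark between the vectors to
the two daughter tips; cleft depth is the perpendicular distance from the
cleft to the tip-to-tip chord; a cleft on the chord gives 0 µm and 180° — a
boundary case, not an error. Branch length is the within-mask geodesic
between the tip and the latest branch point. Sphericity uses the standard
isoperimetric definition `pi^(1/3) (6V)^(2/3) / A`, adopted because the
commercial tool's formula is undocumented.

## The synthetic world

Because no raw microscopy is deposited with this line of work, every stage
is validated against a ground-truthed generator
(`generate_elongation_scenario()`, `generate_bifurcation_scenario()`,
`render_stack()`). The generator states a world; it is not a tuning knob:

* **Geometry.** A branch is a cylinder (radius 25 µm) with a spherical tip
  cap, advancing along its axis. A bifurcation widens the cap (factor 1.5
  over 6 frames), then from T0 grows two daughter capsules separated by
  `daughter_angle` (70°) while a cleft landmark ingresses along the axis at
  `cleft_speed` (10 µm/h).
* **Motility.** Agents move at
  `speed_at_edge * exp(-d / speed_decay_length)` where `d` is the distance
  to the advancing front, with von Mises headings about the local axis
  (kappa = 2), small out-of-plane jitter, and mean-preserving lognormal
  per-step speed dispersion (`speed_noise = 0.25`, clamped at the edge
  speed). The dispersion matters: real track speeds have a large coefficient
  of variation, and a noise-free world makes arbitrarily small numerical
  artifacts statistically "significant". The source work reports no
  quantitative speeds; the defaults — 20 µm/h at the edge, 50 µm decay —
  give leading-front advance of tens of µm over a 10 h movie, the regime the
  tool targets, and are exposed, never hard-coded downstream.
* **Front kinematics.** The mask front advances at the mean intended axial
  displacement of the cohort within 10 µm of the edge (widened to 30 µm,
  else stalled, when empty): the front is made of nuclei and cannot outrun
  them. A consequence adopted deliberately: the measured elongation rate is
  compared against the generator's *true front displacement*, not against
  `speed_at_edge` (heading dispersion makes the realized axial speed lower).
* **Containment.** Agents whose step would exit the epithelium re-draw
  their heading at the same speed (up to 10 attempts) and are reflected as a
  last resort, so realized step speeds equal the nominal law and every cell
  sits strictly inside the rasterized mask (the sampling margin is half a
  mask-voxel diagonal).
* **Cell cycle.** Class is drawn per agent from the positional probability
  (tip 0.5, duct 0.15 by default — qualitative magnitudes from the imaging
  this emulates). In bifurcations the label tracks branch-point membership:
  it is re-drawn with the repressed probability
  (`base x branchpoint_cycle_factor`) when an agent enters the cleft-proximal
  region and with the base probability when it leaves. A strictly fixed
  label cannot realize the configured region-level repression once agents
  cross region boundaries (we measured post-T0 ratios of 0.4–0.9 instead of
  0.3 with a one-time re-draw); piecewise-constant labels with boundary
  re-draws keep the region fractions at the configured factor without
  modelling reporter kinetics.
* **Post-T0 speeds.** Within the bifurcating tip the base speed is uniform
  (`speed_at_edge * exp(-tip_radius / decay)`), so the *only* branch-point
  versus daughter-tip speed contrast is `branchpoint_speed_factor`; with
  null factors the two groups are exchangeable by construction. The
  trailing duct keeps the distance gradient. Any spatial gradient inside
  the tip would otherwise masquerade as branch-point slowdown.
* **Imaging.** `render_stack()` draws each nucleus as a Gaussian blob
  (sigma 2.5 µm) in the channel of its class on an anisotropic grid
  (0.7 µm xy, 2 µm z — the resolution regime of the live imaging this
  emulates), adds Poisson photon noise and Gaussian read noise, and
  quantizes to 8 or 16 bits.

What the generator does *not* emulate — and hence what a green test does not
establish: optical blur anisotropy (PSF tails), photobleaching and the
associated cycle-activity decline in long movies, nuclear shape variation
and touching-nucleus merging, mitotic reporter loss, basement membrane or
mesenchyme signal, and mechanical interactions (tip advance is kinematic;
no force model is stated by the source work). Detection recall measured on
renders is therefore an upper bound on real-data recall.

## Numerical choices and degenerate inputs

* Distance fields: exact EDT by default; chamfer kept as an option with its
  8% error bound tested. Geodesics use 26-connectivity (smoother metric;
  6-connectivity available). Background seeds snap to the nearest
  foreground voxel within `snap_radius`, else error.
* Interpolation: trilinear with NA-corner renormalization; cells fully
  outside the mask become `unassigned` with a warning, never dropped
  silently.
* `cycle_fraction()` keeps empty groups with `NA` fractions; ratios with
  fewer than `min_cells = 10` per region are flagged `reliable = FALSE`
  (ratios of tiny counts are unstable; the source states no floor, so the
  floor is exposed).
* Ties: keratin dominance ties go to K8; daughter-tip/cleft ties to the
  daughter tip; co-detected green/red spots to green. All documented at the
  call sites.
* The linker objective charges one cap per unlinked spot; with hard caps
  this maximizes links first in practice and is oracle-tested against
  exhaustive enumeration.
* `normalize_contrast()` returns constant images unchanged; the saturated
  fraction is split evenly between tails.
* Rayleigh p is clamped to [0, 1] (the corrected series can stray at
  extreme concentration); Watson's asymptotic series is truncated at 25
  terms (machine precision for U² > 0.02).

## Known limitations

* Landmarks (duct/branch-point centers, cleft, T0) are annotations; the
  package does not infer them, by design.
* No lineage reconstruction across division or reporter colour switching,
  no gap closing, no learned segmentation or denoising; a denoising step
  can be applied upstream since detection accepts arbitrary stacks.
* TIFF/OME-TIFF I/O is not provided in this build because no TIFF reader is
  available in the supported dependency set; stacks are in-memory arrays
  with voxel metadata, and all tabular interfaces are CSV/JSON.
* The synthetic bifurcation freezes the parent branch after T0 and does not
  carve the cleft out of the mask volume; cleft geometry lives in the
  landmark series, which is what the morphometric operations consume.
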