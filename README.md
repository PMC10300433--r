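# branchmorph

Quantification of epithelial branching morphogenesis from 3D and 4D
fluorescence microscopy in R.

Embryonic branched organs (the motivating system is the embryonic mammary
gland) elongate terminal branches and split their tips by clefting. With a
two-colour nuclear cell-cycle reporter (Fucci-type: green = S/G2/M, red =
G1/G0) these processes can be quantified cell by cell. `branchmorph`
implements the full measurement pipeline:

- **Detection** — anisotropy-aware Laplacian-of-Gaussian nuclear spot
  detection (conventional diameters 6 µm red / 7 µm green), contrast
  normalization with controlled saturation, regional sphere intensities,
  nucleus size filtering.
- **Geometry** — epithelial masks from nuclear positions (ball union +
  closing), exact and `<3,4,5>` chamfer surface-distance transforms,
  within-mask geodesic distance fields (Dijkstra, 26/6-connectivity),
  basal/inner classification at 6 µm depth, tip/duct/branch-point domains
  at landmark-anchored distances (tip ≤ 100 µm; centers 50–100 µm).
- **Cell-cycle mapping** — green fractions per domain × compartment,
  distance-binned profiles, the branch-point-to-tip ratio time series
  normalized to cleft appearance (T0), keratin K14/K8 dominance with the
  gray-value-25 floor.
- **Tracking** — gap-free per-class linking with 8 / 9.3 µm step caps,
  exclusion of tracks under 2 h, velocity / net velocity / straightness,
  region-transition flows, distance-to-edge changes.
- **Circular statistics** — signed and folded angles to a reference vector,
  rose histograms, the Rayleigh uniformity test, Watson's two-sample U²
  (permutation p by default).
- **Group statistics** — the Shapiro–Wilk → Levene → Student/Welch/Wilcoxon
  decision tree with Bonferroni correction, and Pearson correlation with a
  linear fit.
- **Morphometrics** — tip/neck widths on maximum projections, cleft angle
  and depth from landmark triples, elongation rates, geodesic branch
  lengths, sphericity.
- **Synthetic data** — a ground-truthed generator of elongating and
  bifurcating branches (tipward motility gradient, tip-enriched cycling,
  post-T0 branch-point repression and immobilization) plus a two-channel
  renderer with Poisson–Gaussian noise, so the entire pipeline is testable
  without microscopy data.

The core model, in the field's notation: cell speed follows
`s(d) = s_edge · exp(−d/λ)` with `d` the (geodesic) distance to the leading
edge; track velocity = path length / duration, net velocity = displacement /
duration, straightness = displacement / path length; sphericity =
`π^(1/3)(6V)^(2/3)/A`; directionality is the angle between a track's
displacement vector and the reference vector (leading-edge displacement, or
neck→cleft for bifurcations), folded to 0–180° (0° = parallel,
180° = antiparallel).

## Worked example

```r
library(branchmorph)

# a ground-truthed elongating branch: 500 nuclei, 30 frames at 20 min
p  <- scenario_params(n_cells = 500, n_frames = 30,
                      branch_axis_length = 250, tube_radius = 30, seed = 2001)
gt <- generate_elongation_scenario(p, mask_frames = c(1, 30))

fx <- run_fixed_analysis(gt)        # static spatial analysis (frame 1)
fx$tip_vs_duct[c("tip_fraction", "duct_fraction", "difference")]
#> $tip_fraction
#> [1] 0.5231788
#> $duct_fraction
#> [1] 0.1785714
#> $difference
#> [1] 0.3446074

tl <- run_timelapse_analysis(gt)    # tracking, flow, directionality
tl$velocity_vs_distance$R
#> [1] -0.7361988
tl$flow$transitions[c("tip_to_duct", "duct_to_tip")]
#> $tip_to_duct
#> [1] 0.226
#> $duct_to_tip
#> [1] 0
```

The fixed analysis recovers the generator's tip/duct S-G2-M fractions
(configured 0.50 / 0.15): the tip minus duct difference of ~0.34 is within
binomial error of the configured 0.35. The negative Pearson R says track
velocity falls with distance from the leading edge (the tipward motility
gradient), and retrograde flow (tip→duct) exceeds duct→tip, as expected for
an elongating branch that leaves cells behind.

(Exact numbers above were printed by this code with this seed; they vary
with `seed` within the stated sampling bands.)

## Command line

```sh
Rscript inst/cli/branchmorph.R simulate          --config cfg.json --seed 1 --outdir out/
Rscript inst/cli/branchmorph.R analyze-fixed     --config cfg.json --seed 1 --outdir out/
Rscript inst/cli/branchmorph.R analyze-timelapse --config cfg.json --seed 1 --outdir out/
```

`cfg.json` may carry `scenario` (generator parameters, including an optional
`bifurcation` block) and `config` (analysis thresholds, see `run_config()`).
Outputs are tidy CSVs plus a JSON summary and a plain-text log with
parameter echo.

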