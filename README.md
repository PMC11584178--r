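# spermwall

Wall-relative kinematics of sperm trajectories in fluorescence time-lapse
microscopy.

Rodent spermatozoa migrating through the uterus interact strongly with the
uterine wall: they swim faster and straighter when close to and aligned
with the wall, and after touching it they tend to turn in the direction
their apical head hook points (the *pro-wall-hook* direction). Testing
such claims from imaging data takes a full measurement chain — detecting
fluorescent sperm heads in movie frames, linking detections into tracks,
summarising each track with kinematic statistics, relating every track to
the wall geometry, and applying the right statistics. `spermwall`
implements that chain for R, together with a synthetic-data generator so
that every stage can be validated against known ground truth without any
microscope.

## What it computes

For a track of spots $(x_i, y_i)$ at frames $f_i$ observed at rate
$\mathrm{fps}$, with duration $T = (f_n - f_1)/\mathrm{fps}$:

* **VCL** (curvilinear velocity) $= \sum_i \lVert p_{i+1} - p_i \rVert / T$ — total
  path over duration, µm/s.
* **VSL** (straight-line velocity) $= \lVert p_n - p_1 \rVert / T$.
* **LIN** (linearity of forward progression) $= \mathrm{VSL}/\mathrm{VCL} \in [0, 1]$.
* **SWR** (straight line-to-sideward movement ratio)
  $= \lVert p_n - p_1 \rVert / w$, where $w$ is the maximum sideward
  movement distance: the width of the narrowest band parallel to the
  displacement line that contains every spot (the range of the spot
  projections onto the displacement normal).

The wall is modelled as a straight line fitted by least squares to the
boundary pixels of a binary wall mask; each track contributes a
perpendicular **distance** (from its temporal midpoint spot) and an acute
**angle** (between its displacement line and the wall, folded into
[0, π/2]). Log-transformed kinetic parameters are regressed on these
covariates with `fit_kinetics_model()`.

Turning direction after wall contact is tested with an exact one-tailed
binomial test (null proportion 0.5, alternative "more pro-wall-hook")
with a one-sided Clopper–Pearson lower confidence bound:
`binomial_direction_test(52, 63)` reproduces the published analysis of 52
pro-wall-hook turns among 63 wall contacts.

Tracking follows the standard thresholding-detector + LAP-tracker recipe:
per-frame Gaussian smoothing, Otsu thresholding (with iterative
refinement against multimodal backgrounds) and connected components;
gated frame-to-frame assignment by a Jonker–Volgenant solver
(squared-distance costs, 11 µm gate); gap closing across up to 2 missing
frames within 11 µm; and track filters (≥ 7 spots, displacement
> 2.5 µm).

## Worked example

Simulate a 60-frame, 512×512-pixel, 30-fps field with 20 sperm near a
dark wall region, render it, track it, and analyse it:

```r
library(spermwall)

cfg  <- sim_config(n_sperm = 20, n_frames = 60, seed = 42)
sim  <- simulate_trajectories(cfg)
sim
#> sperm_sim: 20 tracks, 60 frames, 1 turn events (1 pro / 0 anti)

stack  <- render_image_stack(sim)
res    <- track_stack(stack)
params <- compute_kinematics(res$spots, fps = cfg$fps)
head(round(params[, c("track_id","n_spots","duration_s","vcl","vsl","lin","swr")], 3))
#>   track_id n_spots duration_s    vcl    vsl   lin    swr
#> 1        1      60      1.967 42.839 34.818 0.813  3.427
#> 2        2      60      1.967 19.182 18.017 0.939  8.796
#> 3        3      60      1.967 30.375 28.525 0.939 11.781
#> 4        4      57      1.867 64.770 53.128 0.820  3.743
#> 5        5      60      1.967 23.861 20.900 0.876  5.153
#> 6        6      60      1.967 39.069 36.425 0.932  6.755

wallm <- fit_wall(extract_boundary(make_wall_mask(cfg), cfg$pixel_size_um))
wallm
#> wall_model: through (0.00, 345.00) um at 0.00 deg (n = 512, rmse = 1.01e-13 um)

rel <- wall_relation(res$spots, wallm)
fit_kinetics_model(merge(params, rel, by = "track_id"),
                   "vcl", c("distance_um", "angle_rad"))
#> kinetics_fit: log(vcl) ~ distance_um + angle_rad  [n = 20, dropped 0]
#>                Estimate  Std. Error  t value  Pr(>|t|)
#> (Intercept)  4.29939186  0.07638914  56.2828 < 2.2e-16 ***
#> distance_um -0.00434839  0.00029921 -14.5331 5.108e-11 ***
#> angle_rad   -0.12899198  0.07229028  -1.7844   0.09222 .
```

The tracked-and-fitted distance coefficient (−0.0043 per µm) recovers the
generative log-speed slope (−0.004 per µm): sperm in this simulation swim
about 0.4% slower per micrometre away from the wall, and the whole
measurement chain preserves that effect. The directional test prints the
published turning analysis:

```r
binomial_direction_test(52, 63)
#> Exact binomial test of turning direction (one-tailed, null 0.5)
#>   pro-wall-hook: 52 of 63 (82.54%)
#>   p-value: 8.367e-08
#>   one-sided 95% CI: (0.7276, 1.00)
```

`run_demo("out/")` runs the full simulate → track → analyse pipeline to
files; `inst/cli/spermwall.R` exposes the same stages as shell
subcommands (`simulate`, `track`, `analyze`, `demo`).

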