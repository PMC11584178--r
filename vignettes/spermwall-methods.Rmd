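---
title: "Methods: wall-relative sperm kinematics in spermwall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall-relative sperm kinematics in spermwall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Fluorescently labelled sperm heads are imaged in utero as two-channel
time-lapse stacks (512×512 pixels at 30 frames/s is the reference
geometry; 60-frame, 2-s windows are the unit of analysis). The
scientific questions are wall-relative: do sperm swim faster and
straighter when close to and aligned with the uterine wall, and do they
preferentially turn in the pro-wall-hook direction after contacting it?
Answering them requires a chain of stages — detection, linking,
per-track kinematics, wall geometry, statistics — each of which can fail
silently. `spermwall` implements the chain and, crucially, a generative
simulator with known ground truth so each stage is testable end to end.

# Kinematic parameters

For a track of spots $p_1,\dots,p_n$ at frames $f_1 < \dots < f_n$ and
frame rate $r$, duration is $T = (f_n - f_1)/r$: gap-closed missing
frames count in the span, and a bridged gap contributes one straight
segment to the path (no interpolation — the linking convention of
LAP-style trackers). Then

* VCL $= \sum_i \lVert p_{i+1}-p_i \rVert / T$,
* VSL $= \lVert p_n - p_1 \rVert / T$,
* LIN $= \mathrm{VSL}/\mathrm{VCL}$, reported on $[0,1]$,
* SWR $= \lVert p_n - p_1 \rVert / w$,

where the maximum sideward movement distance $w$ is the width of the
narrowest band parallel to the displacement line containing all spots:
with $u$ the unit displacement vector and $n_\perp$ its normal,
$w = \max_i \langle p_i, n_\perp\rangle - \min_i \langle p_i,
n_\perp\rangle$. Because perpendicular projection is linear, the band
over the spot *polyline* equals the band over the spot *set*, so the two
possible readings of the definition coincide.

Degenerate tracks produce `NA` markers rather than zeros: a single-spot
track has no duration; a zero-displacement track has no displacement
direction (VSL 0, SWR and wall angle undefined); a perfectly straight
track has $w < \varepsilon$ (with $\varepsilon = 10^{-9}$ µm) and its
SWR is undefined rather than infinite. `NA`s propagate into the
statistics layer as missing values with logged counts, so degenerate
tracks cannot bias fitted effects toward zero.

All four parameters are invariant under rigid motions; VCL and VSL scale
linearly under spatial rescaling while LIN and SWR are scale-free. The
test suite asserts these properties on randomly generated tracks and
checks SWR against an independent oracle (rotate the track so the
displacement lies on the x-axis; take the y-extent) at $10^{-9}$
relative tolerance.

# Wall geometry

The wall is a straight line fitted to boundary pixels of a binary wall
mask (foreground pixels with a 4-neighbouring background pixel inside
the image, pixel-centre coordinates, 0-based, scaled to µm). The fit is
ordinary least squares on the axis of larger coordinate extent — y on x
for near-horizontal walls, x on y for near-vertical ones — which avoids
the vertical-slope singularity without changing the result for the
shallow wall angles the method targets; a total-least-squares option is
available for oblique walls.

Per track, the *distance* covariate is the perpendicular distance from
the temporal midpoint spot (index $\lfloor (n-1)/2 \rfloor$, 0-based) to
the line. The midpoint *spot* was chosen over the centroid because the
distance is defined for a single reference point and the midpoint is
robust to unequal dwell at the track ends; the centroid is available via
`ref = "centroid"`. The *angle* covariate is the acute angle between the
displacement line and the wall, $\arccos |u \cdot w| \in [0, \pi/2]$ —
direction sign is deliberately discarded, since the hypotheses concern
alignment, not travel direction.

Turn classification (`classify_turn`) finds the first frame whose spot
lies within the contact threshold (2 µm, about one head length; the
qualitative "upon reaching the wall" rule needs *some* numeric
threshold and head contact is the natural scale), averages headings over
k = 3 frames on each side of contact, and asks whether the post-contact
along-wall direction lies on the hook side of the pre-contact heading
(pro) or the opposite side (anti). The rule is chirality-consistent:
mirroring the scene and flipping the hook side preserves the label.

# Tracking

Detection smooths each frame with a Gaussian (SD in µm), thresholds it,
labels 8-connected components, and takes intensity-weighted centroids;
the equivalent radius $\sqrt{A/\pi}$ must exceed 0.75 µm (a minimum
head-size filter). The default threshold is Otsu's method with
iterative refinement: when the foreground after a split still covers
more than 5% of the frame — which happens when the histogram's dominant
split separates the dark wall region from the lumen instead of
background from blobs — Otsu is recomputed on the foreground alone (at
most 5 rounds). An absolute threshold is available when the intensity
scale is known.

Linking solves, per consecutive frame pair, a rectangular assignment
problem with squared-distance costs, links beyond the 11 µm gate
forbidden, and a non-link alternative priced at $1.05 \cdot
\mathrm{gate}^2$ — the standard LAP-tracker augmentation, under which a
spot links whenever an in-gate partner exists unless a cheaper global
matching says otherwise. The solver is a Jonker–Volgenant shortest
augmenting path implementation written for this package (no assignment
solver is available among the package's dependencies); the test suite
proves it equal to brute-force enumeration of all gated matchings on
every instance with ≤ 5 spots per frame. Gap closing is a second
assignment over segment ends × segment starts with frame gap in
[1, 2] and distance ≤ 11 µm. Determinism: spots are processed in
(frame, x, y) lexicographic order, so equal-cost assignments resolve
reproducibly. Track splitting/merging and motion-model prediction are
out of scope, as is image registration — synthetic stacks are generated
drift-free, and a real-data pipeline would pre-align frames upstream.

The published filter set lists "max distance travel (2.5 µm)" alongside
a minimum spot count. Read literally as a *maximum* displacement gate it
would discard nearly every motile sperm and keep only debris, so the
package applies it as a *minimum* displacement filter (immotile-debris
removal); the gate is configurable (`min_displacement_um`) and every
rejection is reported with its reason.

# The simulator

Each sperm is a persistent random walk in the image plane. At each
frame, speed is
$s = \exp(\beta_0 + \beta_d d + \beta_\theta \theta + \epsilon)$, with
$d$ the current perpendicular wall distance (µm), $\theta$ the acute
heading-to-wall angle (rad), and $\epsilon \sim N(0, \sigma_s)$; the
heading diffuses with SD $\sigma_\phi$ per frame. Defaults:
$\beta_0 = \log 80$ (µm/s at the wall, the fast end of uterine sperm),
$\beta_d = -0.004$/µm (about a five-fold speed decline across a 384 µm
field — a strong but not pathological near-wall contrast),
$\beta_\theta = -0.3$/rad, $\sigma_s = 0.1$ log-units,
$\sigma_\phi = 0.2$ rad/frame, positional jitter 0.1 µm per axis.
Tests that measure effect recovery always set their own $\beta$ values
explicitly.

On *entering* the 2 µm contact band (a refractory rule: the event fires
on the crossing, not on every in-band frame), a turn event fires. With
probability `pro_hook_prob` (default 0.8254, the observed pro fraction)
the new heading is the along-wall direction on the sperm's hook side —
the hook side is a fixed 50/50 left/right anatomical attribute assigned
at birth. Otherwise the sperm leaves the wall: its new heading is the
unit mix of the *opposite* along-wall direction and the away-from-wall
normal. A literal mirror reflection was rejected here: reflection
preserves the incoming tangential direction, which coincides with the
hook side about half the time, making ground-truth "anti" labels
geometrically indistinguishable from "pro" ones and unclassifiable in
principle. The implemented rule makes "anti" mean what it means in the
field — post-contact motion away from the wall with along-wall drift on
the non-hook side — and lets a 95%+ classifier agreement target be
meaningful. Turns are instantaneous; the real pivoting takes several
beat cycles, and no claim about turning mechanics is intended.

Sperm never penetrate the wall (positions mirror off the line) and
reflect at the field boundary. Rendering draws each head as an isotropic
Gaussian blob (SD 1 µm) in the head channel, optionally a trailing blob
in a midpiece channel, darkens the wall-tissue side, adds Gaussian read
noise (Poisson available), and quantizes to 16-bit. Heads only, no
flagellum: the imaging this emulates shows no tail fluorescence, and
head blobs are what the detector sees. No hydrodynamics, no wall
attraction except through the speed model, no sperm–sperm interaction
or train formation, no uterine flow or drift: passing tests show the
measurement chain is correct, not that the biology is.

Reproducibility: each sperm consumes its own RNG sub-stream whose seed
is drawn (by counter) from the configuration seed's stream, so sperm
$i$'s trajectory is bit-identical when `n_sperm` changes, and identical
configurations give bit-identical simulations and renderings. The
rendering stream is the $(n_{\mathrm{sperm}}+1)$-th sub-stream.

# Statistics

The directional test is exact: $p = \sum_{k \ge n_{pro}} \binom{n}{k}
2^{-n}$, with the one-sided 95% Clopper–Pearson lower bound from the
beta-quantile identity `qbeta(0.05, n_pro, n - n_pro + 1)` (0 when
`n_pro` is 0) and the upper bound fixed at 1. For 52 of 63 turns this
gives proportion 82.54%, $p < 10^{-7}$ and lower bound 0.7276 — the
published 0.73 at two decimals. At $n = 63$ the exact test is
conservative: its true size at $\alpha = 0.05$ is
$P(X \ge 39) = 0.0385$, a closed-form fact worth knowing when judging
Monte Carlo estimates of the rejection rate against a 5% ± 1.5% band —
a 1000-replicate estimate has standard error ≈ 0.6 points around 3.85.

Kinetic responses are fitted by fixed-effects least squares of the
(natural-) log response on distance and angle, plus any indicator
covariates (batch, cropping, animal). The original analysis used mixed
models with random intercepts per male and per experiment date; at
simulation scale there is no grouping structure to pool over, and the
quantity of interest — the fixed effect of distance and angle — is what
the acceptance surface checks, so the package fits fixed effects and
leaves room for a mixed-model backend behind the same interface. Fits
refuse rank-deficient designs and fewer than 10 usable rows; constant
responses are flagged degenerate with slopes reported as 0. Zero or
negative responses become missing before the log transform, with
counts logged. LIN is log-transformed by default like the other three
responses (the original methods text says all four were; its figure
axes exempt LIN — the per-response `transform` switch covers either
reading). No multiple-testing correction is applied across the four
models, matching the original analysis.

`compare_groups` gives per-group medians, quartiles and counts — the
boxplot summaries used for sperm-train versus single comparisons — and
deliberately attaches no hypothesis test: with three observed trains in
the motivating data, estimation rather than testing is the honest
summary.

# Problem sizes and numerical choices

The test suite runs the SWR oracle on 1000 random tracks; linking
against brute force on 250 random gated instances; effect recovery on
500 simulated sperm (≈ 14,500 frame records); directional power on 500
and type-I error on 1000 simulator replicates of 63 turns each; and
end-to-end tracking on 512×512×60 rendered stacks with nine
well-separated swimmers (spacing 35 µm, far above the 11 µm gate, with
low heading diffusion so separation persists — the recovery claim is
conditional on separation, since converging sperm merge into one blob
at detection and no detector can split them without a shape model).
Frame-wise effect recovery uses the generator's own records rather than
per-track VCL because per-track log(VCL) regressed on midpoint distance
is attenuated by within-track distance variation; the frame-wise
regression is the exact generative model and is unbiased at the
precision the recovery check demands.

Numerical conventions: 0-based pixel indices with pixel-centre origin,
x = column, y = row, µm after scaling; `frame` is authoritative and
`t_s = frame / fps` is stored redundantly; forbidden assignment costs
use a large finite sentinel ($10^{12}$) rather than `Inf`; 16-bit
quantization rounds to the 65535-level grid; the SWR degeneracy cutoff
is $10^{-9}$ µm.

# Known limitations

Straight walls only — the analysis restricts itself to fields of view
with straight wall segments, as the motivating study did; curved-wall
support would need an arc-length parametrised boundary model. The
tracker has no splitting/merging and no Kalman prediction, so crossing
trajectories can swap identities. The simulator's turn model is
phenomenological. The `cropped` covariate is carried through the stats
table but no principled assignment of it can be reconstructed for the
original data. Real acquisitions drift with uterine contraction;
pre-alignment is assumed done upstream.
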