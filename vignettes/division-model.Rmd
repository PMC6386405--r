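---
title: "A discrete-space stochastic model of plant cell division"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-space stochastic model of plant cell division}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdivide)
```

## The model

A mother cell is represented as a binary occupancy grid of N cubic
voxels (side $a$, in micrometers). A division is a binary partition
$x$ assigning every voxel to daughter 1 or daughter 2, scored by

$$H(x) = H_V(x) + H_A(x),$$

with a volume-ratio constraint term (volumes $V_1, V_2$ counted in
voxels, target ratio $\rho^*$):

$$H_V(x) = \big([V_1(x) - \rho^* V]^2 + [V_2(x) - (1-\rho^*) V]^2\big)^{1/3},$$

and an interface-area term summed once over unordered pairs of sites
in each voxel's 26-neighborhood:

$$H_A(x) = \alpha\, a^2 \sum_{(i,j)\ \text{neighbors}} \mathbf{1}[x_i \ne x_j].$$

Unweighted 26-neighbor pair counting is the lattice analog of an
unweighted Crofton estimate of the interface area: it is cheap and
isotropic enough for energy purposes, though it systematically favors
planes with normals along the grid diagonals and overestimates the
area of oblique planes — which is why *measurement* never uses pair
counts (see below).

$H$ is minimized by the Metropolis algorithm: per attempt, one
uniformly random occupied site is proposed for reassignment to the
other daughter; moves with $\Delta H \le 0$ are always accepted,
others with probability $e^{-\Delta H/kT}$. One Monte-Carlo cycle is
N attempts; the default budget is 5000 cycles. Because $\Delta H$ is
local (only the site's 26 neighbor facets and the two volume counts
change), each attempt is O(1) and the compiled kernel runs the
default budget on a 17 000-voxel cell in a few seconds.

Two aspects of the recipe deserve emphasis, because the model has
two well-defined failure regimes. If the interface coupling is weak
relative to $kT$ ("too hot"), partitions stay noisy: bubbles of one
daughter float inside the other and the interface is rough. If it is
strong ("too cold"), the minority daughter can be eaten entirely
during the early coarsening phase — one daughter invades the cell,
which scores better than any divided state because the cube-root
volume penalty saturates while interface cost keeps growing with
cell size. The divided state is therefore *metastable*, protected by
the steep slope of $H_V$ near the target ratio, and the job of the
parameters is to make that metastability robust for the whole cycle
budget.

## Operating point and why

All defaults were fixed once, on digitized spheres of radii 8–16
voxels at the 0.35 um calibration, before the validation suite was
frozen:

* **$\alpha = 2$, facet area $a^2$ from the calibration.** The
  balance parameter of all reference simulations.
* **$kT = 0.25$.** This puts one discordant neighbor pair at
  $\approx 1\,kT$ (interfaces are smooth but still explore) and a
  one-site ratio violation at $\approx 3.4\,kT$ (volumes stay
  pinned). At $kT \gtrsim 1$ the model sits in the hot regime above
  (measured: ~30 bubble components and interface areas 1.8× the
  analytic disk on a sphere); colder than $\approx 0.1$ the 2D/small-cell
  dynamics freeze before coarsening completes.
* **Unbiased initialization.** Each site starts in either daughter
  with probability 1/2 regardless of $\rho^*$. Initializing at an
  asymmetric Bernoulli($\rho^*$) scatters the minority phase into
  droplets whose curvature makes them evaporate — in our experiments
  every run at $\rho^* = 0.33$ initialized that way lost the
  minority daughter. From the unbiased start both phases percolate,
  coarsen into one interface, and the volume term then slides that
  interface to the target.
* **Target-ratio continuation (`rho_schedule`).** The target is held
  at 0.5 for the first 30% of cycles and moved linearly to $\rho^*$
  between 30% and 70%. This keeps the minority connected at strongly
  asymmetric targets; with the continuation, 40/40 test runs at
  $\rho^* = 0.33$ (radii 8–16) realized the target ratio exactly,
  against 0–70% without it. Disable it to recover the plain
  fixed-target dynamics.
* **Final quench.** The minimizer reports a local minimum of $H$,
  obtained by a zero-temperature descent from the final Metropolis
  state with the realized volume split held within ±2 sites. The
  descent dissolves thermal bubbles and lattice-scale roughness but
  cannot erode an asymmetric cap (the volume band blocks the
  curvature ratchet). Disable `quench` to obtain the raw thermal
  state.

The 2D variant (leaf epidermis geometry) drops $H_V$ entirely:
the initial configuration is drawn at the target ratio and
Kawasaki-type exchanges (one pixel from each daughter swaps labels
per attempt, 8-neighbor interface counting) conserve it exactly.
Exchange dynamics coarsen more slowly than single-site dynamics
because material moves by evaporation–condensation; the 2D reference
conditions therefore use $kT = 0.26$ and 20 000 cycles, under which
12/12 pre-registration sweep runs on disks and 40×10 rectangles
landed within 15% of the analytic minimal bisecting chord (most
within 10%). Occasionally (~5–10% of elongated-shape runs) the
dynamics freeze into a diagonal interface that cannot reorient; such
runs are visible as length outliers and are the reason the
validation criterion is an ensemble proportion, not a per-run bound.

## Measurement

The division interface is extracted as a triangular mesh: the
daughter-1 indicator is extended into the background by nearest-label
propagation, box-smoothed over 3×3×3 voxels, and its 0.5-level
surface is extracted by marching tetrahedra with linear edge
interpolation, then clipped back to the mother-cell interior (the
outer wall never enters the mesh). Smoothing the *scalar field*
before iso-surfacing removes the staircase bias of marching on raw
binary data — up to +73% area for planes with (1,1,1) normals, the
orientations the 26-neighbor energy actually favors — while flat
axis-aligned planes remain exact. No smoothing is ever applied to
the mesh itself.

Plane metrics follow the standard conventions: area is the triangle
sum; the unit normal is the area-weighted mean of facet normals
(oriented daughter 1 → daughter 2; all reported angles are folded to
[0°, 90°] so the orientation convention is immaterial); the plane
centroid is the projection of the area-weighted triangle-centroid
mean onto the mesh; anchor distances are exact point-to-triangle
minima, not vertex-only. The "passes through the centroid" predicate
of the nested rule uses one voxel *diagonal* (0.61 um at reference
calibration) as its admissibility radius: this is the resolution
limit of a centroid-to-plane distance measured on a cubic grid, and
it is required empirically — the least-area near-centroid planes of
the strongly asymmetric 8-to-16-cell transition sit 1-2 voxel sides
from the centroid (as do the corresponding real measurements,
~0.5 um for central cells), so a one-side radius rejects every
candidate and the recursion cannot proceed. The stricter one-side
variant remains available as an argument.

The 16 morphometric features and their estimators are documented in
`?cell_morphometrics`. Two are worth flagging: mean breadth is an
axis-sampled Crofton estimate (mean over the three grid axes of the
integrated 2D-section Euler characteristic) — exact for balls, an
underestimate for strongly anisotropic bodies; convexity uses a
discrete convex closure (iterated line-filling along the 13 lattice
directions) rather than an exact convex hull, which keeps it in
(0, 1] by construction and within a few percent of the hull ratio
for near-convex cells. The three size-ratio shape factors are
normalized so a ball scores 1 on each
($36\pi V^2/S^3$, $6V/(\pi b^3)$, $S/(\pi b^2)$); their precise
normalization is a package convention, tested for scale invariance.

## Ensembles, normalization and the nested rule

Because the minimizer is stochastic, repeated runs on one cell
explore a set of locally minimal division planes. To pool plane
measurements across cells of different sizes, each measured value is
converted to a *relative measure*: the fraction of an alternative
solution set S with strictly smaller value. It is uniform on [0, 1]
when the candidate is statistically equivalent to its references
(tested by simulation), invariant under monotone transforms of the
measured quantity, and ties count zero (a midrank variant exists for
sensitivity analysis). Reference regimes mirror the comparison
designs used in the source analyses: alternatives at the observed
ratio, alternatives at ratios drawn uniformly from 0.2–0.5, and the
latter restricted to solutions passing at least as close to the
centroid as the candidate.

The nested geometrical rule is: exclude fragmented candidates
(either daughter in >1 face-connected component), keep candidates
whose plane passes within one voxel side of the anchor, and among
those select the least interface area (ties: smaller distance, then
smaller seed — deterministic and order-independent). When nothing is
admissible the result says so explicitly; there is no fallback.

## Recursive embryogenesis

`simulate_embryogenesis()` applies the rule recursively from a
truncated sphere (default truncation: a cut removing a quarter of
the diameter, mimicking the shape of the 1-cell embryo proper; depth
and orientation are parameters since the real geometry varies). Per
generation and cell: run an ensemble at the scheduled target ratio
(0.5, 0.5, 0.45, 0.33 for the four transitions to the 16-cell
stage), select by the nested rule with the cell's centroid as anchor
(a nucleus-centroid anchor can be substituted per cell), split the
mask, recurse. No growth between generations, matching the model's
scope. A cell with no admissible solution gets one re-run with a
doubled ensemble before the simulation aborts with a diagnostic.
The simulated 16-cell central interfaces tend to lie parallel to the
first division plane rather than to the outer walls; this
divergence from real embryos is expected from the absence of growth
in the model.

The embryo coordinate frame places its origin at the centroid G1 of
the first division plane D1, takes i as the D1 normal, k as the
normalized projection of the G1-to-suspensor vector onto D1 (sign:
apical = away from the suspensor), and j = i × k. At the 8-cell
generation, the four cells with larger k-projection are apical;
labels propagate down the lineage; at 16 cells each sister pair
splits into internal/external by |i|-projection.

## Problem sizes and reproducibility

The validation suite runs spheres of radius 12–16 voxels (4 000 –
17 000 sites), 10–20 seeds per claim, full 5000-cycle budgets, and a
complete 1C→16C recursion at radius 16 with 10 runs per division;
the 2D checks use 20-pixel-radius disks and 40×10 rectangles. These
sizes keep every quantitative claim testable in minutes on one core
while matching the voxel counts of real segmented embryo cells at
the 0.35 um calibration.

Every entry point is deterministic given its seed: ensembles derive
per-run substream seeds by an integer hash of (master seed, run
index), so single runs can be reproduced in isolation and ensemble
results do not depend on execution order.

## What the synthetic shapes do and do not show

Spheres, half-spheres, quarter spheres and truncated spheres have
analytically known minimal bisecting surfaces, so they validate the
minimizer, the measurement chain and the rule machinery end-to-end.
They do not exercise segmentation noise, wall curvature
irregularities, or non-convex mother cells; for real data the
package consumes segmented label stacks and the connectivity warning
plus fragmentation flags are the guard rails. The lattice energy's
orientation bias (diagonal planes slightly cheaper per physical
area) is invisible in spheres — every diametral plane is equivalent —
but in real cells it can tilt near-degenerate choices; the mesh-based
measurements are unbiased either way.

## Known limitations

* The model is purely geometrical: no growth, mechanics, nucleus
  migration or signaling.
* The printed energy conventions admit several unit readings; this
  implementation fixes volumes in voxel counts and per-pair cost
  $\alpha a^2$, with $kT$ exposed — other readings rescale the same
  two-parameter family.
* Exchange (2D) dynamics can freeze in misoriented interfaces on
  strongly elongated shapes (~5–10% of runs); inspect the length
  distribution, not single runs.
* Mean breadth is axis-sampled; convexity uses the discrete closure;
  both are documented approximations chosen for robustness on
  lattice data.
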