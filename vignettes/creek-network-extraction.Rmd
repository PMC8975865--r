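---
title: "Extracting and parametrising tidal creek networks from elevation grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and parametrising tidal creek networks from elevation grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creekmorph)
```

## The problem

Tidal creeks organise the exchange of water, sediment, nutrients and
propagules between a saltmarsh platform and the sea. In restored coastal
wetlands — especially Managed Realignment schemes, where a seawall is
breached to return embanked land to tidal influence — the development of
the creek network is one of the most informative indicators of
geomorphological recovery, and it can be monitored remotely from repeat
lidar surveys. `creekmorph` extracts the creek network from a gridded
elevation model and reduces it to a standard set of morphometric
parameters that can be compared across sites and years.

Creeks in engineered settings are often excavated rather than formed by
drainage, so flow-accumulation channel extraction (which assumes
topographically consistent drainage) performs poorly. The package
instead uses a *threshold* definition: a creek is a connected feature
lying **lower** than the surrounding marsh whose edges are **steeper**
than the platform. This is deliberately simple, transparent, and
controllable by four user thresholds.

## Pipeline and assumptions

Given an elevation grid (1 m cells are the working standard; the
vertical datum must match the tidal levels), the stages are:

1. *Marsh delimitation.* Cells below the local Highest Astronomical
   Tide, optionally intersected with a boundary polygon, largest
   connected region kept. The assumption is that HAT separates the
   intertidal zone from land, and that seawalls (higher than HAT)
   naturally bound the catchment.
2. *Gap filling.* Lidar collected at low tide still leaves voids over
   residual water. Gaps take the value of the Euclidean-nearest valid
   cell — deliberately *not* an average, which would smooth channel
   walls shut. Ties are resolved to the smallest row then column, making
   the fill deterministic.
3. *Slope.* The Horn 3×3 operator in degrees, reflected padding at the
   edges, nodata propagating to any window that touches it. Horn is the
   de-facto GIS standard and behaves well on noisy lidar.
4. *Detection.* Candidates are in-marsh cells with `z ≤ z_thresh` *or*
   `slope ≥ s_thresh`. The union (rather than intersection) catches both
   flat-bottomed channel interiors and their banks; to stop purely
   slope-defined features (seawall toes, embankment faces) from
   classifying as creeks, a candidate component is kept only if it
   contains at least one elevation-qualified cell.
5. *Repair.* Components below `min_component_px` pixels are noise.
   Remaining fragments are reattached to the largest component by
   rasterizing the straight segment between the closest pixel pair,
   nearest fragment first, recomputing distances after each bridge so
   chains of fragments can reconnect through earlier bridges; fragments
   farther than `max_repair_dist` stay detached and are reported.
6. *Skeletonization.* Topology-preserving thinning of the Zhang–Suen
   family (details below) produces a one-pixel centreline with exactly
   the component structure of the repaired mask.
7. *Graph building and ordering.* Skeleton pixels with one 8-neighbour
   are endpoints, with three or more are junctions; maximal chains
   between them are segments with sinuous lengths (diagonal steps count
   √2). Outlets are found where the creek mask touches the marsh
   boundary; each boundary-contact zone claims its nearest endpoint.
   Reverse Strahler ordering — the convention in which the *entry*
   channel is order 1, so orders remain comparable across networks of
   different maturity — is assigned by pruning: the longest sinuous path
   from the largest outlet is the order-1 channel; every tributary
   branching off an order-*k* channel roots a subnetwork whose own
   longest path from that junction becomes an order-(*k*+1) channel,
   recursively.
8. *Morphometrics.* Per-channel geometry and transect statistics, then
   per-order and whole-network summaries (the `DD, OPL, MCL, TCL, NB,
   CSA, D, PA, TP, SR, MCG` record plus mean elevation above Mean Water
   Spring).

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| `z_thresh` | m (datum) | — (site-specific) | elevation below which cells are creek candidates; may be given relative to a tidal level, e.g. `"mhwn - 0.3"` |
| `s_thresh` | degrees | 40 | creek-edge steepness; raise above the seawall-face slope where embankments abut the marsh |
| `min_component_px` | px | 10 | the smallest feature treated as a creek rather than noise at 1 m cells |
| `max_repair_dist` | m | 10 | the longest plausible gap a drained channel leaves in the detected mask |
| `z_tolerance` | m | 0.15 | threshold perturbation for sensitivity runs; the nominal lidar vertical resolution |
| transect `spacing` / `fit_len` | px | 5 / 5 | station spacing and chord length for cross-sections; stations within `fit_len` of a junction are skipped so transects do not cut confluences |
| tide `radius` / `power` | m / – | 30000 / 1 | port-interpolation search radius; inverse-distance weighting (power 1) — the weighting power is a configuration switch, since only "weighted mean" is prescribed by the method |

## Numerical choices

**Thinning.** The skeletonizer runs four directional sub-passes (N, S,
E, W) per iteration. Each sub-pass snapshots the boundary pixels on that
side that are 8-simple non-endpoints — simplicity tested exactly, by
counting 8-connected components in the punctured neighbourhood and
requiring an orthogonal background neighbour — then deletes them
sequentially, re-verifying simplicity before each deletion. The
snapshot bounds erosion to one boundary layer per sub-pass, so ribbons
collapse onto their centreline instead of eroding away; sequential
simple-point deletion makes connectivity, holes, loop structure and
endpoint preservation exact rather than statistical. A final clean-up
removes the corner/staircase redundancies directional passes leave,
guaranteeing no 2×2 block survives.

**Distance transforms.** Gap filling and the overmarsh-path-length map
use an exact Euclidean distance transform that also returns the argmin
cell, with lexicographic (row, column) tie-breaks. Exactness matters
because the OPL map is defined as a per-cell distance and is validated
against an all-pairs computation.

**Ties and determinism.** Every data-dependent choice has a stated
tie-break: nearest-fill donors and outlet assignment by (row, column);
fragment repair by (distance, row, column); longest-path selection by
length, then mean cross-sectional area, then far-endpoint (row,
column). Two runs on identical inputs produce byte-identical output
bundles (the run log carries no timestamps for the same reason).

**Cycles.** Thinned masks can contain loops (around ponds or eroded
islands). Ordering requires a forest, so each independent cycle loses
its shortest segment (equivalently, a maximum spanning tree is kept)
before pruning; removed segments are reported and carry no order. A
component that is a pure cycle with no endpoint cannot be ordered and is
an error.

**Cross-sections.** Transects run perpendicular to the local centreline
chord, sampled midpoint-style at half-cell steps until they leave the
creek mask on both sides. The bank level is the mean elevation of the
two first out-of-mask cells; width is the in-mask extent; depth is bank
minus minimum elevation; area is the midpoint-rule integral of
`max(0, bank − z)`. Transects that exit the grid before exiting the mask
are flagged and skipped rather than extrapolated. With rectangular and
V-shaped test channels this convention recovers the analytic width,
depth and area to within half a sample step.

**Definitions that the method leaves open** (fixed here, so comparisons
stay self-consistent):

* OPL averages over in-marsh *non-creek* cells — creek cells sit at
  distance zero and would only dilute the statistic.
* The tidal prism TP is the creek volume below the *local bank top*
  (nearest out-of-mask marsh cell per creek cell), which avoids
  dependence on a tidal datum; anyone comparing against externally
  published prisms should note their reference surface may differ.
* Bifurcation ratio is `N(k+1) / N(k)` per consecutive order pair
  (reported on order `k`); with reverse ordering it is ≥ 1 for
  tree-like networks.
* `A/D` is area over depth squared (a dimensionless mean width/depth
  measure); `W/D` is transect width over depth.
* MCG is positive when the channel head lies above the mouth.
* Sensitivity spreads use the sample standard deviation (n − 1), as only
  three perturbed runs contribute.
* The straight-line (Bresenham) bridge reads "shortest Euclidean repair
  path" literally; a least-cost path over the DEM was considered and
  rejected as it reintroduces the flow-routing assumptions the threshold
  method avoids.

## The synthetic marsh generator

`generate_marsh()` exists so that every stage is testable without any
external data download. It emulates the structural features the
detection method assumes: a low-relief platform, a seawall ring with
breaches, dendritic creek trees carved below the platform with
rectangular (or parabolic) cross-sections, per-order widths / depths /
lengths, optional sinusoidal meandering, Gaussian vertical noise
(default σ = 0.15 m, the nominal lidar vertical resolution at 1 m
cells), and nodata speckle standing in for residual water. Tree geometry
is deterministic: children attach at fixed fractions of the parent
chosen so the parent is always the longest path from its root, which
makes the generated orders the reverse-Strahler ground truth by
construction.

What it does **not** emulate — and what passing tests therefore do not
demonstrate about field data: vegetation bias in surface models (the
workflow deliberately uses the raw DSM), water remaining *in* channels
(which makes real lidar depths shallower than surveyed depths),
spatially correlated lidar noise and flight-line artefacts, channels
narrower than the cell size, and natural width/depth tapering along a
channel. Recovery tolerances on real data are accordingly wider than the
synthetic ones, particularly for depth and for high-order (small) creek
counts.

## Problem sizes and test design

The test-suite and the acceptance script use a 420 × 420 m marsh with a
three-order binary creek tree (channel lengths 260 / 80 / 26 m, widths
7 / 5 / 3 m, depths 1.2 / 0.9 / 0.6 m) — large enough that skeleton end
retreat (about half a channel width per channel tip, an intrinsic
property of thinning) stays under the 5 % length-recovery tolerance, and
small enough that the whole pipeline runs in about a second. Recovery
checks run at noise σ = 0.05 m, where the 0.3 m detection margin is six
standard deviations; the generator's default σ = 0.15 m represents
realistic survey conditions rather than a recovery guarantee. Oracle
comparisons (gap fill, labelling, distance maps, aggregation) run on
random grids up to 100 × 100 against all-pairs brute-force
implementations and are exact, not approximate.

## Known limitations

* Junction clusters in thinned rasters occasionally form tiny segments
  and spurious micro-loops; loops are broken deterministically, but
  segment-level statistics immediately at complex confluences should be
  read with that in mind.
* Outlet identification assumes the creek mask physically reaches the
  marsh boundary; a mouth blocked by a nodata void that gap-filling
  could not bridge will not be recognised.
* The threshold is spatially uniform. On marshes with a strong
  platform-elevation gradient a single `z_thresh` may under-detect at
  one end; the tidal-relative threshold syntax mitigates but does not
  remove this.
* Widths are overestimated where adjacent channels merge at the grid
  resolution, and depths are bounded by what the surface model saw —
  both inherent to the data, not the algorithm.
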