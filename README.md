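# creekmorph

Semi-automated extraction and parametrisation of tidal creek networks in
coastal wetlands from gridded elevation data.

Restored coastal wetlands — in particular Managed Realignment (MR)
schemes, where embanked land is returned to tidal influence by breaching
the seawall — are monitored largely through their creek networks: the
channels distribute water, sediment, nutrients and seeds across the
marsh, and their horizontal development is a key indicator of whether a
restoration scheme is converging on natural saltmarsh function.
`creekmorph` turns a lidar-derived elevation grid plus a handful of tidal
levels into a quantitative description of that creek network, suitable
for repeat surveys across sites and years. It is aimed at coastal
geomorphologists and restoration practitioners working with
1 m-resolution DEMs of saltmarshes and MR schemes.

## Method

The tool implements a threshold-based mapping workflow:

1. **Preprocessing** — mosaic merging, block-mean aggregation to a common
   resolution, nearest-neighbour gap interpolation (Euclidean distance,
   deterministic tie-breaks), cropping of the catchment to the local
   Highest Astronomical Tide (HAT), and a Horn 3×3 slope map in degrees.
2. **Detection** — a creek is a connected feature lying lower than the
   surrounding marsh with steeper edges: cells with `z ≤ z_thresh` or
   `slope ≥ s_thresh` form the candidate set; 8-connected components with
   no elevation-qualified cell (seawall toes and embankment faces) are
   discarded.
3. **Repair** — components smaller than `min_component_px` are removed as
   noise; fragmented terminal channels within `max_repair_dist` of the
   network are reconnected along the shortest straight (Bresenham) path,
   nearest first.
4. **Skeletonization** — topology-preserving morphological thinning
   reduces the repaired mask to a one-pixel centreline.
5. **Ordering** — the skeleton becomes a segment graph; outlets are the
   mouths where the creek mask meets the marsh boundary (seawall breach
   or seaward edge). Channels receive **reverse Strahler orders** by
   iterative pruning: the longest path from the largest outlet is the
   order-1 entry channel, and every tributary branching off an order-*k*
   channel roots an order-(*k*+1) channel.
6. **Parametrisation** — per segment: sinuous and straight length,
   sinuosity, junction angle, and transect-based cross-sectional width,
   depth and area. Per order: channel counts, lengths, bifurcation
   ratios, shape ratios (A/D², W/D). For the whole network: drainage
   density `DD = TCL / catchment area` (km/km²), overmarsh path length
   (OPL, the mean Euclidean distance from marsh cells to the creek
   system), main channel length (MCL), total channel length (TCL),
   number of creeks (NB), total mouth cross-sectional area (CSA), main
   channel mouth depth (D), planform area (PA), undermarsh tidal prism
   (TP, creek volume below the local bank tops), sinuosity ratio (SR) and
   main channel gradient (MCG).

A threshold-sensitivity analysis re-runs the pipeline with the elevation
threshold shifted by ±0.15 m (the nominal lidar vertical resolution) and
reports per-parameter spreads, and an elevation-change analysis
attributes vertical change between two epochs to creek proximity
(gains against the most recent creek extent, losses against the initial
one). Tidal levels (HAT, MHWS, MHWN, MWS, MLWN, MLWS) can be
interpolated from a port table by inverse-distance weighting within
30 km, with Chart Datum → ODN conversion.

Because real reference datasets require external lidar archives, the
package ships a **synthetic marsh generator** (`marsh_spec()`,
`generate_marsh()`): a platform ringed by a seawall with breaches, a
carved dendritic creek tree with known per-order widths, depths, lengths
and orders, lidar-like Gaussian noise and nodata speckle — so every stage
of the pipeline is testable against exact ground truth.

## Worked example

```r
library(creekmorph)

spec  <- marsh_spec(noise_sigma = 0.05, seed = 1)   # 420 x 420 m marsh
syn   <- generate_marsh(spec)
tides <- tidal_levels(hat = 2.5, mhws = 2.2, mhwn = 1.5,
                      mws = 0, mlwn = -1, mlws = -2)

an <- creek_analysis(syn$grid, syn$truth$config,
                     tides = tides, marsh = syn$marsh)
summary(an)
```

```
Per-order statistics:
 order n_channels total_length mean_length bifurcation_ratio mean_sinuosity
     1          1       258.66      258.66                 2          1.006
     2          2       158.25       79.12                 2          1.026
     3          4        95.66       23.91                NA          1.027
 ...
<network_metrics>
  Drainage density (km/km^2)                 3.00182
  Overmarsh path length (m)                  100.185
  Main channel length (m)                    258.657
  Total channel length (m)                   514.563
  Number of creeks                           7
  Total mouth cross-sectional area (m^2)     9.04654
  Main channel mouth depth (m)               1.37601
  Planform area (m^2)                        2678
  Undermarsh tidal prism (m^3)               2874.59
  Sinuosity ratio                            1.01642
  Main channel gradient (deg)                0.0183506
  Mean elevation above MWS (m)               1.98324
  Catchment area (m^2)                       171417
```

The generator carved one order-1 entry channel of 260 m, two order-2
tributaries of 80 m and four order-3 tributaries of 26 m (total 524 m),
7 m / 5 m / 3 m wide and 1.2 m / 0.9 m / 0.6 m deep: the extracted
channel counts are exact, total length is recovered within 2 %, widths
within a cell or two and depths within the noise level. `plot(an)` draws
the DEM with the skeleton coloured by reverse Strahler order.

For shell use, a thin CLI over the same functions is installed under
`inst/cli/creekmorph.R` (`generate` and `run` subcommands); `run_site()`
writes the full per-epoch output bundle (area and creek XYZ maps, ordered
skeleton XYC map, per-order and network CSVs, sensitivity and change
tables, deterministic run log).

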