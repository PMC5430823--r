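---
title: "Detecting membrane nanodomains from bilayer trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting membrane nanodomains from bilayer trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodomains)
```

## The scientific problem

Binary mixtures of a saturated phospholipid (DPPC) with cholesterol are the
minimal membrane in which cholesterol-driven lateral heterogeneity can
arise. At intermediate cholesterol content and temperatures slightly above
the lipid's main transition, such membranes can organize into nanometre
scale ordered domains rather than macroscopic coexisting phases. The
structure of interest has three concentric ingredients: a hexagonally
packed, cholesterol-poor core; a fluid, ordered, cholesterol-rich annulus
around it; and a disordered background. The ordered regions of the two
leaflets face each other (registration), and cholesterol at the domain
boundary can flip between leaflets.

`nanodomains` provides the quantitative toolkit for finding this structure
in molecular-dynamics trajectories: chain-order statistics and their
decomposition into phase-like components, thickness/order/mobility maps,
interleaflet registration, hexagonal-packing detection, region
classification with domain-area tracking, and flip-flop detection with
boundary localization. Because microsecond trajectories of ~1000-lipid
membranes are not practical test fixtures, the package also contains a
synthetic bilayer generator that reproduces the *statistics* each analysis
consumes, with exact ground truth.

## Chain order

For every C–H bond, `S_CD = <(3 cos^2 theta - 1)/2>` with `theta` the angle
between the bond and the membrane normal (z). Values are reported as
`-S_CD`, so ordered chains score high (gel ~0.4, liquid-ordered ~0.3,
liquid-disordered ~0.2 along the plateau carbons). `per_chain_order()`
averages over both attached hydrogens and all frames of the analysis
window; the per-chain scalar order is the mean over acyl carbons 2–15 by
default (the terminal methyl is noisy, and sn-2 is the conventionally
reported chain). Distributions (`order_distribution()`) are histograms of
the *per-chain time averages*, not of instantaneous values: a membrane
with coexisting ordered and disordered environments then shows a
multimodal distribution even though each instantaneous snapshot is broad.
Default bins are 0.01 wide over [-0.1, 0.55], which resolves the
gel/Lo/Ld modes; both bin edges and averaging window are configurable.
For united-atom inputs without explicit hydrogens, C–H directions can be
reconstructed as the two unit vectors perpendicular to the local
C(i-1)→C(i+1) axis (all-trans geometry); this is off by default and stated
in the output provenance when used.

## Phase decomposition

A heterogeneous distribution is modelled as `sum_i f_i ref_i` over
homogeneous reference distributions with `f_i >= 0`, `sum f_i = 1`,
minimizing squared deviation over all carbon–bin cells (carbons weighted
equally; the histograms are per-carbon normalized so no carbon dominates).
The equality constraint is enforced exactly: the solver enumerates active
sets of the KKT system, which is exact and fast for the 2–12 components
this analysis uses. Collinear (degenerate) reference sets resolve to the
minimum-norm fraction vector through the pseudo-inverse. The reproduction
error is L1-relative, `100 * sum|target - fit| / sum target`, a stated and
testable definition. Fitting uses the full distributions rather than mean
profiles, because mean profiles of different mixtures can coincide while
their distributions cannot.

## Spatial maps

All maps share one periodic grid convention: `N = round(L / cell)` cells
per axis (cells are stretched a fraction of a percent so the grid tiles
the box exactly). The default cell is 0.5 nm and the default smoothing
sigma is 1.0 nm, which resolves a ~10 nm domain with ~20 cells across
while suppressing single-lipid noise.

Surfaces are built from DPPC phosphorus positions only (sterols are not
part of the headgroup surface). Two numerical choices matter here and were
made after explicit failure analysis on ground-truth fixtures:

1. **Nearest-data infill before smoothing.** Regions differ in both lipid
   density and mobility, so they differ in how many distinct grid cells
   their headgroups visit: slow, sparse regions leave many cells empty
   while mobile regions paint most of theirs. Any kernel average taken
   over *observed* cells therefore drags interfaces toward the
   better-sampled side (we measured ~0.1 nm of spurious interface shift
   for a mobility contrast alone). `surface_map()` instead averages
   within cells, fills empty cells from their nearest data by iterative
   4-neighbour averaging, and then smooths all cells with equal weight.
   Interfaces land at the geometric midpoint of the data gap regardless
   of sampling contrast. Cells with no observation within 3 sigma remain
   flagged empty (NaN).
2. **Narrow smoothing for classification maps.** Isotropic smoothing of a
   curved step moves the mid-level contour inward by about
   `sigma^2 / (2R)`; at sigma = 1 nm this biases the area of a 5-nm disc
   by ~4%. Display maps keep sigma = 1.0; classification and
   domain-area tracking default to sigma = 0.5 nm, where the curvature
   bias is below the cell size for any domain larger than ~2 nm.

The thickness map is the upper minus the lower surface. The order map
assigns each chain's time-averaged scalar order to the cell of its
chain-carbon centroid, frame by frame. The jump map accumulates each
lipid's unwrapped in-plane displacement over 1 ns windows (the window is
configurable) at its start cell: gel-like cores show up as near-zero
patches. Registration is measured on the two leaflets' order maps as a
joint histogram over co-located cells plus the Pearson correlation and the
mass within a diagonal band |upper - lower| <= 0.05.

## Packing

Neighbour counting is cutoff-based with the cutoff defaulting to the first
minimum of the periodic 2D RDF computed from the sites themselves — a
self-calibrating choice that needs no prior knowledge of the lattice
constant. For a hexagonal lattice the result is cutoff-independent
anywhere between the first and second shells (`a` to `a*sqrt(3)`). The
RDF's sharp first peak is located on a lightly smoothed curve and then
refined to the raw argmax, since box-filter smoothing alone flattens
delta-like lattice peaks into plateaus. A Voronoi-adjacency alternative is
not provided (no triangulation library is used by the package); the cutoff
construction is the default and the documented method.

Cholesterol partitioning versus thickness (`thickness_occupancy()`)
compares the histogram of local thickness over all cells with the
histogram over cells occupied by at least one sterol ring centroid
("occupied" is per frame, accumulated over frames — the simplest reading
of an occupancy-conditioned histogram). Chain tilt uses the first
principal component of the chain carbons (robust to gauche defects);
"collective tilt" is the mean resultant of the unit in-plane tilt
directions, 0 for azimuthally uncorrelated tilt. Sterol face orientation
compares the in-plane direction from ring centroid to methyl marker (the
rough beta face) with the local order-map gradient; sterols where the
gradient magnitude is below 0.02 nm^-1 are excluded as "no boundary", and
the preference is tested against 0.5 with a binomial test.

## Regions and domain tracking

Classification thresholds on thickness are either user-fixed `(t1, t2)` or
derived automatically by fitting a 3-component Gaussian mixture to the
thickness histogram and placing thresholds at the density crossing points
between adjacent components. The EM fit is initialized from a k-means
partition seeded at evenly spaced values across the data range; quantile
seeding was observed to collapse two components onto a dominant mode when
class sizes are very unequal, which this initialization avoids. Failure to
separate three modes is an explicit error with guidance, not a silent
fallback. Patches smaller than 4 cells (4-connectivity, periodic) are
reassigned to their dominant neighbour class to suppress speckle.
Domain-area tracking splits the trajectory into equal windows, classifies
each window's thickness map, and reports the final/initial ratio of the
ordered-plus-core area — the statistic used for sterol-replacement
(domain-shrinkage) experiments.

## Flip-flop detection

The leaflet trace is the sterol ring-centroid height relative to the
*local* (grid) midplane, so membrane ripples do not fake events. A flip
commits only when the trace, having last been beyond `+delta`, passes
beyond `-delta` and stays on the new side of the midplane for at least
`tau_min` (and symmetrically); excursions confined to `(-delta, +delta)`
never count. Defaults are `delta = 0.4` nm and `tau_min = 1` ns — a
hysteresis-plus-dwell detector whose event count is monotonically
non-increasing in both parameters, which the tests assert. The commit time
and lateral position are taken at the first crossing of the far threshold.
Boundary enrichment compares the fraction of events within a shell of the
region boundary against that shell's area fraction; the area fraction is
probed on a 2x refined sub-lattice so that continuous event positions and
the area measure see the same geometry (cell-centre sampling alone
understates the shell area by several percent at 0.5-nm cells).

## The synthetic generator

The generator targets the statistics the analyses consume, not molecular
realism: chains are rigid rods with decorative hydrogens, domains are
placed, never evolved, and there is no energetics. Key constructions:

- **Order by construction.** Each chain is tilted by `beta` from the
  membrane normal with a fresh uniform azimuth every frame. Its two
  hydrogens are mutually perpendicular and both perpendicular to the
  chain axis, so over that orthonormal triple the three P2 projections
  sum to zero and the two-hydrogen mean of `-S_CD` equals
  `P2(cos beta)/2` *identically*, independent of azimuth. Choosing
  `beta = acos(sqrt((4 S + 1)/3))` realizes any target in [0, 0.5]
  exactly at every frame; targets below zero (down to -0.125) use a
  two-point beta distribution (90 degrees with probability `-4S`, the
  magic angle otherwise). Per-chain spread around the regional target is
  a configurable Gaussian.
- **Regions.** Discs (innermost wins) over one background region, each
  with its own headgroup height, order target, lattice, cholesterol mole
  fraction and mobility. Chain sites sit on hexagonal lattices (an even
  row count keeps the A/B row alternation consistent across the periodic
  wrap) with static jitter per region plus a small per-frame wobble
  (0.02 nm) so RDF peaks have finite width. Sites keep a 0.35-lattice-
  constant clearance from region boundaries, and molecules' random walks
  are rejected outside the same zone, so data gaps at interfaces are
  symmetric. Two row-adjacent chain sites pair into one DPPC (head at
  the pair midpoint); a distance guard prevents pairs from straddling an
  excluded disc. Cholesterol takes single sites at
  `C = x n / (2 - x)` per region, which yields mole fraction
  `x = C/(C + D)` when DPPC uses two sites.
- **Study conditions.** The default three-region membrane uses lattice
  constants from area per lipid — core a = 0.49 nm (0.42 nm^2/lipid,
  gel-like), annulus a = 0.52 (0.47 nm^2, Lo-like), background a = 0.613
  (0.65 nm^2, Ld-like) — order targets 0.42/0.30/0.18, head heights
  2.3/2.1/1.9 nm (bilayer thickness 4.6/4.2/3.8 nm), cholesterol mole
  fractions 0/0.25/0.05 (boundary-enriched annulus, cholesterol-free
  core), and per-frame step widths 0.005/0.02/0.05 nm.
- **Registration modes.** `registered` uses identical region layouts in
  both leaflets. `antiregistered` keeps the geometry and inverts the
  order/thickness scale in the lower leaflet (`S -> Smax + Smin - S`):
  ordered patches face disordered ones everywhere, which is the only
  construction that can reach strong negative interleaflet correlation —
  laterally shifting a disc layout cannot push the Pearson correlation of
  a mostly-background field below about `-f/(1-f)` for domain area
  fraction `f`. `independent` redraws disc centres.
- **Scripts.** Flip-flops are scripted per sterol as (molecule, time):
  the leaflet sign ramps across the midplane over 3 frames and the event
  list is recorded as ground truth. Scheduled disc radii (functions of
  time) implement domain shrinkage; molecules re-evaluate their
  effective region each frame, switching height and order accordingly.

What the generator does *not* emulate: conformational chain disorder
(order enters through rigid tilt, so reconstructed-hydrogen workflows see
idealized geometry), thermal undulations beyond per-frame wobble,
diffusive mixing between regions, energetic coupling between leaflets,
and any kinetics of domain formation. Passing tests therefore demonstrate
that the *analyses* measure what they claim on data with known structure —
not that real membranes behave this way.

## Problem sizes and determinism

The validation suite runs at desk scale: the nanodomain membrane is a
24 x 24 nm box (~850 DPPC + ~180 cholesterol, ~145k particles) over 25
frames; order-target recovery uses 6 x 6 nm patches over 500 frames; the
shrinkage experiment a 16 x 16 nm box over 40 frames. Every stochastic
step draws from one seed (`withr::with_seed` in the generator; the
acceptance script derives per-stage seeds from its `--seed` argument), so
all results are bit-reproducible for a given seed.

## Known limitations

- Orthorhombic boxes only; triclinic input is rejected explicitly.
- The membrane normal is fixed to z; strongly curved or vesicular
  geometries are out of scope.
- Leaflet assignment assumes a bilayer with two populated leaflets;
  micelles or pores will fail the degenerate-geometry checks.
- `fit_mixture()` enumerates active sets and is limited to 12 components.
- The flip-flop detector reports counts and locations, not kinetic rate
  constants.
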