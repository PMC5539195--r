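---
title: "Virtual plasmodium networks over terrain: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual plasmodium networks over terrain: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physarumnet)
```

## The model

`physarumnet` simulates the foraging plasmodium of *Physarum polycephalum*
as a population of identical mobile particles on a 2D lattice, in the
multi-agent tradition in which each particle stands for a hypothetical unit
of gel/sol interaction: the aggregate of particle positions is the
protoplasmic network, and particle motion is the protoplasmic flux within
it. Particles deposit chemoattractant into a discrete floating-point trail
lattice and steer by comparing three sensor readings taken `sensor_offset`
cells ahead at angles \{-SA, 0, +SA\} relative to their heading:

* front maximal (or all sensors equal): keep the heading;
* left or right strictly maximal: rotate by -RA or +RA;
* front strictly minimal with equal sides: rotate RA in a random direction;
* any other tie: keep the heading.

Movement is the classic collision-constrained update: each particle, in a
fresh random permutation per step, tries to advance `step_size` cells along
its heading. If the destination cell is habitable and unoccupied the
particle moves and deposits `deposit` trail units there; otherwise it stays
and adopts a uniform random heading (the "strong" collision response, which
gives robust network minimisation from dense inoculation). The gel matrix's
resistance to flux is exactly these collisions: dense regions are
effectively stiff, open lanes carry flux.

The trail lattice is smoothed each step by a `k x k` mean filter (the
in-bounds neighbourhood mean, so no mass leaks in from outside the grid)
and decays by the factor `1 - decay`. Nutrient sites project
`site_stimulus` trail units into their cell each step before particles
sense, which is what couples the emergent network to the arena's regional
centres.

Population adaptation turns a dense inoculum into a sparse transport
network. Every `growth_interval` steps a particle with between `growth_min`
and `growth_max` particles in its `growth_window` square (itself included)
spawns an offspring into a free 4-neighbour cell; every `shrink_interval`
steps a particle with fewer than `shrink_min` *other* particles in its
`shrink_window` square is removed. Under these rules pores open in the
material, grow, and leave behind a minimised network anchored at the
stimuli. When growth and shrinkage fall on the same step, growth runs
first.

### Terrain coupling

Terrain enters through an 8-bit greyscale heightfield (grey `g` maps to
elevation `g/255`). The coupling is deliberately minimal: sensing is
penalised subtractively, a sensor at cell `c` reading
`trail(c) - height_weight * height(c)`, while movement itself is not
blocked (an optional impassable cutoff `height_cutoff` exists but is off by
default). This single mechanism reproduces both terrain effects of
interest: networks route around high ground, and during adaptation pores
open preferentially at high elevations, since particles drift off ridges
before the network crystallises. Cells outside the grid or off the
habitability mask read `-Inf`, so particles never prefer them; this also
prevents edge-hugging artifacts on masked arenas.

The exact height-coupling mechanism used in the original full-scale runs is
not described at the lattice level anywhere we could consult; subtractive
sensing is this package's own design choice and is flagged as such.

## Parameters and calibration

The defaults are the canonical values of this model family: `SA = RA =
45` degrees, `sensor_offset = 9` cells, `step_size = 1`, `deposit = 5`,
`decay = 0.1`, a 3x3 mean diffusion kernel, growth window 9 with bounds
[1, 10] every 5 steps, shrink window 5 with threshold 1 every 5 steps. All
are exposed in `sim_config()`.

Three defaults were calibrated on the packaged arenas, once, and frozen:

* `site_stimulus = 25.5`. A single-cell stimulus must locally dominate the
  lane trail (which equilibrates around `deposit / decay` = 50 spread over
  a band) for sites to anchor the adapting network. At values of order 1
  the network forms but attaches to arena geometry rather than the sites;
  25.5 — the full grey range of an 8-bit stimulus map — anchors reliably.
* `height_weight = 10`. On the packaged ridge arena (amplitude 0.9) this
  makes the height penalty at the crest comparable to a strong lane trail,
  enough that networks detour and pores localise on the ridge; it is the
  value the terrain experiments use.
* Extraction defaults (below).

The full-scale protocol inoculates the habitable area with 70,000
particles; `target_population` supports exact counts, and `init_density`
seeds each habitable cell independently. Note that a density of exactly 1
freezes the system — no particle can ever move, so no trail forms and no
pores open — so near-full coverage (the terrain experiments use 0.85) is
the meaningful "fully grown" condition.

## Network extraction

A finished run is turned into a region-region adjacency matrix in four
steps: binarize a field at threshold `tau`, repair hairline gaps with one
3x3 morphological closing, thin to a 1-pixel skeleton (Zhang-Suen,
8-connectivity, component-preserving), and resolve the skeleton into a
node/edge graph. Junction cells (3 or more skeleton neighbours) are merged
into Steiner nodes by 8-connected clustering so thick crossings yield one
junction; each site captures its nearest skeleton cell within
`capture_radius`; skeleton components containing no region node — the
"trapped" trail remnants that terrain can strand — are discarded; Steiner
nodes left with degree below 3 are smoothed away. Regions connected by a
path whose interior nodes are all Steiner nodes count as directly adjacent,
at unlimited depth by default (a `strict` mode allows at most one
intermediate junction, the minimal reading of a single-junction example).

The digitisation rule for simulated trails is not fixed by any published
description, so its three knobs are package decisions, calibrated jointly
on the flat three-site protocol and then frozen:

* source: the **trail field** (smoothed once with the diffusion kernel),
  not particle occupancy. The trail carries both the lanes and the
  stimulus dots at the sites — exactly the bright features a digitized
  network image shows — so sites remain attached to the network they
  anchor; occupancy lacks the anchor and loses sites in a third of runs.
* `tau = deposit / 2` on that field; one closing iteration bridges the
  occasional one-cell gap where a lane momentarily dips below threshold.
* `capture_radius = 12` cells: thinning extracts the centreline of trail
  bands that are commonly ~20 cells wide at these densities, so a site
  engulfed by a band can legitimately sit up to half a band width from the
  skeleton.

With these settings the flat three-site protocol connected all sites in
40 of 40 calibration runs across two disjoint seed sets.

## The replicate-statistics layer

Replicate experiments are summarised as a weighted Physarum graph
P = (C, R, p): regions C, the union R of observed region-region edges, and
per-edge frequency p = count/N over N replicates, kept as exact rationals.
The threshold transform T(R) retains edges with p(e) >= theta. Two
published phrasings of this rule conflict (prose says edges "less than or
equal to theta are removed", the displayed rule keeps at equality); this
package follows the displayed keep-at-equality rule, which is also the only
reading consistent with transitions phrased as thresholds being
*exceeded*. Thresholds can be given as `"k/N"` strings or integer counts,
both compared exactly (`count * b >= a * N`), so no float round-off can
flip an equality case.

Planarity is decided exactly by Demoucron's face-embedding algorithm
(per biconnected block; the embedding's faces are returned as a
certificate). The edge-count statistics use the sample (n-1) standard
deviation; whether the published figure used the sample or population
estimator cannot be verified because the underlying replicate sets were
never released. Mean-degree rankings break ties by region name, descending
mean degree first; the published tables show near-ties but no tie rule.

## Fixtures and what they do (and do not) show

The 13 laboratory replicate adjacency sets behind the published threshold
analysis are unpublished. `lab_fixture()` therefore ships an **openly
synthetic** edge-observation table over the 17 regional centres,
constructed only from the qualitative transitions that analysis reports
(planarity at 2/13, the Tomis and Sirmium-Singidunum detachments above
3/13, the four isolates at 6/13, the three triads at 7/13, the lone
Traianoupolis-Hadrianopolis edge at 10/13), and validated against every
one of those constraints at construction time. Passing the fixture sweep
shows the *analysis code* reproduces the reported transition structure; it
says nothing about the laboratory data themselves. One published
inconsistency is resolved in the fixture's favourite reading: an edge that
survives to 10/13 necessarily also survives at 7/13, so the "three
segments" at 7/13 are taken to be the three-node segments, with the
long-lived two-node segment also present.

Similarly, `synth_heightfield()` builds terrains as clipped sums of
anisotropic Gaussian ridges. These share with real elevation rasters the
features the model responds to (smooth gradients, ridges with passes around
them) but none of the fractal roughness, drainage structure, or coastline
masking of satellite-derived terrain; the packaged demo site list for the
Balkans is likewise approximate and non-authoritative
(`balkans_sites_synthetic.csv`). Results on these fixtures validate
mechanisms, not geography.

## Study protocols and problem sizes

Two scaled-down protocols are packaged as functions so the same procedure
runs in tests, the acceptance script, and interactive use:

* `connectivity_experiment()`: flat 200x200 arena, three equilateral
  sites, 6,000 particles, 2,000 adaptation steps per seed; measures whether
  the extracted network connects all three sites.
* `terrain_experiment()`: 200x200 ridge arena, inoculation density 0.85,
  1,000 steps, run per seed with `height_weight` 10 and 0; measures the
  mean elevation under network cells (avoidance) and the split of empty
  cells above/below the arena's median elevation (pore localisation).

These sizes were chosen as the smallest at which the three qualitative
phenomena — network formation spanning the stimuli, terrain avoidance, and
high-ground pores — are stable across seeds. Twenty seeds per experiment
estimate the success fraction.

## Numerical choices and degenerate inputs

* All simulation randomness flows from one PCG32 stream seeded from
  `cfg$seed`, consumed in a fixed documented order (shuffle, steering
  ties, collision re-orientation, spawn placement), so trajectories are
  bit-reproducible for a given (arena, config, seed) independent of R's
  RNG state.
* Sensor and movement targets discretise continuous positions with
  round-half-away-from-zero (`llround`), matching the storage convention
  that a particle's cell is its rounded position.
* Heights are normalised to [0, 1]; `height_weight` absorbs the 8-bit
  scale.
* The diffusion mean filter divides by the in-bounds neighbourhood size,
  so border cells neither gain nor invent mass; the toroidal variant
  (used for mass-balance verification) multiplies total mass by exactly
  `1 - decay`.
* Degenerate cases are defined, not errors: zero steps returns the
  inoculated state; an empty site list projects nothing; an empty or
  all-below-threshold field yields a skeleton with no edges and isolated
  region nodes; a site more than `capture_radius` from any skeleton cell
  becomes an isolated region node.
* Two sites capturing the same skeleton cell are kept as distinct region
  nodes joined by a zero-length link (they are trivially adjacent).

## Known limitations

* The substrate is a heightfield-modulated plane, not a voxel volume: no
  overhangs, bridges, or true 3D flow, and no oscillatory shuttle
  streaming or nutrient depletion.
* Stimulus projection is unconditional; the refinement that suppresses
  projection while a site is occupied is omitted, which can slightly
  over-brighten site cells in long runs.
* Demoucron's algorithm is quadratic and run per biconnected block —
  exact and fast for region-scale graphs (tens of nodes), not meant for
  thousands of vertices.
* Extraction calibration targets the packaged 200x200 protocols; other
  arena scales may need `tau`, `closing`, or `capture_radius` revisited
  in proportion to band width.
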