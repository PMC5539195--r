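# physarumnet

Slime-mould-inspired transport network formation over terrain, in R.

The plasmodium of *Physarum polycephalum* spans sources of nutrients with a
network of protoplasmic tubes that approximates efficient proximity graphs,
which has made it a popular biological analogue for evaluating human
transport networks. `physarumnet` implements the computational side of that
research programme for terrain-aware settings:

1. **A multi-agent virtual plasmodium.** A population of particles on a 2D
   lattice, each a hypothetical unit of gel/sol interaction: particles
   sense a shared chemoattractant trail with three offset sensors, move
   under collision constraints, deposit trail, and grow/shrink by local
   density rules. Inoculated as a dense mass, the population opens pores
   and minimises into a stable transport network anchored at nutrient
   sites. A greyscale heightfield (pixel intensity = topographic height)
   modulates sensing subtractively, so networks route around high ground
   and pores open preferentially on it.
2. **Network extraction.** Trail images are binarized, thinned to 1-pixel
   skeletons (Zhang–Suen), and resolved into graphs of region nodes and
   Steiner (junction) nodes; regions joined through Steiner nodes count as
   directly connected, yielding a region–region adjacency matrix per
   replicate.
3. **Physarum-graph statistics.** Replicates aggregate into the weighted
   graph **P** = (**C**, **R**, p) with exact rational edge frequencies
   p(e) = count/N. The threshold transform T(**R**) keeps edges with
   p(e) ≥ θ; sweeping θ (equivalently an integer edge weight w = θN)
   reveals connectivity transitions. Reports include connected components,
   isolated regions, exact planarity (Demoucron's embedding algorithm),
   per-replicate edge-count statistics, and mean-degree rankings.

Everything runs offline: seeded synthetic terrains, packaged test arenas,
and an openly synthetic 13-replicate fixture over 17 regional centres
(built to the qualitative threshold transitions reported for the Balkans
study; the original laboratory data are unpublished) make every stage
testable without downloads.

## Worked example

Threshold analysis of the packaged replicate fixture:

```r
library(physarumnet)

fx <- lab_fixture()
P  <- build_physarum_graph(fx)
glance(P)
#> # A tibble: 1 × 6
#>   n_regions n_edges n_replicates n_components n_isolated planar
#>       <int>   <int>        <int>        <int>      <int> <lgl>
#> 1        17      23           13            1          0 FALSE

edge_probability(3, 13)   # the worked frequency example
#> 3/13 = 0.230769
```

The union graph over all 13 replicates is connected and non-planar; the
transition structure appears under thresholding. At θ = 7/13 the surviving
multi-node segments are three triads plus the single most persistent edge:

```r
rep7 <- connectivity_report(threshold_graph(P, "7/13"))
rep7$components[lengths(rep7$components) >= 2]
#> [[1]] "Thessaloniki"  "Philippoi"     "Scupi"
#> [[2]] "Nicopolis"     "Dyrrachium"    "Doclea"
#> [[3]] "Serdica"       "Remesiana"     "Philippopolis"
#> [[4]] "Traianoupolis" "Hadrianopolis"

edge_count_stats(fx)[c("mean", "sd")]   # per-replicate edge counts
#> $mean [1] 8.615385
#> $sd   [1] 1.260725

head(mean_degree_table(fx), 3)
#> # A tibble: 3 × 3
#>   region       mean_degree  rank
#> 1 Thessaloniki        1.77     1
#> 2 Dyrrachium          1.62     2
#> 3 Hadrianopolis       1.62     3
```

`mean_degree_table()` ranks regions by their degree averaged over
replicates — the influence ranking used to compare terrain and no-terrain
conditions. A full simulate → extract → aggregate round trip:

```r
arena <- triangle_arena()                       # flat 200x200, 3 sites
cfg   <- sim_config(steps = 2000, target_population = 6000, seed = 1)
state <- run_simulation(arena, cfg)
rec   <- extract_network(state, arena, cfg)     # region adjacency matrix
tidy(rec)                                       # observed region pairs
```

`autoplot()` methods render arenas, trail fields, and Physarum graphs;
`ridge_arena()` provides the two-site terrain testbed, and
`terrain_experiment()` / `connectivity_experiment()` run the packaged
multi-seed protocols.

A command-line pipeline wraps the same functions:

```sh
Rscript inst/cli/physarumnet.R simulate --config inst/config/default.yaml \
    --replicates 20 --seed 1 --out runs/
Rscript inst/cli/physarumnet.R report --records runs/ --theta 4/13,7/13
```

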