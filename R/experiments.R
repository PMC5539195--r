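#' Replicate connectivity experiment on the flat three-site arena
#'
#' The scaled-down full-coverage adaptation protocol: on [triangle_arena()],
#' 6,000 particles adapt for 2,000 steps under three nutrient stimuli; the
#' emergent network is extracted and the experiment asks whether all three
#' sites end up in one connected component. One independent simulation per
#' seed.
#'
#' @param seeds integer vector of seeds (one replicate each).
#' @param steps,particles protocol size (defaults are the study conditions).
#' @param cfg optional base [sim_config()]; `steps`, `target_population` and
#'   `seed` are overridden per replicate.
#' @return A tibble: `seed`, `n_edges`, `connected`.
#' @export
connectivity_experiment <- function(seeds = 1:20, steps = 2000L,
                                    particles = 6000L, cfg = sim_config()) {
  arena <- triangle_arena()
  purrr::map_dfr(seeds, function(s) {
    cfg$steps <- as.integer(steps)
    cfg$target_population <- as.integer(particles)
    cfg$seed <- as.integer(s)
    st <- run_simulation(arena, cfg)
    rec <- extract_network(st, arena, cfg, replicate_id = s)
    g <- igraph::graph_from_adjacency_matrix(unclass(rec),
                                             mode = "undirected")
    tibble::tibble(seed = s, n_edges = sum(rec) / 2,
                   connected = igraph::is_connected(g))
  })
}

#' Terrain modulation experiment on the ridge arena
#'
#' For each seed, runs the near-full-coverage adaptation on [ridge_arena()]
#' twice — once with the height penalty active and once with it off — and
#' measures two terrain effects:
#'
#' * **avoidance**: the mean elevation under network cells (the binarized
#'   trail band) is lower with the penalty than without, i.e. the network
#'   routes around high ground;
#' * **pore localisation**: among habitable cells left empty after
#'   adaptation under the penalty, more lie above the arena's median
#'   elevation than below it, i.e. pores open preferentially on high
#'   ground.
#'
#' @param seeds integer vector of seeds.
#' @param steps adaptation steps per run.
#' @param init_density inoculation density (near-full coverage; exactly 1
#'   freezes the lattice since no particle could ever move).
#' @param height_weight the active height penalty w_h.
#' @param cfg optional base [sim_config()].
#' @return A tibble per seed: `seed`, `elev_height` and `elev_flat` (mean
#'   network elevation with/without penalty), `avoidance` (logical),
#'   `pores_above`, `pores_below`, `pore_localised` (logical).
#' @export
terrain_experiment <- function(seeds = 1:20, steps = 1000L,
                               init_density = 0.85, height_weight = 10,
                               cfg = sim_config()) {
  arena <- ridge_arena()
  hf <- unclass(arena$heightfield)
  med <- stats::median(hf[arena$mask])
  net_mask <- function(st, cfg) {
    field <- cpp_diffuse_decay(st$trail, cfg$diffusion_kernel, 0, FALSE)
    close_mask(binarize_trails(field, cfg$deposit / 2), 1L)
  }
  purrr::map_dfr(seeds, function(s) {
    cfg$steps <- as.integer(steps)
    cfg$init_density <- init_density
    cfg$target_population <- NULL
    cfg$seed <- as.integer(s)
    cfg$height_weight <- height_weight
    st_h <- run_simulation(arena, cfg)
    cfg$height_weight <- 0
    st_0 <- run_simulation(arena, cfg)
    elev_h <- mean(hf[net_mask(st_h, cfg)])
    elev_0 <- mean(hf[net_mask(st_0, cfg)])
    empty <- arena$mask & !(st_h$occupancy > 0)
    above <- sum(hf[empty] > med)
    below <- sum(hf[empty] < med)
    tibble::tibble(
      seed = s, elev_height = elev_h, elev_flat = elev_0,
      avoidance = elev_h < elev_0,
      pores_above = above, pores_below = below,
      pore_localised = above > below
    )
  })
}
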