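#' Simulation configuration
#'
#' Parameters of the multi-agent virtual plasmodium. Defaults are the
#' canonical values of the three-sensor particle model family; all are
#' exposed because published descriptions of such runs rarely restate them.
#'
#' @param sensor_angle sensor arm angle SA, degrees in (0, 180); the left and
#'   right sensors sit at heading +/- SA.
#' @param rotation_angle rotation step RA, degrees in (0, 180).
#' @param sensor_offset sensor distance SO ahead of the particle, cells.
#' @param step_size forward step SS per update, cells.
#' @param deposit trail deposited on a successful move, trail units.
#' @param decay trail decay fraction per step, in `[0, 1)`.
#' @param diffusion_kernel odd width of the mean-filter diffusion kernel.
#' @param height_weight subtractive height penalty w_h applied during sensing
#'   (trail units per unit normalised elevation); 0 disables terrain
#'   modulation. The default is calibrated on the packaged ridge arena so
#'   that networks route around high ground.
#' @param site_stimulus nutrient stimulus w_f projected into the trail at
#'   each region site every step. It must dominate the local lane trail for
#'   sites to anchor the adapting network; with deposit 5 and decay 0.1 the
#'   default 25.5 (the full grey-scale range of an 8-bit stimulus map) does,
#'   while values of order 1 leave the network anchored to arena geometry
#'   instead of the nutrient sites.
#' @param init_density inoculation density d0 in (0, 1]: each habitable cell
#'   is independently seeded with this probability.
#' @param target_population optional exact initial particle count (used
#'   instead of `init_density` when given); the full-scale Balkans runs of
#'   the source model used 70,000 particles.
#' @param growth_window,growth_min,growth_max,growth_interval growth rule:
#'   every `growth_interval` steps, a particle whose `growth_window` square
#'   window holds between `growth_min` and `growth_max` particles (itself
#'   included) spawns one offspring into a random free 4-neighbour cell.
#'   `growth_interval = 0` disables growth.
#' @param shrink_window,shrink_min,shrink_interval shrink rule: every
#'   `shrink_interval` steps, a particle with fewer than `shrink_min` other
#'   particles in its `shrink_window` square window is removed.
#'   `shrink_interval = 0` disables shrinkage.
#' @param height_cutoff optional impassable elevation h_max: cells at or
#'   above it block movement (sensing already penalises them). `NULL`
#'   disables the cutoff.
#' @param steps number of simulation steps for [run_simulation()].
#' @param seed integer seed of the simulator's own PCG32 generator.
#' @param snapshot_every record trail/occupancy snapshots every this many
#'   steps (0 = none).
#' @return A `sim_config` list.
#' @export
sim_config <- function(sensor_angle = 45, rotation_angle = 45,
                       sensor_offset = 9, step_size = 1, deposit = 5,
                       decay = 0.1, diffusion_kernel = 3L,
                       height_weight = 10, site_stimulus = 25.5,
                       init_density = 1, target_population = NULL,
                       growth_window = 9L, growth_min = 1L, growth_max = 10L,
                       growth_interval = 5L, shrink_window = 5L,
                       shrink_min = 1L, shrink_interval = 5L,
                       height_cutoff = NULL, steps = 2000L, seed = 1L,
                       snapshot_every = 0L) {
  cfg <- list(
    sensor_angle = sensor_angle, rotation_angle = rotation_angle,
    sensor_offset = sensor_offset, step_size = step_size, deposit = deposit,
    decay = decay, diffusion_kernel = as.integer(diffusion_kernel),
    height_weight = height_weight, site_stimulus = site_stimulus,
    init_density = init_density, target_population = target_population,
    growth_window = as.integer(growth_window),
    growth_min = as.integer(growth_min),
    growth_max = as.integer(growth_max),
    growth_interval = as.integer(growth_interval),
    shrink_window = as.integer(shrink_window),
    shrink_min = as.integer(shrink_min),
    shrink_interval = as.integer(shrink_interval),
    height_cutoff = height_cutoff,
    steps = as.integer(steps), seed = as.integer(seed),
    snapshot_every = as.integer(snapshot_every)
  )
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  stopifnot_msg(cfg$decay >= 0 && cfg$decay < 1, "decay must be in [0, 1)")
  stopifnot_msg(cfg$sensor_angle > 0 && cfg$sensor_angle < 180,
                "sensor_angle must be in (0, 180)")
  stopifnot_msg(cfg$rotation_angle > 0 && cfg$rotation_angle < 180,
                "rotation_angle must be in (0, 180)")
  stopifnot_msg(cfg$sensor_offset >= 1, "sensor_offset must be >= 1")
  stopifnot_msg(cfg$init_density > 0 && cfg$init_density <= 1,
                "init_density must be in (0, 1]")
  stopifnot_msg(cfg$diffusion_kernel %% 2L == 1L,
                "diffusion_kernel must be odd")
  stopifnot_msg(cfg$steps >= 0, "steps must be >= 0")
  invisible(cfg)
}

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

new_sim_state <- function(particles, trail, occupancy, step, rng) {
  structure(
    list(particles = particles, trail = trail, occupancy = occupancy,
         step = step, rng = rng),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> step %d, %d particles, total trail %.2f\n",
              x$step, nrow(x$particles), sum(x$trail)))
  invisible(x)
}

particles_tbl <- function(res) {
  tibble::tibble(
    row = res$row, col = res$col, heading = res$heading,
    cell_row = as.integer(round(res$row)),
    cell_col = as.integer(round(res$col))
  )
}

#' Inoculate a full-coverage virtual plasmodium
#'
#' Seeds the arena with particles, emulating inoculation "as a single mass":
#' with `init_density` d0, each habitable cell is independently occupied with
#' probability d0 (d0 = 1 fills every habitable cell); with
#' `target_population` set, exactly that many distinct habitable cells are
#' occupied. Headings are uniform random; the trail field starts at zero.
#' Deterministic given the config seed.
#'
#' @param arena an [make_arena()] arena.
#' @param cfg a [sim_config()].
#' @param seed optional seed override (defaults to `cfg$seed`).
#' @return A `sim_state`.
#' @export
inoculate_full <- function(arena, cfg = sim_config(), seed = NULL) {
  validate_config(cfg)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  res <- cpp_inoculate(arena$mask, cfg$init_density, cfg$target_population,
                       seed)
  trail <- matrix(0, nrow(arena$mask), ncol(arena$mask))
  new_sim_state(particles_tbl(res), trail, res$occupancy, 0L, res$rng)
}

#' Effective sensed value at a cell
#'
#' What a particle sensor reads: the chemoattractant trail minus the height
#' penalty `w_h * height`. Cells outside the grid or off the habitability
#' mask read `-Inf`, so they are never preferred.
#'
#' @param trail numeric trail matrix.
#' @param heightfield optional [heightfield()] (`NULL` = no-height).
#' @param cell length-2 integer vector, 0-based `(row, col)`.
#' @param height_weight penalty weight w_h.
#' @param mask optional logical habitability matrix (default: all habitable).
#' @return A scalar, possibly `-Inf`.
#' @export
effective_value <- function(trail, heightfield = NULL, cell,
                            height_weight = 0, mask = NULL) {
  r <- cell[1] + 1L
  c <- cell[2] + 1L
  if (r < 1 || r > nrow(trail) || c < 1 || c > ncol(trail)) return(-Inf)
  if (!is.null(mask) && !mask[r, c]) return(-Inf)
  v <- trail[r, c]
  if (!is.null(heightfield)) v <- v - height_weight * heightfield[r, c]
  v
}

#' Three-sensor steering rule
#'
#' Samples the effective trail value at three sensors `sensor_offset` cells
#' ahead at angles `{-SA, 0, +SA}` relative to the heading. If the front
#' sensor is maximal (or all are equal) the heading is unchanged; if the left
#' (right) sensor is strictly maximal the particle rotates by `-RA` (`+RA`);
#' if the front reads strictly less than both sides and the sides tie, the
#' rotation direction is a single random draw. Other ties leave the heading
#' unchanged.
#'
#' @param particle list or one-row data frame with `row`, `col`, `heading`.
#' @param trail trail matrix.
#' @param arena arena (mask and optional heightfield).
#' @param cfg [sim_config()].
#' @param rng 16-byte raw PCG32 state ([sim_rng()]).
#' @return List with the new `heading` and advanced `rng` state.
#' @export
sense_and_steer <- function(particle, trail, arena, cfg = sim_config(),
                            rng = sim_rng(1)) {
  hf <- if (is.null(arena$heightfield)) NULL else unclass(arena$heightfield)
  res <- cpp_steer(particle$heading, particle$row, particle$col, trail,
                   arena$mask, hf, cfg, rng)
  list(heading = res$heading, rng = res$rng)
}

#' One motor pass over all particles
#'
#' Processes particles in a fresh random permutation. Each particle first
#' applies the steering rule, then attempts to advance `step_size` along its
#' heading: if the destination cell is habitable and unoccupied it moves and
#' deposits `deposit` trail there; otherwise (collision, boundary, or
#' impassable elevation) it stays put, adopts a uniform random heading, and
#' deposits nothing.
#'
#' @param state a `sim_state`.
#' @param arena the arena.
#' @param cfg [sim_config()].
#' @return Updated `sim_state`.
#' @export
motor_step <- function(state, arena, cfg = sim_config()) {
  hf <- if (is.null(arena$heightfield)) NULL else unclass(arena$heightfield)
  res <- cpp_move_pass(state$particles$row, state$particles$col,
                       state$particles$heading, state$trail, arena$mask, hf,
                       cfg, state$rng)
  new_sim_state(particles_tbl(res), res$trail, res$occupancy,
                state$step, res$rng)
}

#' Project nutrient stimuli at region sites
#'
#' Adds `site_stimulus` to the trail at every site cell (sites sharing a
#' cell accumulate additively); all other cells are unchanged.
#'
#' @param trail trail matrix.
#' @param sites site tibble with 0-based `row`, `col`.
#' @param site_stimulus stimulus w_f per site per step.
#' @return The updated trail matrix.
#' @export
project_stimuli <- function(trail, sites, site_stimulus = 2.55) {
  if (NROW(sites) == 0L) return(trail)
  if (any(sites$row < 0 | sites$row >= nrow(trail) |
          sites$col < 0 | sites$col >= ncol(trail))) {
    stop("site outside grid", call. = FALSE)
  }
  for (i in seq_len(nrow(sites))) {
    trail[sites$row[i] + 1L, sites$col[i] + 1L] <-
      trail[sites$row[i] + 1L, sites$col[i] + 1L] + site_stimulus
  }
  trail
}

#' Diffuse and decay the trail field
#'
#' Each cell is replaced by the mean of its in-bounds `k x k` neighbourhood
#' and then multiplied by `1 - decay`. Non-negativity is preserved. The
#' toroidal variant wraps at the edges (used for exact mass-balance checks:
#' on a torus total mass is multiplied by exactly `1 - decay`).
#'
#' @param trail trail matrix.
#' @param cfg [sim_config()] supplying `diffusion_kernel` and `decay`.
#' @param toroidal wrap at the edges instead of truncating the kernel.
#' @return The new trail matrix.
#' @export
diffuse_decay <- function(trail, cfg = sim_config(), toroidal = FALSE) {
  if (cfg$diffusion_kernel %% 2L != 1L) {
    stop("diffusion_kernel must be odd", call. = FALSE)
  }
  cpp_diffuse_decay(trail, cfg$diffusion_kernel, cfg$decay, toroidal)
}

#' Population adaptation (growth and shrinkage)
#'
#' Applies the growth and/or shrink passes described in [sim_config()], each
#' as one randomized-order sweep over the current particles. Growth spawns
#' offspring into free 4-neighbour cells; shrinkage removes particles with
#' fewer than `shrink_min` other particles in their window.
#'
#' @param state a `sim_state`.
#' @param arena the arena.
#' @param cfg [sim_config()].
#' @param do_growth,do_shrink which passes to apply.
#' @return Updated `sim_state`.
#' @export
adapt_population <- function(state, arena, cfg = sim_config(),
                             do_growth = TRUE, do_shrink = TRUE) {
  hf <- if (is.null(arena$heightfield)) NULL else unclass(arena$heightfield)
  res <- cpp_adapt(state$particles$row, state$particles$col,
                   state$particles$heading, state$trail, arena$mask, hf, cfg,
                   do_growth, do_shrink, state$rng)
  new_sim_state(particles_tbl(res), res$trail, res$occupancy,
                state$step, res$rng)
}

#' Fresh PCG32 state for the simulator
#' @param seed integer seed.
#' @return A 16-byte raw vector.
#' @export
sim_rng <- function(seed) cpp_rng_new(as.numeric(seed))

#' Run the virtual plasmodium to completion
#'
#' Full pipeline, per step: project stimuli at the sites, one shuffled
#' sense-and-move pass over all particles, population adaptation on its
#' schedule (growth pass before shrink pass when both fall on a step), then
#' trail diffusion and decay. Bit-reproducible given `(arena, cfg, seed)`:
#' all randomness flows from one PCG32 stream in a fixed documented order
#' (permutation draws, steering ties, collision re-orientation, spawn
#' placement).
#'
#' @param arena an arena.
#' @param cfg a [sim_config()]; `cfg$steps` steps are run (`steps = 0`
#'   returns the inoculated state unchanged).
#' @param state optional starting `sim_state` (default: [inoculate_full()]).
#' @param check_exclusion assert after every step that no two particles share
#'   a cell and all sit on habitable cells (debug mode).
#' @return A `sim_state` with extra fields `population` (per-step particle
#'   counts) and `snapshots` (list of trail/occupancy matrices when
#'   `snapshot_every > 0`).
#' @export
run_simulation <- function(arena, cfg = sim_config(), state = NULL,
                           check_exclusion = FALSE) {
  validate_config(cfg)
  if (is.null(state)) state <- inoculate_full(arena, cfg)
  if (cfg$steps == 0L) return(state)
  hf <- if (is.null(arena$heightfield)) NULL else unclass(arena$heightfield)
  sites_rc <- cbind(arena$sites$row, arena$sites$col)
  storage.mode(sites_rc) <- "integer"
  res <- cpp_run(state$particles$row, state$particles$col,
                 state$particles$heading, state$trail, arena$mask, hf,
                 sites_rc, cfg, cfg$steps, state$rng, cfg$snapshot_every,
                 check_exclusion)
  out <- new_sim_state(particles_tbl(res), res$trail, res$occupancy,
                       state$step + cfg$steps, res$rng)
  out$population <- res$population
  if (cfg$snapshot_every > 0L) {
    out$snapshots <- list(step = res$snapshot_steps,
                          trail = res$snapshot_trail,
                          occupancy = res$snapshot_occupancy)
  }
  out
}

#' Particle occupancy as a binary matrix
#' @param state a `sim_state`.
#' @return Numeric 0/1 matrix of occupied cells.
#' @export
occupancy_matrix <- function(state) {
  (state$occupancy > 0) * 1
}

#' Write run snapshots to disk
#'
#' Exports the trail field as 16-bit PGM (rescaled to the snapshot maximum)
#' and particle occupancy as 8-bit PGM, one pair per sampled step, plus a
#' JSON sidecar echoing the configuration and seed.
#'
#' @param state a `sim_state` from [run_simulation()] with snapshots.
#' @param dir output directory (created if needed).
#' @param cfg the config to echo into the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_snapshots <- function(state, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snaps <- state$snapshots
  if (!is.null(snaps)) {
    for (i in seq_along(snaps$step)) {
      tr <- snaps$trail[[i]]
      mx <- max(tr, 1e-12)
      write_pgm(round(tr / mx * 65535),
                file.path(dir, sprintf("trail_%06d.pgm", snaps$step[[i]])),
                maxval = 65535L)
      write_pgm((snaps$occupancy[[i]] > 0) * 255L,
                file.path(dir, sprintf("occupancy_%06d.pgm", snaps$step[[i]])))
    }
  }
  sidecar <- file.path(dir, "run.json")
  meta <- list(step = state$step, n_particles = nrow(state$particles))
  if (!is.null(cfg)) {
    meta$config <- cfg[!vapply(cfg, is.null, logical(1))]
  }
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}
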