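# Default run configuration for the physarumnet CLI.
# CLI flags (--replicates, --seed, --height/--no-height, --out) override
# the values here.

# Arena: either a packaged fixture name ("triangle" or "ridge") or explicit
# raster/CSV paths. For explicit input, supply an 8-bit greyscale mask
# raster (non-zero grey = habitable), a sites CSV with header
# region_id,name,row,col (0-based coordinates), and optionally an 8-bit
# greyscale heightfield raster of the same dimensions.
arena:
  fixture: triangle
  # mask: arena_mask.pgm
  # sites: sites.csv
  # heightfield: terrain.pgm

# Use the heightfield (terrain condition) or ignore it (no-height condition).
use_height: true

# Number of replicate simulations; replicate r uses seed base_seed + r - 1.
replicates: 1
base_seed: 1

# Output directory for adjacency CSVs, manifest, and optional snapshots.
out: physarumnet_run

# Write trail/occupancy PGM snapshots per replicate (16-bit / 8-bit).
snapshots: false

# Simulation parameters (defaults shown; see ?sim_config for units).
sim:
  steps: 2000          # adaptation steps
  target_population: 6000  # exact particle count; omit to use init_density
  # init_density: 0.85 # per-cell inoculation probability when no target
  sensor_angle: 45     # degrees
  rotation_angle: 45   # degrees
  sensor_offset: 9     # cells
  step_size: 1         # cells per step
  deposit: 5           # trail units per successful move
  decay: 0.1           # trail decay fraction per step
  diffusion_kernel: 3  # odd kernel width (mean filter)
  height_weight: 10    # subtractive sensing penalty per unit elevation
  site_stimulus: 25.5  # trail units projected at each site per step
  growth_interval: 5   # steps between growth events (0 disables)
  shrink_interval: 5   # steps between shrink events (0 disables)

# Network extraction (see ?extract_network).
extract:
  source: trail        # "trail" or "occupancy"
  # tau: 2.5           # binarization threshold; default deposit/2
  closing: 1           # morphological closing iterations
  capture_radius: 12   # site capture distance in cells
  strict: false        # restrict Steiner transparency to one junction
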