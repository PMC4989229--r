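# Shared fixtures and independent oracles. All fixtures are generated in
# code; sizes are kept small (256^2 rasters) so the full suite stays fast.

# Compact well: 1.6 mm well, 0.5 mm zone, 256 x 256 raster.
small_geom <- function(zone_center_offset = c(0, 0))
  well_geometry(800, 250, zone_center_offset = zone_center_offset,
                pixel_size = 6.25)

# Confluent-scale configuration for the small well (similar areal density to
# the default full-size assay).
quick_cfg <- function(n_cells = 3000, duration = 6, speed = 60, ...)
  assay_config(n_cells = n_cells, duration = duration, speed = speed, ...)

quick_channel <- function(name = "violet", psf_sigma = 15, ...)
  channel_spec(name, psf_sigma = psf_sigma, ...)

# Hand-built cell table.
make_cells <- function(x, y, dye_violet = 1, dye_farred = 0, generation = 0L,
                       heading = 0) {
  n <- length(x)
  data.frame(cell_id = seq_len(n), lineage_id = seq_len(n),
             generation = as.integer(rep_len(generation, n)),
             x_um = x, y_um = y, heading = rep_len(heading, n),
             dye_violet = rep_len(dye_violet, n),
             dye_farred = rep_len(dye_farred, n), alive = rep_len(TRUE, n))
}

# Positions with a guaranteed minimum pairwise separation (rejection
# placement), for fixtures whose contract assumes non-overlapping spots.
separated_positions <- function(n, r_max, min_sep) {
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    x <- stats::runif(1, -r_max, r_max); y <- stats::runif(1, -r_max, r_max)
    if (x^2 + y^2 > r_max^2) next
    if (length(xs) && any((xs - x)^2 + (ys - y)^2 < min_sep^2)) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  cbind(xs, ys)
}

# Integer-pixel translation of a raster (zero fill), emulating a well imaged
# off the raster center.
shift_raster <- function(m, dx, dy) {
  w <- ncol(m)
  out <- matrix(0, nrow(m), w)
  sr <- seq_len(nrow(m)) - dy
  sc <- seq_len(w) - dx
  ok_r <- sr >= 1 & sr <= nrow(m)
  ok_c <- sc >= 1 & sc <= w
  out[ok_r, ok_c] <- m[sr[ok_r], sc[ok_c]]
  out
}

# Independent brute-force ROI intensity oracle: explicit per-row boolean
# masks and explicit clipping, sharing no code with the package's
# vectorized path.
oracle_roi_sum <- function(pixels, center, radius, bg) {
  total <- 0
  for (i in seq_len(nrow(pixels))) {
    y <- i - 1
    for_row <- pixels[i, ]
    xs <- seq_len(ncol(pixels)) - 1
    inside <- (xs - center[1])^2 + (y - center[2])^2 <= radius^2
    if (any(inside)) {
      v <- for_row[inside] - bg
      v[v < 0] <- 0
      total <- total + sum(v)
    }
  }
  total
}

oracle_background <- function(pixels, center, radius) {
  keep <- c()
  for (i in seq_len(nrow(pixels))) {
    y <- i - 1
    xs <- seq_len(ncol(pixels)) - 1
    outside <- (xs - center[1])^2 + (y - center[2])^2 > radius^2
    keep <- c(keep, pixels[i, outside])
  }
  stats::median(keep)
}

# 20x-magnification-scale field used for per-cell cytometry fixtures.
cyto_geom <- function() well_geometry(1100, 100, pixel_size = 2)
cyto_channel <- function(name) channel_spec(name, psf_sigma = 5)

# Mixed and single-labeled co-culture images plus the simulator's
# ground-truth transferred-mass ledger.
mixed_culture_images <- function(tau, seed = 17, n_cells = 300) {
  tg <- cyto_geom()
  cfg <- assay_config(n_cells = n_cells, duration = 24, dt = 0.1, speed = 10,
                      transfer_rate = tau, transfer_radius = 25,
                      rng_seed = seed, seed_exclusion = FALSE)
  sim <- run_mixed_culture(cfg, tg)
  sv <- run_mixed_culture(cfg, tg, fraction_violet = 1)
  sf <- run_mixed_culture(cfg, tg, fraction_violet = 0)
  set.seed(seed + 1)
  r <- function(s, ch) render(s$cells_tf, tg, cyto_channel(ch), "tf")
  list(truth = transfer_ground_truth(sim),
       mixed_violet = r(sim, "violet"), mixed_farred = r(sim, "far_red"),
       single_violet = list(violet = r(sv, "violet"),
                            far_red = r(sv, "far_red")),
       single_farred = list(violet = r(sf, "violet"),
                            far_red = r(sf, "far_red")))
}

# Paired division-on/off simulations sharing seeding and initial-cohort
# motility noise.
paired_division_runs <- function(seed, n_cells = 1200, duration = 24,
                                 geometry = small_geom(), ...) {
  base <- assay_config(n_cells = n_cells, duration = duration,
                       rng_seed = seed, ...)
  on <- base
  on$division_rate <- log(2) / 24
  list(off = run_assay(base, geometry), on = run_assay(on, geometry))
}
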