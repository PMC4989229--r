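# Canonical cell table. One row per cell; dye content is per channel in
# arbitrary units (only ratios ever enter a statistic).
new_cell_table <- function(n = 0L) {
  data.frame(cell_id = integer(n), lineage_id = integer(n),
             generation = integer(n), x_um = numeric(n), y_um = numeric(n),
             heading = numeric(n), dye_violet = numeric(n),
             dye_farred = numeric(n), alive = logical(n))
}

dye_cols <- c(violet = "dye_violet", far_red = "dye_farred")

#' Seed cells into the well
#'
#' Places `n_cells` cells uniformly at random over the well disk, excluding
#' the exclusion zone when `config$seed_exclusion` is `TRUE` (the barrier
#' assay geometry: the silicon insert keeps the central zone cell-free during
#' attachment). All cells start at generation 0 with identical dye content
#' (`config$initial_dye`) and headings uniform on `[0, 2*pi)`.
#'
#' Uses the global RNG; call [set.seed()] (or use [run_assay()], which
#' manages seeding) for reproducibility.
#'
#' @param config An [assay_config()].
#' @param geometry A [well_geometry()].
#' @return A cell table (`data.frame`), one row per cell.
#' @export
seed_cells <- function(config, geometry) {
  stopifnot(inherits(config, "assay_config"), inherits(geometry, "well_geometry"))
  if (geometry$zone_radius >= geometry$well_radius)
    stop("seed_cells: degenerate annulus (zone_radius >= well_radius)")
  n <- config$n_cells
  cells <- new_cell_table(n)
  if (n == 0L) return(cells)
  R <- geometry$well_radius
  zc <- geometry$zone_center_offset
  zr <- geometry$zone_radius
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 64L)
    x <- runif(m, -R, R); y <- runif(m, -R, R)
    keep <- x^2 + y^2 <= R^2
    if (config$seed_exclusion)
      keep <- keep & ((x - zc[1])^2 + (y - zc[2])^2 > zr^2)
    xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
  }
  cells$cell_id <- seq_len(n)
  cells$lineage_id <- seq_len(n)
  cells$generation <- 0L
  cells$x_um <- xs[seq_len(n)]
  cells$y_um <- ys[seq_len(n)]
  cells$heading <- runif(n, 0, 2 * pi)
  cells$dye_violet <- rep(unname(config$initial_dye["violet"]), n)
  cells$dye_farred <- rep(unname(config$initial_dye["far_red"]), n)
  cells$alive <- TRUE
  cells
}

# Advance positions given precomputed heading increments; reflects at the
# well boundary (specular reflection of the heading, radial fold-back of the
# overshoot). Shared by step_motility and the run_assay inner loop.
motility_advance <- function(cells, speed, dt, geometry, dheading) {
  h <- cells$heading + dheading
  x <- cells$x_um + speed * dt * cos(h)
  y <- cells$y_um + speed * dt * sin(h)
  R <- geometry$well_radius
  r <- sqrt(x^2 + y^2)
  out <- which(r > R)
  if (length(out)) {
    nx <- x[out] / r[out]; ny <- y[out] / r[out]
    fold <- (2 * R - r[out]) / r[out]
    x[out] <- x[out] * fold
    y[out] <- y[out] * fold
    dx <- cos(h[out]); dy <- sin(h[out])
    dot <- dx * nx + dy * ny
    h[out] <- atan2(dy - 2 * dot * ny, dx - 2 * dot * nx)
  }
  cells$heading <- h
  cells$x_um <- x
  cells$y_um <- y
  cells
}

#' One motility step (persistent random walk)
#'
#' Perturbs each heading by a Gaussian increment with variance
#' `2 * dt / persistence_time` (so that the velocity autocorrelation decays
#' as `exp(-t / persistence_time)` and the mean squared displacement follows
#' the Fürth form `2 * speed^2 * P * (t - P * (1 - exp(-t / P)))`), then
#' advances each position by `speed * dt` along the heading. Positions that
#' escape the well are reflected back across the boundary. Dye content is
#' untouched.
#'
#' @param cells A cell table.
#' @param config An [assay_config()] (supplies `speed` and
#'   `persistence_time`).
#' @param geometry A [well_geometry()].
#' @param dt Time step, h (defaults to `config$dt`).
#' @return The advanced cell table.
#' @export
step_motility <- function(cells, config, geometry, dt = config$dt) {
  stopifnot(inherits(config, "assay_config"))
  if (dt > config$persistence_time)
    warning("step_motility: dt exceeds persistence_time; ",
            "heading discretization will be coarse")
  n <- nrow(cells)
  if (n == 0L) return(cells)
  dh <- stats::rnorm(n, 0, sqrt(2 * dt / config$persistence_time))
  motility_advance(cells, config$speed, dt, geometry, dh)
}

#' Divide one cell with dye dilution
#'
#' The two daughters receive `dye * split` and `dye * (1 - split)` in every
#' channel; their sum equals the parental content exactly (the second
#' daughter is assigned the floating-point remainder). With `split = 0.5`
#' each daughter carries exactly half the parental dye, giving the 2-fold
#' per-generation dilution the lineage dyes are used for. Daughters sit at
#' the parent position offset by +/- `offset_um` along a uniform random
#' axis, inherit the parent heading and lineage, and advance one generation.
#'
#' @param parent A single-row cell table.
#' @param split Fraction of dye for the first daughter, in `(0, 1]`.
#' @param offset_um Daughter placement offset, um.
#' @return A two-row cell table (daughters).
#' @export
divide_cell <- function(parent, split = 0.5, offset_um = 5) {
  stopifnot(is.data.frame(parent), nrow(parent) == 1L)
  if (!isTRUE(parent$alive)) stop("divide_cell: parent is not alive")
  if (!is.numeric(split) || split <= 0 || split > 1)
    stop("divide_cell: split must be in (0, 1]")
  ang <- stats::runif(1, 0, 2 * pi)
  daughters <- parent[c(1L, 1L), , drop = FALSE]
  rownames(daughters) <- NULL
  for (col in dye_cols) {
    d1 <- parent[[col]] * split
    daughters[[col]] <- c(d1, parent[[col]] - d1)
  }
  daughters$generation <- parent$generation + 1L
  daughters$x_um <- parent$x_um + c(1, -1) * offset_um * cos(ang)
  daughters$y_um <- parent$y_um + c(1, -1) * offset_um * sin(ang)
  daughters
}

# Vectorized division used by run_assay: rows `idx` divide; the parent row
# becomes daughter 1, daughter 2 is appended. `angles` are the placement
# axes, one per dividing cell.
divide_rows <- function(cells, idx, split, angles, offset_um, next_id) {
  if (!length(idx)) return(cells)
  d2 <- cells[idx, , drop = FALSE]
  for (col in dye_cols) {
    d1 <- cells[[col]][idx] * split
    d2[[col]] <- cells[[col]][idx] - d1
    cells[[col]][idx] <- d1
  }
  gen <- cells$generation[idx] + 1L
  cells$generation[idx] <- gen
  d2$generation <- gen
  dx <- offset_um * cos(angles); dy <- offset_um * sin(angles)
  d2$x_um <- cells$x_um[idx] - dx
  d2$y_um <- cells$y_um[idx] - dy
  cells$x_um[idx] <- cells$x_um[idx] + dx
  cells$y_um[idx] <- cells$y_um[idx] + dy
  d2$cell_id <- next_id + seq_along(idx) - 1L
  rownames(d2) <- NULL
  rbind(cells, d2)
}

# Index pairs (i, j), i < j, with pairwise distance <= radius. Dense matrix
# for small n, uniform-grid binning otherwise.
neighbor_pairs <- function(x, y, radius) {
  n <- length(x)
  if (n < 2L) return(cbind(i = integer(0), j = integer(0)))
  if (n <= 3000L) {
    d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    w <- which(d2 <= radius^2 & upper.tri(d2), arr.ind = TRUE)
    return(cbind(i = w[, 1], j = w[, 2]))
  }
  gx <- as.integer(floor(x / radius)); gy <- as.integer(floor(y / radius))
  gx <- gx - min(gx); gy <- gy - min(gy)
  ng <- max(gx) + 2L
  key <- gy * ng + gx
  members <- split(seq_len(n), key)
  keys <- as.integer(names(members))
  lookup <- new.env(hash = TRUE, size = length(keys))
  for (k in seq_along(keys)) assign(as.character(keys[k]), k, envir = lookup)
  res_i <- vector("list", length(keys) * 5L); res_j <- res_i; nres <- 0L
  r2 <- radius^2
  push <- function(ii, jj) {
    if (!length(ii)) return()
    keep <- (x[ii] - x[jj])^2 + (y[ii] - y[jj])^2 <= r2
    if (any(keep)) {
      nres <<- nres + 1L
      res_i[[nres]] <<- ii[keep]; res_j[[nres]] <<- jj[keep]
    }
  }
  for (k in seq_along(keys)) {
    a <- members[[k]]
    if (length(a) > 1L) {
      cmb <- utils::combn(a, 2L)
      push(cmb[1L, ], cmb[2L, ])
    }
    # forward neighbor bins: E, SW, S, SE
    for (off in c(1L, ng - 1L, ng, ng + 1L)) {
      kk <- as.character(keys[k] + off)
      idx <- mget(kk, envir = lookup, ifnotfound = list(NULL))[[1L]]
      if (!is.null(idx)) {
        b <- members[[idx]]
        g <- expand.grid(a = a, b = b)
        push(g$a, g$b)
      }
    }
  }
  if (nres == 0L) return(cbind(i = integer(0), j = integer(0)))
  ii <- unlist(res_i[seq_len(nres)]); jj <- unlist(res_j[seq_len(nres)])
  sw <- ii > jj
  cbind(i = ifelse(sw, jj, ii), j = ifelse(sw, ii, jj))
}

#' Dye decay and neighbor transfer over one time step
#'
#' Each cell's dye is first multiplied by `exp(-decay_rate * dt)` per
#' channel. Then, for every unordered pair of cells closer than
#' `transfer_radius`, a fraction `transfer_rate * dt` of each cell's dye
#' moves to its partner (symmetric exchange). Total dye over all cells is
#' conserved exactly by the exchange, so with zero decay the dye mass is
#' invariant.
#'
#' @param cells A cell table.
#' @param config An [assay_config()].
#' @param dt Time step, h.
#' @return The updated cell table.
#' @export
apply_dye_kinetics <- function(cells, config, dt = config$dt) {
  stopifnot(inherits(config, "assay_config"))
  n <- nrow(cells)
  if (n == 0L) return(cells)
  for (ch in names(dye_cols)) {
    rate <- config$dye_decay_rate[[ch]]
    if (rate > 0) cells[[dye_cols[[ch]]]] <- cells[[dye_cols[[ch]]]] * exp(-rate * dt)
  }
  tau <- config$transfer_rate * dt
  if (tau > 0 && n >= 2L) {
    if (tau >= 1) stop("apply_dye_kinetics: transfer_rate * dt >= 1 is unstable")
    p <- neighbor_pairs(cells$x_um, cells$y_um, config$transfer_radius)
    if (nrow(p)) {
      k <- tabulate(c(p[, 1], p[, 2]), nbins = n)
      grp <- c(p[, 1], p[, 2])
      for (col in dye_cols) {
        v <- cells[[col]]
        nb <- numeric(n)
        s <- rowsum(c(v[p[, 2]], v[p[, 1]]), group = grp)
        nb[as.integer(rownames(s))] <- s[, 1]
        cells[[col]] <- v - tau * k * v + tau * nb
      }
    }
  }
  cells
}

in_zone <- function(cells, geometry) {
  zc <- geometry$zone_center_offset
  (cells$x_um - zc[1])^2 + (cells$y_um - zc[2])^2 <= geometry$zone_radius^2
}

ground_truth_row <- function(cells, geometry, time) {
  z <- in_zone(cells, geometry)
  data.frame(time = time, n_cells = nrow(cells),
             total_violet = sum(cells$dye_violet),
             total_farred = sum(cells$dye_farred),
             violet_in_zone = sum(cells$dye_violet[z]),
             farred_in_zone = sum(cells$dye_farred[z]),
             count_in_zone = sum(z))
}

#' Run a full exclusion-zone assay simulation
#'
#' Seeds the well, then iterates motility, stochastic division (per-cell
#' probability `division_rate * dt` per step, at most one division per cell
#' per step) and dye kinetics for `duration / dt` steps. Treatments are
#' resolved into effective speed and division-rate multipliers before the
#' run. Per-step ground-truth totals (cell count, dye per channel, dye and
#' count inside the zone) are recorded throughout.
#'
#' Randomness is organized in two streams so that paired experiments can
#' share motility noise: stream A (seeded from `rng_seed`) drives seeding
#' and the motility increments of the initial cohort; stream B (derived from
#' `rng_seed`) drives division timing, daughter placement and the motility of
#' cells born during the run. Two runs with the same `rng_seed` that differ
#' only in `division_rate` therefore move their initial cells along
#' identical trajectories. Identical configuration and seed give
#' bitwise-identical results.
#'
#' @param config An [assay_config()].
#' @param geometry A [well_geometry()].
#' @param init_cells Optional pre-built cell table used instead of
#'   [seed_cells()] (e.g. a mixed-label culture); the table becomes the t0
#'   snapshot.
#' @return An object of class `assay_sim`: list with `cells_t0` (post-seeding
#'   snapshot), `cells_tf`, `geometry`, `config`, and the per-step
#'   `ground_truth` data frame.
#' @examples
#' res <- run_assay(assay_config(n_cells = 200, duration = 1, rng_seed = 1),
#'                  well_geometry())
#' nrow(res$cells_tf)
#' @export
run_assay <- function(config, geometry, init_cells = NULL) {
  stopifnot(inherits(config, "assay_config"), inherits(geometry, "well_geometry"))
  eff <- effective_config(config)
  if (eff$dt > eff$persistence_time)
    warning("run_assay: dt exceeds persistence_time")
  if (!is.null(eff$rng_seed)) {
    seedA <- eff$rng_seed
    seedB <- as.integer((as.double(eff$rng_seed) + 1000003) %% 2147483647)
  } else {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    s <- sample.int(2147483646L, 2L)
    seedA <- s[1]; seedB <- s[2]
  }
  set.seed(seedA); stream_a <- .Random.seed
  set.seed(seedB); stream_b <- .Random.seed

  use_a <- function(expr) {
    assign(".Random.seed", stream_a, envir = globalenv())
    on.exit(stream_a <<- get(".Random.seed", envir = globalenv()))
    expr
  }
  use_b <- function(expr) {
    assign(".Random.seed", stream_b, envir = globalenv())
    on.exit(stream_b <<- get(".Random.seed", envir = globalenv()))
    expr
  }

  cells <- if (is.null(init_cells)) use_a(seed_cells(eff, geometry)) else {
    stopifnot(is.data.frame(init_cells),
              all(names(new_cell_table()) %in% names(init_cells)))
    init_cells
  }
  n0 <- nrow(cells)
  cells_t0 <- cells
  n_steps <- floor(eff$duration / eff$dt + 1e-9)
  gt <- vector("list", n_steps + 1L)
  gt[[1L]] <- ground_truth_row(cells, geometry, 0)
  sd_h <- sqrt(2 * eff$dt / eff$persistence_time)
  p_div <- eff$division_rate * eff$dt
  next_id <- n0 + 1L

  for (s in seq_len(n_steps)) {
    n <- nrow(cells)
    n_init <- min(n, n0)
    dh <- numeric(n)
    if (n_init > 0L) dh[seq_len(n_init)] <- use_a(stats::rnorm(n_init, 0, sd_h))
    if (n > n_init) dh[(n_init + 1L):n] <- use_b(stats::rnorm(n - n_init, 0, sd_h))
    cells <- motility_advance(cells, eff$speed, eff$dt, geometry, dh)
    if (p_div > 0 && n > 0L) {
      draws <- use_b(stats::runif(n))
      idx <- which(draws < p_div)
      if (length(idx)) {
        angles <- use_b(stats::runif(length(idx), 0, 2 * pi))
        cells <- divide_rows(cells, idx, eff$dye_split_fraction, angles,
                             offset_um = 5, next_id = next_id)
        next_id <- next_id + length(idx)
      }
    }
    cells <- apply_dye_kinetics(cells, eff, eff$dt)
    gt[[s + 1L]] <- ground_truth_row(cells, geometry, s * eff$dt)
  }
  structure(list(cells_t0 = cells_t0, cells_tf = cells,
                 geometry = geometry, config = config,
                 ground_truth = do.call(rbind, gt)),
            class = "assay_sim")
}

#' @export
print.assay_sim <- function(x, ...) {
  cat(sprintf(
    "assay_sim: %d -> %d cells over %g h; dye in zone %0.2f%% (violet) at tf\n",
    nrow(x$cells_t0), nrow(x$cells_tf), x$config$duration,
    100 * utils::tail(x$ground_truth$violet_in_zone, 1) /
      max(utils::tail(x$ground_truth$total_violet, 1), .Machine$double.xmin)))
  invisible(x)
}

#' Write simulation outputs as CSV
#'
#' `write_cells_csv` writes a cell table with a `timepoint` column;
#' `write_ground_truth_csv` writes the per-step totals.
#'
#' @param cells A cell table.
#' @param path Output file.
#' @param timepoint Label stored in the `timepoint` column.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(cells, path, timepoint = "tf") {
  out <- cells[, c("cell_id", "lineage_id", "generation", "x_um", "y_um",
                   "dye_violet", "dye_farred")]
  out$timepoint <- timepoint
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @param sim An `assay_sim` result.
#' @export
write_ground_truth_csv <- function(sim, path) {
  utils::write.csv(sim$ground_truth, path, row.names = FALSE)
  invisible(path)
}
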