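test_that("seeding fills the annulus uniformly and spares the zone", {
  g <- small_geom()
  set.seed(1)
  cells <- seed_cells(quick_cfg(n_cells = 1000), g)
  expect_identical(nrow(cells), 1000L)
  expect_true(all(cells$x_um^2 + cells$y_um^2 <= g$well_radius^2))
  expect_identical(sum(cells$x_um^2 + cells$y_um^2 <= g$zone_radius^2), 0L)
  expect_true(all(cells$generation == 0L))
  expect_true(all(cells$dye_violet == 1))
  expect_identical(nrow(seed_cells(quick_cfg(n_cells = 0), g)), 0L)

  # chi-squared goodness of fit of radial bin counts against annulus-area
  # proportions, alpha = 0.01
  set.seed(2)
  big <- seed_cells(quick_cfg(n_cells = 10000), g)
  r <- sqrt(big$x_um^2 + big$y_um^2)
  breaks <- seq(g$zone_radius, g$well_radius, length.out = 9)
  obs <- table(cut(r, breaks))
  p_area <- diff(breaks^2) / (g$well_radius^2 - g$zone_radius^2)
  expect_gt(stats::chisq.test(obs, p = p_area)$p.value, 0.01)

  # plain cultures seed the full disk
  set.seed(3)
  full <- seed_cells(quick_cfg(n_cells = 2000, seed_exclusion = FALSE), g)
  expect_gt(sum(full$x_um^2 + full$y_um^2 <= g$zone_radius^2), 0)
})

test_that("motility is a persistent random walk with reflective boundary", {
  g <- small_geom()
  cfg0 <- quick_cfg(n_cells = 50, speed = 0)
  set.seed(4)
  cells <- seed_cells(cfg0, g)
  moved <- step_motility(cells, cfg0, g, dt = 0.1)
  expect_identical(moved$x_um, cells$x_um)
  expect_identical(moved$dye_violet, cells$dye_violet)

  # one step, no boundary: displacement is exactly speed * dt
  cfg1 <- quick_cfg(n_cells = 1, speed = 10)
  one <- make_cells(0, 0)
  set.seed(5)
  out <- step_motility(one, cfg1, g, dt = 1)
  expect_equal(sqrt(out$x_um^2 + out$y_um^2), 10, tolerance = 1e-12)

  # Furth mean-squared-displacement law, free space, t >> P
  free <- well_geometry(1e6, 1, pixel_size = 1e4)
  v <- 30; P <- 1.5; dt <- 0.1
  cfgF <- assay_config(n_cells = 4000, duration = 9, dt = dt, speed = v,
                       persistence_time = P, seed_exclusion = FALSE)
  set.seed(6)
  cells <- seed_cells(cfgF, free)
  cells$x_um <- 0; cells$y_um <- 0
  for (s in seq_len(90)) cells <- step_motility(cells, cfgF, free, dt)
  msd <- mean(cells$x_um^2 + cells$y_um^2)
  t_end <- 9
  furth <- 2 * v^2 * P * (t_end - P * (1 - exp(-t_end / P)))
  expect_lt(abs(msd - furth) / furth, 0.05)

  # containment after a long confined run
  sim <- run_assay(quick_cfg(n_cells = 300, duration = 12, speed = 120,
                             rng_seed = 7), g)
  expect_true(all(sim$cells_tf$x_um^2 + sim$cells_tf$y_um^2 <=
                    g$well_radius^2 + 1e-9))
})

test_that("division dilutes dye 2-fold and conserves it exactly", {
  p <- make_cells(0, 0, dye_violet = 10)
  set.seed(8)
  d <- divide_cell(p, split = 0.5)
  expect_identical(d$dye_violet, c(5, 5))
  expect_identical(d$generation, c(1L, 1L))
  d0 <- divide_cell(make_cells(0, 0, dye_violet = 0), split = 0.5)
  expect_identical(d0$dye_violet, c(0, 0))
  d7 <- divide_cell(make_cells(0, 0, dye_violet = 10), split = 0.7)
  expect_identical(d7$dye_violet, c(7, 3))
  expect_error(divide_cell(p, split = 0), "split")
  expect_error(divide_cell(p, split = 1.1), "split")
  # exact conservation for arbitrary dye content and split
  set.seed(9)
  for (k in 1:50) {
    dye <- stats::runif(1, 0, 100)
    s <- stats::runif(1, 0.05, 0.95)
    dd <- divide_cell(make_cells(0, 0, dye_violet = dye), split = s)
    expect_identical(sum(dd$dye_violet), dye)
  }
})

test_that("dye kinetics follow first-order decay and conservative exchange", {
  g <- small_geom()
  cfg <- quick_cfg(n_cells = 10)
  set.seed(10)
  cells <- seed_cells(cfg, g)
  expect_identical(apply_dye_kinetics(cells, cfg, dt = 1)$dye_violet,
                   cells$dye_violet)

  # isolated cell, half-life decay
  cfg_d <- quick_cfg(n_cells = 1, dye_decay_rate = log(2))
  one <- make_cells(0, 0, dye_violet = 8)
  expect_equal(apply_dye_kinetics(one, cfg_d, dt = 1)$dye_violet, 4,
               tolerance = 1e-12)

  # two adjacent cells: symmetric exchange, total conserved exactly
  cfg_t <- quick_cfg(n_cells = 2, transfer_rate = 0.05, transfer_radius = 25)
  two <- make_cells(c(0, 10), c(0, 0), dye_violet = c(10, 0))
  out <- apply_dye_kinetics(two, cfg_t, dt = 1)
  expect_equal(out$dye_violet, c(9.5, 0.5), tolerance = 1e-12)
  expect_identical(sum(out$dye_violet), 10)

  expect_error(apply_dye_kinetics(two, quick_cfg(transfer_rate = 10), dt = 1),
               "unstable")

  # many-cell exchange conserves total dye to machine precision
  cfg_m <- quick_cfg(n_cells = 400, transfer_rate = 5e-3,
                     transfer_radius = 60, seed_exclusion = FALSE)
  set.seed(11)
  many <- seed_cells(cfg_m, g)
  many$dye_violet <- stats::runif(400, 0, 3)
  tot0 <- sum(many$dye_violet)
  for (k in 1:10) many <- apply_dye_kinetics(many, cfg_m, dt = 0.1)
  expect_lt(abs(sum(many$dye_violet) - tot0) / tot0, 1e-12)
})

test_that("full runs conserve dye mass, track generations, and reproduce", {
  g <- small_geom()
  sim <- run_assay(quick_cfg(n_cells = 800, duration = 12,
                             division_rate = log(2) / 24, rng_seed = 12), g)
  gt <- sim$ground_truth
  tot0 <- gt$total_violet[1]
  expect_true(all(abs(gt$total_violet - tot0) / tot0 < 1e-12))
  expect_gt(nrow(sim$cells_tf), nrow(sim$cells_t0))
  # generation bookkeeping: per-cell dye is exactly 2^(-generation)
  expect_identical(sim$cells_tf$dye_violet, 2^(-sim$cells_tf$generation))
  # ground-truth rows equal direct sums over the recorded cell lists
  z <- (sim$cells_tf$x_um^2 + sim$cells_tf$y_um^2) <= g$zone_radius^2
  last <- nrow(gt)
  expect_identical(gt$n_cells[last], nrow(sim$cells_tf))
  expect_identical(gt$violet_in_zone[last], sum(sim$cells_tf$dye_violet[z]))
  expect_identical(gt$count_in_zone[last], sum(z))

  # no division: constant cell count, dye constant
  sim0 <- run_assay(quick_cfg(n_cells = 500, duration = 6, rng_seed = 13), g)
  expect_true(all(sim0$ground_truth$n_cells == 500L))
  expect_identical(sim0$ground_truth$total_violet[1],
                   sim0$ground_truth$total_violet[nrow(sim0$ground_truth)])

  # branching expectation: count doubles in 24 h within 3 standard errors
  simd <- run_assay(quick_cfg(n_cells = 2000, duration = 24,
                              division_rate = log(2) / 24, rng_seed = 14), g)
  ratio <- nrow(simd$cells_tf) / 2000
  se <- sqrt(2 * (2 - 1) / 2000)  # branching process variance m(m-1)/n
  expect_lt(abs(ratio - 2), 3 * se)

  # determinism: identical seed, bitwise identical result
  a <- run_assay(quick_cfg(n_cells = 400, duration = 3,
                           division_rate = log(2) / 24, rng_seed = 15), g)
  b <- run_assay(quick_cfg(n_cells = 400, duration = 3,
                           division_rate = log(2) / 24, rng_seed = 15), g)
  expect_identical(a$cells_tf, b$cells_tf)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("paired runs share seeding and initial-cohort motility noise", {
  runs <- paired_division_runs(seed = 16, n_cells = 600, duration = 6,
                               speed = 60)
  expect_identical(runs$off$cells_t0, runs$on$cells_t0)
  # initial cells that never divided in the division arm followed the exact
  # same trajectory as in the no-division arm
  on_tf <- runs$on$cells_tf
  undivided <- on_tf[on_tf$generation == 0L & on_tf$cell_id <= 600, ]
  expect_gt(nrow(undivided), 0)
  match_off <- runs$off$cells_tf[match(undivided$cell_id,
                                       runs$off$cells_tf$cell_id), ]
  expect_identical(undivided$x_um, match_off$x_um)
  expect_identical(undivided$y_um, match_off$y_um)
})

test_that("treatments act as pure multipliers on speed and division", {
  g <- small_geom()
  mmc <- quick_cfg(n_cells = 300, duration = 6,
                   division_rate = log(2) / 24, rng_seed = 17,
                   treatments = list(treatment_preset("mitomycin_C")))
  sim <- run_assay(mmc, g)
  expect_true(all(sim$ground_truth$n_cells == 300L))

  cyto <- quick_cfg(n_cells = 300, duration = 6, speed = 60, rng_seed = 18,
                    treatments = list(treatment_preset("cytochalasin_D")))
  ctrl <- quick_cfg(n_cells = 300, duration = 6, speed = 60, rng_seed = 18)
  disp <- function(sim) {
    d <- sim$cells_tf
    s <- sim$cells_t0
    mean(sqrt((d$x_um - s$x_um)^2 + (d$y_um - s$y_um)^2))
  }
  expect_lt(disp(run_assay(cyto, g)), 0.3 * disp(run_assay(ctrl, g)))
})

test_that("dye mass fraction in the zone is division-invariant while the
           parental-referenced count is not", {
  # simulation-level statement of proliferation insensitivity: paired
  # replicates with shared motility noise
  R <- 50
  dye_off <- dye_on <- cnt_off <- cnt_on <- numeric(R)
  for (r in seq_len(R)) {
    runs <- paired_division_runs(seed = 100 + r, n_cells = 1000,
                                 duration = 12, speed = 90)
    frac <- function(sim) {
      gt <- sim$ground_truth[nrow(sim$ground_truth), ]
      c(dye = gt$violet_in_zone / gt$total_violet,
        cnt = gt$count_in_zone / nrow(sim$cells_t0))
    }
    f_off <- frac(runs$off); f_on <- frac(runs$on)
    dye_off[r] <- f_off["dye"]; dye_on[r] <- f_on["dye"]
    cnt_off[r] <- f_off["cnt"]; cnt_on[r] <- f_on["cnt"]
  }
  d_dye <- dye_on - dye_off
  se_dye <- stats::sd(d_dye) / sqrt(R)
  expect_lt(abs(mean(d_dye)), 2 * se_dye + 1e-4)
  # count fraction referenced to the parental population is strictly larger
  # with division on (one-sided paired test, alpha = 0.01)
  tt <- stats::t.test(cnt_on, cnt_off, paired = TRUE,
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_gt(mean(cnt_on - cnt_off), 0)
})
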