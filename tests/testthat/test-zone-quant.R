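# Render one small confluent t0 field (and optionally a migrated tf field).
render_well <- function(seed, zone_offset = c(0, 0), duration = 6,
                        n_cells = 3000, division_rate = 0, both = FALSE) {
  g <- small_geom(zone_center_offset = zone_offset)
  sim <- run_assay(quick_cfg(n_cells = n_cells, duration = duration,
                             division_rate = division_rate, rng_seed = seed), g)
  set.seed(seed + 5000)
  t0 <- render(sim$cells_t0, g, quick_channel(), timepoint = "t0")
  if (!both) return(list(geom = g, sim = sim, t0 = t0))
  tf <- render(sim$cells_tf, g, quick_channel(), timepoint = "tf")
  list(geom = g, sim = sim, t0 = t0, tf = tf)
}

test_that("well and zone circles are recovered from rendered images", {
  fx <- render_well(seed = 30)
  roi1 <- detect_well_roi(fx$t0)
  expect_lt(max(abs(roi1$center - c(128, 128))), 2)
  expect_lt(abs(roi1$radius - 128) / 128, 0.02)
  roi2 <- detect_exclusion_zone(fx$t0, roi1)
  expect_lt(max(abs(roi2$center - c(128, 128))), 3)
  expect_lt(abs(roi2$radius - 40) / 40, 0.03)

  # deliberately offset zone: recovered center tracks the offset
  fx2 <- render_well(seed = 31, zone_offset = c(100, -62.5))
  pair <- detect_roi_pair(fx2$t0)
  truth <- c(128 + 100 / 6.25, 128 - 62.5 / 6.25)
  expect_lt(max(abs(pair$roi2$center - truth)), 3)

  # blank image and confluent well are detection errors
  g <- fx$geom
  blank <- field_image(matrix(0, 256, 256), "violet", "t0", g)
  expect_error(detect_well_roi(blank), "blank|foreground")
  conf_sim <- run_assay(quick_cfg(n_cells = 3000, duration = 1,
                                  seed_exclusion = FALSE, rng_seed = 32),
                        well_geometry(800, 250, pixel_size = 6.25))
  set.seed(33)
  conf <- render(conf_sim$cells_tf, g, quick_channel(), timepoint = "t0")
  r1 <- detect_well_roi(conf)
  expect_error(detect_exclusion_zone(conf, r1), "cell-free")
})

test_that("a well imaged off the raster center is recovered", {
  fx <- render_well(seed = 34)
  shifted <- field_image(shift_raster(fx$t0$pixels, 10, -6), "violet", "t0",
                         fx$geom)
  roi1 <- detect_well_roi(shifted)
  expect_lt(max(abs(roi1$center - c(138, 122))), 2)
})

test_that("ROI pairs align by translation only and preserve their offset", {
  fx <- render_well(seed = 35, zone_offset = c(50, 25), both = TRUE)
  pair <- detect_roi_pair(fx$t0)
  off_before <- pair$roi2$center - pair$roi1$center

  # tf identical to t0: translation ~ 0
  aligned0 <- align_roi_pair(pair, fx$t0)
  expect_lt(max(abs(aligned0$roi1$center - pair$roi1$center)), 0.5)

  # integer-shifted tf: translation recovered within a pixel
  tf_shift <- field_image(shift_raster(fx$tf$pixels, 7, -3), "violet", "tf",
                          fx$geom)
  aligned <- align_roi_pair(pair, tf_shift)
  expect_lt(max(abs(aligned$roi1$center - (pair$roi1$center + c(7, -3)))), 1)
  # rigid: relative offset preserved to machine precision
  expect_equal(aligned$roi2$center - aligned$roi1$center, off_before,
               tolerance = 1e-13)
  expect_identical(aligned$roi2$radius, pair$roi2$radius)
  expect_error(align_roi_pair(standard_roi_pair(fx$geom), fx$tf), "standard")
})

test_that("relative migration reduces to area ratios on uniform fields", {
  g <- small_geom()
  px <- matrix(0, 256, 256)
  roi1 <- circle_roi(c(128, 128), 100)
  px[zonemig:::circle_mask(roi1, 256)] <- 100
  img <- field_image(px, "violet", "tf", g)
  pair <- roi_pair(roi1, circle_roi(c(128, 128), 50), source = "standard")
  res <- relative_migration(img, pair, background = "none")
  expect_equal(res$percent_migration, 25, tolerance = 0.2)

  # zero signal in the zone
  px2 <- px
  px2[zonemig:::circle_mask(circle_roi(c(128, 128), 50), 256)] <- 0
  res2 <- relative_migration(field_image(px2, "violet", "tf", g), pair,
                             background = "none")
  expect_identical(res2$i_roi2, 0)
  expect_identical(res2$percent_migration, 0)

  # undefined statistic on an empty image
  expect_error(relative_migration(field_image(matrix(0, 256, 256), "violet",
                                              "tf", g),
                                  pair, background = "none"),
               "undefined")
})

test_that("intensity sums agree with the brute-force mask oracle", {
  g <- small_geom()
  set.seed(36)
  for (k in 1:20) {
    n <- sample(50:250, 1)
    cells <- make_cells(stats::runif(n, -700, 700), stats::runif(n, -700, 700),
                        dye_violet = stats::runif(n, 0.2, 2))
    img <- render(cells, g, quick_channel(), timepoint = "tf")
    c1 <- c(stats::runif(1, 110, 146), stats::runif(1, 110, 146))
    r1 <- stats::runif(1, 70, 100)
    c2 <- c1 + stats::runif(2, -20, 20)
    r2 <- stats::runif(1, 20, 40)
    pair <- roi_pair(circle_roi(c1, r1), circle_roi(c2, r2),
                     source = "standard")
    res <- relative_migration(img, pair)
    bg <- oracle_background(img$pixels, c1, r1)
    o1 <- oracle_roi_sum(img$pixels, c1, r1, bg)
    o2 <- oracle_roi_sum(img$pixels, c2, r2, bg)
    expect_equal(res$background_per_px, bg)
    expect_lt(abs(res$i_roi1 - o1) / o1, 1e-9)
    expect_lt(abs(res$i_roi2 - o2) / max(o2, 1), 1e-9)
  }
})

test_that("the statistic is invariant to intensity rescaling", {
  fx <- render_well(seed = 37, both = TRUE)
  pair <- detect_roi_pair(fx$t0)
  aligned <- align_roi_pair(pair, fx$tf)
  base <- relative_migration(fx$tf, aligned)
  for (k in c(0.25, 3, 117.3)) {
    scaled <- field_image(fx$tf$pixels * k, "violet", "tf", fx$geom)
    res <- relative_migration(scaled, aligned)
    expect_lt(abs(res$percent_migration - base$percent_migration), 1e-9)
  }
  # repeated evaluation is deterministic
  expect_identical(relative_migration(fx$tf, aligned)$percent_migration,
                   base$percent_migration)
})

test_that("the pre-migration image itself reads out background only", {
  fx <- render_well(seed = 38)
  pair <- detect_roi_pair(fx$t0)
  res <- relative_migration(fx$t0, pair)
  expect_lt(res$percent_migration, 1)
})

test_that("single-image mode matches dual mode on centered wells", {
  fx <- render_well(seed = 39, both = TRUE)
  pair <- detect_roi_pair(fx$t0)
  dual <- relative_migration(fx$tf, align_roi_pair(pair, fx$tf))
  single <- single_image_migration(fx$tf, standard_roi_pair(fx$geom))
  expect_lt(abs(dual$percent_migration - single$percent_migration), 0.5)
  expect_identical(single$mode, "single")

  # a strongly mis-centered zone biases single mode measurably: the
  # standard centered ROI-2 misses part of the true zone signal
  fx_off <- render_well(seed = 40, zone_offset = c(150, 0), both = TRUE)
  pair_off <- detect_roi_pair(fx_off$t0)
  dual_off <- relative_migration(fx_off$tf, align_roi_pair(pair_off, fx_off$tf))
  single_off <- single_image_migration(fx_off$tf, standard_roi_pair(small_geom()))
  expect_gt(abs(dual_off$percent_migration - single_off$percent_migration),
            abs(dual$percent_migration - single$percent_migration))
})

test_that("count-based readout is confounded by division while the dye
           readout is not", {
  g <- small_geom()
  base <- quick_cfg(n_cells = 2500, duration = 8, speed = 60, rng_seed = 41)
  on <- base; on$division_rate <- log(2) / 8  # one doubling over the run
  sim_off <- run_assay(base, g)
  sim_on <- run_assay(on, g)
  chn <- quick_channel("nuclear")
  quantify <- function(sim, seed) {
    set.seed(seed)
    t0v <- render(sim$cells_t0, g, quick_channel(), "t0")
    tfv <- render(sim$cells_tf, g, quick_channel(), "tf")
    t0n <- render(sim$cells_t0, g, chn, "t0")
    tfn <- render(sim$cells_tf, g, chn, "tf")
    pair <- align_roi_pair(detect_roi_pair(t0v), tfv)
    c(dye = relative_migration(tfv, pair)$percent_migration,
      cnt = count_based_migration(tfn, pair, t0_nuclear = t0n,
                                  method = "intensity")$percent_migration)
  }
  q_off <- quantify(sim_off, 42)
  q_on <- quantify(sim_on, 43)
  expect_lt(abs(q_on["dye"] - q_off["dye"]), 2)
  expect_gt(q_on["cnt"] - q_off["cnt"], 2)
  # with division off the nuclear and dye readouts coincide
  expect_lt(abs(q_off["cnt"] - q_off["dye"]), 1)
})

test_that("nucleus-count sub-mode matches simulated occupancy on sparse
           fields", {
  g <- well_geometry(3200, 1000, pixel_size = 6.25)
  set.seed(44)
  pos <- separated_positions(400, 3100, 40)
  cells <- make_cells(pos[, 1], pos[, 2])
  nuc <- render(cells, g, channel_spec("nuclear", psf_sigma = 6), "tf")
  pair <- standard_roi_pair(g)
  res <- count_based_migration(nuc, pair, method = "count")
  truth2 <- sum(pos[, 1]^2 + pos[, 2]^2 <= 1000^2)
  truth1 <- nrow(pos)
  expect_lt(abs(res$i_roi2 - truth2), max(0.02 * truth1, 2))
  expect_lt(abs(res$i_roi1 - truth1), 0.02 * truth1 + 2)

  blankpair <- standard_roi_pair(small_geom())
  blank <- field_image(matrix(0, 256, 256), "nuclear", "tf", small_geom())
  expect_error(count_based_migration(blank, blankpair, method = "count"),
               "undefined")
})
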