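#' Segment cells in a field image
#'
#' Global Otsu threshold, connected components, removal of sub-cellular
#' specks, and a distance-transform watershed to split touching objects.
#' Per-object centroid, area, and background-corrected mean and integrated
#' intensity are measured on the segmented image and on any additional
#' channels supplied (all registered to the same raster).
#'
#' The default minimum object area is `pi * (psf_sigma / pixel_size)^2 / 4`
#' square pixels — a quarter of the nominal spot area — which rejects noise
#' speckles while scaling with the rendering parameters.
#'
#' @param img A [field_image()] (nuclear or dye channel).
#' @param channels Named list of additional [field_image()]s to measure.
#' @param psf_sigma Spot scale used for the default minimum area, um.
#' @param min_area Override for the minimum object area, px^2.
#' @return An object of class `cell_mask`: `label_raster` (0 = background),
#'   `n_objects`, and `per_object` (data.frame with `label`, `centroid_x`,
#'   `centroid_y` in 0-based px, `area_px`, and `mean_*` / `integrated_*`
#'   per measured channel).
#' @export
segment_cells <- function(img, channels = list(), psf_sigma = 15,
                          min_area = NULL) {
  stopifnot(inherits(img, "field_image"))
  f <- img$pixels
  w <- ncol(f)
  if (is.null(min_area))
    min_area <- pi * (psf_sigma / img$geometry$pixel_size)^2 / 4
  empty <- function() {
    po <- data.frame(label = integer(0), centroid_x = numeric(0),
                     centroid_y = numeric(0), area_px = numeric(0))
    structure(list(label_raster = matrix(0L, w, w), n_objects = 0L,
                   per_object = po), class = "cell_mask")
  }
  if (max(f) <= 0) return(empty())
  # Otsu on the square inscribed in the well: the zeros outside the well
  # circle would otherwise dominate the histogram and pull the threshold
  # below the in-well background.
  half <- floor(img$geometry$well_radius / img$geometry$pixel_size / sqrt(2) * 0.95)
  ctr <- w / 2
  lo <- max(round(ctr - half), 0) + 1L
  hi <- min(round(ctr + half), w - 1) + 1L
  crop <- f[lo:hi, lo:hi]
  th <- otsu_threshold(crop)
  # a threshold barely above the typical in-well level means the histogram
  # is unimodal background: there is nothing to segment
  if (th <= 1.5 * max(stats::median(crop), .Machine$double.eps))
    return(empty())
  fg <- f > th
  if (!any(fg)) return(empty())
  dm <- EBImage::distmap(fg)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  if (!length(keep)) return(empty())
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  n_obj <- length(keep)

  idx <- which(lab > 0L, arr.ind = TRUE)
  g <- lab[lab > 0L]
  area <- tabulate(g, nbins = n_obj)
  cx <- rowsum(as.numeric(idx[, 2] - 1), g)[, 1] / area
  cy <- rowsum(as.numeric(idx[, 1] - 1), g)[, 1] / area
  po <- data.frame(label = seq_len(n_obj), centroid_x = cx, centroid_y = cy,
                   area_px = area)
  meas <- c(stats::setNames(list(img), img$channel), channels)
  lin <- (idx[, 2] - 1L) * nrow(lab) + idx[, 1]
  for (nm in names(meas)) {
    v <- meas[[nm]]$pixels
    bg <- stats::median(v[lab == 0L & v > 0])
    if (!is.finite(bg)) bg <- 0
    vv <- v[lin] - bg
    po[[paste0("integrated_", nm)]] <- rowsum(vv, g)[, 1]
    po[[paste0("mean_", nm)]] <- po[[paste0("integrated_", nm)]] / area
  }
  structure(list(label_raster = lab, n_objects = n_obj, per_object = po),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell_mask: %d objects\n", x$n_objects))
  invisible(x)
}

#' Count stained nuclei in an image
#'
#' Number of segmented objects in a nuclear-channel image (see
#' [segment_cells()]); the automated-counting readout of the conventional
#' proliferation assay.
#'
#' @inheritParams segment_cells
#' @return Integer count.
#' @export
count_nuclei <- function(img, psf_sigma = 15, min_area = NULL) {
  segment_cells(img, psf_sigma = psf_sigma, min_area = min_area)$n_objects
}

#' Dye retention over a time series of whole-well images
#'
#' Background-corrected total well intensity at each timepoint, expressed as
#' a percentage of the first timepoint. Stable cytosolic retention shows as
#' a flat series at 100%.
#'
#' @param series List of [field_image()]s of the same well and channel at
#'   increasing timepoints.
#' @param timepoints Numeric acquisition times, h.
#' @param background `"outside"` (median outside the well circle), or an
#'   explicit counts-per-pixel value.
#' @return A data.frame of class `retention_series`: `timepoint_h`,
#'   `total_intensity`, `percent_retained`.
#' @export
dye_retention <- function(series, timepoints = seq_along(series) - 1,
                          background = "outside") {
  stopifnot(is.list(series), length(series) >= 1L,
            length(timepoints) == length(series))
  if (is.unsorted(timepoints))
    stop("dye_retention: timepoints must be increasing")
  totals <- vapply(series, function(img) {
    stopifnot(inherits(img, "field_image"))
    w <- ncol(img$pixels)
    well <- circle_roi(c(w / 2, w / 2),
                       img$geometry$well_radius / img$geometry$pixel_size)
    bg <- if (is.numeric(background)) background else estimate_background(img, well)
    px <- img$pixels - bg
    px[px < 0] <- 0
    sum(px[circle_mask(well, w)])
  }, numeric(1))
  structure(data.frame(timepoint_h = timepoints, total_intensity = totals,
                       percent_retained = 100 * totals / totals[1]),
            class = c("retention_series", "data.frame"))
}

# Segment one population of a mixed culture on its ON channel and keep only
# objects whose normalized on-channel signal beats the other channel
# (median-of-population normalization; ties are excluded). Objects that are
# bright in *both* channels after normalization are merged violet/far-red
# cell pairs that segmentation failed to split; they are gated out like
# doublets in flow cytometry, since genuine dye transfer never approaches
# channel parity.
assign_population <- function(seg_po, on_name, off_name, norm_on, norm_off,
                              doublet_gate = 0.5) {
  po <- seg_po
  if (!nrow(po)) return(po)
  z_on <- po[[paste0("mean_", on_name)]] / norm_on
  z_off <- po[[paste0("mean_", off_name)]] / norm_off
  po[z_on > z_off & z_off < doublet_gate * z_on, , drop = FALSE]
}

# Channel intensity scale: median per-pixel object intensity of the cells
# that are bright in that channel (its own labeled population).
channel_norm <- function(seg_po, channel) {
  v <- seg_po[[paste0("mean_", channel)]]
  if (!length(v)) return(1)
  n <- stats::median(v[v > 0])
  if (!is.finite(n) || n <= 0) 1 else n
}

transfer_result <- function(donor, recipient, mixed_off, single_bg, single_on) {
  structure(list(donor_dye = donor, recipient_population = recipient,
                 mixed_offchannel_mean = mixed_off,
                 single_label_background_mean = single_bg,
                 single_label_onchannel_mean = single_on,
                 percent_transfer = 100 * (mixed_off - single_bg) / single_on),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("transfer_result: %s -> %s population: %.2f%% transferred\n",
              x$donor_dye, x$recipient_population, x$percent_transfer))
  invisible(x)
}

#' Mixed-culture dye transfer by image cytometry
#'
#' Quantifies unwanted dye movement between neighboring cells. Two
#' populations, labeled with the violet and far-red dye respectively, are
#' co-cultured and imaged in both channels; single-labeled cultures imaged
#' in both channels provide the on-channel reference and the off-channel
#' background. For each recipient population,
#' `percent_transfer = 100 * (mean off-channel per-cell intensity in the
#' mixed culture - the same quantity in the single-labeled culture) /
#' (mean on-channel per-cell intensity of the donor population in its
#' single-labeled culture)`. Per-cell intensity is the integrated,
#' background-corrected intensity within the segmented object mask.
#'
#' @param mixed_violet,mixed_farred [field_image()]s of the mixed culture in
#'   the violet and far-red channels.
#' @param single_violet Named list `list(violet =, far_red =)` of images of
#'   the violet-only culture.
#' @param single_farred Same for the far-red-only culture.
#' @param psf_sigma Spot scale passed to [segment_cells()], um.
#' @return List of two `transfer_result`s: `violet_to_farred` and
#'   `farred_to_violet`.
#' @export
dye_transfer <- function(mixed_violet, mixed_farred, single_violet,
                         single_farred, psf_sigma = 6) {
  stopifnot(inherits(mixed_violet, "field_image"),
            inherits(mixed_farred, "field_image"))
  for (l in list(single_violet, single_farred))
    stopifnot(is.list(l), all(c("violet", "far_red") %in% names(l)))

  seg_mv <- segment_cells(mixed_violet, channels = list(far_red = mixed_farred),
                          psf_sigma = psf_sigma)$per_object
  seg_mf <- segment_cells(mixed_farred, channels = list(violet = mixed_violet),
                          psf_sigma = psf_sigma)$per_object
  if (!nrow(seg_mv) || !nrow(seg_mf))
    stop("dye_transfer: population assignment failed - a labeled population ",
         "is absent from the mixed images")
  norm_v <- channel_norm(seg_mv, "violet")
  norm_fr <- channel_norm(seg_mf, "far_red")
  pop_v <- assign_population(seg_mv, "violet", "far_red", norm_v, norm_fr)
  pop_fr <- assign_population(seg_mf, "far_red", "violet", norm_fr, norm_v)
  if (!nrow(pop_v) || !nrow(pop_fr))
    stop("dye_transfer: population assignment failed - a labeled population ",
         "is absent from the mixed images")

  # single-labeled references, segmented on their on-channel
  seg_sv <- segment_cells(single_violet$violet,
                          channels = list(far_red = single_violet$far_red),
                          psf_sigma = psf_sigma)$per_object
  seg_sf <- segment_cells(single_farred$far_red,
                          channels = list(violet = single_farred$violet),
                          psf_sigma = psf_sigma)$per_object
  if (!nrow(seg_sv) || !nrow(seg_sf))
    stop("dye_transfer: no cells segmented in a single-labeled reference")

  on_v <- mean(seg_sv$integrated_violet)
  on_fr <- mean(seg_sf$integrated_far_red)
  if (on_v <= 0 || on_fr <= 0)
    stop("dye_transfer: donor on-channel mean is zero; statistic undefined")

  v_to_fr <- transfer_result(
    donor = "violet", recipient = "far_red",
    mixed_off = mean(pop_fr$mean_violet * pop_fr$area_px),
    single_bg = mean(seg_sf$integrated_violet),
    single_on = on_v)
  fr_to_v <- transfer_result(
    donor = "far_red", recipient = "violet",
    mixed_off = mean(pop_v$mean_far_red * pop_v$area_px),
    single_bg = mean(seg_sv$integrated_far_red),
    single_on = on_fr)
  list(violet_to_farred = v_to_fr, farred_to_violet = fr_to_v)
}

#' Simulate a mixed two-dye culture
#'
#' Seeds a plain (no exclusion zone) culture, labels a fraction of the cells
#' with the violet dye and the rest with the far-red dye, then runs the
#' simulation — the in-silico version of the co-culture dye transfer
#' experiment. Lineage ids of the violet population are `1..n_violet`.
#'
#' @param config An [assay_config()]; its `initial_dye` is ignored and
#'   `seed_exclusion` is forced off.
#' @param geometry A [well_geometry()].
#' @param fraction_violet Fraction of cells labeled violet.
#' @return An `assay_sim` (see [run_assay()]).
#' @export
run_mixed_culture <- function(config, geometry, fraction_violet = 0.5) {
  cfg <- config
  cfg$seed_exclusion <- FALSE
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  cells <- seed_cells(cfg, geometry)
  n_v <- round(nrow(cells) * fraction_violet)
  cells$dye_violet <- c(rep(1, n_v), rep(0, nrow(cells) - n_v))
  cells$dye_farred <- 1 - cells$dye_violet
  run_assay(cfg, geometry, init_cells = cells)
}

#' Ground-truth transferred dye mass of a simulation
#'
#' From the simulator's dye ledger: the percentage of each dye's total mass
#' that resides, at the end of the run, in cells of the *other* lineage
#' population (population membership is defined by the dye carried at t0).
#'
#' @param sim An `assay_sim` from [run_mixed_culture()].
#' @return Named numeric: `violet_to_farred`, `farred_to_violet`, percent.
#' @export
transfer_ground_truth <- function(sim) {
  t0 <- sim$cells_t0
  donor_v <- t0$lineage_id[t0$dye_violet > 0]
  tf <- sim$cells_tf
  in_v <- tf$lineage_id %in% donor_v
  c(violet_to_farred = 100 * sum(tf$dye_violet[!in_v]) / sum(tf$dye_violet),
    farred_to_violet = 100 * sum(tf$dye_farred[in_v]) / sum(tf$dye_farred))
}
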