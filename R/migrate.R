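# Boolean pixel mask of a circular ROI on a square raster: a pixel belongs
# to the ROI when its center lies at distance <= radius (ties inside).
circle_mask <- function(roi, width) {
  coords <- 0:(width - 1)
  outer((coords - roi$center[2])^2, (coords - roi$center[1])^2, "+") <=
    roi$radius^2
}

# Background per pixel: median over pixels outside ROI-1.
estimate_background <- function(img, roi1) {
  m <- !circle_mask(roi1, ncol(img$pixels))
  if (!any(m)) return(0)
  stats::median(img$pixels[m])
}

migration_result <- function(i_roi1, i_roi2, background_per_px, mode) {
  if (i_roi1 <= 0)
    stop("migration statistic undefined: ROI-1 intensity is zero")
  structure(list(i_roi1 = i_roi1, i_roi2 = i_roi2,
                 background_per_px = background_per_px,
                 percent_migration = 100 * i_roi2 / i_roi1,
                 mode = mode),
            class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf(
    "migration_result (%s): %.2f%%  [I_ROI-1 = %.4g, I_ROI-2 = %.4g, bg/px = %.3g]\n",
    x$mode, x$percent_migration, x$i_roi1, x$i_roi2, x$background_per_px))
  invisible(x)
}

resolve_background <- function(background, img, roi1) {
  if (is.numeric(background)) return(background)
  switch(match.arg(background, c("outside", "none")),
         outside = estimate_background(img, roi1),
         none = 0)
}

#' Relative migration from a post-migration image
#'
#' The core readout of the assay: the summed intensity inside the
#' exclusion-zone ROI as a percentage of the summed intensity inside the
#' whole-well ROI, `100 * I_ROI2 / I_ROI1`. On a lineage-dye channel the
#' total intensity tracks the conserved parental dye mass, so the statistic
#' measures how much of the original population's fluorescence has moved
#' into the zone — independent of how many divisions diluted it.
#'
#' By default each pixel is background-corrected (median intensity outside
#' ROI-1, clipped at zero) before summation; `background = "none"` sums raw
#' intensities, reproducing the bare ratio formula.
#'
#' @param tf A [field_image()] at the end of migration (same channel as the
#'   labeling dye).
#' @param pair An aligned [roi_pair()].
#' @param background `"outside"` (default), `"none"`, or an explicit
#'   counts-per-pixel value.
#' @return A `migration_result`: `i_roi1`, `i_roi2`, `background_per_px`,
#'   `percent_migration`, `mode = "dual"`.
#' @export
relative_migration <- function(tf, pair, background = "outside") {
  stopifnot(inherits(tf, "field_image"), inherits(pair, "roi_pair"))
  w <- ncol(tf$pixels)
  bg <- resolve_background(background, tf, pair$roi1)
  px <- tf$pixels - bg
  px[px < 0] <- 0
  i1 <- sum(px[circle_mask(pair$roi1, w)])
  i2 <- sum(px[circle_mask(pair$roi2, w)])
  migration_result(i1, i2, bg, mode = "dual")
}

#' Single-image relative migration with a standard ROI pair
#'
#' Applies one fixed, reference ROI pair to a post-migration image: the well
#' circle is detected on the t_f image and the standard pair is translated
#' so ROI-1 sits on the detected well center (radii and relative offset
#' unchanged), then the relative-migration statistic is computed. This
#' variant needs no pre-migration image per well, at the cost of ignoring
#' per-well variation in zone placement and size.
#'
#' @param tf A [field_image()] at the end of migration.
#' @param standard A [roi_pair()] with `source = "standard"` (see
#'   [standard_roi_pair()] / [read_roi_pair()]).
#' @param background As in [relative_migration()].
#' @return A `migration_result` with `mode = "single"`.
#' @export
single_image_migration <- function(tf, standard, background = "outside") {
  stopifnot(inherits(standard, "roi_pair"))
  if (standard$source != "standard")
    stop("single_image_migration: pair must be a standard reference pair")
  tf_well <- detect_well_roi(tf)
  aligned <- translate_roi_pair(standard, tf_well$center - standard$roi1$center)
  res <- relative_migration(tf, aligned, background = background)
  res$mode <- "single"
  res
}

#' Count-based (proliferation-confounded) migration readout
#'
#' The conventional exclusion-zone readout on the nuclear-stain channel,
#' against which the dye-based statistic is compared. Two sub-modes:
#' `method = "intensity"` applies the relative-migration intensity formula
#' to the nuclear image (total nuclear signal is proportional to cell
#' count); `method = "count"` segments nuclei ([segment_cells()]) and counts
#' objects whose centroids fall inside each ROI.
#'
#' The denominator defaults to the same t_f image (the literal
#' zone-over-well ratio). Supplying `t0_nuclear` references the zone signal
#' to the *parental* (pre-migration) population instead — the colony
#' expansion readout: cells born in (or out of) the zone during the assay
#' inflate it, which is exactly the proliferation confound the lineage-dye
#' statistic avoids. In a spatially homogeneous culture the t_f-normalized
#' ratio hides that confound by construction (both numerator and denominator
#' scale with growth), so demonstrations of proliferation sensitivity use
#' the t0 reference; see the methods vignette.
#'
#' @param tf_nuclear A nuclear-channel [field_image()] at t_f.
#' @param pair An aligned [roi_pair()].
#' @param t0_nuclear Optional nuclear-channel [field_image()] at t0 used as
#'   the parental reference for ROI-1.
#' @param method `"intensity"` or `"count"`.
#' @param background As in [relative_migration()] (intensity method).
#' @return A `migration_result` with `mode = "count_based"`.
#' @export
count_based_migration <- function(tf_nuclear, pair, t0_nuclear = NULL,
                                  method = c("intensity", "count"),
                                  background = "outside") {
  method <- match.arg(method)
  stopifnot(inherits(tf_nuclear, "field_image"), inherits(pair, "roi_pair"))
  w <- ncol(tf_nuclear$pixels)
  if (method == "intensity") {
    bg <- resolve_background(background, tf_nuclear, pair$roi1)
    px <- tf_nuclear$pixels - bg
    px[px < 0] <- 0
    i2 <- sum(px[circle_mask(pair$roi2, w)])
    ref_img <- if (is.null(t0_nuclear)) px else {
      bg0 <- resolve_background(background, t0_nuclear, pair$roi1)
      p0 <- t0_nuclear$pixels - bg0
      p0[p0 < 0] <- 0
      p0
    }
    i1 <- sum(ref_img[circle_mask(pair$roi1, w)])
    res <- migration_result(i1, i2, bg, mode = "count_based")
  } else {
    mask_tf <- segment_cells(tf_nuclear)
    cen <- mask_tf$per_object
    inside <- function(cen, roi)
      (cen$centroid_x - roi$center[1])^2 + (cen$centroid_y - roi$center[2])^2 <=
        roi$radius^2
    i2 <- if (nrow(cen)) sum(inside(cen, pair$roi2)) else 0
    i1 <- if (is.null(t0_nuclear)) {
      if (nrow(cen)) sum(inside(cen, pair$roi1)) else 0
    } else {
      cen0 <- segment_cells(t0_nuclear)$per_object
      if (nrow(cen0)) sum(inside(cen0, pair$roi1)) else 0
    }
    res <- migration_result(i1, i2, NA_real_, mode = "count_based")
  }
  res
}
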