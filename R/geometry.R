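#' Physical layout of one assay well
#'
#' Describes the circular well, the initially cell-free circular exclusion
#' zone at (or near) its center, and the pixel scale used when rendering or
#' reading micrographs of the well.
#'
#' Defaults correspond to a 96-well barrier-insert plate imaged at low
#' magnification: a 6.4 mm diameter well with a 2 mm diameter exclusion zone,
#' rasterized at 12.5 um/px to a 512 x 512 image.
#'
#' @param well_radius Well radius in um.
#' @param zone_radius Exclusion-zone radius in um.
#' @param zone_center_offset Numeric length-2, zone center relative to the
#'   well center, um.
#' @param pixel_size Pixel pitch in um/px.
#' @return An object of class `well_geometry`.
#' @examples
#' geom <- well_geometry()
#' raster_width(geom)
#' @export
well_geometry <- function(well_radius = 3200, zone_radius = 1000,
                          zone_center_offset = c(0, 0), pixel_size = 12.5) {
  stopifnot(is.numeric(well_radius), length(well_radius) == 1L,
            is.numeric(zone_radius), length(zone_radius) == 1L,
            is.numeric(zone_center_offset), length(zone_center_offset) == 2L,
            is.numeric(pixel_size), length(pixel_size) == 1L)
  if (!is.finite(well_radius) || !is.finite(zone_radius) ||
      any(!is.finite(zone_center_offset)) || !is.finite(pixel_size))
    stop("well_geometry: all fields must be finite")
  if (pixel_size <= 0) stop("well_geometry: pixel_size must be > 0")
  if (zone_radius <= 0 || zone_radius >= well_radius)
    stop("well_geometry: need 0 < zone_radius < well_radius")
  if (sqrt(sum(zone_center_offset^2)) + zone_radius >= well_radius)
    stop("well_geometry: exclusion zone must lie entirely inside the well")
  structure(list(well_radius = well_radius, zone_radius = zone_radius,
                 zone_center_offset = as.numeric(zone_center_offset),
                 pixel_size = pixel_size),
            class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf(
    "well_geometry: well r = %g um, zone r = %g um, zone offset = (%g, %g) um, %g um/px (%d px raster)\n",
    x$well_radius, x$zone_radius, x$zone_center_offset[1],
    x$zone_center_offset[2], x$pixel_size, raster_width(x)))
  invisible(x)
}

#' Raster side length implied by a geometry
#'
#' Images of a well are square with side `ceiling(2 * well_radius /
#' pixel_size)` pixels.
#'
#' @param geometry A [well_geometry()].
#' @return Integer raster side length in pixels.
#' @export
raster_width <- function(geometry) {
  as.integer(ceiling(2 * geometry$well_radius / geometry$pixel_size))
}

# um -> 0-based pixel coordinates (pixel-center convention; pixel (0,0) is
# the top-left pixel center, x grows with column, y with row).
um_to_px <- function(xy_um, geometry) {
  w <- raster_width(geometry)
  cbind(xy_um[, 1] / geometry$pixel_size + w / 2,
        xy_um[, 2] / geometry$pixel_size + w / 2)
}

px_to_um <- function(xy_px, geometry) {
  w <- raster_width(geometry)
  cbind((xy_px[, 1] - w / 2) * geometry$pixel_size,
        (xy_px[, 2] - w / 2) * geometry$pixel_size)
}

#' Circular region of interest
#'
#' A circle in 0-based pixel coordinates (x right, y down, pixel-center
#' convention). A pixel belongs to the ROI when its center lies at distance
#' `<= radius` from the center (boundary ties count as inside).
#'
#' @param center Numeric length-2, circle center `(x, y)` in pixels, 0-based.
#' @param radius Circle radius in pixels.
#' @return An object of class `circle_roi`.
#' @export
circle_roi <- function(center, radius) {
  stopifnot(is.numeric(center), length(center) == 2L,
            is.numeric(radius), length(radius) == 1L)
  if (!all(is.finite(center)) || !is.finite(radius) || radius <= 0)
    stop("circle_roi: radius must be finite and > 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "circle_roi")
}

#' @export
print.circle_roi <- function(x, ...) {
  cat(sprintf("circle_roi: center (%.2f, %.2f) px, radius %.2f px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Pair of quantification ROIs
#'
#' ROI-1 circumscribes the whole labeled well field; ROI-2 delineates the
#' exclusion zone. The pair is rigid: any translation applied to it preserves
#' the relative offset `roi2$center - roi1$center`.
#'
#' @param roi1,roi2 [circle_roi()] objects; `roi2` must lie inside `roi1`.
#' @param source Either `"detected_t0"` (fitted on a pre-migration image) or
#'   `"standard"` (a fixed reference pair applied to many wells).
#' @return An object of class `roi_pair`.
#' @export
roi_pair <- function(roi1, roi2, source = c("detected_t0", "standard")) {
  source <- match.arg(source)
  stopifnot(inherits(roi1, "circle_roi"), inherits(roi2, "circle_roi"))
  d <- sqrt(sum((roi2$center - roi1$center)^2))
  if (d + roi2$radius > roi1$radius + 1e-6)
    stop("roi_pair: roi2 must lie entirely inside roi1")
  structure(list(roi1 = roi1, roi2 = roi2, source = source),
            class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("roi_pair (%s):\n  ROI-1 ", x$source)); print(x$roi1)
  cat("  ROI-2 "); print(x$roi2)
  invisible(x)
}

#' Translate an ROI pair rigidly
#'
#' @param pair A [roi_pair()].
#' @param shift Numeric length-2 `(dx, dy)` in pixels.
#' @return The translated pair (radii and relative offset unchanged).
#' @export
translate_roi_pair <- function(pair, shift) {
  stopifnot(inherits(pair, "roi_pair"), is.numeric(shift), length(shift) == 2L)
  offset <- pair$roi2$center - pair$roi1$center
  pair$roi1$center <- pair$roi1$center + shift
  # rebuild roi2 from the stored offset so the relative position is
  # preserved exactly, not just to rounding
  pair$roi2$center <- pair$roi1$center + offset
  pair
}

#' Standard ROI pair from declared geometry
#'
#' Builds the reference pair used by single-image quantification directly
#' from the nominal well geometry: ROI-1 is the well circle, ROI-2 the
#' exclusion-zone circle, both centered per the geometry.
#'
#' @param geometry A [well_geometry()].
#' @return A [roi_pair()] with `source = "standard"`.
#' @export
standard_roi_pair <- function(geometry) {
  w <- raster_width(geometry)
  c0 <- c(w / 2, w / 2)
  zc <- c0 + geometry$zone_center_offset / geometry$pixel_size
  roi_pair(circle_roi(c0, geometry$well_radius / geometry$pixel_size),
           circle_roi(zc, geometry$zone_radius / geometry$pixel_size),
           source = "standard")
}

#' Save / load a standard ROI pair as JSON
#'
#' The file stores geometry-relative quantities (center offsets and radii in
#' um) so a standard pair transfers across magnifications; pixel coordinates
#' are reconstructed against the supplied geometry on load.
#'
#' @param pair A [roi_pair()].
#' @param path File path.
#' @param geometry A [well_geometry()] giving the pixel scale.
#' @return `write_roi_pair` returns `path` invisibly; `read_roi_pair` returns
#'   a [roi_pair()] with `source = "standard"`.
#' @export
write_roi_pair <- function(pair, path, geometry) {
  ps <- geometry$pixel_size
  w <- raster_width(geometry)
  obj <- list(
    roi1_center_offset_um = (pair$roi1$center - w / 2) * ps,
    roi1_radius_um = pair$roi1$radius * ps,
    roi2_center_offset_um = (pair$roi2$center - w / 2) * ps,
    roi2_radius_um = pair$roi2$radius * ps)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_pair
#' @export
read_roi_pair <- function(path, geometry) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ps <- geometry$pixel_size
  w <- raster_width(geometry)
  roi_pair(
    circle_roi(obj$roi1_center_offset_um / ps + w / 2,
               obj$roi1_radius_um / ps),
    circle_roi(obj$roi2_center_offset_um / ps + w / 2,
               obj$roi2_radius_um / ps),
    source = "standard")
}
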