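#' Fluorescence channel specification
#'
#' Describes how one acquisition channel turns per-cell dye content into
#' pixel intensities: an isotropic Gaussian spot per cell (sigma
#' `psf_sigma`, integrated flux `gain * dye`), a flat background inside the
#' well, optional Poisson (shot) resampling and additive Gaussian read
#' noise. The `nuclear` channel images a nucleic-acid counterstain: every
#' cell contributes flux `gain * 1` regardless of dye content, which makes
#' it the counting channel.
#'
#' The default gain puts the peak of a generation-0 cell near 20% of the
#' 16-bit range, leaving at least five dye halvings clearly above the noise
#' floor.
#'
#' @param name `"violet"`, `"far_red"` or `"nuclear"`.
#' @param psf_sigma Spot sigma, um.
#' @param gain Intensity units per dye unit (integrated over the spot).
#' @param background_level Flat background, counts per pixel.
#' @param read_noise_sd Additive Gaussian noise SD, counts.
#' @param poisson_noise Apply Poisson resampling of the expected image.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name = c("violet", "far_red", "nuclear"),
                         psf_sigma = 15, gain = 1e5,
                         background_level = 100, read_noise_sd = 5,
                         poisson_noise = TRUE) {
  name <- match.arg(name)
  if (psf_sigma <= 0 || gain <= 0 || background_level < 0 || read_noise_sd < 0)
    stop("channel_spec: invalid parameter")
  structure(list(name = name, psf_sigma = psf_sigma, gain = gain,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise)),
            class = "channel_spec")
}

#' A single-channel micrograph raster with metadata
#'
#' Pixel `(0, 0)` is the top-left pixel center; physical coordinates map to
#' pixels via `x / pixel_size + width / 2` (0-based). `pixels[row, col]`
#' stores row = y, col = x.
#'
#' @param pixels Square non-negative numeric matrix with side
#'   [raster_width()] of `geometry`.
#' @param channel Channel name.
#' @param timepoint Timepoint label (e.g. `"t0"`, `"tf"`).
#' @param geometry A [well_geometry()].
#' @param bit_depth `"float"`, `8` or `16`.
#' @param well Optional well label (e.g. `"B03"`).
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, channel, timepoint, geometry,
                        bit_depth = "float", well = NA_character_) {
  w <- raster_width(geometry)
  if (!is.matrix(pixels) || nrow(pixels) != w || ncol(pixels) != w)
    stop(sprintf("field_image: raster must be %d x %d for this geometry", w, w))
  if (any(pixels < 0)) stop("field_image: negative pixel values")
  structure(list(pixels = pixels, channel = channel, timepoint = timepoint,
                 geometry = geometry, bit_depth = bit_depth, well = well),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image: %s %s %s, %d x %d px, range [%g, %g]\n",
              x$well, x$timepoint, x$channel, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Unit-sum Gaussian kernel on a wrapped (periodic) grid of side n.
gaussian_kernel_fft <- function(n, sigma_px) {
  d <- c(0:(n %/% 2), rev(seq_len(n - n %/% 2 - 1L)))
  g <- exp(-d^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  stats::fft(k / sum(k))
}

#' Render a cell snapshot into a synthetic micrograph
#'
#' Each cell contributes an isotropic Gaussian spot of sigma
#' `channel$psf_sigma` integrating to `gain * dye[channel]` (to `gain` per
#' cell for the nuclear channel), on top of a flat background inside the
#' well. Spots are placed with sub-pixel accuracy (bilinear splatting) and
#' convolved with the point-spread kernel by FFT on a padded grid, so the
#' rendered image is exactly linear in dye content and conserves total flux
#' up to field-of-view truncation. With `noise = TRUE` the expected image is
#' Poisson-resampled (if the channel says so) and Gaussian read noise is
#' added from the global RNG. Pixels outside the well circle are zeroed and
#' negative values clipped.
#'
#' @param cells A cell table (see [seed_cells()]).
#' @param geometry A [well_geometry()].
#' @param channel A [channel_spec()].
#' @param timepoint Timepoint label stored in the image.
#' @param noise Master noise switch; `FALSE` returns the deterministic
#'   expected image.
#' @param well Optional well label.
#' @return A [field_image()].
#' @examples
#' geom <- well_geometry(800, 250, pixel_size = 6.25)
#' cells <- seed_cells(assay_config(n_cells = 50, rng_seed = 1), geom)
#' img <- render(cells, geom, channel_spec("violet"), noise = FALSE)
#' @export
render <- function(cells, geometry, channel, timepoint = "t0",
                   noise = TRUE, well = NA_character_) {
  stopifnot(inherits(geometry, "well_geometry"), inherits(channel, "channel_spec"))
  w <- raster_width(geometry)
  sigma_px <- channel$psf_sigma / geometry$pixel_size
  pad <- as.integer(ceiling(4 * sigma_px)) + 2L
  wp <- w + 2L * pad
  img <- matrix(0, w, w)
  n <- nrow(cells)
  if (n > 0L) {
    amp <- if (channel$name == "nuclear") rep(channel$gain, n)
           else channel$gain * cells[[dye_cols[[channel$name]]]]
    pxy <- um_to_px(cbind(cells$x_um, cells$y_um), geometry)
    # bilinear splat into the padded grid (0-based coords + pad)
    px <- pxy[, 1] + pad; py <- pxy[, 2] + pad
    keep <- px >= 0 & px <= wp - 1 & py >= 0 & py <= wp - 1 & amp > 0
    px <- px[keep]; py <- py[keep]; amp <- amp[keep]
    if (length(px)) {
      j0 <- pmin(floor(px), wp - 2); i0 <- pmin(floor(py), wp - 2)
      fx <- px - j0; fy <- py - i0
      acc <- matrix(0, wp, wp)
      idx <- function(i, j) i + 1L + j * wp  # column-major linear index
      add <- function(ii, jj, wgt) {
        lin <- idx(ii, jj)
        s <- rowsum(amp * wgt, group = lin)
        acc[as.integer(rownames(s))] <<- acc[as.integer(rownames(s))] + s[, 1]
      }
      add(i0,     j0,     (1 - fx) * (1 - fy))
      add(i0 + 1, j0,     (1 - fx) * fy)
      add(i0,     j0 + 1, fx * (1 - fy))
      add(i0 + 1, j0 + 1, fx * fy)
      kf <- gaussian_kernel_fft(wp, sigma_px)
      sm <- Re(stats::fft(stats::fft(acc) * kf, inverse = TRUE)) / wp^2
      img <- sm[(pad + 1):(pad + w), (pad + 1):(pad + w)]
      img[img < 0] <- 0  # FFT ringing at machine-precision level
    }
  }
  img <- img + channel$background_level
  if (noise) {
    if (channel$poisson_noise)
      img <- matrix(stats::rpois(w * w, img), w, w)
    if (channel$read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(w * w, 0, channel$read_noise_sd), w, w)
  }
  # zero outside the well circle (pixel-center rule)
  ctr <- w / 2
  coords <- (0:(w - 1)) - ctr
  outside <- outer(coords^2, coords^2, "+") > (geometry$well_radius / geometry$pixel_size)^2
  img[outside] <- 0
  img[img < 0] <- 0
  field_image(img, channel$name, timepoint, geometry, bit_depth = "float",
              well = well)
}

#' Canonical image file name
#'
#' The naming dialect is `{well}_{timepoint}_{channel}.tif`, e.g.
#' `B03_t0_violet.tif`.
#'
#' @param well,timepoint,channel Labels.
#' @return File name (no directory).
#' @export
image_filename <- function(well, timepoint, channel) {
  sprintf("%s_%s_%s.tif", well, timepoint, channel)
}

parse_image_filename <- function(path) {
  base <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3L)
    stop("cannot parse image file name (want {well}_{timepoint}_{channel}.tif): ",
         path)
  list(well = paste(parts[seq_len(length(parts) - 2L)], collapse = "_"),
       timepoint = parts[length(parts) - 1L],
       channel = parts[length(parts)])
}

#' Write / read a field image as TIFF
#'
#' Images are stored as single-plane grayscale TIFF. 16-bit output is
#' lossless for integer counts in `[0, 65535]`: `read_image(write_image(x))`
#' reproduces the quantized raster exactly; values beyond the range saturate.
#'
#' @param img A [field_image()].
#' @param path File path; for `read_image` an existing TIFF.
#' @param bit_depth 8 or 16.
#' @return `write_image` returns `path` invisibly. `read_image` returns a
#'   [field_image()] whose metadata is parsed from the file name.
#' @export
write_image <- function(img, path, bit_depth = 16L) {
  stopifnot(inherits(img, "field_image"), bit_depth %in% c(8L, 16L))
  maxval <- 2^bit_depth - 1
  q <- round(img$pixels)
  q[q < 0] <- 0
  q[q > maxval] <- maxval
  tiff::writeTIFF(q / maxval, path, bits.per.sample = bit_depth,
                  compression = "none")
  invisible(path)
}

#' @rdname write_image
#' @param geometry A [well_geometry()]; raster dimensions must match.
#' @param channel Optional channel override (otherwise parsed from the file
#'   name).
#' @export
read_image <- function(path, geometry, channel = NULL) {
  if (!file.exists(path)) stop("cannot read image (no such file): ", path)
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                 error = function(e) stop("cannot read image ", path, ": ",
                                          conditionMessage(e)))
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  w <- raster_width(geometry)
  if (nrow(px) != w || ncol(px) != w)
    stop(sprintf("image %s is %d x %d but geometry implies %d x %d",
                 path, nrow(px), ncol(px), w, w))
  meta <- parse_image_filename(path)
  field_image(px, channel %||% meta$channel, meta$timepoint, geometry,
              bit_depth = 16, well = meta$well)
}

#' Read a directory of well images
#'
#' Reads every `*.tif` matching the `{well}_{timepoint}_{channel}.tif`
#' dialect and returns the images along with a manifest.
#'
#' @param dir Directory path.
#' @param geometry A [well_geometry()].
#' @return List with `images` (list of [field_image()]) and `manifest`
#'   (data.frame: file, well, timepoint, channel).
#' @export
read_image_dir <- function(dir, geometry) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("no TIFF images found in ", dir)
  imgs <- lapply(files, read_image, geometry = geometry)
  manifest <- do.call(rbind, lapply(seq_along(files), function(i)
    data.frame(file = basename(files[i]), well = imgs[[i]]$well,
               timepoint = imgs[[i]]$timepoint, channel = imgs[[i]]$channel)))
  list(images = imgs, manifest = manifest)
}
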