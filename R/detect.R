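# --- circle fitting ---------------------------------------------------------

# Algebraic least-squares circle fit (Kasa): solve 2*cx*x + 2*cy*y + c =
# x^2 + y^2.
fit_circle_kasa <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  c(cx = sol[1], cy = sol[2],
    r = sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, .Machine$double.eps)))
}

# Geometric Gauss-Newton refinement of (cx, cy, r).
refine_circle_gn <- function(x, y, p, iters = 2L) {
  for (k in seq_len(iters)) {
    dx <- x - p[1]; dy <- y - p[2]
    d <- sqrt(dx^2 + dy^2)
    d[d < 1e-9] <- 1e-9
    J <- cbind(-dx / d, -dy / d, -1)
    res <- d - p[3]
    step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
    p <- p + step
  }
  names(p) <- c("cx", "cy", "r")
  p
}

# --- image helpers ----------------------------------------------------------

# Light Gaussian smoothing (EBImage, sigma 1 px) to suppress pixel noise
# before thresholding; heavier smoothing is applied separately where the
# granularity of the cell field itself must be averaged out.
smooth_for_detection <- function(mat, sigma = 1) {
  mx <- max(mat)
  if (mx <= 0) return(mat)
  as.matrix(EBImage::gblur(mat / mx, sigma = sigma)) * mx
}

otsu_threshold <- function(mat) {
  mx <- max(mat)
  if (mx <= 0) stop("otsu_threshold: image has no signal")
  EBImage::otsu(EBImage::Image(mat / mx), range = c(0, 1), levels = 256L) * mx
}

# Bilinear sampling at 0-based pixel coordinates; NA outside the raster.
sample_bilinear <- function(mat, x, y) {
  w <- ncol(mat); h <- nrow(mat)
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  j0 <- pmin(floor(x), w - 2); i0 <- pmin(floor(y), h - 2)
  fx <- x - j0; fy <- y - i0
  v00 <- mat[cbind(i0 + 1, j0 + 1)]; v10 <- mat[cbind(i0 + 2, j0 + 1)]
  v01 <- mat[cbind(i0 + 1, j0 + 2)]; v11 <- mat[cbind(i0 + 2, j0 + 2)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v10 * (1 - fx) * fy +
    v01 * fx * (1 - fy) + v11 * fx * fy
  out
}

# Sub-pixel refinement of a circle by radial edge localization. The image
# is sampled on polar sectors around the current center; profiles are
# averaged over the rays of each sector (suppressing the granularity of the
# discrete cell field), and each sector contributes the radius at which its
# averaged profile crosses the midpoint between the global inside and
# outside levels. A circle is re-fit (Kasa + Gauss-Newton) to the crossing
# points; two passes let the center estimate converge. `rising = FALSE` for
# a bright-inside edge (the well boundary), `TRUE` for a dark-inside edge
# (the exclusion zone).
refine_circle_edge <- function(mat, p, rising, n_sectors = 36L,
                               rays_per_sector = 7L, span = 8, step = 0.5,
                               iters = 2L) {
  for (it in seq_len(iters)) {
    # sample well beyond the edge so the inside/outside levels are taken
    # clear of the blurred edge ramp
    rs <- seq(max(p[3] - 2 * span, 0.5), p[3] + 2 * span, by = step)
    mid <- (seq_len(n_sectors) - 0.5) / n_sectors * 2 * pi
    prof_by_sector <- vector("list", n_sectors)
    inner_lv <- outer_lv <- rep(NA_real_, n_sectors)
    for (s in seq_len(n_sectors)) {
      dth <- (seq_len(rays_per_sector) - (rays_per_sector + 1) / 2) /
        rays_per_sector * (2 * pi / n_sectors)
      acc <- matrix(NA_real_, length(rs), rays_per_sector)
      for (j in seq_len(rays_per_sector)) {
        th <- mid[s] + dth[j]
        acc[, j] <- sample_bilinear(mat, p[1] + rs * cos(th),
                                    p[2] + rs * sin(th))
      }
      prof <- rowMeans(acc)
      if (mean(is.na(prof)) > 0.35) next
      prof_by_sector[[s]] <- prof
      inner_lv[s] <- stats::median(prof[rs < p[3] - span], na.rm = TRUE)
      outer_lv[s] <- stats::median(prof[rs > p[3] + span], na.rm = TRUE)
    }
    inner <- stats::median(inner_lv, na.rm = TRUE)
    outer_ <- stats::median(outer_lv, na.rm = TRUE)
    if (!is.finite(inner) || !is.finite(outer_)) return(p)
    half <- (inner + outer_) / 2
    pts_x <- numeric(0); pts_y <- numeric(0)
    for (s in seq_len(n_sectors)) {
      prof <- prof_by_sector[[s]]
      if (is.null(prof)) next
      sgn <- if (rising) prof > half else prof < half
      cross <- which(!is.na(sgn) & sgn & c(FALSE, !sgn[-length(sgn)]))
      cross <- cross[cross > 1L]
      if (!length(cross)) next
      k <- cross[which.min(abs(rs[cross] - p[3]))]
      v1 <- prof[k - 1L]; v2 <- prof[k]
      frac <- if (is.na(v1) || v2 == v1) 0.5 else (half - v1) / (v2 - v1)
      rc <- rs[k - 1L] + frac * step
      pts_x <- c(pts_x, p[1] + rc * cos(mid[s]))
      pts_y <- c(pts_y, p[2] + rc * sin(mid[s]))
    }
    if (length(pts_x) < max(8L, n_sectors %/% 3L)) return(p)
    p <- refine_circle_gn(pts_x, pts_y, fit_circle_kasa(pts_x, pts_y))
  }
  p
}

# Initial circle through the outermost pixels of a labeled component:
# per-angle maximum radius about the component centroid, Kasa + GN.
component_outer_circle <- function(rows, cols, n_bins = 90L) {
  x <- cols - 1; y <- rows - 1  # 0-based pixel coords
  cx <- mean(x); cy <- mean(y)
  ang <- atan2(y - cy, x - cx)
  rad <- sqrt((x - cx)^2 + (y - cy)^2)
  bin <- pmin(floor((ang + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  sel <- vapply(split(seq_along(rad), bin),
                function(ii) ii[which.max(rad[ii])], integer(1))
  p <- fit_circle_kasa(x[sel], y[sel])
  refine_circle_gn(x[sel], y[sel], p)
}

# --- ROI detection ----------------------------------------------------------

#' Detect the whole-well ROI on a pre-migration image
#'
#' Thresholds the median-filtered image (Otsu), takes the largest connected
#' foreground component (the labeled cell field), fits a circle to its
#' outermost edge pixels by least squares, and refines center and radius to
#' sub-pixel accuracy by localizing the falling intensity edge along radial
#' profiles. The fitted circle corresponds to ROI-1: it circumscribes the
#' labeled field, which coincides with the inner wall of the well.
#'
#' @param t0 A [field_image()] of the labeled cell field (dye channel).
#' @return A [circle_roi()] in 0-based pixel coordinates.
#' @export
detect_well_roi <- function(t0) {
  stopifnot(inherits(t0, "field_image"))
  f <- smooth_for_detection(t0$pixels)
  if (max(f) <= 0) stop("detect_well_roi: blank image, no foreground")
  th <- otsu_threshold(f)
  fg <- f > th
  if (!any(fg)) stop("detect_well_roi: no foreground after thresholding")
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  w <- which(lab == comp, arr.ind = TRUE)
  p <- component_outer_circle(w[, 1], w[, 2])
  p <- refine_circle_edge(f, p, rising = FALSE)
  circle_roi(c(p[1], p[2]), p[3])
}

#' Detect the exclusion-zone ROI on a pre-migration image
#'
#' Inside ROI-1, thresholds the image (Otsu computed on the central region),
#' takes the connected below-threshold component that contains the ROI-1
#' center — the cell-free exclusion zone — and fits and refines a circle to
#' its boundary (rising radial edge). Fails with an informative error when
#' no central cell-free region exists (well already confluent, or t0/tf
#' swapped).
#'
#' @param t0 A [field_image()] of the labeled cell field at t0.
#' @param roi1 The [circle_roi()] from [detect_well_roi()] on the same image.
#' @return A [circle_roi()] delineating the exclusion zone.
#' @export
detect_exclusion_zone <- function(t0, roi1) {
  stopifnot(inherits(t0, "field_image"), inherits(roi1, "circle_roi"))
  f <- smooth_for_detection(t0$pixels)
  # Heavier blur for the zone *component*: averages out the granularity of
  # the confluent cell field so inter-cell gaps cannot connect the zone to
  # voids in the field. Edge positions are refined on the lightly smoothed
  # image afterwards.
  g <- smooth_for_detection(t0$pixels, sigma = 5)
  # Otsu on the square inscribed in roi1: contains the zone plus labeled
  # field, unpolluted by the outside-well zeros.
  half <- roi1$radius / sqrt(2) * 0.95
  r0 <- max(round(roi1$center[2] - half), 0) + 1L
  r1 <- min(round(roi1$center[2] + half), nrow(g) - 1) + 1L
  c0 <- max(round(roi1$center[1] - half), 0) + 1L
  c1 <- min(round(roi1$center[1] + half), ncol(g) - 1) + 1L
  th <- otsu_threshold(g[r0:r1, c0:c1])
  w <- ncol(f)
  coords <- 0:(w - 1)
  inside1 <- outer((coords - roi1$center[2])^2, (coords - roi1$center[1])^2,
                   "+") <= roi1$radius^2
  bg <- (g < th) & inside1
  # morphological opening severs any remaining thin bridges between the
  # zone and chance voids in the cell field
  bg <- as.matrix(EBImage::opening(bg, EBImage::makeBrush(5, "disc"))) > 0
  ci <- round(roi1$center[2]) + 1L; cj <- round(roi1$center[1]) + 1L
  if (ci < 1L || ci > nrow(f) || cj < 1L || cj > ncol(f) || !bg[ci, cj])
    stop("detect_exclusion_zone: no cell-free zone at the well center ",
         "(migration complete, or t0/tf images swapped)")
  lab <- EBImage::bwlabel(bg)
  comp <- lab[ci, cj]
  wpix <- which(lab == comp, arr.ind = TRUE)
  if (nrow(wpix) < 16L)
    stop("detect_exclusion_zone: central cell-free component too small")
  p <- component_outer_circle(wpix[, 1], wpix[, 2])
  p <- refine_circle_edge(f, p, rising = TRUE)
  roi2 <- circle_roi(c(p[1], p[2]), p[3])
  d <- sqrt(sum((roi2$center - roi1$center)^2))
  if (d + roi2$radius > roi1$radius)
    stop("detect_exclusion_zone: fitted zone extends outside the well ROI")
  roi2
}

#' Detect both ROIs on a pre-migration image
#'
#' Convenience wrapper: [detect_well_roi()] then [detect_exclusion_zone()].
#'
#' @param t0 A [field_image()] at t0 (dye channel).
#' @return A [roi_pair()] with `source = "detected_t0"`.
#' @export
detect_roi_pair <- function(t0) {
  roi1 <- detect_well_roi(t0)
  roi2 <- detect_exclusion_zone(t0, roi1)
  roi_pair(roi1, roi2, source = "detected_t0")
}

#' Align an ROI pair onto a post-migration image
#'
#' Detects the well circle on the t_f image (same procedure as
#' [detect_well_roi()]) and translates the pair rigidly so that ROI-1 is
#' centered on it — the pasting step of the assay: both ROIs keep their
#' radii and relative offset, and only a translation is applied (a circular
#' well offers no rotation cue).
#'
#' @param pair A [roi_pair()] detected on the matching t0 image.
#' @param tf A [field_image()] at the end of the migration period.
#' @return The translated [roi_pair()].
#' @export
align_roi_pair <- function(pair, tf) {
  stopifnot(inherits(pair, "roi_pair"))
  if (pair$source != "detected_t0")
    stop("align_roi_pair: pair must come from t0 detection; ",
         "standard pairs are aligned inside single_image_migration()")
  tf_well <- detect_well_roi(tf)
  translate_roi_pair(pair, tf_well$center - pair$roi1$center)
}
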