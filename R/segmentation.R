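#' Binary mask with physical scale
#'
#' Lightweight container pairing a logical pixel matrix with its physical
#' pixel size (nm/px) and, optionally, the time-lapse frame it belongs to.
#'
#' @param pixels logical matrix (TRUE = inside the structure).
#' @param pixel_size_nm physical pixel size, nm per pixel.
#' @param frame optional frame index the mask was computed from.
#' @return An object of class `org_mask`.
#' @export
new_mask <- function(pixels, pixel_size_nm, frame = NULL) {
  if (is.numeric(pixels)) pixels <- pixels > 0.5
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix")
  stop_if_not_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 frame = frame), class = "org_mask")
}

#' @export
print.org_mask <- function(x, ...) {
  cat(sprintf("<org_mask> %d x %d px, %.3g nm/px, %d positive (%.1f%%)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              sum(x$pixels), 100 * mean(x$pixels),
              if (is.null(x$frame)) "" else sprintf(", frame %d", x$frame)))
  invisible(x)
}

as_mask <- function(x, pixel_size_nm = NULL) {
  if (inherits(x, "org_mask")) return(x)
  if (is.null(pixel_size_nm))
    stop("a raw matrix mask needs an explicit `pixel_size_nm`")
  new_mask(x, pixel_size_nm)
}

# Exhaustive Otsu: quantize to 256 levels across the intensity range and
# return the cut maximizing between-class variance, in original units.
# Ties resolve to the lowest cut.
otsu_threshold <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) stop("image contains non-finite values")
  if (rng[1] == rng[2])
    stop("constant image: Otsu threshold is undefined")
  lev <- pmin(255L, as.integer(floor((img - rng[1]) / (rng[2] - rng[1]) * 256)))
  h <- tabulate(as.vector(lev) + 1L, nbins = 256L)
  n <- sum(h)
  cw <- cumsum(h)                       # pixels at level <= t
  cm <- cumsum(h * (0:255))             # level-weighted cumulative sum
  total_mean <- cm[256] / n
  t_all <- 0:254
  w1 <- cw[t_all + 1L] / n
  m1 <- ifelse(w1 > 0, cm[t_all + 1L] / cw[t_all + 1L], 0)
  w2 <- 1 - w1
  m2 <- ifelse(w2 > 0, (cm[256] - cm[t_all + 1L]) / (n - cw[t_all + 1L]), 0)
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  t_star <- t_all[which.max(bcv)]
  # threshold in original units: upper edge of the optimal level
  rng[1] + (t_star + 1) / 256 * (rng[2] - rng[1])
}

#' Segment an organelle channel into a binary mask
#'
#' Thresholds a fluorescence frame (Otsu's method or a fixed cutoff) and
#' removes connected components smaller than `min_object_px`.
#'
#' @param frame intensity matrix.
#' @param method `"otsu"` (histogram-based, exhaustive over 256 levels) or
#'   `"fixed_threshold"`.
#' @param threshold intensity cutoff, required for `"fixed_threshold"`;
#'   pixels strictly above it are foreground.
#' @param min_object_px components with fewer pixels are dropped.
#' @param pixel_size_nm physical pixel size recorded on the mask.
#' @param frame_index optional frame index recorded on the mask.
#' @return An [new_mask()] object.
#' @examples
#' img <- matrix(10, 64, 64); img[20:30, 20:40] <- 200
#' m <- segment_organelle(img, pixel_size_nm = 80)
#' sum(m$pixels) == 11 * 21
#' @export
segment_organelle <- function(frame,
                              method = c("otsu", "fixed_threshold"),
                              threshold = NULL, min_object_px = 0L,
                              pixel_size_nm = 80, frame_index = NULL) {
  method <- match.arg(method)
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("`frame` must be a numeric matrix")
  thr <- switch(method,
    otsu = otsu_threshold(frame),
    fixed_threshold = {
      stop_if_not_scalar_number(threshold %||% stop("`threshold` required"),
                                "threshold")
      threshold
    })
  px <- frame > thr
  if (min_object_px > 0 && any(px)) {
    lab <- label_components(px)
    counts <- tabulate(lab[lab > 0])
    keep <- which(counts >= min_object_px)
    px <- matrix(lab %in% keep, nrow(px), ncol(px)) & px
  }
  m <- new_mask(px, pixel_size_nm, frame_index)
  m$threshold <- thr
  m
}

#' Segment the cytoplasm from a plasma-membrane stain
#'
#' Finds the closed cell outline drawn by a membrane stain, fills its
#' interior and returns the largest connected region. Small gaps in the
#' outline (up to about twice `close_radius_px`) are sealed by morphological
#' closing before filling.
#'
#' @param membrane_frame intensity matrix of the membrane channel.
#' @param pixel_size_nm physical pixel size recorded on the mask.
#' @param close_radius_px radius of the closing brush, px.
#' @return An [new_mask()] object covering the filled cell interior.
#' @export
segment_cytoplasm <- function(membrane_frame, pixel_size_nm = 80,
                              close_radius_px = 3L) {
  thr <- otsu_threshold(membrane_frame)  # errors on a blank/constant frame
  ring <- membrane_frame > thr
  if (!any(ring)) stop("no membrane signal above threshold")
  closed <- dilate_mask(ring, close_radius_px)
  filled <- fill_holes(closed)
  interior_gain <- sum(filled) - sum(closed)
  if (interior_gain < sum(ring))
    stop("no closed membrane contour found: filling added almost no interior")
  cell <- largest_component(erode_mask(filled, close_radius_px))
  new_mask(cell, pixel_size_nm)
}

#' Euclidean distance map to a mask
#'
#' Per-pixel minimal Euclidean distance, in nanometres, from each pixel
#' center to the nearest mask-positive pixel center; exactly zero on the
#' mask itself.
#'
#' @param mask an [new_mask()] object (or logical matrix plus
#'   `pixel_size_nm`).
#' @param pixel_size_nm used only when `mask` is a raw matrix.
#' @return An object of class `distance_map`: list with `distances_nm`
#'   (numeric matrix) and `pixel_size_nm`.
#' @examples
#' px <- matrix(FALSE, 64, 64); px[10, 13] <- TRUE
#' dm <- distance_map(new_mask(px, 80))
#' dm$distances_nm[10, 10]  # 3 px * 80 nm = 240 nm
#' @export
distance_map <- function(mask, pixel_size_nm = NULL) {
  mask <- as_mask(mask, pixel_size_nm)
  if (!any(mask$pixels))
    stop("empty mask: distance map is undefined")
  d_px <- EBImage::imageData(
    EBImage::distmap(as_ebimage(!mask$pixels), metric = "euclidean"))
  structure(list(distances_nm = d_px * mask$pixel_size_nm,
                 pixel_size_nm = mask$pixel_size_nm),
            class = "distance_map")
}

#' Minimal distances from subpixel points to a mask
#'
#' Exact Euclidean distance, in nanometres, from each subpixel `(row, col)`
#' point to the nearest mask-positive pixel center. A point whose nearest
#' integer pixel is itself mask-positive lies inside the structure and gets
#' distance 0. This is evaluated exactly (ring search over pixel centers),
#' not by interpolating a distance map.
#'
#' @param mask an [new_mask()] object or logical matrix.
#' @param row,col numeric vectors of subpixel coordinates (1-based, pixel
#'   centers at integers).
#' @param pixel_size_nm used only when `mask` is a raw matrix.
#' @return Numeric vector of distances, nm.
#' @export
point_mask_distance <- function(mask, row, col, pixel_size_nm = NULL) {
  mask <- as_mask(mask, pixel_size_nm)
  if (!any(mask$pixels))
    stop("empty mask: distances are undefined")
  nearest_mask_dist_px(mask$pixels, as.numeric(row), as.numeric(col)) *
    mask$pixel_size_nm
}
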