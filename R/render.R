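#' Render a synthetic multi-channel time-lapse stack
#'
#' Renders four channels per frame: `puncta` (Gaussian spots of SD
#' `psf_sigma_nm` at the simulated trajectory positions), `er` and `mito`
#' (the per-frame organelle masks blurred by the PSF), and `membrane` (the
#' cytoplasm outline, as drawn by a plasma-membrane stain). Shot noise is
#' applied as Poisson resampling at `noise_poisson_scale` photons per
#' intensity unit, followed by additive Gaussian read noise; setting both
#' noise parameters to 0 gives a noiseless render.
#'
#' @param cell a [generate_cell_geometry()] result.
#' @param ts the matching [simulate_puncta_tracks()] result.
#' @param params the [cell_params()] used (defaults to `cell$params`).
#' @param spot_amplitude peak intensity of one punctum above background.
#' @param organelle_intensity intensity of organelle mask pixels before blur.
#' @param background baseline intensity of every channel.
#' @return An object of class `image_stack`: list with `data` (array
#'   `rows x cols x 4 channels x n_frames`), `channels`, `pixel_size_nm`.
#' @export
render_timelapse <- function(cell, ts, params = cell$params,
                             spot_amplitude = 150, organelle_intensity = 140,
                             background = 10) {
  stopifnot(inherits(cell, "synthetic_cell"), inherits(ts, "track_set"))
  ps <- params$pixel_size_nm
  sigma_px <- params$psf_sigma_nm / ps
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  nf <- ts$n_frames
  channels <- c("puncta", "er", "mito", "membrane")
  arr <- array(background, dim = c(nr, nc, 4L, nf),
               dimnames = list(NULL, NULL, channels, NULL))

  er_masks <- frame_organelle_masks(cell, ts, "er")
  mito_masks <- frame_organelle_masks(cell, ts, "mito")
  cyto <- cell$cytoplasm_mask$pixels
  ring <- cyto & !erode_mask(cyto, 3L)

  blur <- function(m) {
    if (!any(m)) return(matrix(0, nr, nc))
    EBImage::imageData(EBImage::gblur(as_ebimage(m), sigma = sigma_px))
  }
  ring_img <- organelle_intensity * blur(ring)

  for (f in seq_len(nf)) {
    pts <- ts$tracks[ts$tracks$frame == f, , drop = FALSE]
    arr[, , "puncta", f] <- arr[, , "puncta", f] +
      render_spots(nr, nc, pts$row_px, pts$col_px, sigma_px, spot_amplitude)
    arr[, , "er", f] <- arr[, , "er", f] +
      organelle_intensity * blur(er_masks[[f]]$pixels)
    arr[, , "mito", f] <- arr[, , "mito", f] +
      organelle_intensity * blur(mito_masks[[f]]$pixels)
    arr[, , "membrane", f] <- arr[, , "membrane", f] + ring_img
  }

  with_seed(params$seed, offset = 303L, {
    if (params$noise_poisson_scale > 0) {
      lam <- pmax(arr * params$noise_poisson_scale, 0)
      arr[] <- rpois(length(lam), lam) / params$noise_poisson_scale
    }
    if (params$noise_gaussian_sd > 0)
      arr[] <- arr + rnorm(length(arr), 0, params$noise_gaussian_sd)
  })

  structure(list(data = arr, channels = channels, pixel_size_nm = ps,
                 cell_id = ts$cell_id), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d channels (%s), %d frames, %.3g nm/px\n",
              d[1], d[2], d[3], paste(x$channels, collapse = "/"),
              d[4], x$pixel_size_nm))
  invisible(x)
}

#' Extract one frame of one channel from an image stack
#'
#' @param stack an `image_stack`.
#' @param channel channel name (`"puncta"`, `"er"`, `"mito"`, `"membrane"`).
#' @param frame frame index.
#' @return Intensity matrix.
#' @export
stack_frame <- function(stack, channel, frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  channel <- match.arg(channel, stack$channels)
  stack$data[, , channel, frame]
}

# Additive Gaussian spots, evaluated on a +/- 4 sigma window per spot.
render_spots <- function(nr, nc, row, col, sigma_px, amplitude) {
  img <- matrix(0, nr, nc)
  w <- as.integer(ceiling(4 * sigma_px))
  for (i in seq_along(row)) {
    r0 <- max(1L, as.integer(floor(row[i])) - w)
    r1 <- min(nr, as.integer(ceiling(row[i])) + w)
    c0 <- max(1L, as.integer(floor(col[i])) - w)
    c1 <- min(nc, as.integer(ceiling(col[i])) + w)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    g <- amplitude *
      exp(-(outer((rr - row[i])^2, (cc - col[i])^2, `+`)) / (2 * sigma_px^2))
    img[rr, cc] <- img[rr, cc] + g
  }
  img
}
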