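#' Track set container
#'
#' A set of punctum trajectories from one cell: a long-format data frame of
#' time-ordered subpixel detections plus the physical scale and frame count.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `row_px`,
#'   `col_px` and optionally `intensity`. Frames must be strictly increasing
#'   within each track and track ids unique per cell.
#' @param pixel_size_nm physical pixel size, nm per pixel.
#' @param n_frames number of frames in the source movie.
#' @param cell_id identifier of the source cell.
#' @param truth optional data.frame (`track_id`, `associated`) carrying
#'   generator ground truth.
#' @param organelle_offsets optional per-frame rigid organelle offsets
#'   (columns `frame`, `er_drow_px`, `er_dcol_px`, `mito_drow_px`,
#'   `mito_dcol_px`) recorded by the simulator.
#' @param step_magnitudes_px optional per-track list of stored step lengths
#'   (px); set by [randomize_tracks()] so that rigid motions preserve step
#'   lengths exactly rather than to floating-point rounding.
#' @return An object of class `track_set`.
#' @export
new_track_set <- function(tracks, pixel_size_nm, n_frames,
                          cell_id = "cell_1", truth = NULL,
                          organelle_offsets = NULL,
                          step_magnitudes_px = NULL) {
  req <- c("track_id", "frame", "row_px", "col_px")
  if (!is.data.frame(tracks) || !all(req %in% names(tracks)))
    stop("`tracks` needs columns track_id, frame, row_px, col_px")
  if (!"intensity" %in% names(tracks))
    tracks$intensity <- rep(NA_real_, nrow(tracks))
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  bad <- vapply(split(tracks$frame, tracks$track_id),
                function(f) any(diff(f) <= 0), logical(1))
  if (any(bad)) stop("frame indices must be strictly increasing per track")
  stop_if_not_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(list(tracks = tracks, pixel_size_nm = pixel_size_nm,
                 n_frames = as.integer(n_frames), cell_id = cell_id,
                 truth = truth, organelle_offsets = organelle_offsets,
                 step_magnitudes_px = step_magnitudes_px),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> cell %s: %d tracks, %d detections over %d frames\n",
              x$cell_id, length(unique(x$tracks$track_id)),
              nrow(x$tracks), x$n_frames))
  invisible(x)
}

#' Within-track step lengths of a track set
#'
#' Frame-to-frame displacement magnitudes, pooled over tracks, in pixels.
#' For track sets produced by [randomize_tracks()] the stored step lengths
#' of the parent set are returned, making rigid-motion shape preservation
#' exact (bit-identical) rather than up to floating-point rounding.
#'
#' @param ts a [new_track_set()] object.
#' @return Numeric vector of step lengths (px), ordered by track then frame.
#' @export
track_step_magnitudes <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (!is.null(ts$step_magnitudes_px))
    return(unlist(ts$step_magnitudes_px, use.names = FALSE))
  unlist(lapply(split(ts$tracks, ts$tracks$track_id), function(tr) {
    sqrt(diff(tr$row_px)^2 + diff(tr$col_px)^2)
  }), use.names = FALSE)
}

#' Simulate punctum trajectories inside a synthetic cell
#'
#' Seeds `n_puncta` puncta at frame 1 - each one organelle-associated with
#' probability `p_assoc` (placed within `assoc_radius_nm` of the target
#' organelle) or else uniformly in the cytoplasm - and propagates them over
#' frames. Free puncta take isotropic Gaussian steps
#' (`diffusion_step_sd_nm`/frame) reflected at the cytoplasm boundary.
#' Associated puncta ride their organelle's per-frame rigid jitter plus a
#' small mean-reverting tether residual (an AR(1) with SD one quarter of the
#' free step SD), so they track the organelle instead of diffusing away.
#' Every trajectory point lies inside the cytoplasm mask.
#'
#' @param cell a [generate_cell_geometry()] result.
#' @param params the [cell_params()] used (defaults to `cell$params`).
#' @return A [new_track_set()] with ground-truth `truth$associated` flags
#'   and the per-frame `organelle_offsets` realised for this cell.
#' @export
simulate_puncta_tracks <- function(cell, params = cell$params) {
  stopifnot(inherits(cell, "synthetic_cell"), inherits(params, "cell_params"))
  ps <- params$pixel_size_nm
  cyto <- cell$cytoplasm_mask$pixels
  target <- switch(params$assoc_target, er = cell$er_mask$pixels,
                   mito = cell$mito_mask$pixels)
  if (params$p_assoc > 0 && !any(target))
    stop(sprintf("p_assoc > 0 but the %s mask is empty: association is unsatisfiable",
                 params$assoc_target))
  with_seed(params$seed, offset = 202L, {
    nf <- params$n_frames; np <- params$n_puncta
    # rigid organelle jitter: cumulative Gaussian walk, px units, frame 1 = 0
    sd_org <- params$organelle_motion_sd_nm / ps
    offs <- data.frame(frame = seq_len(nf),
                       er_drow_px = cumsum(c(0, rnorm(nf - 1, 0, sd_org))),
                       er_dcol_px = cumsum(c(0, rnorm(nf - 1, 0, sd_org))),
                       mito_drow_px = cumsum(c(0, rnorm(nf - 1, 0, sd_org))),
                       mito_dcol_px = cumsum(c(0, rnorm(nf - 1, 0, sd_org))))
    associated <- if (np > 0) runif(np) < params$p_assoc else logical(0)

    seed_pos <- seed_puncta(cyto, target, associated,
                            params$assoc_radius_nm / ps)

    sd_free <- params$diffusion_step_sd_nm / ps
    sd_res <- 0.25 * sd_free
    org_cols <- if (params$assoc_target == "er")
      c("er_drow_px", "er_dcol_px") else c("mito_drow_px", "mito_dcol_px")

    pos <- array(NA_real_, dim = c(np, 2L, nf))
    pos[, , 1] <- seed_pos
    res <- matrix(0, np, 2L)  # tether residual of associated puncta
    if (nf > 1) for (f in 2:nf) {
      step_free <- matrix(rnorm(2L * np, 0, max(sd_free, 0)), np, 2L)
      step_res <- matrix(rnorm(2L * np, 0, max(sd_res, 0)), np, 2L)
      for (i in seq_len(np)) {
        prev <- pos[i, , f - 1]
        if (associated[i]) {
          res_new <- 0.7 * res[i, ] + step_res[i, ]
          prop <- seed_pos[i, ] + as.numeric(offs[f, org_cols]) + res_new
          if (all(points_in_mask(cyto, prop[1], prop[2]))) {
            pos[i, , f] <- prop; res[i, ] <- res_new
          } else pos[i, , f] <- prev
        } else {
          prop <- prev + step_free[i, ]
          if (points_in_mask(cyto, prop[1], prop[2])) {
            pos[i, , f] <- prop
          } else {
            refl <- prev - step_free[i, ]  # reflected step
            pos[i, , f] <- if (points_in_mask(cyto, refl[1], refl[2]))
              refl else prev
          }
        }
      }
    }

    tracks <- data.frame(
      track_id = rep(seq_len(np), each = nf),
      frame = rep(seq_len(nf), times = np),
      row_px = as.vector(aperm(pos, c(3, 1, 2))[, , 1]),
      col_px = as.vector(aperm(pos, c(3, 1, 2))[, , 2]))
    new_track_set(tracks, ps, nf, cell_id = sprintf("cell_%d", params$seed),
                  truth = data.frame(track_id = seq_len(np),
                                     associated = associated),
                  organelle_offsets = offs)
  })
}

# Frame-1 positions: associated puncta within assoc_radius_px of the target
# mask (verified on the exact subpixel distance), free puncta uniform over
# the cytoplasm. Subpixel jitter is uniform within the chosen pixel.
seed_puncta <- function(cyto, target, associated, assoc_radius_px) {
  np <- length(associated)
  out <- matrix(NA_real_, np, 2L)
  if (np == 0L) return(out)
  cyto_idx <- which(cyto, arr.ind = TRUE)
  cand_idx <- NULL
  if (any(associated)) {
    d_px <- EBImage::imageData(
      EBImage::distmap(as_ebimage(!target), metric = "euclidean"))
    cand <- cyto & d_px <= assoc_radius_px
    cand_idx <- which(cand, arr.ind = TRUE)
    if (nrow(cand_idx) == 0L)
      stop("no cytoplasm pixel lies within the association radius of the organelle")
  }
  for (i in seq_len(np)) {
    pool <- if (associated[i]) cand_idx else cyto_idx
    for (try in 1:200) {
      p <- pool[sample.int(nrow(pool), 1L), ] + runif(2, -0.5, 0.5)
      ok <- points_in_mask(cyto, p[1], p[2])
      if (ok && associated[i])
        ok <- nearest_mask_dist_px(target, p[1], p[2]) <= assoc_radius_px
      if (ok) { out[i, ] <- p; break }
    }
    if (anyNA(out[i, ])) {  # fall back to the pixel center, always valid
      p <- pool[sample.int(nrow(pool), 1L), ]
      out[i, ] <- as.numeric(p)
    }
  }
  out
}

#' Per-frame organelle masks under the simulated rigid jitter
#'
#' Shifts the frame-1 organelle mask by the rounded per-frame offsets
#' realised by [simulate_puncta_tracks()], clipped to the cytoplasm.
#'
#' @param cell a [generate_cell_geometry()] result.
#' @param ts the [simulate_puncta_tracks()] result holding the offsets.
#' @param organelle `"er"` or `"mito"`.
#' @return List of [new_mask()] objects, one per frame.
#' @export
frame_organelle_masks <- function(cell, ts, organelle = c("er", "mito")) {
  organelle <- match.arg(organelle)
  stopifnot(inherits(cell, "synthetic_cell"), inherits(ts, "track_set"))
  offs <- ts$organelle_offsets
  if (is.null(offs)) stop("track set carries no organelle offsets")
  base <- switch(organelle, er = cell$er_mask$pixels,
                 mito = cell$mito_mask$pixels)
  cyto <- cell$cytoplasm_mask$pixels
  lapply(seq_len(ts$n_frames), function(f) {
    dr <- offs[[paste0(organelle, "_drow_px")]][f]
    dc <- offs[[paste0(organelle, "_dcol_px")]][f]
    new_mask(shift_mask_px(base, dr, dc) & cyto, ts$pixel_size_nm, frame = f)
  })
}
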