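#' Full measurement pipeline for one rendered cell
#'
#' Runs the complete analysis a real movie would get: segment the cytoplasm
#' from the membrane channel, segment the organelle channel per frame
#' (Otsu), detect puncta per frame (LoG), link them into trajectories, then
#' compute observed and trajectory-randomized association fractions against
#' the organelle masks.
#'
#' @param stack an `image_stack` (see [render_timelapse()]).
#' @param organelle `"er"` or `"mito"`: channel to measure proximity to.
#' @param threshold_nm inclusive association threshold, nm.
#' @param cfg a [randomization_config()].
#' @param log_sigma_px,min_response detection parameters
#'   (see [detect_puncta()]).
#' @param max_disp_px,max_gap,min_track_length linking parameters
#'   (see [link_tracks()]).
#' @param min_object_px smallest organelle component kept by segmentation.
#' @param static_organelle if `TRUE`, segment the organelle once on frame 1
#'   instead of per frame (faster; the default re-segments every frame
#'   because organelle networks are mobile).
#' @return List: `observed`, `randomized_mean`, `randomized_per_replicate`,
#'   `samples`, plus the intermediate `tracks`, `cytoplasm` and
#'   `organelle_masks`.
#' @export
analyze_stack <- function(stack, organelle = c("er", "mito"),
                          threshold_nm = 100,
                          cfg = randomization_config(),
                          log_sigma_px = 1.6, min_response = 30,
                          max_disp_px = 5, max_gap = 1L,
                          min_track_length = 3L, min_object_px = 9L,
                          static_organelle = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  organelle <- match.arg(organelle)
  ps <- stack$pixel_size_nm
  n_frames <- dim(stack$data)[4]

  cytoplasm <- segment_cytoplasm(stack_frame(stack, "membrane", 1L),
                                 pixel_size_nm = ps)
  organelle_masks <- if (static_organelle) {
    segment_organelle(stack_frame(stack, organelle, 1L),
                      min_object_px = min_object_px, pixel_size_nm = ps)
  } else {
    lapply(seq_len(n_frames), function(f)
      segment_organelle(stack_frame(stack, organelle, f),
                        min_object_px = min_object_px, pixel_size_nm = ps,
                        frame_index = f))
  }

  det <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    d <- detect_puncta(stack_frame(stack, "puncta", f),
                       log_sigma_px = log_sigma_px,
                       min_response = min_response)
    if (nrow(d)) cbind(frame = f, d) else NULL
  }))
  if (is.null(det) || nrow(det) == 0L)
    stop("no puncta detected in any frame")
  tracks <- link_tracks(det, max_disp_px = max_disp_px, max_gap = max_gap,
                        min_track_length = min_track_length,
                        pixel_size_nm = ps,
                        cell_id = stack$cell_id %||% "cell_1")
  if (nrow(tracks$tracks) == 0L)
    stop("no trajectory survived linking")

  res <- cell_association_fractions(tracks, organelle_masks, cytoplasm,
                                    threshold_nm = threshold_nm, cfg = cfg)
  c(res, list(tracks = tracks, cytoplasm = cytoplasm,
              organelle_masks = organelle_masks))
}

#' Simulate and analyze a multi-cell association experiment
#'
#' For each cell: generate geometry, simulate trajectories, compute observed
#' and randomized association fractions against the ground-truth organelle
#' masks, then aggregate across cells with [compare_observed_vs_random()].
#' This is the synthetic analogue of a multi-cell live-imaging experiment
#' analyzed at the trajectory level (rendering and detection are exercised
#' separately by [analyze_stack()]).
#'
#' @param n_cells number of cells.
#' @param base_params a [cell_params()]; each cell gets `seed + i`.
#' @param threshold_nm inclusive association threshold, nm.
#' @param cfg a [randomization_config()]; each cell's randomization seed is
#'   offset by its index.
#' @param organelle organelle to measure against (defaults to the
#'   association target of `base_params`).
#' @return An `association_summary` with the per-cell results attached.
#' @export
simulate_association_experiment <- function(n_cells = 13L,
                                            base_params = cell_params(),
                                            threshold_nm = 100,
                                            cfg = randomization_config(),
                                            organelle = NULL) {
  organelle <- organelle %||% base_params$assoc_target
  obs <- rnd <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    p <- base_params; p$seed <- base_params$seed + i
    cell <- generate_cell_geometry(p)
    ts <- simulate_puncta_tracks(cell, p)
    masks <- frame_organelle_masks(cell, ts, organelle)
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    res <- cell_association_fractions(ts, masks, cell$cytoplasm_mask,
                                      threshold_nm = threshold_nm,
                                      cfg = cfg_i)
    obs[i] <- res$observed; rnd[i] <- res$randomized_mean
  }
  compare_observed_vs_random(obs, rnd, threshold_nm = threshold_nm)
}
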