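#' Write / read a binary mask as 8-bit TIFF
#'
#' @param mask an [new_mask()] object.
#' @param path output file.
#' @return `write_mask_tiff` returns `path` invisibly; `read_mask_tiff`
#'   returns an `org_mask`.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "org_mask"))
  tiff::writeTIFF(mask$pixels * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param pixel_size_nm physical pixel size to record on the mask read
#'   back (TIFF carries none).
#' @export
read_mask_tiff <- function(path, pixel_size_nm = 80) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  new_mask(m > 0.5, pixel_size_nm)
}

#' Write / read a multi-channel time-lapse stack as multi-page TIFF
#'
#' Pages are ordered frame-major (all channels of frame 1, then frame 2,
#' ...). Intensities are scaled into `[0, 1]` by the stack maximum; the
#' scale, channel order and pixel size are stored in a YAML sidecar
#' (`<path>.yaml`) so the stack round-trips exactly up to quantization.
#'
#' @param stack an `image_stack` (see [render_timelapse()]).
#' @param path output TIFF file.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an `image_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  top <- max(stack$data, 1e-12)
  lo <- min(stack$data, 0)
  pages <- list()
  for (f in seq_len(d[4])) for (ch in seq_len(d[3]))
    pages[[length(pages) + 1L]] <-
      (stack$data[, , ch, f] - lo) / (top - lo)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_size_nm = stack$pixel_size_nm,
                        channels = as.list(stack$channels),
                        n_frames = d[4], intensity_min = lo,
                        intensity_max = top, cell_id = stack$cell_id),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- unlist(meta$channels)
  n_ch <- length(channels); n_f <- meta$n_frames
  d1 <- dim(pages[[1]])
  arr <- array(NA_real_, dim = c(d1[1], d1[2], n_ch, n_f),
               dimnames = list(NULL, NULL, channels, NULL))
  k <- 1L
  for (f in seq_len(n_f)) for (ch in seq_len(n_ch)) {
    arr[, , ch, f] <- pages[[k]] * (meta$intensity_max - meta$intensity_min) +
      meta$intensity_min
    k <- k + 1L
  }
  structure(list(data = arr, channels = channels,
                 pixel_size_nm = meta$pixel_size_nm,
                 cell_id = meta$cell_id %||% "cell_1"),
            class = "image_stack")
}

#' Write / read a track set as CSV
#'
#' Long format: `cell_id`, `track_id`, `frame`, `row_px`, `col_px`,
#' `intensity`, plus `associated_truth` when the set carries generator
#' ground truth.
#'
#' @param ts a [new_track_set()].
#' @param path output CSV file.
#' @return `write_tracks_csv` returns `path` invisibly; `read_tracks_csv`
#'   returns a `track_set`.
#' @export
write_tracks_csv <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  df <- cbind(cell_id = ts$cell_id, ts$tracks)
  if (!is.null(ts$truth))
    df$associated_truth <-
      ts$truth$associated[match(df$track_id, ts$truth$track_id)]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param pixel_size_nm,n_frames metadata for the track set read back.
#' @export
read_tracks_csv <- function(path, pixel_size_nm = 80, n_frames = NULL) {
  df <- read.csv(path)
  truth <- NULL
  if ("associated_truth" %in% names(df)) {
    u <- unique(df[, c("track_id", "associated_truth")])
    truth <- data.frame(track_id = u$track_id,
                        associated = as.logical(u$associated_truth))
  }
  new_track_set(df[, c("track_id", "frame", "row_px", "col_px",
                       intersect("intensity", names(df)))],
                pixel_size_nm, n_frames %||% max(df$frame),
                cell_id = as.character(df$cell_id[1] %||% "cell_1"),
                truth = truth)
}

#' Write gold-field annotations as CSV
#'
#' Two files: `<stem>_clusters.csv` (`image_id`, `group`, `cluster_id`,
#' `x_um`, `y_um`, `associated`) and `<stem>_regions.csv` (`image_id`,
#' `region_id`, `vertex_index`, `x_um`, `y_um`).
#'
#' @param images list of [gold_image()] objects.
#' @param stem path stem for the two CSV files.
#' @return The two paths, invisibly.
#' @export
write_gold_csv <- function(images, stem) {
  cl <- do.call(rbind, lapply(images, function(im) {
    if (nrow(im$clusters) == 0L) return(NULL)
    cbind(image_id = im$image_id, group = im$group, im$clusters)
  }))
  rg <- do.call(rbind, lapply(images, function(im) {
    if (is.null(im$regions) || nrow(im$regions) == 0L) return(NULL)
    r <- im$regions
    r$vertex_index <- stats::ave(seq_len(nrow(r)), r$region_id,
                                 FUN = seq_along)
    cbind(image_id = im$image_id,
          r[, c("region_id", "vertex_index", "x_um", "y_um")])
  }))
  p1 <- paste0(stem, "_clusters.csv"); p2 <- paste0(stem, "_regions.csv")
  write.csv(cl %||% data.frame(), p1, row.names = FALSE)
  write.csv(rg %||% data.frame(), p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read gold-field annotations from CSV
#'
#' @param stem the path stem used by [write_gold_csv()].
#' @param area_um2 imaged area per micrograph, um^2.
#' @return List of [gold_image()] objects.
#' @export
read_gold_csv <- function(stem, area_um2 = 11.125) {
  cl <- read.csv(paste0(stem, "_clusters.csv"))
  rg_path <- paste0(stem, "_regions.csv")
  rg <- if (file.exists(rg_path)) read.csv(rg_path) else NULL
  if (!is.null(rg) && !nrow(rg)) rg <- NULL
  ids <- unique(cl$image_id)
  lapply(ids, function(id) {
    ci <- cl[cl$image_id == id, ]
    ri <- if (!is.null(rg)) rg[rg$image_id == id, ] else NULL
    if (!is.null(ri) && nrow(ri))
      ri <- ri[order(ri$region_id, ri$vertex_index),
               c("region_id", "x_um", "y_um")]
    else ri <- NULL
    cols <- intersect(c("cluster_id", "x_um", "y_um", "associated"),
                      names(ci))
    gold_image(image_id = id, area_um2 = area_um2,
               clusters = ci[, cols], regions = ri,
               group = as.character(ci$group[1]))
  })
}

#' Write an association summary as JSON
#'
#' @param summary an `association_summary`
#'   (see [compare_observed_vs_random()]).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "association_summary"))
  jsonlite::write_json(list(
    n_cells = summary$n_cells, threshold_nm = summary$threshold_nm,
    mean_observed = summary$mean_observed,
    sem_observed = summary$sem_observed,
    mean_randomized = summary$mean_randomized,
    sem_randomized = summary$sem_randomized,
    per_cell_observed = summary$per_cell_observed,
    per_cell_randomized = summary$per_cell_randomized,
    paired_t = summary$paired_test$t_stat,
    df = summary$paired_test$df,
    p_two_sided = summary$paired_test$p_two_sided),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
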