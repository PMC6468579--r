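# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `offset` decorrelates sub-streams of one user-facing seed while
# keeping the derived seed a valid 32-bit integer.
with_seed <- function(seed, expr, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  derived <- (as.double(seed) %% 2147480000) + as.double(offset)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(derived %% 2147483647))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

as_ebimage <- function(m) EBImage::Image(m * 1)

# Binary morphology wrappers on plain logical matrices.
dilate_mask <- function(pixels, radius_px) {
  if (radius_px <= 0) return(pixels)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius_px)) + 1L, "disc")
  EBImage::imageData(EBImage::dilate(as_ebimage(pixels), brush)) > 0.5
}

erode_mask <- function(pixels, radius_px) {
  if (radius_px <= 0) return(pixels)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius_px)) + 1L, "disc")
  EBImage::imageData(EBImage::erode(as_ebimage(pixels), brush)) > 0.5
}

fill_holes <- function(pixels) {
  EBImage::imageData(EBImage::fillHull(as_ebimage(pixels))) > 0.5
}

label_components <- function(pixels) {
  EBImage::imageData(EBImage::bwlabel(as_ebimage(pixels)))
}

largest_component <- function(pixels) {
  lab <- label_components(pixels)
  if (max(lab) < 1) return(pixels & FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

n_components <- function(pixels) max(label_components(pixels))

# Shift a logical matrix by whole pixels, padding with FALSE.
shift_mask_px <- function(pixels, drow, dcol) {
  drow <- as.integer(round(drow)); dcol <- as.integer(round(dcol))
  nr <- nrow(pixels); nc <- ncol(pixels)
  out <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - drow; src_c <- seq_len(nc) - dcol
  ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- pixels[src_r[ok_r], src_c[ok_c]]
  out
}

# TRUE for points whose nearest pixel center is mask-positive.
points_in_mask <- function(pixels, row, col) {
  r <- as.integer(round(row)); c <- as.integer(round(col))
  ok <- r >= 1L & r <= nrow(pixels) & c >= 1L & c <= ncol(pixels)
  inside <- ok
  inside[ok] <- pixels[cbind(r[ok], c[ok])]
  inside
}

# Draw a thick line segment into a logical matrix (supersampled walk).
draw_segment <- function(pixels, r0, c0, r1, c1, half_width_px) {
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  n <- max(2L, as.integer(ceiling(len * 2)))
  t <- seq(0, 1, length.out = n)
  rr <- r0 + t * (r1 - r0); cc <- c0 + t * (c1 - c0)
  w <- as.integer(ceiling(half_width_px))
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  offs <- offs[offs$dr^2 + offs$dc^2 <= half_width_px^2 + 0.25, , drop = FALSE]
  r_all <- as.integer(round(outer(rr, offs$dr, `+`)))
  c_all <- as.integer(round(outer(cc, offs$dc, `+`)))
  keep <- r_all >= 1L & r_all <= nrow(pixels) & c_all >= 1L & c_all <= ncol(pixels)
  pixels[cbind(r_all[keep], c_all[keep])] <- TRUE
  pixels
}

# Minimum spanning tree over points (rows of a 2-column matrix), Prim's
# algorithm; returns an edge list (from, to). Small n only.
mst_edges <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  d <- as.matrix(dist(pts))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best_d <- d[1L, ]; best_from <- rep(1L, n)
  edges <- matrix(integer(0), 0, 2)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_d[cand])]
    edges <- rbind(edges, c(best_from[v], v))
    in_tree[v] <- TRUE
    upd <- !in_tree & d[v, ] < best_d
    best_d[upd] <- d[v, upd]; best_from[upd] <- v
  }
  edges
}
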