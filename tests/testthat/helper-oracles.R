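# Independent oracles and shared fixtures for the suite.

# O(N * M) brute force: exact distance (nm) from subpixel points to the
# nearest positive pixel center, 0 when the rounded pixel is positive.
brute_mask_dist_nm <- function(pixels, pixel_size_nm, row, col) {
  pos <- which(pixels, arr.ind = TRUE)
  vapply(seq_along(row), function(k) {
    r0 <- round(row[k]); c0 <- round(col[k])
    if (r0 >= 1 && r0 <= nrow(pixels) && c0 >= 1 && c0 <= ncol(pixels) &&
        pixels[r0, c0]) return(0)
    if (nrow(pos) == 0L) return(Inf)
    sqrt(min((pos[, 1] - row[k])^2 + (pos[, 2] - col[k])^2)) * pixel_size_nm
  }, numeric(1))
}

# Exhaustive Otsu over all 256 integer levels of an 8-bit image.
brute_otsu_level <- function(v) {
  best <- -Inf; bt <- 0L
  for (t in 0:254) {
    g1 <- v[v <= t]; g2 <- v[v > t]
    if (!length(g1) || !length(g2)) next
    w1 <- length(g1) / length(v)
    bc <- w1 * (1 - w1) * (mean(g1) - mean(g2))^2
    if (bc > best) { best <- bc; bt <- t }
  }
  bt
}

# Exhaustive optimum of frame-to-frame linking for small complete cases:
# equal detection counts per frame, every particle present in every frame,
# every link admissible. With full bipartite freedom per transition the
# optimal total squared displacement decomposes into independent
# per-transition assignment problems, each solved by enumerating all
# permutations.
brute_link_cost <- function(per_frame) {
  m <- nrow(per_frame[[1]])
  perms <- gen_perms(m)
  sum(vapply(seq_len(length(per_frame) - 1L), function(tr) {
    a <- per_frame[[tr]]; b <- per_frame[[tr + 1L]]
    min(vapply(seq_len(nrow(perms)), function(pi) {
      p <- perms[pi, ]
      sum((a[, 1] - b[p, 1])^2 + (a[, 2] - b[p, 2])^2)
    }, numeric(1)))
  }, numeric(1)))
}

gen_perms <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- gen_perms(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(i) {
    cbind(i, matrix(setdiff(seq_len(m), i)[sub], nrow(sub), m - 1L))
  }))
}

greedy_link_cost <- function(ts) {
  sum(unlist(lapply(split(ts$tracks, ts$tracks$track_id), function(tr) {
    diff(tr$row_px)^2 + diff(tr$col_px)^2
  })))
}

# Cell fixtures are expensive; cache them per test run.
.cell_cache <- new.env(parent = emptyenv())
cached_cell <- function(seed, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.cell_cache[[key]])) {
    p <- cell_params(seed = seed, ...)
    cell <- generate_cell_geometry(p)
    ts <- simulate_puncta_tracks(cell, p)
    .cell_cache[[key]] <- list(params = p, cell = cell, tracks = ts)
  }
  .cell_cache[[key]]
}

# Fraction of the cytoplasm within `threshold_nm` of a mask, by subpixel
# quadrature (4 x 4 offsets per pixel) of the exact point distance.
footprint_fraction <- function(mask, domain_px, threshold_nm) {
  idx <- which(domain_px, arr.ind = TRUE)
  offs <- seq(-0.375, 0.375, by = 0.25)
  vals <- vapply(offs, function(dr) {
    vapply(offs, function(dc) {
      mean(point_mask_distance(mask, idx[, 1] + dr, idx[, 2] + dc) <=
             threshold_nm)
    }, numeric(1))
  }, numeric(length(offs)))
  mean(vals)
}
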