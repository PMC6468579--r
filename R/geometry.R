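#' Generate synthetic cell geometry (cytoplasm, ER, mitochondria masks)
#'
#' Builds one synthetic cell: a single connected blob-shaped cytoplasm, a
#' tubular ER network (random spanning tree over nodes scattered in the
#' cytoplasm, edges drawn 2-4 px wide), and disjoint elongated mitochondrial
#' blobs (random ellipses with aspect ratio 2-6). Both organelle masks are
#' strictly contained in the cytoplasm mask.
#'
#' @param params a [cell_params()] object.
#' @return An object of class `synthetic_cell`: list with `org_mask` members
#'   `cytoplasm_mask`, `er_mask`, `mito_mask`, plus the `params` used.
#'   Identical `params` (including `seed`) give bit-identical masks.
#' @examples
#' cell <- generate_cell_geometry(cell_params(seed = 7))
#' mean(cell$er_mask$pixels[cell$cytoplasm_mask$pixels])
#' @export
generate_cell_geometry <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  with_seed(params$seed, offset = 101L, {
    nr <- params$image_shape[1]; nc <- params$image_shape[2]

    cyto <- random_blob_mask(nr, nc)
    # keep organelles off the cytoplasm rim so that per-frame organelle
    # jitter and mask dilation cannot escape the cell
    inner <- erode_mask(cyto, 4L)

    er <- er_network_mask(inner, params$er_nodes_per_kpx)
    mito <- mito_blob_mask(inner & !dilate_mask(er, 1L),
                           params$mito_region_count)

    list2cell(cyto, er & inner, mito & inner, params)
  })
}

list2cell <- function(cyto, er, mito, params) {
  ps <- params$pixel_size_nm
  structure(list(cytoplasm_mask = new_mask(cyto, ps),
                 er_mask = new_mask(er, ps),
                 mito_mask = new_mask(mito, ps),
                 params = params),
            class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  a <- sum(x$cytoplasm_mask$pixels)
  cat(sprintf(
    "<synthetic_cell> %d x %d px; cytoplasm %d px; ER %.1f%%, mito %.1f%% of cytoplasm\n",
    nrow(x$cytoplasm_mask$pixels), ncol(x$cytoplasm_mask$pixels), a,
    100 * sum(x$er_mask$pixels) / a, 100 * sum(x$mito_mask$pixels) / a))
  invisible(x)
}

# Star-convex blob: radius modulated by a few low-frequency sinusoids.
# Star-convexity about the center guarantees a single connected component.
random_blob_mask <- function(nr, nc) {
  cr <- nr / 2; cc <- nc / 2
  base_r <- 0.40 * min(nr, nc)
  k <- 2:4
  amp <- runif(3, 0.03, 0.10)
  phase <- runif(3, 0, 2 * pi)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  theta <- atan2(rows - cr, cols - cc)
  rad <- sqrt((rows - cr)^2 + (cols - cc)^2)
  rmax <- base_r * (1 + amp[1] * sin(k[1] * theta + phase[1]) +
                        amp[2] * sin(k[2] * theta + phase[2]) +
                        amp[3] * sin(k[3] * theta + phase[3]))
  rad <= rmax
}

# Tubular web: MST over nodes scattered in the allowed region, edges drawn
# as thick segments; a handful of extra short edges add loops, mimicking a
# reticulated network rather than a pure tree.
er_network_mask <- function(allowed, nodes_per_kpx) {
  idx <- which(allowed, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(allowed & FALSE)
  n_nodes <- max(3L, as.integer(round(nrow(idx) * nodes_per_kpx / 1000)))
  n_nodes <- min(n_nodes, nrow(idx))
  pts <- idx[sample.int(nrow(idx), n_nodes), , drop = FALSE]
  er <- matrix(FALSE, nrow(allowed), ncol(allowed))
  edges <- mst_edges(pts)
  widths <- runif(nrow(edges), 1.0, 2.0)  # half-widths -> 2-4 px tubules
  for (e in seq_len(nrow(edges))) {
    a <- pts[edges[e, 1], ]; b <- pts[edges[e, 2], ]
    er <- draw_segment(er, a[1], a[2], b[1], b[2], widths[e])
  }
  # extra loop-closing edges between nearby non-adjacent nodes
  if (n_nodes >= 8L) {
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    n_extra <- max(1L, n_nodes %/% 10L)
    for (i in sample.int(n_nodes, n_extra)) {
      j <- order(d[i, ])[3L]  # third-nearest: usually not an MST neighbour
      er <- draw_segment(er, pts[i, 1], pts[i, 2], pts[j, 1], pts[j, 2],
                         runif(1, 1.0, 2.0))
    }
  }
  er & allowed
}

# Disjoint elongated ellipses (aspect 2-6); placement by rejection so blobs
# keep a 2 px gap from each other.
mito_blob_mask <- function(allowed, count) {
  mito <- matrix(FALSE, nrow(allowed), ncol(allowed))
  if (count < 1L) return(mito)
  idx <- which(allowed, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(mito)
  rows <- matrix(seq_len(nrow(allowed)), nrow(allowed), ncol(allowed))
  cols <- matrix(seq_len(ncol(allowed)), nrow(allowed), ncol(allowed),
                 byrow = TRUE)
  placed <- 0L; attempts <- 0L
  while (placed < count && attempts < count * 60L) {
    attempts <- attempts + 1L
    ctr <- idx[sample.int(nrow(idx), 1L), ]
    aspect <- runif(1, 2, 6)
    a <- runif(1, 8, 18)            # semi-major axis, px
    b <- max(1.5, a / aspect)       # semi-minor axis, px
    phi <- runif(1, 0, pi)
    dr <- rows - ctr[1]; dc <- cols - ctr[2]
    u <- dc * cos(phi) + dr * sin(phi)
    v <- -dc * sin(phi) + dr * cos(phi)
    ell <- (u / a)^2 + (v / b)^2 <= 1
    ell <- ell & allowed
    if (!any(ell)) next
    if (any(dilate_mask(ell, 2L) & mito)) next  # would touch an earlier blob
    mito <- mito | ell
    placed <- placed + 1L
  }
  mito
}
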