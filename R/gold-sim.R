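#' Generate synthetic immunogold fields
#'
#' Simulates a group of fixed-area electron micrographs: each image gets
#' disjoint elliptical mitochondrial profiles covering about
#' `mito_region_area_fraction` of the area, and a Poisson number of gold
#' clusters (`cluster_density * image_area_um2` expected). Each cluster is
#' associated with probability `assoc_fraction` - placed uniformly inside a
#' mitochondrial profile - or else placed uniformly outside the association
#' reach (`assoc_distance_um` of any profile). Ground-truth labels are
#' stored in the `associated` column.
#'
#' @param params a [gold_field_params()] object.
#' @return List of [gold_image()] objects of length `params$n_images`.
#' @export
generate_gold_field <- function(params) {
  stopifnot(inherits(params, "gold_field_params"))
  side <- sqrt(params$image_area_um2)
  with_seed(params$seed, offset = 606L, {
    lapply(seq_len(params$n_images), function(img_i) {
      regions <- place_gold_regions(side, params$mito_region_count,
                                    params$mito_region_area_fraction,
                                    params$assoc_distance_um)
      n_clusters <- rpois(1L, params$cluster_density * params$image_area_um2)
      if (n_clusters > 0L) {
        assoc <- runif(n_clusters) < params$assoc_fraction
        xy <- matrix(NA_real_, n_clusters, 2L)
        for (k in seq_len(n_clusters)) {
          xy[k, ] <- if (assoc[k])
            sample_inside_region(regions)
          else
            sample_outside_reach(side, regions, params$assoc_distance_um)
        }
        clusters <- data.frame(cluster_id = seq_len(n_clusters),
                               x_um = xy[, 1], y_um = xy[, 2],
                               associated = assoc)
      } else {
        clusters <- data.frame(cluster_id = integer(0), x_um = numeric(0),
                               y_um = numeric(0), associated = logical(0))
      }
      gold_image(image_id = sprintf("img_%03d", img_i),
                 area_um2 = params$image_area_um2,
                 clusters = clusters, regions = regions)
    })
  })
}

# Disjoint elliptical profiles as 64-vertex polygons; disjointness enforced
# with a conservative circumscribed-circle test including the association
# reach, so "associated" and "unassociated" placements cannot be ambiguous
# across regions.
place_gold_regions <- function(side, count, area_fraction, reach_um) {
  if (count < 1L || area_fraction <= 0)
    return(data.frame(region_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0)))
  area_each <- side^2 * area_fraction / count
  out <- list()
  centers <- matrix(numeric(0), 0, 2L)
  radii <- numeric(0)
  placed <- 0L; attempts <- 0L
  while (placed < count && attempts < count * 80L) {
    attempts <- attempts + 1L
    aspect <- runif(1, 2, 6)
    a <- sqrt(area_each * aspect / pi)    # semi-major, um
    b <- area_each / (pi * a)             # semi-minor
    margin <- a + reach_um
    if (2 * margin >= side) { aspect <- 2; a <- sqrt(area_each * 2 / pi)
      b <- area_each / (pi * a); margin <- a + reach_um }
    ctr <- runif(2, margin, side - margin)
    if (nrow(centers) &&
        any(sqrt(colSums((t(centers) - ctr)^2)) <
            radii + a + 2 * reach_um + 0.02)) next
    phi <- runif(1, 0, pi)
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    ex <- a * cos(th); ey <- b * sin(th)
    out[[length(out) + 1L]] <- data.frame(
      region_id = placed + 1L,
      x_um = ctr[1] + ex * cos(phi) - ey * sin(phi),
      y_um = ctr[2] + ex * sin(phi) + ey * cos(phi))
    centers <- rbind(centers, ctr); radii <- c(radii, a)
    placed <- placed + 1L
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(region_id = integer(0), x_um = numeric(0), y_um = numeric(0))
}

sample_inside_region <- function(regions) {
  ids <- unique(regions$region_id)
  # choose a region with probability proportional to its polygon area
  areas <- vapply(ids, function(id) {
    p <- regions[regions$region_id == id, ]
    abs(sum(p$x_um * c(p$y_um[-1], p$y_um[1]) -
            c(p$x_um[-1], p$x_um[1]) * p$y_um)) / 2
  }, numeric(1))
  id <- ids[sample.int(length(ids), 1L, prob = areas)]
  p <- regions[regions$region_id == id, ]
  repeat {
    cand <- c(runif(1, min(p$x_um), max(p$x_um)),
              runif(1, min(p$y_um), max(p$y_um)))
    if (point_in_polygon(cand[1], cand[2], p$x_um, p$y_um)) return(cand)
  }
}

sample_outside_reach <- function(side, regions, reach_um) {
  repeat {
    cand <- runif(2, 0, side)
    if (!nrow(regions)) return(cand)
    if (!classify_association(cand[1], cand[2], regions, reach_um))
      return(cand)
  }
}
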