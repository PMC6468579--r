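#' One annotated immunogold micrograph
#'
#' A fixed-area electron-microscopy image with gold-cluster centroids and,
#' optionally, mitochondrial region outlines. Clusters may carry a curated
#' `associated` annotation; regions allow geometric (re-)classification.
#'
#' @param image_id identifier.
#' @param area_um2 imaged area, um^2 (the image is treated as the square
#'   of side `sqrt(area_um2)` for coordinate bounds).
#' @param clusters data.frame with `cluster_id`, `x_um`, `y_um` and
#'   optionally `associated` (logical annotation).
#' @param regions optional data.frame of polygon outlines: `region_id`,
#'   `x_um`, `y_um`, vertices in order (one polygon per `region_id`).
#' @param group group label, e.g. `"antibody"` or `"control"`.
#' @return An object of class `gold_image`.
#' @export
gold_image <- function(image_id, area_um2 = 11.125,
                       clusters = data.frame(cluster_id = integer(0),
                                             x_um = numeric(0),
                                             y_um = numeric(0)),
                       regions = NULL, group = "antibody") {
  stop_if_not_scalar_number(area_um2, "area_um2", positive = TRUE)
  req <- c("cluster_id", "x_um", "y_um")
  if (!is.data.frame(clusters) || !all(req %in% names(clusters)))
    stop("`clusters` needs columns cluster_id, x_um, y_um")
  side <- sqrt(area_um2)
  if (nrow(clusters) &&
      any(clusters$x_um < 0 | clusters$x_um > side |
          clusters$y_um < 0 | clusters$y_um > side))
    stop("cluster coordinates must lie within the image bounds")
  if (!is.null(regions)) {
    reqr <- c("region_id", "x_um", "y_um")
    if (!is.data.frame(regions) || !all(reqr %in% names(regions)))
      stop("`regions` needs columns region_id, x_um, y_um")
  }
  structure(list(image_id = image_id, group = group, area_um2 = area_um2,
                 clusters = clusters, regions = regions),
            class = "gold_image")
}

#' Classify gold clusters as organelle-associated
#'
#' A cluster is "directly associated" when its centroid lies inside a
#' mitochondrial outline or within `assoc_distance_um` of one. The default
#' reach of 0.03 um (30 nm) acknowledges that silver-enhanced gold can sit
#' tens of nanometres from its epitope while remaining strict.
#'
#' @param x_um,y_um cluster centroid coordinates, um.
#' @param regions polygon data.frame (`region_id`, `x_um`, `y_um`) or a
#'   logical mask matrix with attribute `um_per_px`; `NULL` or empty means
#'   no regions (everything unassociated).
#' @param assoc_distance_um association reach beyond the outline, um.
#' @return Logical vector, one entry per cluster.
#' @export
classify_association <- function(x_um, y_um, regions,
                                 assoc_distance_um = 0.03) {
  stop_if_not_scalar_number(assoc_distance_um, "assoc_distance_um",
                            nonneg = TRUE)
  n <- length(x_um)
  if (length(y_um) != n) stop("x_um and y_um must have equal length")
  if (n == 0L) return(logical(0))
  if (is.null(regions) ||
      (is.data.frame(regions) && nrow(regions) == 0L))
    return(rep(FALSE, n))
  if (is.matrix(regions) && is.logical(regions)) {
    um_px <- attr(regions, "um_per_px")
    if (is.null(um_px)) stop("mask regions need a `um_per_px` attribute")
    if (!any(regions)) return(rep(FALSE, n))
    d <- nearest_mask_dist_px(regions, y_um / um_px + 0.5,
                              x_um / um_px + 0.5) * um_px
    return(d <= assoc_distance_um)
  }
  polys <- split(regions[, c("x_um", "y_um")], regions$region_id)
  out <- rep(FALSE, n)
  for (poly in polys) {
    px <- poly$x_um; py <- poly$y_um
    inside <- point_in_polygon(x_um, y_um, px, py)
    near <- if (assoc_distance_um > 0)
      dist_to_polygon(x_um, y_um, px, py) <= assoc_distance_um
    else inside
    out <- out | inside | near
    if (all(out)) break
  }
  out
}

# Ray-casting point-in-polygon, vectorized over query points.
point_in_polygon <- function(x, y, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Minimal distance from points to a polygon boundary (closed ring).
dist_to_polygon <- function(x, y, poly_x, poly_y) {
  n <- length(poly_x)
  best <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- poly_x[j]; ay <- poly_y[j]; bx <- poly_x[i]; by <- poly_y[i]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    else 0
    d <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
    best <- pmin(best, d)
    j <- i
  }
  best
}

#' Quantify gold-cluster density and mitochondria association for a group
#'
#' Per-image cluster densities (clusters/um^2) with their mean and SEM over
#' images, plus the pooled association count and fraction. Association uses
#' the curated `associated` annotation when every cluster carries one
#' (`association = "annotated"`, the default behaviour for annotated data);
#' otherwise clusters are classified geometrically against the region
#' outlines via [classify_association()].
#'
#' @param images list of [gold_image()] objects (>= 1).
#' @param assoc_distance_um association reach for geometric classification.
#' @param association `"auto"` (annotation if complete, else geometric),
#'   `"annotated"`, or `"geometric"`.
#' @return An object of class `gold_quant_result`: `group`, `n_images`,
#'   `n_clusters`, `density_mean`, `density_sem`, `per_image_density`,
#'   `n_associated`, `association_fraction` (NA when there are no
#'   clusters).
#' @export
quantify_group <- function(images, assoc_distance_um = 0.03,
                           association = c("auto", "annotated", "geometric")) {
  association <- match.arg(association)
  if (inherits(images, "gold_image")) images <- list(images)
  if (!length(images) || !all(vapply(images, inherits, logical(1), "gold_image")))
    stop("`images` must be a non-empty list of gold_image objects")
  n_img <- length(images)
  counts <- vapply(images, function(im) nrow(im$clusters), integer(1))
  areas <- vapply(images, function(im) im$area_um2, numeric(1))
  dens <- counts / areas
  n_clusters <- sum(counts)

  has_annot <- all(vapply(images, function(im) {
    nrow(im$clusters) == 0L ||
      ("associated" %in% names(im$clusters) &&
         !anyNA(im$clusters$associated))
  }, logical(1)))
  use_annot <- switch(association,
                      auto = has_annot,
                      annotated = {
                        if (!has_annot)
                          stop("association = 'annotated' but some clusters lack annotations")
                        TRUE
                      },
                      geometric = FALSE)
  n_assoc <- sum(vapply(images, function(im) {
    if (nrow(im$clusters) == 0L) return(0L)
    if (use_annot) sum(as.logical(im$clusters$associated))
    else sum(classify_association(im$clusters$x_um, im$clusters$y_um,
                                  im$regions, assoc_distance_um))
  }, integer(1)))

  structure(list(
    group = images[[1]]$group, n_images = n_img, n_clusters = n_clusters,
    density_mean = mean(dens),
    density_sem = if (n_img > 1) sd(dens) / sqrt(n_img) else NA_real_,
    per_image_density = dens,
    n_associated = n_assoc,
    association_fraction = if (n_clusters > 0) n_assoc / n_clusters
    else NA_real_), class = "gold_quant_result")
}

#' @export
print.gold_quant_result <- function(x, ...) {
  cat(sprintf(
    "<gold_quant_result> group %s: %d clusters over %d images\n  density %.3f +/- %.3f clusters/um^2 (mean +/- SEM)\n  associated %d/%d (%s)\n",
    x$group, x$n_clusters, x$n_images, x$density_mean,
    x$density_sem %||% NA, x$n_associated, x$n_clusters,
    if (is.na(x$association_fraction)) "undefined"
    else sprintf("%.2f%%", 100 * x$association_fraction)))
  invisible(x)
}
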