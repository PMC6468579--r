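square <- function(cx, cy, half) {
  data.frame(region_id = 1L,
             x_um = cx + half * c(-1, 1, 1, -1),
             y_um = cy + half * c(-1, -1, 1, 1))
}

test_that("points inside, near and far from a region classify correctly", {
  reg <- square(1, 1, 0.3)
  expect_true(classify_association(1.0, 1.0, reg))
  expect_true(classify_association(1.32, 1.0, reg, assoc_distance_um = 0.03))
  expect_false(classify_association(1.40, 1.0, reg, assoc_distance_um = 0.03))
  expect_false(classify_association(2.5, 2.5, reg))
  expect_equal(classify_association(c(1, 2.5), c(1, 2.5), NULL), c(FALSE, FALSE))
})

test_that("association is invariant to a global translation", {
  set.seed(81)
  reg <- square(1.2, 0.9, 0.4)
  x <- runif(50, 0, 3); y <- runif(50, 0, 3)
  a <- classify_association(x, y, reg)
  reg2 <- reg; reg2$x_um <- reg$x_um + 0.7; reg2$y_um <- reg$y_um - 0.3
  b <- classify_association(x + 0.7, y - 0.3, reg2)
  expect_identical(a, b)
})

test_that("mask-based regions classify through the pixel distance", {
  px <- matrix(FALSE, 100, 100); px[40:60, 40:60] <- TRUE
  attr(px, "um_per_px") <- 0.01  # 1 um field
  expect_true(classify_association(0.50, 0.50, px))
  expect_false(classify_association(0.90, 0.90, px))
})

test_that("the fixed-area worked example reproduces printed precision", {
  per_image <- rep(363 %/% 41, 41)
  per_image[seq_len(363 %% 41)] <- per_image[seq_len(363 %% 41)] + 1L
  assoc_left <- 220L
  images <- lapply(seq_len(41), function(i) {
    n <- per_image[i]
    k <- min(assoc_left, n); assoc_left <<- assoc_left - k
    gold_image(sprintf("img%02d", i), area_um2 = 11.125,
               clusters = data.frame(cluster_id = seq_len(n),
                                     x_um = runif(n, 0, sqrt(11.125)),
                                     y_um = runif(n, 0, sqrt(11.125)),
                                     associated = seq_len(n) <= k))
  })
  res <- quantify_group(images)
  expect_equal(res$n_clusters, 363)
  expect_equal(res$n_associated, 220)
  expect_equal(round(res$density_mean, 3), 0.796)
  expect_equal(round(100 * res$association_fraction, 2), 60.61)
})

test_that("equal-area densities satisfy the counting identity", {
  set.seed(82)
  imgs <- generate_gold_field(gold_field_params(n_images = 10, seed = 7))
  res <- quantify_group(imgs)
  expect_equal(res$density_mean * res$n_images * 11.125, res$n_clusters,
               tolerance = 1e-9)
})

test_that("zero density produces empty images and undefined association", {
  imgs <- generate_gold_field(gold_field_params(cluster_density = 0,
                                                n_images = 5, seed = 3))
  expect_true(all(vapply(imgs, function(im) nrow(im$clusters) == 0L,
                         logical(1))))
  res <- quantify_group(imgs)
  expect_equal(res$density_mean, 0)
  expect_true(is.na(res$association_fraction))
})

test_that("total cluster counts follow the Poisson oracle", {
  total <- 0
  for (s in 1:3) {
    imgs <- generate_gold_field(gold_field_params(cluster_density = 0.8,
                                                  n_images = 41, seed = s))
    total <- total + sum(vapply(imgs, function(im) nrow(im$clusters),
                                integer(1)))
  }
  lambda <- 3 * 0.8 * 41 * 11.125   # pooled expectation, 1094.7
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("full association forces an association fraction of one", {
  imgs <- generate_gold_field(gold_field_params(assoc_fraction = 1,
                                                n_images = 6, seed = 11))
  res <- quantify_group(imgs, association = "geometric")
  expect_equal(res$association_fraction, 1)
})

test_that("geometric classification recovers the generating fraction", {
  imgs <- generate_gold_field(gold_field_params(assoc_fraction = 0.6,
                                                n_images = 41, seed = 13))
  res_geo <- quantify_group(imgs, association = "geometric")
  res_truth <- quantify_group(imgs, association = "annotated")
  # generator places associated clusters inside regions and the rest
  # outside the association reach, so geometry must agree with the labels
  expect_equal(res_geo$n_associated, res_truth$n_associated)
  se <- sqrt(0.6 * 0.4 / res_geo$n_clusters)
  expect_lt(abs(res_geo$association_fraction - 0.6), 3 * se)
})

test_that("association without regions is rejected at construction", {
  expect_error(gold_field_params(assoc_fraction = 0.5, mito_region_count = 0),
               "region")
})

test_that("cluster coordinates outside the image bounds are rejected", {
  expect_error(gold_image("a", 11.125,
                          clusters = data.frame(cluster_id = 1, x_um = 9,
                                                y_um = 1)),
               "bounds")
})
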