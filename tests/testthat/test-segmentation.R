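test_that("a two-level image thresholds at the bright level", {
  img <- matrix(10, 64, 64); img[20:30, 20:40] <- 200
  m <- segment_organelle(img, pixel_size_nm = 80)
  expect_identical(m$pixels, img == 200)
})

test_that("otsu matches exhaustive between-class-variance search on 8-bit images", {
  set.seed(31)
  for (i in 1:5) {
    v <- as.integer(round(c(rnorm(250, 60, 25), rnorm(150, 180, 30))))
    v <- pmin(255L, pmax(0L, v))
    v[1:2] <- c(0L, 255L)  # pin the range so levels are the integer values
    img <- matrix(v, 20, 20)
    m <- segment_organelle(img, pixel_size_nm = 80)
    lvl <- brute_otsu_level(as.vector(img))
    expect_identical(m$pixels, img > lvl)
  }
})

test_that("small components are removed by min_object_px", {
  img <- matrix(10, 64, 64)
  img[5:7, 5] <- 200          # 3 px speck
  img[30:40, 30:40] <- 200    # large object
  m <- segment_organelle(img, min_object_px = 5, pixel_size_nm = 80)
  expect_false(any(m$pixels[1:10, 1:10]))
  expect_true(all(m$pixels[30:40, 30:40]))
})

test_that("constant images make Otsu error", {
  expect_error(segment_organelle(matrix(7, 64, 64)), "constant")
  expect_error(segment_cytoplasm(matrix(0, 64, 64)), "constant")
})

test_that("a closed ring fills to a disk", {
  img <- matrix(0, 96, 96)
  rows <- matrix(seq_len(96), 96, 96)
  cols <- matrix(seq_len(96), 96, 96, byrow = TRUE)
  rad <- sqrt((rows - 48)^2 + (cols - 48)^2)
  img[rad >= 30 & rad <= 32] <- 100
  cy <- segment_cytoplasm(img)
  disk <- rad <= 32
  jac <- sum(cy$pixels & disk) / sum(cy$pixels | disk)
  expect_gt(jac, 0.95)
  expect_equal(punctaprox:::n_components(cy$pixels), 1)
})

test_that("cytoplasm segmentation recovers the generator ground truth", {
  fix <- cached_cell(12, noise_poisson_scale = 0, noise_gaussian_sd = 0)
  st <- render_timelapse(fix$cell, fix$tracks, fix$params)
  cy <- segment_cytoplasm(stack_frame(st, "membrane", 1))
  truth <- fix$cell$cytoplasm_mask$pixels
  jac <- sum(cy$pixels & truth) / sum(cy$pixels | truth)
  expect_gte(jac, 0.95)
})

test_that("an open arc does not segment as a closed cell", {
  img <- matrix(0, 96, 96)
  rows <- matrix(seq_len(96), 96, 96)
  cols <- matrix(seq_len(96), 96, 96, byrow = TRUE)
  rad <- sqrt((rows - 48)^2 + (cols - 48)^2)
  arc <- rad >= 30 & rad <= 32 & cols > 48  # half ring only
  img[arc] <- 100
  expect_error(segment_cytoplasm(img), "closed")
})

test_that("distance map gives exact pixel-center distances", {
  px <- matrix(FALSE, 64, 64); px[10, 13] <- TRUE
  dm <- distance_map(new_mask(px, 80))
  expect_equal(dm$distances_nm[10, 10], 240)
  expect_equal(dm$distances_nm[10, 13], 0)
  expect_equal(dm$distances_nm[13, 17], sqrt(3^2 + 4^2) * 80)
})

test_that("distance map equals brute force on random masks", {
  set.seed(41)
  for (i in 1:5) {
    px <- matrix(runif(32 * 32) < 0.04, 32, 32)
    if (!any(px)) px[17, 3] <- TRUE
    dm <- distance_map(new_mask(px, 80))
    pos <- which(px, arr.ind = TRUE)
    for (r in seq_len(32)) for (c in seq_len(32)) {
      bf <- sqrt(min((pos[, 1] - r)^2 + (pos[, 2] - c)^2)) * 80
      expect_equal(dm$distances_nm[r, c], bf, tolerance = 1e-12)
    }
  }
})

test_that("distance map is translation invariant away from borders", {
  set.seed(42)
  px <- matrix(FALSE, 48, 48)
  px[15:20, 12:14] <- TRUE
  d0 <- distance_map(new_mask(px, 80))$distances_nm
  d1 <- distance_map(new_mask(punctaprox:::shift_mask_px(px, 5, 7),
                              80))$distances_nm
  core_r <- 10:35; core_c <- 10:30
  expect_equal(d1[core_r + 5, core_c + 7], d0[core_r, core_c])
})

test_that("dilating a mask never increases distances", {
  set.seed(43)
  px <- matrix(runif(48 * 48) < 0.02, 48, 48)
  px[25, 25] <- TRUE
  d0 <- distance_map(new_mask(px, 80))$distances_nm
  d1 <- distance_map(new_mask(punctaprox:::dilate_mask(px, 2), 80))$distances_nm
  expect_true(all(d1 <= d0 + 1e-9))
})

test_that("empty masks are rejected", {
  expect_error(distance_map(new_mask(matrix(FALSE, 8, 8), 80)), "empty")
  expect_error(point_mask_distance(new_mask(matrix(FALSE, 8, 8), 80), 1, 1),
               "empty")
})
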