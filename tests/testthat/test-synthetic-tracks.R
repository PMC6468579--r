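test_that("forced association places every frame-1 punctum within reach", {
  fix <- cached_cell(5, p_assoc = 1)
  ts <- fix$tracks
  f1 <- ts$tracks[ts$tracks$frame == 1, ]
  d <- point_mask_distance(fix$cell$er_mask, f1$row_px, f1$col_px)
  expect_true(all(d <= 100))
  expect_true(all(fix$tracks$truth$associated))
})

test_that("unassociated seeding matches the dilated-organelle area fraction", {
  # Monte Carlo across 20 seeds: with p_assoc = 0 the frame-1 fraction
  # within 100 nm must equal the area fraction of the 100 nm neighbourhood
  # of the ER within the cytoplasm, up to binomial error.
  hits <- 0L; n <- 0L; f_ref <- numeric(0)
  for (s in 1:20) {
    fix <- cached_cell(600 + s, p_assoc = 0, n_frames = 1)
    f1 <- fix$tracks$tracks
    d <- point_mask_distance(fix$cell$er_mask, f1$row_px, f1$col_px)
    hits <- hits + sum(d <= 100); n <- n + nrow(f1)
    f_ref <- c(f_ref, footprint_fraction(fix$cell$er_mask,
                                         fix$cell$cytoplasm_mask$pixels, 100))
  }
  f0 <- mean(f_ref)
  se <- sqrt(f0 * (1 - f0) / n)
  expect_lt(abs(hits / n - f0), 3 * se + 0.01)
})

test_that("zero motion parameters freeze every trajectory", {
  fix <- cached_cell(6, diffusion_step_sd_nm = 0, organelle_motion_sd_nm = 0,
                     n_frames = 5)
  spans <- vapply(split(fix$tracks$tracks, fix$tracks$tracks$track_id),
                  function(tr) max(diff(range(tr$row_px)),
                                   diff(range(tr$col_px))), numeric(1))
  expect_true(all(spans == 0))
})

test_that("every trajectory point stays inside the cytoplasm", {
  fix <- cached_cell(7, n_frames = 12)
  tr <- fix$tracks$tracks
  inside <- punctaprox:::points_in_mask(fix$cell$cytoplasm_mask$pixels,
                                        tr$row_px, tr$col_px)
  expect_true(all(inside))
})

test_that("association toward an absent organelle errors", {
  cell <- generate_cell_geometry(cell_params(seed = 8, mito_region_count = 0,
                                             assoc_target = "mito"))
  expect_error(simulate_puncta_tracks(cell), "unsatisfiable")
})

test_that("simulation is deterministic for a fixed seed", {
  p <- cell_params(seed = 9)
  cell <- generate_cell_geometry(p)
  expect_identical(simulate_puncta_tracks(cell, p)$tracks,
                   simulate_puncta_tracks(cell, p)$tracks)
})

test_that("noiseless rendering localizes a static punctum to < 0.25 px", {
  fix <- cached_cell(10, n_puncta = 1, n_frames = 1,
                     diffusion_step_sd_nm = 0, organelle_motion_sd_nm = 0,
                     noise_poisson_scale = 0, noise_gaussian_sd = 0)
  st <- render_timelapse(fix$cell, fix$tracks, fix$params)
  img <- stack_frame(st, "puncta", 1) - 10  # background
  rows <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  cols <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  cr <- sum(rows * img) / sum(img); cc <- sum(cols * img) / sum(img)
  tr <- fix$tracks$tracks
  expect_lt(abs(cr - tr$row_px[1]), 0.25)
  expect_lt(abs(cc - tr$col_px[1]), 0.25)
})

test_that("a cell without puncta renders a background-only puncta channel", {
  fix <- cached_cell(11, n_puncta = 0, n_frames = 1,
                     noise_poisson_scale = 0, noise_gaussian_sd = 0)
  st <- render_timelapse(fix$cell, fix$tracks, fix$params)
  expect_true(all(stack_frame(st, "puncta", 1) == 10))
})

test_that("detection recovers most ground-truth puncta at default noise", {
  for (s in 1:4) {
    fix <- cached_cell(700 + s)
    st <- render_timelapse(fix$cell, fix$tracks, fix$params)
    det <- detect_puncta(stack_frame(st, "puncta", 1))
    tr <- fix$tracks$tracks[fix$tracks$tracks$frame == 1, ]
    d <- sqrt(outer(det$row_px, tr$row_px, "-")^2 +
              outer(det$col_px, tr$col_px, "-")^2)
    recall <- mean(apply(d, 2, min) <= 2)
    precision <- mean(apply(d, 1, min) <= 2)
    expect_gte(recall, 0.9)
    expect_gte(precision, 0.9)
  }
})
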