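test_that("distances are zero inside and exact outside the mask", {
  px <- matrix(FALSE, 64, 64); px[30, 30] <- TRUE
  m <- new_mask(px, 80)
  tr <- data.frame(track_id = 1, frame = 1:4, row_px = 30, col_px = 33)
  ts <- new_track_set(tr, 80, 4)
  d <- track_distances(ts, m)
  expect_equal(d$distance_nm, rep(240, 4))
  tr2 <- data.frame(track_id = 1, frame = 1:3, row_px = 30.3, col_px = 29.8)
  expect_equal(track_distances(new_track_set(tr2, 80, 3), m)$distance_nm,
               rep(0, 3))
})

test_that("subpixel distances match the brute-force oracle", {
  set.seed(61)
  for (i in 1:5) {
    px <- matrix(runif(32 * 32) < 0.05, 32, 32)
    if (!any(px)) px[5, 5] <- TRUE
    r <- runif(20, 1, 32); c <- runif(20, 1, 32)
    expect_equal(point_mask_distance(new_mask(px, 80), r, c),
                 brute_mask_dist_nm(px, 80, r, c), tolerance = 1e-12)
  }
})

test_that("per-frame masks are required and must be nonempty", {
  tr <- data.frame(track_id = 1, frame = 1:2, row_px = 5, col_px = 5)
  ts <- new_track_set(tr, 80, 2)
  good <- new_mask(matrix(TRUE, 8, 8), 80)
  bad <- new_mask(matrix(FALSE, 8, 8), 80)
  expect_error(track_distances(ts, list(good)), "frame 2")
  expect_error(track_distances(ts, list(good, bad)), "empty")
})

test_that("randomization preserves step-length multisets bit-for-bit", {
  fix <- cached_cell(13, n_frames = 8)
  orig <- sort(track_step_magnitudes(fix$tracks))
  for (mode in c("translate_rotate", "translate")) {
    reps <- randomize_tracks(fix$tracks, fix$cell$cytoplasm_mask,
                             randomization_config(n_replicates = 4,
                                                  mode = mode, seed = 3))
    for (r in reps)
      expect_identical(sort(track_step_magnitudes(r)), orig)
  }
})

test_that("randomized placements stay inside the cytoplasm", {
  fix <- cached_cell(13, n_frames = 8)
  reps <- randomize_tracks(fix$tracks, fix$cell$cytoplasm_mask,
                           randomization_config(n_replicates = 3, seed = 4))
  for (r in reps) {
    inside <- punctaprox:::points_in_mask(fix$cell$cytoplasm_mask$pixels,
                                          r$tracks$row_px, r$tracks$col_px)
    expect_true(all(inside))
  }
})

test_that("impossible placements fall back to the original with a warning", {
  px <- matrix(FALSE, 70, 70); px[10:12, 10:12] <- TRUE  # tiny cytoplasm
  tr <- data.frame(track_id = 1, frame = 1:2, row_px = c(11, 11),
                   col_px = c(11, 41))  # 30 px span cannot fit
  ts <- new_track_set(tr, 80, 2)
  expect_warning(
    reps <- randomize_tracks(ts, new_mask(px, 80),
                             randomization_config(n_replicates = 1,
                                                  max_attempts = 20,
                                                  seed = 5)),
    "original")
  expect_equal(reps[[1]]$tracks$col_px, tr$col_px)
})

test_that("empty cytoplasm is rejected", {
  tr <- data.frame(track_id = 1, frame = 1, row_px = 5, col_px = 5)
  expect_error(randomize_tracks(new_track_set(tr, 80, 1),
                                new_mask(matrix(FALSE, 8, 8), 80),
                                randomization_config(seed = 1)),
               "empty")
})

test_that("distance histograms normalize to unit integral", {
  d <- distance_distribution(rep(0, 10), bin_width_nm = 50)
  expect_equal(d$density_per_nm[1] * 50, 1)
  d2 <- distance_distribution(c(50, 150), bin_width_nm = 100)
  expect_equal(d2$density_per_nm, c(0.005, 0.005))
  set.seed(62)
  d3 <- distance_distribution(rexp(500, 1 / 200), bin_width_nm = 37)
  expect_equal(sum(d3$density_per_nm * 37), 1, tolerance = 1e-9)
})

test_that("the empirical CDF reproduces fraction-within at any threshold", {
  cdf <- cumulative_distribution(c(50, 150, 250))
  expect_equal(cdf(100), 1 / 3)
  expect_equal(cdf(250), 1)
  set.seed(63)
  d <- runif(1000, 0, 400)
  samples <- data.frame(cell_id = "c1", distance_nm = d)
  expect_equal(cumulative_distribution(d)(100),
               unname(fraction_within(samples, 100)))
})

test_that("fraction-within is inclusive and monotone in the threshold", {
  expect_equal(unname(fraction_within(c(0, 0, 0), 100)), 1)
  expect_equal(unname(fraction_within(c(50, 150, 250), 100)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(unname(fraction_within(c(100, 150), 100)), 0.5)  # inclusive
  set.seed(64)
  d <- runif(200, 0, 500)
  f <- vapply(seq(0, 500, by = 25), function(th)
    unname(fraction_within(d, th)), numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("summary means and SEMs recompute from the per-cell values", {
  obs <- c(0.7, 0.8, 0.6); rnd <- c(0.4, 0.5, 0.45)
  s <- compare_observed_vs_random(obs, rnd)
  expect_equal(s$mean_observed, mean(obs))
  expect_equal(s$sem_observed, sd(obs) / sqrt(3))
  expect_equal(s$mean_randomized, mean(rnd))
  expect_equal(s$sem_randomized, sd(rnd) / sqrt(3))
  # textbook closed form for the paired test on d = obs - rnd
  d <- obs - rnd
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(s$paired_test$t_stat, t_hand)
  expect_equal(s$paired_test$df, 2)
  expect_equal(s$paired_test$p_two_sided, 2 * pt(-abs(t_hand), 2))
})

test_that("identical observed and randomized fractions are degenerate", {
  expect_error(compare_observed_vs_random(c(0.5, 0.6), c(0.5, 0.6)),
               "degenerate")
})

test_that("ground-truth association is recovered through the statistic", {
  # generator-level recovery: with p_assoc = 0.7 the expected observed
  # fraction is p + (1 - p) * f where f is the chance-level footprint
  obs <- f <- numeric(6)
  n_samp <- 0L
  for (s in 1:6) {
    fix <- cached_cell(800 + s, p_assoc = 0.7, n_frames = 1)
    d <- track_distances(fix$tracks, fix$cell$er_mask)
    obs[s] <- unname(fraction_within(d, 100))
    f[s] <- footprint_fraction(fix$cell$er_mask,
                               fix$cell$cytoplasm_mask$pixels, 100)
    n_samp <- n_samp + nrow(d)
  }
  expected <- 0.7 + 0.3 * mean(f)
  se <- sqrt(expected * (1 - expected) / n_samp) +
    sqrt(0.7 * 0.3 / n_samp)  # binomial + assignment noise, conservative
  expect_lt(abs(mean(obs) - expected), 3 * se + 0.02)
})
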