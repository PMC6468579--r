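test_that("a blank frame yields no detections", {
  expect_equal(nrow(detect_puncta(matrix(5, 64, 64))), 0)
})

test_that("two separated noiseless spots are both found to subpixel accuracy", {
  img <- matrix(10, 80, 80)
  truth <- rbind(c(30.4, 25.7), c(50.1, 45.3))
  img <- img + punctaprox:::render_spots(80, 80, truth[, 1], truth[, 2],
                                         1.6, 150)
  det <- detect_puncta(img)
  expect_equal(nrow(det), 2)
  det <- det[order(det$row_px), ]
  expect_lt(max(abs(det$row_px - truth[, 1])), 0.25)
  expect_lt(max(abs(det$col_px - truth[, 2])), 0.25)
})

test_that("a single drifting spot links into one full-length track", {
  det <- data.frame(frame = 1:10, row_px = 20 + (0:9), col_px = 30)
  ts <- link_tracks(det, max_disp_px = 3)
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  expect_equal(nrow(ts$tracks), 10)
})

test_that("two distant static spots never swap identities", {
  det <- rbind(data.frame(frame = rep(1:8, each = 2),
                          row_px = rep(c(10, 60), 8),
                          col_px = rep(c(10, 60), 8)))
  ts <- link_tracks(det, max_disp_px = 5)
  expect_equal(length(unique(ts$tracks$track_id)), 2)
  for (tr in split(ts$tracks, ts$tracks$track_id)) {
    expect_equal(length(unique(tr$row_px)), 1)
    expect_equal(nrow(tr), 8)
  }
})

test_that("greedy linking attains the enumerated optimum on sparse cases", {
  set.seed(51)
  for (case in 1:6) {
    m <- sample(2:3, 1); nf <- sample(3:4, 1)
    base <- cbind(runif(m, 15, 85), runif(m, 15, 85))
    # enforce mutual separation >> step size so the optimum is unambiguous
    while (m > 1 && min(dist(base)) < 25)
      base <- cbind(runif(m, 15, 85), runif(m, 15, 85))
    per_frame <- lapply(seq_len(nf), function(f)
      base + matrix(rnorm(2 * m, 0, 1), m, 2))
    det <- do.call(rbind, lapply(seq_len(nf), function(f)
      data.frame(frame = f, row_px = per_frame[[f]][, 1],
                 col_px = per_frame[[f]][, 2])))
    ts <- link_tracks(det, max_disp_px = 5, min_track_length = 1)
    expect_equal(length(unique(ts$tracks$track_id)), m)
    expect_equal(greedy_link_cost(ts), brute_link_cost(per_frame),
                 tolerance = 1e-12)
  }
})

test_that("no link exceeds the per-gap displacement budget", {
  set.seed(52)
  det <- data.frame(frame = sample(1:6, 40, replace = TRUE),
                    row_px = runif(40, 1, 60), col_px = runif(40, 1, 60))
  ts <- link_tracks(det, max_disp_px = 4, max_gap = 1, min_track_length = 1)
  for (tr in split(ts$tracks, ts$tracks$track_id)) {
    if (nrow(tr) < 2) next
    gaps <- diff(tr$frame)
    steps <- sqrt(diff(tr$row_px)^2 + diff(tr$col_px)^2)
    expect_true(all(steps <= 4 * gaps + 1e-9))
    expect_true(all(gaps <= 2))
  }
})

test_that("linking is invariant to detection order within frames", {
  set.seed(53)
  det <- data.frame(frame = rep(1:5, each = 4),
                    row_px = runif(20, 1, 60), col_px = runif(20, 1, 60))
  ts1 <- link_tracks(det, min_track_length = 1)
  ts2 <- link_tracks(det[sample.int(20), ], min_track_length = 1)
  key <- function(ts) {
    k <- lapply(split(ts$tracks, ts$tracks$track_id), function(tr)
      paste(tr$frame, round(tr$row_px, 9), round(tr$col_px, 9),
            collapse = ";"))
    sort(unlist(k))
  }
  expect_identical(unname(key(ts1)), unname(key(ts2)))
})

test_that("gap closing bridges a single missed frame", {
  det <- data.frame(frame = c(1, 2, 4, 5), row_px = c(10, 11, 13, 14),
                    col_px = 20)
  ts <- link_tracks(det, max_disp_px = 3, max_gap = 1, min_track_length = 1)
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  ts2 <- link_tracks(det, max_disp_px = 3, max_gap = 0, min_track_length = 1)
  expect_equal(length(unique(ts2$tracks$track_id)), 2)
})

test_that("short tracks are filtered by min_track_length", {
  det <- data.frame(frame = c(1, 2, 1, 2, 3, 4),
                    row_px = c(10, 10, 50, 50, 50, 50), col_px = 20)
  ts <- link_tracks(det, min_track_length = 3)
  expect_equal(length(unique(ts$tracks$track_id)), 1)
  expect_equal(unique(ts$tracks$row_px), 50)
})
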