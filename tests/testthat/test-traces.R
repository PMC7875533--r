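# Kymograph construction, cluster size in kbp, compaction time.

make_spot_stack <- function(n_frames = 30, nr = 40, nc = 120, spot_col = 60,
                            noise_sd = 0) {
  # horizontal DNA line on row 20 with a growing spot at spot_col
  lapply(seq_len(n_frames), function(f) {
    m <- matrix(0, nr, nc)
    m[19:21, 10:110] <- 1
    amp <- 5 * min(1, f / 20)
    m[19:21, ] <- m[19:21, ] +
      amp * matrix(rep(exp(-(seq_len(nc) - spot_col)^2 / 8), each = 3), 3)
    if (noise_sd > 0) m <- m + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    m
  })
}

test_that("build_kymograph recovers a flat profile and the spot position", {
  stack <- make_spot_stack()
  line <- rbind(c(20, 10), c(20, 110))
  ky <- build_kymograph(stack, line, frame_interval = 0.5, pixel_size = 0.1)
  expect_s3_class(ky, "bips_kymograph")
  expect_equal(ncol(ky$mat), 30)
  # spot position: argmax of late frames at truth +/- 1 px (line starts at 10)
  late <- rowMeans(ky$mat[, 25:30])
  expect_lt(abs(which.max(late) - (60 - 10 + 1)), 2)

  # uniform line, no spot: normalized profile is flat along the DNA
  flat <- lapply(1:12, function(f) {
    m <- matrix(0, 40, 120); m[19:21, 10:110] <- 2; m
  })
  kf <- build_kymograph(flat, line)
  inner <- kf$mat[10:90, ]
  # background subtraction removes the uniform signal: profile is a constant
  expect_lt(diff(range(inner)), 0.05)
})

test_that("build_kymograph guards zero frames and rejects bad lines", {
  stack <- lapply(1:12, function(f) matrix(0, 30, 30))
  ky <- build_kymograph(stack, rbind(c(15, 2), c(15, 28)))
  expect_true(all(ky$mat == 0))
  expect_error(build_kymograph(stack, rbind(c(15, 2), c(15, 40))), "outside")
})

test_that("cluster_size_kbp converts intensity ratios and masks bad frames", {
  t <- 1:50
  roi <- intensity_trace(t, rep(10, 50))
  tot <- intensity_trace(t, rep(10, 50))
  expect_equal(cluster_size_kbp(roi, tot)$intensity, rep(48.5, 50))
  zero <- intensity_trace(t, rep(0, 50))
  expect_equal(cluster_size_kbp(zero, tot)$intensity, rep(0, 50))
  # scale invariance: common gain cancels
  sc <- cluster_size_kbp(intensity_trace(t, 7.3 * rep(10, 50)),
                         intensity_trace(t, 7.3 * rep(10, 50)))
  expect_equal(sc$intensity, rep(48.5, 50))
  # non-positive total is masked with a warning
  bad <- intensity_trace(t, c(rep(10, 49), 0))
  expect_warning(out <- cluster_size_kbp(roi, bad), "masked")
  expect_true(is.na(out$intensity[50]))
})

test_that("compaction_time is exact on ramps and invariant to affine
           transforms and time shifts", {
  mk <- function(t0, dur, gain = 1, offset = 0, tmax = 200) {
    t <- seq(0.1, tmax, by = 0.1)
    y <- pmin(1, pmax(0, (t - t0) / dur)) * gain + offset
    intensity_trace(t, y)
  }
  ct <- compaction_time(mk(20, 100), savgol_window = 11)
  expect_equal(ct, 90, tolerance = 0.2)
  # affine intensity transform and time translation leave it unchanged
  expect_equal(compaction_time(mk(40, 100, gain = 37.2, offset = -5,
                                  tmax = 220), savgol_window = 11),
               ct, tolerance = 0.2)
  # step function: compaction within one frame interval
  st <- mk(100, 0.0001)
  expect_lt(compaction_time(st, savgol_window = 1), 0.11)
})

test_that("compaction_time shrinks an oversized window and demands a plateau", {
  t <- seq(0.1, 30, by = 0.1)
  ramp <- intensity_trace(t, pmin(1, t / 15))   # plateau half the trace
  expect_no_error(compaction_time(ramp, savgol_window = 1e5))
  drift <- intensity_trace(t, t)                # never plateaus
  expect_error(compaction_time(drift, savgol_window = 11), "plateau")
})

test_that("compaction times at measurement-like noise match the generator", {
  cts <- vapply(1:30, function(s) {
    g <- gen_compaction_kymograph(duration = 30, t_start = 10,
                                  noise_sd = 0.05, seed = s)
    kbp <- suppressWarnings(cluster_size_kbp(g$roi_trace, g$total_trace))
    compaction_time(kbp, savgol_window = 51)
  }, numeric(1))
  expect_gt(mean(cts), 24)
  expect_lt(mean(cts), 30)
})

test_that("count_complexes divides by the unit step and propagates error", {
  expect_equal(count_complexes(9, 3), 3)
  expect_equal(count_complexes(2220, 3.0), 740)
  expect_equal(count_complexes(0, 3), 0)
  expect_error(count_complexes(10, 0), "positive")
  n <- count_complexes(2220, 3.0, cluster_sd = 222, unit_sd = 1.2)
  expect_equal(as.numeric(n), 740)
  expect_equal(attr(n, "sd"), 740 * sqrt((222 / 2220)^2 + (1.2 / 3)^2),
               tolerance = 1e-10)
})
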