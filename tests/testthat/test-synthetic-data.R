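# Generators: determinism, ground-truth bookkeeping, and exactness of the
# matched estimators on noise-free data.

test_that("every generator is bit-identical under a repeated seed", {
  a <- gen_compaction_kymograph(noise_sd = 0.05, seed = 12)
  b <- gen_compaction_kymograph(noise_sd = 0.05, seed = 12)
  expect_identical(a, b)
  expect_false(identical(
    a$kymo$mat, gen_compaction_kymograph(noise_sd = 0.05, seed = 13)$kymo$mat))

  expect_identical(gen_bleach_staircase(4, noise_sd = 0.5, seed = 3),
                   gen_bleach_staircase(4, noise_sd = 0.5, seed = 3))
  expect_identical(
    gen_exponential_trace("decay", 10, noise_sd = 0.1, seed = 9),
    gen_exponential_trace("decay", 10, noise_sd = 0.1, seed = 9))
  expect_identical(gen_droplet_image(noise_sd = 0.02, seed = 4),
                   gen_droplet_image(noise_sd = 0.02, seed = 4))
  gr <- data.frame(x_nm = 100, y_nm = 120, height_nm = 2, sd_nm = 5)
  expect_identical(gen_afm_heightmap(gr, noise_sd = 0.1, seed = 8),
                   gen_afm_heightmap(gr, noise_sd = 0.1, seed = 8))
})

test_that("noiseless compaction kymograph conserves intensity and reads back
           its plateau and compaction time", {
  g <- gen_compaction_kymograph(total_kbp = 48.5, plateau_kbp = 20,
                                t_start = 10, duration = 100, noise_sd = 0,
                                frame_interval = 0.1, seed = 1)
  # intensity conservation: total is constant over frames
  tot <- colSums(g$kymo$mat)
  expect_lt(diff(range(tot)) / mean(tot), 1e-10)
  # plateau reads exactly 20 kbp through the cluster-size estimator
  kbp <- cluster_size_kbp(g$roi_trace, g$total_trace)
  n <- nrow(kbp)
  expect_equal(mean(kbp$intensity[seq.int(n - 20, n)]), 20, tolerance = 1e-7)
  expect_lt(max(abs(kbp$intensity[g$roi_trace$time < 10])), 1e-6)
  # 5-95% of the noiseless linear ramp spans 0.9 * duration
  ct <- compaction_time(kbp, savgol_window = 11)
  expect_equal(ct, 90, tolerance = 0.2)
  expect_equal(g$truth$compaction_time_5_95, 90)
})

test_that("compaction kymograph rejects a plateau exceeding the total", {
  expect_error(gen_compaction_kymograph(total_kbp = 48.5, plateau_kbp = 50),
               "plateau_kbp")
  expect_error(gen_compaction_kymograph(duration = -3), "duration")
})

test_that("noiseless staircase has exactly its n_steps downward transitions", {
  for (n_steps in c(1, 3, 6)) {
    g <- gen_bleach_staircase(n_steps, noise_sd = 0, seed = n_steps)
    jumps <- which(diff(g$trace$intensity) < -1e-9)
    expect_length(jumps, n_steps)
    expect_equal(g$trace$intensity[1], n_steps * 3)
    expect_equal(tail(g$trace$intensity, 1), 0)
  }
})

test_that("noiseless exponential traces invert exactly through the fitter", {
  g <- gen_exponential_trace("decay", tau = 10, noise_sd = 0, seed = 1)
  f <- fit_exponential(g$trace, "decay")
  expect_equal(f$tau, 10, tolerance = 1e-6)
  g2 <- gen_exponential_trace("recovery", tau = 126, noise_sd = 0, seed = 1)
  f2 <- fit_exponential(g2$trace, "recovery")
  expect_equal(f2$tau, 126, tolerance = 1e-4)
})

test_that("point-source image is the analytic PSF with the predicted
           20%-of-max width", {
  g <- gen_droplet_image("circle", radius_or_axes = 0, psf_sd = 0.159,
                         pixel_size = 0.065, noise_sd = 0, seed = 1)
  expect_equal(g$truth$point_fw20_um, 2 * 0.159 * sqrt(2 * log(5)),
               tolerance = 1e-12)
  d <- gaussian_diameter(g$image)
  expect_equal(as.numeric(d), g$truth$point_fw20_um, tolerance = 0.02)
})

test_that("single noise-free grain recovers the analytic Gaussian volume", {
  gr <- data.frame(x_nm = 250, y_nm = 250, height_nm = 2, sd_nm = 5)
  g <- gen_afm_heightmap(gr, noise_sd = 0, pixel_size_nm = 2,
                         field_px = c(250, 250), seed = 1)
  expect_equal(g$truth$grain_volumes_nm3, 2 * pi * 2 * 25, tolerance = 1e-12)
  gs <- grain_volumes(g$map, min_height = 0.02)
  expect_equal(nrow(gs), 1L)
  expect_equal(gs$volume_nm3, 2 * pi * 2 * 25, tolerance = 0.02)
})

test_that("empty AFM field yields an empty grain set", {
  g <- gen_afm_heightmap(NULL, noise_sd = 0.05, seed = 2)
  gs <- grain_volumes(g$map)
  expect_equal(nrow(gs), 0L)
})
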