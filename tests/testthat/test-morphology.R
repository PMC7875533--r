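# Droplet geometry and AFM volumetry.

disk_mask <- function(r, n = 2 * r + 21) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

ellipse_mask <- function(a, b, n = 2 * a + 21) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - ctr) / b)^2 + ((j - ctr) / a)^2 <= 1)
}

test_that("circularity approaches 1 for disks and matches the
           elliptic-integral oracle for a 2:1 ellipse", {
  expect_equal(circularity(disk_mask(50)), 1, tolerance = 0.02)
  # convergence with radius, never exceeding 1 + discretization tolerance
  for (r in c(20, 35, 50, 80)) {
    ci <- circularity(disk_mask(r))
    expect_lt(abs(ci - 1), 0.03)
    expect_lt(ci, 1.02)
  }
  a <- 80; b <- 40
  oracle <- 4 * pi * (pi * a * b) / oracle_ellipse_perimeter(a, b)^2
  expect_equal(oracle, 0.84, tolerance = 0.005)
  expect_equal(circularity(ellipse_mask(a, b)), oracle, tolerance = 0.01)
})

test_that("circularity rejects empty and multi-component masks", {
  expect_error(circularity(matrix(FALSE, 10, 10)), "empty")
  two <- matrix(FALSE, 40, 40)
  two[5:10, 5:10] <- TRUE
  two[25:30, 25:30] <- TRUE
  expect_error(circularity(two), "components")
})

test_that("geometry outputs are invariant under translation and rotations", {
  m <- ellipse_mask(30, 18, n = 101)
  c0 <- circularity(m)
  expect_equal(circularity(t(m)), c0, tolerance = 1e-6)          # 90 degrees
  expect_equal(circularity(m[101:1, ]), c0, tolerance = 1e-6)    # flip
  shifted <- matrix(FALSE, 121, 121)
  shifted[8 + seq_len(101), 3 + seq_len(101)] <- m
  expect_equal(circularity(shifted), c0, tolerance = 1e-6)
})

test_that("gaussian_diameter reads 3.588 SD on a pure Gaussian and rejects
           double peaks", {
  g <- gen_droplet_image("circle", radius_or_axes = 0, psf_sd = 0.2,
                         pixel_size = 0.05, noise_sd = 0, seed = 1)
  d <- gaussian_diameter(g$image)
  expect_equal(as.numeric(d), 2 * 0.2 * sqrt(2 * log(5)), tolerance = 0.01)
  # clearly resolved double peak (5 PSF widths apart)
  m <- g$image$mat
  shift <- 20
  two <- m + cbind(m[, (shift + 1):ncol(m)], m[, 1:shift])
  expect_error(gaussian_diameter(bips_image(two, 0.05)), "peak")
})

test_that("droplet versus point-source apparent size reproduces the 2.0
           diffraction ratio", {
  pt <- gen_droplet_image("circle", radius_or_axes = 0, psf_sd = 0.159,
                          pixel_size = 0.065, noise_sd = 0, seed = 1)
  d_pt <- as.numeric(gaussian_diameter(pt$image))
  expect_equal(d_pt, 0.57, tolerance = 0.02)
  dr <- gen_droplet_image("circle", radius_or_axes = 0.46, psf_sd = 0.159,
                          pixel_size = 0.065, noise_sd = 0, seed = 1)
  d_dr <- as.numeric(gaussian_diameter(dr$image))
  expect_equal(d_dr / d_pt, 2.0, tolerance = 0.08)
})

test_that("grain volumes integrate thresholded height and conserve totals", {
  gr <- data.frame(x_nm = c(150, 350), y_nm = c(150, 350),
                   height_nm = c(2, 3), sd_nm = c(5, 6))
  g <- gen_afm_heightmap(gr, noise_sd = 0, pixel_size_nm = 2,
                         field_px = c(256, 256), seed = 1)
  gs <- grain_volumes(g$map, min_height = 0.05)
  expect_equal(nrow(gs), 2L)
  expect_equal(sort(gs$volume_nm3), sort(g$truth$grain_volumes_nm3),
               tolerance = 0.03)
  # conservation: total volume equals the integral of the thresholded field
  total <- sum(g$map$mat[g$map$mat >= 0.05]) * 4
  expect_equal(sum(gs$volume_nm3), total, tolerance = 1e-12)
  # 90-degree rotation leaves volumes unchanged
  rot <- afm_heightmap(t(g$map$mat), 2)
  expect_equal(sort(grain_volumes(rot, min_height = 0.05)$volume_nm3),
               sort(gs$volume_nm3), tolerance = 1e-12)
})

test_that("background flattening recovers grain volumes on a tilted plane", {
  set.seed(4)
  gr <- data.frame(x_nm = runif(20, 60, 450), y_nm = runif(20, 60, 450),
                   height_nm = runif(20, 1.5, 3), sd_nm = runif(20, 4, 7))
  g <- gen_afm_heightmap(gr, background_poly = c(1, 4, -3),
                         noise_sd = 0.03, pixel_size_nm = 2,
                         field_px = c(256, 256), seed = 4)
  flat <- afm_flatten(g$map, order = 1)
  gs <- grain_volumes(flat, min_height = 0.1)
  # match grains to truth by position and compare total volume
  expect_gte(nrow(gs), 18)
  expect_equal(sum(gs$volume_nm3), sum(g$truth$grain_volumes_nm3),
               tolerance = 0.05)
})

test_that("mean + 7 SD threshold reproduces the single-molecule cutoff", {
  expect_equal(single_molecule_threshold(rep(300, 10)), 300)
  expect_equal(single_molecule_threshold(c(100, 200, 300), k = 0), 200)
  set.seed(9)
  v <- rnorm(20000, 300, 262)
  expect_equal(single_molecule_threshold(v), 300 + 7 * 262, tolerance = 0.02)
  expect_error(single_molecule_threshold(c(1, 2)), "at least 3")
})

test_that("stoichiometry floors the volume ratio", {
  expect_identical(cluster_stoichiometry(3000, 300), 10L)
  expect_identical(cluster_stoichiometry(51000, 300), 170L)
  expect_identical(cluster_stoichiometry(200, 300), 0L)
  expect_error(cluster_stoichiometry(100, 0), "positive")
})

test_that("bridging classification separates straight contours, hairpins and
           unbound proteins", {
  straight <- cbind(seq(0, 100, by = 1), 0)
  expect_equal(classify_bridging(straight, c(50, 1), 3), "unbridged")
  hairpin <- rbind(cbind(seq(0, 50, 1), 0), cbind(seq(49, 0, -1), 4))
  expect_equal(classify_bridging(hairpin, c(25, 2), 3), "bridged")
  expect_error(classify_bridging(straight, c(50, 50), 3), "not bound")
})

test_that("planted bridged fraction is recovered within 5 points", {
  set.seed(12)
  n <- 200
  planted <- runif(n) < 0.4
  calls <- vapply(seq_len(n), function(i) {
    if (planted[i]) {
      gap <- runif(1, 2, 5)
      contour <- rbind(cbind(seq(0, 60, 1), 0), cbind(seq(59, 0, -1), gap))
      p <- c(runif(1, 20, 40), gap / 2)
    } else {
      contour <- cbind(seq(0, 120, 1), 0)
      p <- c(runif(1, 20, 100), runif(1, -1, 1))
    }
    classify_bridging(contour, p, 3)
  }, character(1))
  frac <- mean(calls == "bridged")
  expect_lt(abs(frac - mean(planted)), 0.05)
})
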