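# Radius of gyration, power-law fits and the critical looping length.

test_that("radius_of_gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(3, -1, 2), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)  # d/2
  # straight rod of N beads, spacing a: sqrt(a^2 (N^2 - 1) / 12)
  for (N in c(3, 10, 57)) {
    a <- 0.7
    rod <- cbind(a * (seq_len(N) - 1), 0, 0)
    expect_equal(radius_of_gyration(rod), sqrt(a^2 * (N^2 - 1) / 12),
                 tolerance = 1e-12)
  }
  expect_error(radius_of_gyration(matrix(numeric(0), 0, 3)), "empty")
})

test_that("radius_of_gyration is invariant under rigid motions", {
  set.seed(11)
  pts <- matrix(rnorm(60), ncol = 3)
  rg0 <- radius_of_gyration(pts)
  for (i in 1:10) {
    # random rotation via QR of a Gaussian matrix, plus random translation
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    moved <- sweep(pts %*% q, 2, rnorm(3, sd = 10), "+")
    expect_equal(radius_of_gyration(moved), rg0, tolerance = 1e-10)
  }
})

test_that("critical looping length reproduces 2 pi^2 l_P", {
  cl <- critical_looping_length(50)
  expect_equal(cl$nm, 2 * pi^2 * 50, tolerance = 1e-12)
  expect_equal(cl$nm, 986.96, tolerance = 1e-4)
  expect_equal(cl$bp, 2903L)
  # inversion: l_P chosen so that l_C is exactly one base pair
  inv <- critical_looping_length(0.34 / (2 * pi^2))
  expect_equal(inv$nm, 0.34, tolerance = 1e-12)
  expect_equal(inv$bp, 1L)
  # linearity in l_P
  half <- critical_looping_length(25)
  expect_equal(half$nm, cl$nm / 2, tolerance = 1e-12)
  expect_equal(half$bp, 1451L)
})

test_that("fit_power_law recovers exact exponents and errors on bad input", {
  l <- c(500, 1000, 3000, 9000, 20000)
  f <- fit_power_law(l, 2 * l^0.45)
  expect_equal(f$alpha, 0.45, tolerance = 1e-10)
  expect_lt(f$alpha_sd, 1e-8)
  expect_equal(f$prefactor, 2, tolerance = 1e-6)

  f0 <- fit_power_law(l, rep(20, 5))
  expect_equal(f0$alpha, 0, tolerance = 1e-12)

  expect_error(fit_power_law(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(fit_power_law(c(1, 2), c(1, 2)))
})

test_that("piecewise fit finds the constructed breakpoint and flags fallback", {
  lengths <- c(300, 700, 1500, 3000, 6000, 12000, 24000, 48000)
  level <- 20
  sizes <- ifelse(lengths <= 3000, level,
                  level * (lengths / 3000)^0.45)
  f <- piecewise_scaling_fit(lengths, sizes)
  expect_equal(f$breakpoint_bp, 3000)
  expect_equal(f$alpha, 0.45, tolerance = 1e-6)
  expect_equal(f$constant_level, 20, tolerance = 1e-6)
  expect_false(f$fallback)

  expect_warning(fp <- piecewise_scaling_fit(lengths[5:8],
                                             2 * lengths[5:8]^0.45),
                 "single power law")
  expect_true(fp$fallback)
})

test_that("piecewise breakpoint is robust to lognormal scatter", {
  lengths <- rep(c(300, 700, 1500, 3000, 6000, 12000, 24000, 48000), each = 3)
  true_bp <- 3000
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    sizes <- ifelse(lengths <= true_bp, 20, 20 * (lengths / true_bp)^0.45) *
      exp(rnorm(length(lengths), sd = log(1.3)))
    f <- piecewise_scaling_fit(lengths, sizes)
    if (!f$fallback && f$breakpoint_bp >= true_bp / 2 &&
        f$breakpoint_bp <= true_bp * 2) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
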