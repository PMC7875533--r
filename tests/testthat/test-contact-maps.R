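# Contact maps and compartment scoring.

test_that("snapshot contacts match geometry and the brute-force oracle", {
  # two beads at half the capture radius: contact
  m <- snapshot_contacts(rbind(c(0, 0, 0), c(1, 0, 0)), r_c = 2)
  expect_equal(m, matrix(1L, 2, 2))
  # straight rod with r_c = 1.5 sigma: banded with bandwidth 1
  rod <- cbind(seq_len(12), 0, 0)
  mr <- snapshot_contacts(rod, 1.5)
  expect_equal(mr, oracle_contacts(rod, 1.5))
  expect_true(all(mr[abs(row(mr) - col(mr)) == 1] == 1))
  expect_true(all(mr[abs(row(mr) - col(mr)) >= 2] == 0))
  # random coil, open and periodic: identical to the O(N^2) oracle
  set.seed(21)
  pos <- matrix(runif(70 * 3, 0, 10), ncol = 3)
  expect_equal(snapshot_contacts(pos, 1.2), oracle_contacts(pos, 1.2))
  expect_equal(snapshot_contacts(pos, 1.2, box = 10),
               oracle_contacts(pos, 1.2, box = 10))
})

test_that("aggregate_map averages snapshots and is deterministic", {
  ch <- chain_config(45)
  pr <- sim_params(n_steps = 6000, snapshot_every = 300, seed = 2)
  traj <- simulate_bips(ch, NULL, pr)
  map <- aggregate_map(traj, r_c_nm = 25)
  expect_s3_class(map, "bips_contact_map")
  expect_equal(map$map, t(map$map))
  expect_true(all(diag(map$map) == 1))
  expect_true(all(map$map >= 0 & map$map <= 1))
  # replay determinism
  traj2 <- simulate_bips(ch, NULL, pr)
  expect_identical(aggregate_map(traj2, r_c_nm = 25)$map, map$map)
  # single snapshot: aggregate equals that snapshot's matrix
  one <- traj
  one$snapshots <- traj$snapshots[1]
  m1 <- aggregate_map(one, r_c_nm = 25, discard_fraction = 0,
                      min_snapshots = 1)
  expect_equal(m1$map,
               snapshot_contacts(traj$snapshots[[1]]$pos[1:45, ], 2.5,
                                 box = traj$final$box) * 1.0)
  expect_error(aggregate_map(one, r_c_nm = 25), "at least 10")
  # frozen configuration repeated: entries stay binary
  frozen <- traj
  frozen$snapshots <- rep(traj$snapshots[1], 12)
  for (i in seq_along(frozen$snapshots))
    frozen$snapshots[[i]]$step <- i
  mf <- aggregate_map(frozen, r_c_nm = 25, discard_fraction = 0)
  expect_true(all(mf$map %in% c(0, 1)))
})

test_that("ideal-chain contact probability decays roughly as s^(-3/2)", {
  # freely jointed phantom chains start in equilibrium: use init ensembles
  ch <- chain_config(120, persistence_length_nm = 0)
  acc <- matrix(0, 120, 120)
  for (r in 1:150) {
    set.seed(300 + r)
    st <- init_state(ch, NULL, sim_params(), excluded_volume = FALSE,
                     box_sigma = 1e6)
    acc <- acc + snapshot_contacts(st$pos, 1.0)
  }
  p <- vapply(2:40, function(s) {
    idx <- seq_len(120 - s)
    mean(acc[cbind(idx, idx + s)]) / 150
  }, numeric(1))
  sep <- 2:40
  keep <- p > 0 & sep >= 4
  slope <- coef(lm(log(p[keep]) ~ log(sep[keep])))[[2]]
  expect_gt(slope, -1.8)
  expect_lt(slope, -1.2)
})

test_that("compartment strength scores plaid maps and ignores uniform decay", {
  n <- 60
  s <- abs(outer(1:n, 1:n, "-"))
  base <- (s + 1)^-1.2
  diag(base) <- 1
  expect_lt(compartment_strength(base), 0.05)

  # two-block plaid: within-block contacts enriched 2x
  blocks <- rep(c(TRUE, FALSE), each = 10, length.out = n)
  same <- outer(blocks, blocks, "==")
  plaid <- base * ifelse(same, 2, 1)
  diag(plaid) <- 1
  score <- compartment_strength(plaid)
  expect_gt(score, 0.2)

  # brute-force block-average oracle on the same O/E correlation matrix
  oe <- plaid / base
  cc <- suppressWarnings(cor(oe))
  cc[!is.finite(cc)] <- 0
  within <- c(cc[blocks, blocks][upper.tri(cc[blocks, blocks])],
              cc[!blocks, !blocks][upper.tri(cc[!blocks, !blocks])])
  oracle <- mean(within) - mean(cc[blocks, !blocks])
  expect_equal(score, min(1, max(0, oracle)), tolerance = 0.05)
})

test_that("compartment strength is invariant under block-preserving
           relabeling and zero for degenerate maps", {
  n <- 60
  s <- abs(outer(1:n, 1:n, "-"))
  blocks <- rep(c(TRUE, FALSE), each = 15, length.out = n)
  plaid <- (s + 1)^-1 * ifelse(outer(blocks, blocks, "=="), 2, 1)
  diag(plaid) <- 1
  sc <- compartment_strength(plaid)
  rev_idx <- n:1  # reversal preserves the block pattern
  expect_equal(compartment_strength(plaid[rev_idx, rev_idx]), sc,
               tolerance = 1e-8)
  expect_equal(compartment_strength(matrix(1, 50, 50)), 0)
})
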