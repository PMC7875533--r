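# Force-field and binding physics of the bead-spring simulator.

test_that("init_state builds a correct minimal chain with no bonds", {
  ch <- chain_config(2)
  for (s in c(1, 99)) {
    set.seed(s)
    st <- init_state(ch, bridge_config(2), sim_params(seed = s))
    expect_equal(nrow(st$bonds), 0L)
    d <- st$pos[1, ] - st$pos[2, ]
    d <- d - st$box * round(d / st$box)
    expect_equal(sqrt(sum(d^2)), 0.97, tolerance = 0.01)
  }
})

test_that("initial conformations match the worm-like-chain closed form", {
  ch <- chain_config(50)
  ree2 <- vapply(1:400, function(r) {
    set.seed(r)
    st <- init_state(ch, NULL, sim_params(), excluded_volume = FALSE,
                     box_sigma = 1e6)
    chain_stats(st)$ree_nm^2
  }, numeric(1))
  L <- 49 * 0.97 * 10          # contour at the FENE+WCA rest length, nm
  expect_equal(mean(ree2), wlc_ree2(L, 50), tolerance = 0.1)
})

test_that("a free dumbbell diffuses with D = kT / (total friction)", {
  ch <- chain_config(2, persistence_length_nm = 0)
  set.seed(7)
  msd <- vapply(1:600, function(r) {
    st <- init_state(ch, NULL, sim_params(), excluded_volume = FALSE,
                     box_sigma = 1e6)
    com0 <- colMeans(st$pos)
    st <- integrate_state(st, 10000)
    sum((colMeans(st$pos) - com0)^2)
  }, numeric(1))
  t_tot <- 10000 * 0.01
  gam <- 2 * sim_params()$friction           # total friction of the dumbbell
  d_com <- 1 / gam                           # kT / (total friction)
  tau_p <- 2 / gam                           # ballistic time, total mass 2
  expected <- 6 * d_com * (t_tot - tau_p * (1 - exp(-t_tot / tau_p)))
  expect_equal(mean(msd), expected, tolerance = 0.05)
})

test_that("tangent correlations decay with the configured persistence length", {
  ch <- chain_config(100)
  acc <- matrix(0, 0, 12)
  for (r in 1:70) {
    set.seed(100 + r)
    st <- init_state(ch, NULL, sim_params(), excluded_volume = FALSE,
                     box_sigma = 1e6)
    st <- integrate_state(st, 4000)
    p <- st$pos              # box is huge: coordinates are never wrapped
    b <- diff(p[seq_len(100), ])
    b <- b / sqrt(rowSums(b^2))
    acc <- rbind(acc, vapply(1:12, function(s)
      mean(rowSums(b[1:(nrow(b) - s), ] * b[(1 + s):nrow(b), ])), numeric(1)))
  }
  m <- colMeans(acc)
  lp_beads <- -1 / coef(lm(log(m) ~ seq_len(12)))[[2]]
  expect_equal(lp_beads * 10, 50, tolerance = 0.1)  # nm
})

test_that("identical seeds give identical trajectories", {
  ch <- chain_config(40)
  br <- bridge_config(2)
  pr <- sim_params(n_steps = 5000, snapshot_every = 1000, seed = 31)
  t1 <- simulate_bips(ch, br, pr)
  t2 <- simulate_bips(ch, br, pr)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$final$pos, t2$final$pos)
  expect_identical(t1$final$bonds, t2$final$bonds)
})

test_that("the valence cap is never violated", {
  ch <- chain_config(60)
  for (val in c(2L, 3L)) {
    br <- bridge_config(val, binding_energy = 6)
    pr <- sim_params(n_steps = 20000, snapshot_every = 1000, seed = 17)
    traj <- simulate_bips(ch, br, pr)
    for (sn in traj$snapshots) {
      if (nrow(sn$bonds) == 0) next
      expect_lte(max(table(sn$bonds[, "bridge"])), val)
    }
  }
})

test_that("frozen-position binding matches the enumeration oracle", {
  # small rigid geometry: 8 beads on a line, 2 bridges parked close to it
  ch <- chain_config(8)
  br <- bridge_config(2, binding_energy = 1)
  set.seed(5)
  st <- init_state(ch, br, sim_params(seed = 5), box_sigma = 40)
  bead_pos <- cbind(20 + 0.97 * (seq_len(8) - 4), 20, 20)
  bridge_pos <- rbind(c(20 - 1.2, 21.0, 20), c(20 + 1.6, 21.1, 20))
  st$pos <- rbind(bead_pos, bridge_pos)
  st$n_bridges <- 2L
  st$vel <- st$vel[1:10, , drop = FALSE]

  expected <- oracle_binding_enumeration(bead_pos, bridge_pos, eps = 1,
                                         valence = 2)
  set.seed(42)
  st2 <- update_binding(st, n_sweeps = 60000, record_every = 10)
  counts <- attr(st2, "n_bonds_trace")
  counts <- counts[-seq_len(500)]           # burn-in
  se <- sd(counts) / sqrt(length(counts) / 20)  # crude autocorrelation guard
  expect_lt(abs(mean(counts) - expected), max(4 * se, 0.05))
})

test_that("binding respects the segment-exclusion rule and capture radius", {
  ch <- chain_config(60)
  br <- bridge_config(3, binding_energy = 6)
  pr <- sim_params(n_steps = 20000, snapshot_every = 2000, seed = 23)
  traj <- simulate_bips(ch, br, pr)
  for (sn in traj$snapshots) {
    if (nrow(sn$bonds) < 2) next
    by_bridge <- split(sn$bonds[, "bead"], sn$bonds[, "bridge"])
    for (beads in by_bridge)
      if (length(beads) > 1) expect_gt(min(diff(sort(beads))), 2)
  }
})

test_that("largest_cluster finds bonded bridges and their beads", {
  ch <- chain_config(30)
  br <- bridge_config(2)
  set.seed(3)
  st <- init_state(ch, br, sim_params(seed = 3))
  # unbound, dilute: largest cluster is a single particle
  expect_equal(length(largest_cluster(st)), 1L)
  # place one bridge next to beads 5 and 20 and register the bonds
  p5 <- st$pos[5, ]
  st$pos[20, ] <- p5 + c(2.2, 0, 0)
  st$pos[31, ] <- p5 + c(1.1, 0, 0)    # first bridge between them
  st$bonds <- matrix(c(1L, 1L, 5L, 20L), 2, 2,
                     dimnames = list(NULL, c("bridge", "bead")))
  members <- largest_cluster(st)
  expect_true(all(c(5L, 20L, 31L) %in% members))
})

test_that("chains below the looping length grow no multi-bridge clusters", {
  # bivalent bridges on short stiff chains: the largest cluster stays at the
  # single-bridge scale regardless of length
  sizes <- vapply(c(30, 60, 90), function(n) {
    ch <- chain_config(n)
    br <- bridge_config(2)
    pr <- sim_params(n_steps = 60000, snapshot_every = 10000, seed = 7 + n)
    traj <- simulate_bips(ch, br, pr)
    mean(vapply(seq_along(traj$snapshots), function(i)
      cluster_rg(snapshot_state(traj, i))$n_members, integer(1)))
  }, numeric(1))
  expect_lt(max(sizes), 20)   # a few bridges plus their beads, not a condensate
  expect_lt(diff(range(sizes)) / mean(sizes), 0.6)
})
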