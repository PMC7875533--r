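# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exhaustive dynamic-programming change-point fit: optimal piecewise-constant
# approximation with exactly k breakpoints (minimum total SSE). O(k n^2).
dp_steps <- function(y, k) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  segcost <- function(i, j) {  # y[i..j]
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  # cost[j, m] = best SSE for y[1..j] with m-1 breakpoints
  cost <- matrix(Inf, n, k + 1)
  back <- matrix(0L, n, k + 1)
  for (j in 1:n) cost[j, 1] <- segcost(1, j)
  for (m in 2:(k + 1)) {
    for (j in m:n) {
      best <- Inf; arg <- 0L
      for (i in (m - 1):(j - 1)) {
        v <- cost[i, m - 1] + segcost(i + 1, j)
        if (v < best) { best <- v; arg <- i }
      }
      cost[j, m] <- best
      back[j, m] <- arg
    }
  }
  bps <- integer(k)
  j <- n
  for (m in (k + 1):2) {
    j <- back[j, m]
    bps[m - 1] <- j
  }
  list(breakpoints = bps, sse = cost[n, k + 1])
}

# worm-like-chain mean squared end-to-end distance
wlc_ree2 <- function(L, lp) 2 * lp * L - 2 * lp^2 * (1 - exp(-L / lp))

# ellipse perimeter by direct quadrature of the arc-length integral
oracle_ellipse_perimeter <- function(a, b) {
  th <- seq(0, pi / 2, length.out = 20001)
  f <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  4 * sum((f[-1] + f[-length(f)]) / 2) * diff(th[1:2])
}

# brute-force all-pairs contact matrix (minimum image when box > 0)
oracle_contacts <- function(pos, r_c, box = 0) {
  n <- nrow(pos)
  m <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      if (box > 0) d <- d - box * round(d / box)
      if (sqrt(sum(d^2)) <= r_c) m[i, j] <- m[j, i] <- 1L
    }
  }
  diag(m) <- 1L
  m
}

# exact equilibrium mean bond count for a frozen bead/bridge geometry by
# enumeration over all bond subsets respecting the valence cap and the
# segment-exclusion rule (no two bonds of one bridge within 2 beads)
oracle_binding_enumeration <- function(bead_pos, bridge_pos, eps, valence,
                                       r_capture = 1.5, k_bond = 40,
                                       r0 = 2^(1 / 6), seg_excl = 2) {
  pairs <- list()
  for (b in seq_len(nrow(bridge_pos))) {
    for (j in seq_len(nrow(bead_pos))) {
      r <- sqrt(sum((bridge_pos[b, ] - bead_pos[j, ])^2))
      if (r <= r_capture)
        pairs[[length(pairs) + 1]] <-
          list(bridge = b, bead = j, e = 0.5 * k_bond * (r - r0)^2 - eps)
    }
  }
  np <- length(pairs)
  stopifnot(np <= 16)
  zs <- 0; nbar <- 0
  for (mask in 0:(2^np - 1)) {
    on <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    ok <- TRUE
    for (b in unique(vapply(pairs[on], `[[`, numeric(1), "bridge"))) {
      beads <- vapply(pairs[on], `[[`, numeric(1), "bead")[
        vapply(pairs[on], `[[`, numeric(1), "bridge") == b]
      if (length(beads) > valence) { ok <- FALSE; break }
      if (length(beads) > 1 && min(diff(sort(beads))) <= seg_excl) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    w <- exp(-sum(vapply(pairs[on], `[[`, numeric(1), "e")))
    zs <- zs + w
    nbar <- nbar + length(on) * w
  }
  nbar / zs
}
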