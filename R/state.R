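# Simulation state, initialization, integration and cluster extraction.
#
# Positions are stored in reduced units (sigma = 1), wrapped into the periodic
# box; chain beads come first, bridge rows follow. Conversion to nm happens at
# the analysis surface via chain$sigma_nm.

fene_rest <- 0.97  # backbone bond rest length (FENE + WCA minimum), sigma

#' Initialize a simulation state
#'
#' Places the chain as a persistence-length-correct random walk (bond angles
#' drawn from the Kratky-Porod Boltzmann distribution, so a phantom chain
#' starts in conformational equilibrium) and scatters unbound bridge particles
#' uniformly in the periodic box. With excluded volume on, placements are
#' rejected until non-overlapping; after bounded retries the function fails
#' with a diagnostic.
#'
#' @param chain a [chain_config()].
#' @param bridges a [bridge_config()] or `NULL` for a bridge-free run.
#' @param params a [sim_params()].
#' @param excluded_volume logical; `FALSE` gives a phantom (ideal) chain.
#' @param box_sigma optional box side in sigma units; default
#'   `(n_beads / bead_density)^(1/3)`.
#' @return object of class `bips_state`: positions, velocities, empty bond
#'   registry, configs and step counter.
#' @examples
#' st <- init_state(chain_config(50), bridge_config(2), sim_params(seed = 7))
#' nrow(st$bonds)  # zero bonds at t = 0
#' @export
init_state <- function(chain, bridges = NULL, params = sim_params(),
                       excluded_volume = TRUE, box_sigma = NULL) {
  stopifnot(inherits(chain, "chain_config"),
            is.null(bridges) || inherits(bridges, "bridge_config"),
            inherits(params, "sim_params"))
  n <- chain$n_beads
  box <- if (is.null(box_sigma)) (n / params$bead_density)^(1 / 3) else box_sigma
  n_bridges <- if (is.null(bridges)) 0L else as.integer(round(bridges$density * n))

  # grow a persistent self-avoiding walk with per-step minimum-image overlap
  # checks and bounded backtracking
  walk_once <- function() {
    pos <- matrix(0, n, 3)
    tangents <- matrix(0, n, 3)
    pos[1, ] <- runif(3, 0, box)
    tangents[2, ] <- rand_unit()
    i <- 2
    backtracks <- 0
    while (i <= n) {
      ok <- FALSE
      for (try in 1:80) {
        t_new <- kp_step(tangents[i, ], chain$kappa)
        cand <- pos[i - 1, ] + fene_rest * t_new
        clash <- excluded_volume && i > 2 &&
          min_image_dist(cand, pos[seq_len(i - 2), , drop = FALSE],
                         box) < 0.92
        if (!clash) {
          pos[i, ] <- cand
          if (i < n) tangents[i + 1, ] <- t_new
          ok <- TRUE
          break
        }
      }
      if (ok) {
        i <- i + 1
      } else {
        backtracks <- backtracks + 1
        if (backtracks > 20 * n) return(NULL)
        i <- max(2, i - 10)           # unwind a stretch and regrow
        if (i == 2) tangents[2, ] <- rand_unit()
      }
    }
    pos
  }

  pos <- NULL
  for (attempt in 1:20) {
    cand <- walk_once()
    if (is.null(cand)) next
    wrapped <- cand %% box
    if (excluded_volume) {
      prs <- cpp_pairs_within(wrapped, box, 0.9)
      prs <- prs[abs(prs[, 1] - prs[, 2]) > 1, , drop = FALSE]
      if (nrow(prs) > 0) next
    }
    pos <- wrapped
    break
  }
  if (is.null(pos))
    stop("init_state: could not place a non-overlapping chain of ", n,
         " beads in a box of side ", signif(box, 4),
         " sigma; increase the box or drop the density")

  if (n_bridges > 0) {
    bp <- matrix(NA_real_, n_bridges, 3)
    for (b in seq_len(n_bridges)) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- runif(3, 0, box)
        others <- rbind(pos, bp[seq_len(b - 1), , drop = FALSE])
        if (!excluded_volume || min_image_dist(cand, others, box) > 0.95) {
          bp[b, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("init_state: could not place bridge ", b, " of ", n_bridges,
             " without overlap; box too dense")
    }
    pos <- rbind(pos, bp)
  }

  vel <- matrix(rnorm(nrow(pos) * 3), ncol = 3)  # kT = m = 1
  structure(list(
    pos = pos, vel = vel,
    bonds = matrix(integer(0), 0, 2, dimnames = list(NULL, c("bridge", "bead"))),
    n_beads = n, n_bridges = n_bridges,
    box = box, chain = chain, bridges = bridges, params = params,
    excluded_volume = isTRUE(excluded_volume), step = 0L
  ), class = "bips_state")
}

#' @export
print.bips_state <- function(x, ...) {
  cat(sprintf(
    "bips_state: %d beads + %d bridges, box %.1f sigma, %d bonds, step %d\n",
    x$n_beads, x$n_bridges, x$box, nrow(x$bonds), x$step))
  invisible(x)
}

rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

# next tangent for a discrete Kratky-Porod chain: cos(theta) from the
# Boltzmann density ~ exp(kappa cos theta), azimuth uniform
kp_step <- function(t_hat, kappa) {
  ct <- if (kappa < 1e-8) runif(1, -1, 1) else {
    u <- runif(1)
    1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  }
  st <- sqrt(max(0, 1 - ct^2))
  phi <- runif(1, 0, 2 * pi)
  a <- if (abs(t_hat[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * t_hat) * t_hat
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t_hat[2] * e1[3] - t_hat[3] * e1[2],
          t_hat[3] * e1[1] - t_hat[1] * e1[3],
          t_hat[1] * e1[2] - t_hat[2] * e1[1])
  ct * t_hat + st * (cos(phi) * e1 + sin(phi) * e2)
}

min_image_dist <- function(p, others, box) {
  if (nrow(others) == 0) return(Inf)
  d <- sweep(others, 2, p)
  d <- d - box * round(d / box)
  sqrt(min(rowSums(d^2)))
}

#' Advance the dynamics
#'
#' Runs `n_steps` of Langevin dynamics (BAOAB splitting) under the full force
#' field -- FENE backbone, Kratky-Porod bending, WCA excluded volume,
#' harmonic bead-bridge bonds -- with Metropolis binding sweeps every
#' `binding_every` steps. Randomness is drawn from R's RNG stream, so a
#' `set.seed()` before the call makes the trajectory reproducible.
#'
#' @param state a `bips_state`.
#' @param n_steps number of steps (default `params$n_steps`).
#' @param snapshot_every stride for recording snapshots (0 = none).
#' @return the advanced `bips_state`; recorded snapshots (if any) are in
#'   `attr(, "snapshots")` as a list of `list(pos, bonds, step)`.
#' @export
integrate_state <- function(state, n_steps = NULL, snapshot_every = 0) {
  stopifnot(inherits(state, "bips_state"))
  p <- state$params
  if (is.null(n_steps)) n_steps <- p$n_steps
  ff <- ff_list(state$chain, state$bridges, state$excluded_volume)
  cseed <- runif(1, 0, 2^31)
  res <- cpp_run(state$pos, state$vel, state$bonds, state$n_beads,
                 state$chain$bindable, state$box, ff,
                 p$timestep, p$friction, as.integer(n_steps),
                 if (state$n_bridges > 0) p$binding_every else 0L,
                 as.integer(snapshot_every), cseed)
  out <- state
  out$pos <- res$pos
  out$vel <- res$vel
  out$bonds <- matrix(as.integer(res$bonds), ncol = 2,
                      dimnames = list(NULL, c("bridge", "bead")))
  out$step <- state$step + as.integer(n_steps)
  if (snapshot_every > 0) {
    snaps <- Map(function(pp, bb, s) {
      list(pos = pp,
           bonds = matrix(as.integer(bb), ncol = 2,
                          dimnames = list(NULL, c("bridge", "bead"))),
           step = s)
    }, res$snap_pos, res$snap_bonds,
    state$step + snapshot_every * seq_along(res$snap_pos))
    attr(out, "snapshots") <- snaps
  }
  out
}

#' Metropolis binding update with frozen positions
#'
#' Performs pure bond-move Monte Carlo sweeps (no particle motion): each
#' bridge proposes creation of a bond to a bindable bead within the capture
#' radius or deletion of an existing bond, accepted by the Metropolis rule
#' with energy \eqn{-\epsilon} plus the harmonic bond strain per bond, with
#' proposal-count corrections so detailed balance holds. The valence cap is
#' strictly enforced.
#'
#' @param state a `bips_state`.
#' @param n_sweeps number of sweeps.
#' @param record_every if > 0, record total bond count every that many sweeps.
#' @return updated state; bond-count trace (if recorded) in
#'   `attr(, "n_bonds_trace")`.
#' @export
update_binding <- function(state, n_sweeps = 1, record_every = 0) {
  stopifnot(inherits(state, "bips_state"), state$n_bridges > 0)
  ff <- ff_list(state$chain, state$bridges, state$excluded_volume)
  cseed <- runif(1, 0, 2^31)
  res <- cpp_binding_sweeps(state$pos, state$bonds, state$n_beads,
                            state$chain$bindable, state$box, ff,
                            as.integer(n_sweeps), cseed,
                            as.integer(record_every))
  out <- state
  out$bonds <- matrix(as.integer(res$bonds), ncol = 2,
                      dimnames = list(NULL, c("bridge", "bead")))
  if (record_every > 0) attr(out, "n_bonds_trace") <- res$n_bonds_trace
  out
}

#' Run a full simulation and record a trajectory
#'
#' Seeds the RNG from `params$seed`, initializes the state and integrates,
#' recording snapshots at the `snapshot_every` stride. Identical parameters
#' (including the seed) replay bit-identically.
#'
#' @inheritParams init_state
#' @return object of class `bips_trajectory`: snapshot list plus full
#'   provenance (configs and seed).
#' @export
simulate_bips <- function(chain, bridges = NULL, params = sim_params(),
                          excluded_volume = TRUE, box_sigma = NULL) {
  set.seed(params$seed)
  st <- init_state(chain, bridges, params, excluded_volume, box_sigma)
  st <- integrate_state(st, params$n_steps, params$snapshot_every)
  snaps <- attr(st, "snapshots")
  attr(st, "snapshots") <- NULL
  steps <- vapply(snaps, `[[`, numeric(1), "step")
  stopifnot(!is.unsorted(steps, strictly = TRUE))
  structure(list(
    snapshots = snaps, final = st,
    chain = chain, bridges = bridges, params = params,
    seed = params$seed
  ), class = "bips_trajectory")
}

#' @export
print.bips_trajectory <- function(x, ...) {
  cat(sprintf(
    "bips_trajectory: %d snapshots of %d beads + %d bridges (%.1f kbp, valence %s, seed %d)\n",
    length(x$snapshots), x$final$n_beads, x$final$n_bridges,
    x$chain$length_bp / 1000,
    if (is.null(x$bridges)) "-" else x$bridges$valence, x$seed))
  invisible(x)
}

# cluster edges: explicit bridge-bead bonds plus proximity pairs involving at
# least one bridge. Bead-bead backbone proximity deliberately does not connect
# a cluster: the cluster is the bridge-occupied region, so an unbound chain
# decomposes into single particles.
cluster_edges <- function(pos, bonds, n_beads, box, r_c_sigma) {
  prox <- cpp_pairs_within(pos, box, r_c_sigma)
  if (nrow(prox) > 0)
    prox <- prox[prox[, 1] > n_beads | prox[, 2] > n_beads, , drop = FALSE]
  bond_edges <- if (nrow(bonds) > 0)
    cbind(bonds[, "bead"], n_beads + bonds[, "bridge"]) else
    matrix(integer(0), 0, 2)
  rbind(prox, bond_edges)
}

#' Largest connected cluster
#'
#' Particles (beads and bridges) are linked by registered bonds and by
#' proximity below `r_c_nm` where at least one partner is a bridge; the
#' largest connected component is returned. Deterministic for a given state.
#'
#' @param state a `bips_state` (or a trajectory snapshot together with the
#'   `chain` config via the `trajectory` interface below).
#' @param r_c_nm proximity cutoff in nm (default 1.5 bead diameters).
#' @return integer vector of particle indices (beads `1..n_beads`, bridges
#'   after).
#' @export
largest_cluster <- function(state, r_c_nm = 1.5 * state$chain$sigma_nm) {
  stopifnot(inherits(state, "bips_state"))
  edges <- cluster_edges(state$pos, state$bonds, state$n_beads, state$box,
                         r_c_nm / state$chain$sigma_nm)
  n <- nrow(state$pos)
  if (nrow(edges) == 0) return(1L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  which(comp$membership == which.max(comp$csize))
}

# unwrap a set of member particles across periodic boundaries by walking the
# cluster graph; each particle is placed at the image closest to the neighbour
# it was discovered from
unwrap_members <- function(pos, box, edges, members) {
  idx <- match(seq_len(nrow(pos)), members)
  sub <- edges[!is.na(idx[edges[, 1]]) & !is.na(idx[edges[, 2]]), , drop = FALSE]
  m <- length(members)
  adj <- vector("list", m)
  for (k in seq_len(nrow(sub))) {
    a <- idx[sub[k, 1]]; b <- idx[sub[k, 2]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- matrix(NA_real_, m, 3)
  out[1, ] <- pos[members[1], ]
  queue <- 1L
  seen <- c(TRUE, rep(FALSE, m - 1))
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (seen[nb]) next
      d <- pos[members[nb], ] - out[cur, ]
      d <- d - box * round(d / box)
      out[nb, ] <- out[cur, ] + d
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  # disconnected members (shouldn't happen for a connected cluster): keep raw
  out[!seen, ] <- pos[members[!seen], ]
  out
}

#' All bridge-containing clusters of a state
#'
#' Connected components over the same graph as [largest_cluster()], keeping
#' every component that contains at least one bridge and at least
#' `min_members` particles. This is the per-grain view of a configuration:
#' each cluster is one protein-DNA assembly.
#'
#' @inheritParams largest_cluster
#' @param min_members smallest reported cluster (default 2: a bridge plus at
#'   least one bead).
#' @return data.frame with one row per cluster: `n_members`, `n_beads`,
#'   `n_bridges`, `rg_nm`.
#' @export
bridge_clusters <- function(state, r_c_nm = 1.5 * state$chain$sigma_nm,
                            min_members = 2) {
  stopifnot(inherits(state, "bips_state"))
  edges <- cluster_edges(state$pos, state$bonds, state$n_beads, state$box,
                         r_c_nm / state$chain$sigma_nm)
  n <- nrow(state$pos)
  if (nrow(edges) == 0)
    return(data.frame(n_members = integer(0), n_beads = integer(0),
                      n_bridges = integer(0), rg_nm = numeric(0)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  rows <- lapply(which(comp$csize >= min_members), function(ci) {
    members <- which(comp$membership == ci)
    nb <- sum(members > state$n_beads)
    if (nb == 0) return(NULL)
    up <- unwrap_members(state$pos, state$box, edges, members)
    data.frame(n_members = length(members),
               n_beads = length(members) - nb, n_bridges = nb,
               rg_nm = radius_of_gyration(up) * state$chain$sigma_nm)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(n_members = integer(0), n_beads = integer(0),
                      n_bridges = integer(0), rg_nm = numeric(0)))
  do.call(rbind, rows)
}

#' Radius of gyration of the largest cluster, in nm
#'
#' @param state a `bips_state`.
#' @param r_c_nm proximity cutoff passed to [largest_cluster()].
#' @return list with `rg_nm`, `members`, `n_members`.
#' @export
cluster_rg <- function(state, r_c_nm = 1.5 * state$chain$sigma_nm) {
  members <- largest_cluster(state, r_c_nm)
  if (length(members) == 1)
    return(list(rg_nm = 0, members = members, n_members = 1L))
  edges <- cluster_edges(state$pos, state$bonds, state$n_beads, state$box,
                         r_c_nm / state$chain$sigma_nm)
  up <- unwrap_members(state$pos, state$box, edges, members)
  list(rg_nm = radius_of_gyration(up) * state$chain$sigma_nm,
       members = members, n_members = length(members))
}

#' State view of a trajectory snapshot
#'
#' @param traj a `bips_trajectory`.
#' @param i snapshot index.
#' @return a `bips_state` carrying the snapshot's positions and bonds.
#' @export
snapshot_state <- function(traj, i) {
  st <- traj$final
  st$pos <- traj$snapshots[[i]]$pos
  st$bonds <- traj$snapshots[[i]]$bonds
  st$step <- traj$snapshots[[i]]$step
  st
}

# unwrap the chain along its backbone (min-image bond vectors) and return
# bead coordinates in sigma units
unwrap_chain <- function(pos, n_beads, box) {
  p <- pos[seq_len(n_beads), , drop = FALSE]
  if (n_beads == 1) return(p)
  d <- diff(p)
  d <- d - box * round(d / box)
  cum <- rbind(0, matrix(apply(d, 2, cumsum), ncol = 3))
  sweep(cum, 2, p[1, ], `+`)
}

#' Whole-chain observables (radius of gyration, end-to-end distance)
#'
#' @param state a `bips_state`.
#' @return list with `rg_nm` and `ree_nm` for the unwrapped chain.
#' @export
chain_stats <- function(state) {
  up <- unwrap_chain(state$pos, state$n_beads, state$box)
  ree <- sqrt(sum((up[nrow(up), ] - up[1, ])^2))
  list(rg_nm = radius_of_gyration(up) * state$chain$sigma_nm,
       ree_nm = ree * state$chain$sigma_nm)
}
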