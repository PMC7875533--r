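# In-silico Hi-C: contact maps from trajectories and compartment
# (checkerboard) strength scoring.

#' Contacts of a single configuration
#'
#' Binary symmetric bead-by-bead matrix: entry (i, j) is 1 when beads i and j
#' are within the capture radius `r_c` (minimum image if `box > 0`).
#'
#' @param positions n x 3 matrix of bead coordinates (chain beads only).
#' @param r_c capture radius, same units as the coordinates.
#' @param box periodic box side (0 or negative for open boundaries).
#' @return n x n binary matrix with unit diagonal.
#' @export
snapshot_contacts <- function(positions, r_c, box = 0) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  m <- matrix(0L, n, n)
  prs <- cpp_pairs_within(positions, box, r_c)
  if (nrow(prs) > 0) {
    m[prs] <- 1L
    m[prs[, 2:1, drop = FALSE]] <- 1L
  }
  diag(m) <- 1L
  m
}

#' Aggregate contact map over a trajectory
#'
#' Mean of per-snapshot binary contact matrices over the post-equilibration
#' part of a trajectory (and over trajectories, if several are given).
#'
#' @param trajectory a `bips_trajectory` or a list of them.
#' @param r_c_nm capture radius in nm (default 2.5 bead diameters, the common
#'   polymer Hi-C convention).
#' @param discard_fraction fraction of initial snapshots dropped as burn-in.
#' @param min_snapshots fewest post-burn-in snapshots accepted (default 10;
#'   lower it only for identity checks on frozen configurations).
#' @return object of class `bips_contact_map`: `map` (frequencies in [0, 1],
#'   unit diagonal), `r_c_nm`, `n_snapshots`.
#' @export
aggregate_map <- function(trajectory, r_c_nm = NULL, discard_fraction = 0.5,
                          min_snapshots = 10) {
  trajs <- if (inherits(trajectory, "bips_trajectory")) list(trajectory)
           else trajectory
  stopifnot(all(vapply(trajs, inherits, logical(1), "bips_trajectory")))
  chain <- trajs[[1]]$chain
  if (is.null(r_c_nm)) r_c_nm <- 2.5 * chain$sigma_nm
  r_c_sigma <- r_c_nm / chain$sigma_nm
  n <- chain$n_beads
  acc <- matrix(0, n, n)
  used <- 0L
  for (tr in trajs) {
    ns <- length(tr$snapshots)
    from <- min(ns, floor(discard_fraction * ns) + 1)
    for (i in from:ns) {
      pos <- tr$snapshots[[i]]$pos[seq_len(n), , drop = FALSE]
      acc <- acc + snapshot_contacts(pos, r_c_sigma, tr$final$box)
      used <- used + 1L
    }
  }
  if (used < min_snapshots)
    stop("aggregate_map: only ", used, " post-burn-in snapshots; need at least ",
         min_snapshots)
  structure(list(map = acc / used, r_c_nm = r_c_nm, n_snapshots = used),
            class = "bips_contact_map")
}

#' @export
print.bips_contact_map <- function(x, ...) {
  cat(sprintf("bips_contact_map: %d beads, r_c = %g nm, %d snapshots\n",
              nrow(x$map), x$r_c_nm, x$n_snapshots))
  invisible(x)
}

#' @export
plot.bips_contact_map <- function(x, ...) {
  n <- nrow(x$map)
  graphics::image(seq_len(n), seq_len(n), log10(x$map + 1e-4),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "bead", ylab = "bead", ...)
  invisible(x)
}

# observed/expected normalization by mean contact frequency at each sequence
# separation
oe_normalize <- function(m) {
  n <- nrow(m)
  sep_mean <- vapply(0:(n - 1), function(s) {
    idx <- seq_len(n - s)
    mean(m[cbind(idx, idx + s)])
  }, numeric(1))
  oe <- m
  for (s in 0:(n - 1)) {
    idx <- seq_len(n - s)
    v <- if (sep_mean[s + 1] > 0) m[cbind(idx, idx + s)] / sep_mean[s + 1] else 0
    oe[cbind(idx, idx + s)] <- v
    oe[cbind(idx + s, idx)] <- v
  }
  oe
}

#' Compartment (checkerboard) strength of a contact map
#'
#' The standard A/B compartment pipeline: observed/expected normalization by
#' sequence separation, Pearson correlation matrix, leading eigenvector. Beads
#' are partitioned by eigenvector sign, and the score is the difference
#' between the mean within-block and mean between-block correlation, clipped
#' to [0, 1]. A map with no plaid structure scores ~0; a perfect two-phase
#' checkerboard approaches 1.
#'
#' @param map a `bips_contact_map` or a plain symmetric matrix.
#' @return scalar in [0, 1].
#' @export
compartment_strength <- function(map) {
  m <- if (inherits(map, "bips_contact_map")) map$map else as.matrix(map)
  n <- nrow(m)
  stopifnot(n >= 40, isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
  oe <- oe_normalize(m)
  keep <- apply(oe, 1, stats::sd) > 1e-12
  if (sum(keep) < 40) return(0)
  cc <- suppressWarnings(stats::cor(oe[keep, keep]))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)
  e1 <- ev$vectors[, 1]
  blocks <- e1 >= 0
  if (all(blocks) || !any(blocks)) return(0)
  within <- c(cc[blocks, blocks][upper.tri(cc[blocks, blocks])],
              cc[!blocks, !blocks][upper.tri(cc[!blocks, !blocks])])
  between <- cc[blocks, !blocks]
  score <- mean(within) - mean(between)
  min(1, max(0, score))
}
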