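# Cluster-size scaling analysis: radius of gyration, power-law fits of
# R_G ~ l^alpha, the two-regime (constant below / power law above l_C) fit,
# and the analytic critical looping length 2 pi^2 l_P.

#' Radius of gyration
#'
#' Root mean squared distance of a point set from its centroid, with equal
#' weights. Units follow the input coordinates.
#'
#' @param points numeric matrix (n x d) of coordinates.
#' @return scalar radius of gyration.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)))  # d/2 = 0.5
#' @export
radius_of_gyration <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("radius_of_gyration: empty point set")
  ctr <- colMeans(points)
  sqrt(mean(rowSums(sweep(points, 2, ctr)^2)))
}

#' Critical looping length
#'
#' The minimal contour length at which thermal fluctuations let a semiflexible
#' polymer bend back onto itself, \eqn{l_C = 2\pi^2 l_P}; below it no
#' bridging-induced cluster can nucleate.
#'
#' @param lp_nm persistence length in nm (50 for double-stranded DNA).
#' @param nm_per_bp contour length per base pair (0.34 nm).
#' @return list with `nm` (exact) and `bp` (rounded to the nearest base pair).
#' @examples
#' critical_looping_length(50)  # 987 nm, 2903 bp
#' @export
critical_looping_length <- function(lp_nm = 50, nm_per_bp = 0.34) {
  stopifnot(lp_nm > 0, nm_per_bp > 0)
  nm <- 2 * pi^2 * lp_nm
  list(nm = nm, bp = as.integer(round(nm / nm_per_bp)))
}

#' Fit a power law R_G ~ l^alpha
#'
#' Ordinary least squares on log10-log10 axes; the exponent is the slope and
#' its quoted uncertainty is the standard error of the slope from the fit
#' covariance.
#'
#' @param lengths DNA lengths (bp), all positive.
#' @param sizes cluster sizes (nm), all positive.
#' @return object of class `scaling_fit` with fields `alpha`, `alpha_sd`,
#'   `prefactor`, `breakpoint_bp` (NA for a plain fit), `data`.
#' @examples
#' f <- fit_power_law(c(1, 2, 4, 8) * 1e3, 2 * (c(1, 2, 4, 8) * 1e3)^0.45)
#' coef(f)["alpha"]
#' @export
fit_power_law <- function(lengths, sizes) {
  stopifnot(length(lengths) == length(sizes), length(unique(lengths)) >= 3)
  if (any(lengths <= 0) || any(sizes <= 0))
    stop("fit_power_law: lengths and sizes must be positive")
  fit <- lm(log10(sizes) ~ log10(lengths))
  sm <- suppressWarnings(summary(fit))  # exact data: 'perfect fit' warning
  structure(list(
    alpha = unname(coef(fit)[2]),
    alpha_sd = unname(sm$coefficients[2, 2]),
    prefactor = 10^unname(coef(fit)[1]),
    breakpoint_bp = NA_real_,
    constant_level = NA_real_,
    fallback = FALSE,
    data = data.frame(length_bp = lengths, size_nm = sizes)
  ), class = "scaling_fit")
}

#' Two-regime scaling fit: constant below a breakpoint, power law above
#'
#' Fits a continuous kinked model on log-log axes -- constant level below the
#' breakpoint, a power law through the same point above it -- scanning
#' candidate breakpoints at the observed lengths and keeping the one with the
#' minimum total squared residual. If no candidate leaves at least two points
#' in each regime, or the kinked model does not beat a single power law, the
#' single power law is returned with the `fallback` flag set.
#'
#' @inheritParams fit_power_law
#' @return a `scaling_fit` with `breakpoint_bp` and `constant_level` filled in.
#' @export
piecewise_scaling_fit <- function(lengths, sizes) {
  stopifnot(length(lengths) == length(sizes))
  if (any(lengths <= 0) || any(sizes <= 0))
    stop("piecewise_scaling_fit: lengths and sizes must be positive")
  ls <- sort(unique(lengths))
  lx <- log10(lengths); ly <- log10(sizes)
  single <- lm(ly ~ lx)
  rss_single <- sum(single$residuals^2)
  best <- NULL
  for (bp in ls) {
    lo <- lengths <= bp
    if (sum(lo) < 2 || length(unique(lengths[!lo])) < 2) next
    hinge <- pmax(0, lx - log10(bp))
    fit <- lm(ly ~ hinge)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(bp = bp, fit = fit, rss = rss)
  }
  if (is.null(best) || best$rss >= rss_single * (1 + 1e-9) + 1e-12) {
    out <- fit_power_law(lengths, sizes)
    out$fallback <- TRUE
    warning("piecewise_scaling_fit: no supported breakpoint; ",
            "single power law used")
    return(out)
  }
  sm <- suppressWarnings(summary(best$fit))
  cf <- coef(best$fit)
  structure(list(
    alpha = unname(cf[2]),
    alpha_sd = unname(sm$coefficients[2, 2]),
    prefactor = 10^(unname(cf[1]) - unname(cf[2]) * log10(best$bp)),
    breakpoint_bp = best$bp,
    constant_level = 10^unname(cf[1]),
    fallback = FALSE,
    data = data.frame(length_bp = lengths, size_nm = sizes)
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling fit R_G ~ l^alpha: alpha = %.3f +/- %.3f\n",
              x$alpha, x$alpha_sd))
  if (!is.na(x$breakpoint_bp))
    cat(sprintf("  breakpoint l_C ~ %.0f bp, constant level %.2f nm\n",
                x$breakpoint_bp, x$constant_level))
  if (x$fallback) cat("  (fallback: single power law, no breakpoint found)\n")
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(alpha = object$alpha, prefactor = object$prefactor,
    breakpoint_bp = object$breakpoint_bp)
}

#' @export
plot.scaling_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$length_bp, d$size_nm, log = "xy",
                 xlab = "DNA length (bp)", ylab = expression(R[G] ~ (nm)), ...)
  lx <- range(d$length_bp)
  if (!is.na(x$breakpoint_bp)) {
    graphics::segments(lx[1], x$constant_level, x$breakpoint_bp,
                       x$constant_level, col = "darkgreen", lwd = 2)
    lx[1] <- x$breakpoint_bp
  }
  xx <- exp(seq(log(lx[1]), log(lx[2]), length.out = 50))
  graphics::lines(xx, x$prefactor * xx^x$alpha, col = "red", lwd = 2)
  invisible(x)
}

# running-mean plateau test: relative drift of the running mean over the last
# third of the series below `tol`
equilibrated <- function(series, tol = 0.02) {
  n <- length(series)
  if (n < 6) return(FALSE)
  rm_ <- cumsum(series) / seq_len(n)
  tail_idx <- seq.int(floor(2 * n / 3), n)
  drift <- diff(range(rm_[tail_idx])) / abs(mean(series[tail_idx]))
  is.finite(drift) && drift < tol
}

#' Cluster-size scaling experiment
#'
#' Runs the simulator over a ladder of chain lengths at fixed bridge valence
#' and bulk concentration, measures the largest-cluster radius of gyration on
#' post-equilibration snapshots (median per run), and returns a tidy table
#' ready for [fit_power_law()] / [piecewise_scaling_fit()].
#'
#' Equilibration is declared when the running mean of the cluster R_G series
#' drifts by less than 2% over the last third of the run; the median is taken
#' over the last half of the snapshots.
#'
#' @param valence bridge valence (2, 3 or ~10); `NULL` runs bridge-free
#'   chains and measures the whole-chain R_G (control experiments).
#' @param lengths_beads integer vector of chain lengths in beads.
#' @param replicates independent runs per length (seeds derived from `seed`);
#'   a vector is recycled along `lengths_beads`, so short chains -- whose
#'   cluster sizes fluctuate most between runs -- can get more replicates at
#'   little cost.
#' @param n_steps step cap per run.
#' @param min_steps steps before the plateau test may stop a run.
#' @param chunk_steps integration chunk between plateau tests.
#' @param seed master seed.
#' @param excluded_volume logical; `FALSE` gives phantom chains.
#' @param bending logical; `FALSE` removes the bending stiffness (freely
#'   jointed control).
#' @param binding_energy epsilon in kT for the bridges.
#' @param snapshot_every snapshot stride.
#' @param bead_density chain beads per sigma^3 (sets the box).
#' @return data.frame with columns `length_beads`, `length_bp`, `replicate`,
#'   `rg_nm`, `n_members`, `steps_run`, `equilibrated`.
#' @export
scaling_experiment <- function(valence = 2,
                               lengths_beads = c(150, 220, 330, 500),
                               replicates = c(3, 3, 2, 2),
                               n_steps = 6e5, min_steps = 3e5,
                               chunk_steps = 1e5, seed = 1,
                               excluded_volume = TRUE, bending = TRUE,
                               binding_energy = 4, snapshot_every = 2e4,
                               bead_density = 0.02) {
  rows <- list()
  replicates <- rep_len(replicates, length(lengths_beads))
  for (li in seq_along(lengths_beads)) {
    n <- lengths_beads[li]
    chain <- chain_config(n, persistence_length_nm = if (bending) 50 else 0)
    br <- if (is.null(valence)) NULL else
      bridge_config(valence = valence, binding_energy = binding_energy)
    for (r in seq_len(replicates[li])) {
      params <- sim_params(n_steps = n_steps, snapshot_every = snapshot_every,
                           bead_density = bead_density,
                           seed = seed + 1000L * li + r)
      set.seed(params$seed)
      st <- init_state(chain, br, params, excluded_volume = excluded_volume)
      rgs <- numeric(0)
      nmem <- integer(0)
      eq <- FALSE
      # integrate in chunks until the cluster-size running mean plateaus
      # (relative drift < 2% over the last third) or the step cap is reached
      while (st$step < n_steps) {
        st <- integrate_state(st, min(chunk_steps, n_steps - st$step),
                              snapshot_every)
        for (sn in attr(st, "snapshots")) {
          view <- st
          view$pos <- sn$pos
          view$bonds <- sn$bonds
          if (is.null(valence)) {
            rgs <- c(rgs, chain_stats(view)$rg_nm)
            nmem <- c(nmem, n)
          } else {
            cr <- cluster_rg(view)
            rgs <- c(rgs, cr$rg_nm)
            nmem <- c(nmem, cr$n_members)
          }
        }
        attr(st, "snapshots") <- NULL
        if (st$step >= min_steps && equilibrated(rgs)) {
          eq <- TRUE
          break
        }
      }
      # post-equilibration median: the tested plateau window, or the second
      # half when the run capped out without passing the drift test
      keep <- if (eq) seq.int(floor(2 * length(rgs) / 3), length(rgs))
              else seq.int(max(1, floor(length(rgs) / 2)), length(rgs))
      rows[[length(rows) + 1]] <- data.frame(
        length_beads = n, length_bp = chain$length_bp, replicate = r,
        rg_nm = median(rgs[keep]), n_members = nmem[length(nmem)],
        steps_run = st$step, equilibrated = eq)
    }
  }
  do.call(rbind, rows)
}

#' Median cluster size per length and scaling fit
#'
#' Collapses a [scaling_experiment()] table to per-length medians and fits the
#' power law.
#'
#' @param df output of [scaling_experiment()].
#' @param piecewise use [piecewise_scaling_fit()] instead of a single power law.
#' @return a `scaling_fit`.
#' @export
fit_scaling_experiment <- function(df, piecewise = FALSE) {
  med <- stats::aggregate(rg_nm ~ length_bp, data = df, FUN = median)
  if (piecewise) piecewise_scaling_fit(med$length_bp, med$rg_nm)
  else fit_power_law(med$length_bp, med$rg_nm)
}
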