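# Photobleaching step detection: iterative single-step placement minimizing
# the residual chi-square, then backward elimination in which every step must
# beat a counter-fit (the same window refit with the step at the worst
# generic position, the window centre) by a chi-square ratio threshold.

# best single split of y[from..to]: returns list(pos, gain) where pos is the
# last index of the left part (absolute), gain the SSE reduction
best_split <- function(y, from, to) {
  m <- to - from + 1
  if (m < 2) return(NULL)
  seg <- y[from:to]
  cs <- cumsum(seg)
  tot <- cs[m]
  sse0 <- sum(seg^2) - tot^2 / m
  k <- seq_len(m - 1)
  left <- cs[k]^2 / k
  right <- (tot - cs[k])^2 / (m - k)
  sse1 <- sum(seg^2) - left - right
  i <- which.min(sse1)
  list(pos = from + i - 1, gain = sse0 - sse1[i])
}

seg_sse <- function(y, from, to) {
  if (to < from) return(0)
  seg <- y[from:to]
  sum(seg^2) - sum(seg)^2 / length(seg)
}

# chi-square ratio of a candidate step at `bp` within the window capped at
# `cap` frames per side (bounded by the neighbouring steps): counter-fit puts
# the step at the window centre instead. `noise_var` floors the fit
# chi-square at its noise expectation so that near-empty windows (typical of
# spurious step clusters) cannot produce spuriously large ratios; the floor
# is zero for noise-free traces, keeping exactness there.
step_ratio <- function(y, bp, left, right, cap = 25, eps = 1e-12,
                       noise_var = 0) {
  a <- max(left + 1, bp - cap + 1)
  b <- min(right, bp + cap)
  nw <- b - a + 1
  chi_fit <- max(seg_sse(y, a, bp) + seg_sse(y, bp + 1, b),
                 noise_var * max(nw - 2, 1))
  # counter step at the midpoint of the longer side: the worst generic
  # placement that cannot coincide with (or sit next to) the tested step
  ctr <- if (bp - a + 1 >= b - bp) floor((a - 1 + bp) / 2)
         else floor((bp + b) / 2)
  # window too small to place a counter: no supporting evidence
  if (ctr < a || ctr >= b || ctr == bp) return(1)
  chi_counter <- seg_sse(y, a, ctr) + seg_sse(y, ctr + 1, b)
  if (chi_fit < eps) return(if (chi_counter < eps) 1 else Inf)
  chi_counter / chi_fit
}

# optimal placement of exactly k breakpoints (minimum-SSE piecewise-constant
# fit) by dynamic programming; O(k n^2), used for small n only
dp_refine <- function(y, k) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  cost <- matrix(Inf, n, k + 1)
  back <- matrix(0L, n, k + 1)
  j <- seq_len(n)
  cost[, 1] <- (cs2[j + 1] - cs2[1]) - (cs[j + 1] - cs[1])^2 / j
  for (m in 2:(k + 1)) {
    for (jj in m:n) {
      i <- (m - 1):(jj - 1)
      v <- cost[i, m - 1] + (cs2[jj + 1] - cs2[i + 1]) -
        (cs[jj + 1] - cs[i + 1])^2 / (jj - i)
      best <- which.min(v)
      cost[jj, m] <- v[best]
      back[jj, m] <- i[best]
    }
  }
  bps <- integer(k)
  jj <- n
  for (m in (k + 1):2) {
    jj <- back[jj, m]
    bps[m - 1] <- jj
  }
  bps
}

#' Find intensity steps in a photobleaching trace
#'
#' Change-point detection in two passes. Steps are first placed one at a time,
#' each at the position that most reduces the residual chi-square of a
#' piecewise-constant fit. Candidate steps are then eliminated backwards:
#' within a window around each step (reaching to the neighbouring steps, at
#' most `window` frames per side), the step fit must beat a counter-fit with
#' the step at the window centre by a chi-square ratio above `threshold`;
#' the weakest step is removed and the survivors re-tested until all pass.
#' Zero steps is a valid result.
#'
#' @param trace an [intensity_trace()] with at least 10 points.
#' @param max_steps largest step count considered.
#' @param threshold counter-fit/fit chi-square acceptance ratio.
#' @param window cap on the test window, frames per side.
#' @param remove_spikes drop adjacent opposite-sign step pairs bracketing a
#'   plateau of at most `spike_max` frames (fluorophore blinks).
#' @param spike_max longest plateau treated as a transient spike, frames.
#' @return object of class `step_train`: `step_times` (s), `step_sizes`
#'   (a.u., negative for downward steps), `levels` (plateau means; one more
#'   than the number of steps), `breakpoints` (sample indices).
#' @examples
#' tr <- gen_bleach_staircase(3, noise_sd = 0, seed = 2)$trace
#' find_steps(tr)$step_times
#' @export
find_steps <- function(trace, max_steps = NULL, threshold = 1.5,
                       window = 25, remove_spikes = TRUE, spike_max = 5) {
  y <- trace$intensity
  t <- trace$time
  n <- length(y)
  if (n < 10) stop("find_steps: trace must have at least 10 points")
  if (is.null(max_steps)) max_steps <- max(1, min(50, floor(n / 4)))
  eps <- max(1e-12, 1e-10 * stats::var(y))

  # pass 1: greedy insertion
  bps <- integer(0)
  for (k in seq_len(max_steps)) {
    bounds <- c(0, bps, n)
    best <- NULL
    for (i in seq_len(length(bounds) - 1)) {
      sp <- best_split(y, bounds[i] + 1, bounds[i + 1])
      if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) best <- sp
    }
    if (is.null(best) || best$gain <= eps) break
    bps <- sort(c(bps, best$pos))
  }

  # pass 2: backward elimination against the counter-fit; robust noise scale
  # from first differences (insensitive to the steps themselves)
  noise_var <- (median(abs(diff(y))) / 0.6745)^2 / 2
  repeat {
    if (length(bps) == 0) break
    bounds <- c(0, bps, n)
    ratios <- vapply(seq_along(bps), function(i)
      step_ratio(y, bps[i], bounds[i], bounds[i + 2], cap = window,
                 eps = eps, noise_var = noise_var), numeric(1))
    if (min(ratios) <= threshold) {
      bps <- bps[-which.min(ratios)]
      next
    }
    if (!remove_spikes || length(bps) < 2) break
    # transient spikes: adjacent opposite-sign steps bracketing a plateau of
    # at most `spike_max` frames are blinks, not bleaching steps
    bounds <- c(0, bps, n)
    lv <- vapply(seq_len(length(bounds) - 1), function(i)
      mean(y[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    sizes <- diff(lv)
    spike <- which(sign(sizes[-length(sizes)]) * sign(sizes[-1]) < 0 &
                     diff(bps) <= spike_max)
    if (length(spike) == 0) break
    bps <- bps[-c(spike[1], spike[1] + 1)]
  }

  # exact placement: on short traces, re-place the selected number of steps
  # by dynamic programming (globally optimal piecewise-constant fit)
  if (length(bps) > 0 && n <= 400) bps <- dp_refine(y, length(bps))

  if (length(bps) == 0) {
    return(structure(list(step_times = numeric(0), step_sizes = numeric(0),
                          levels = mean(y), breakpoints = integer(0),
                          trace = trace),
                     class = "step_train"))
  }
  bounds <- c(0, bps, n)
  levels <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(y[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  structure(list(
    step_times = (t[bps] + t[bps + 1]) / 2,
    step_sizes = diff(levels),
    levels = levels,
    breakpoints = bps,
    trace = trace
  ), class = "step_train")
}

#' @export
print.step_train <- function(x, ...) {
  cat(sprintf("step_train: %d steps, %d plateaus\n",
              length(x$step_sizes), length(x$levels)))
  if (length(x$step_sizes) > 0) {
    cat("  times (s):", paste(signif(x$step_times, 4), collapse = ", "), "\n")
    cat("  sizes    :", paste(signif(x$step_sizes, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.step_train <- function(x, ...) {
  graphics::plot(x$trace$time, x$trace$intensity, type = "l", col = "grey60",
                 xlab = "time (s)", ylab = "intensity (a.u.)", ...)
  bounds <- c(1, x$breakpoints, nrow(x$trace))
  for (i in seq_along(x$levels)) {
    graphics::segments(x$trace$time[bounds[i]], x$levels[i],
                       x$trace$time[bounds[i + 1]], x$levels[i],
                       col = "red", lwd = 2)
  }
  invisible(x)
}
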