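# Seeded generators for fluorescence time series: compaction kymographs,
# photobleaching staircases and exponential recovery/decay traces. Every
# generator returns the full ground truth used to build the data, so each
# matched estimator can be scored without further information.
#
# Noise is additive Gaussian throughout (camera statistics are not modelled).

#' Synthetic compaction kymograph
#'
#' Emulates a doubly tethered DNA with a growing compaction spot: a uniform
#' DNA signal plus a localized Gaussian spot whose integrated excess intensity
#' ramps linearly from 0 to `plateau_kbp / total_kbp` of the total during
#' `[t_start, t_start + duration]`, then plateaus. Total integrated intensity
#' is conserved per frame: DNA moves into the spot, it is not created.
#'
#' @param total_kbp DNA length represented by the full signal (48.5 for
#'   lambda DNA).
#' @param t_start compaction onset, s.
#' @param duration linear ramp duration, s (the 5-95% compaction time of the
#'   noiseless ramp is `0.9 * duration`; about 30 s emulates the measured
#'   kinetics).
#' @param plateau_kbp DNA amount in the cluster at the plateau (20 kbp is the
#'   typical measured cluster).
#' @param noise_sd additive Gaussian noise per pixel, a.u.
#' @param frame_interval s per frame.
#' @param n_positions pixels along the DNA axis.
#' @param n_frames frames; default covers onset, ramp and a plateau tail.
#' @param seed RNG seed; same seed, bit-identical output.
#' @return list with `kymo` (a [kymograph()]), `roi_trace` and `total_trace`
#'   ([intensity_trace()], background-subtracted), and `truth`.
#' @export
gen_compaction_kymograph <- function(total_kbp = 48.5, t_start = 10,
                                     duration = 30, plateau_kbp = 20,
                                     noise_sd = 0.02, frame_interval = 0.1,
                                     n_positions = 100, n_frames = NULL,
                                     seed = 1) {
  if (!(plateau_kbp > 0 && plateau_kbp <= total_kbp))
    stop("gen_compaction_kymograph: need 0 < plateau_kbp <= total_kbp")
  stopifnot(duration > 0)
  set.seed(seed)
  if (is.null(n_frames))
    n_frames <- ceiling((t_start + duration + max(10, 0.5 * duration)) /
                          frame_interval)
  time <- seq_len(n_frames) * frame_interval
  dna_px <- seq.int(floor(0.1 * n_positions) + 1, ceiling(0.9 * n_positions))
  n_dna <- length(dna_px)
  total_I <- n_dna                          # 1 a.u. per DNA pixel when uncompacted
  f_max <- plateau_kbp / total_kbp
  frac <- f_max * pmin(1, pmax(0, (time - t_start) / duration))

  spot_centre <- dna_px[floor(n_dna / 2)]
  spot_sd <- 1.5                            # pixels
  spot_profile <- exp(-(seq_len(n_positions) - spot_centre)^2 / (2 * spot_sd^2))
  spot_profile <- spot_profile / sum(spot_profile)

  mat <- matrix(0, n_positions, n_frames)
  for (f in seq_len(n_frames)) {
    mat[dna_px, f] <- (1 - frac[f]) * total_I / n_dna
    mat[, f] <- mat[, f] + frac[f] * total_I * spot_profile
  }
  clean <- mat
  if (noise_sd > 0) mat <- mat + matrix(rnorm(length(mat), 0, noise_sd),
                                        nrow = n_positions)

  roi <- which(abs(seq_len(n_positions) - spot_centre) <= 6 * spot_sd)
  bg_px <- setdiff(dna_px, roi)
  roi_raw <- colSums(mat[roi, , drop = FALSE])
  bg_per_px <- apply(mat[bg_px, , drop = FALSE], 2, median)
  roi_excess <- roi_raw - bg_per_px * length(roi)
  total_raw <- colSums(mat[dna_px, , drop = FALSE])

  list(
    kymo = kymograph(mat, frame_interval, 0.1, background = "none (synthetic)"),
    roi_trace = intensity_trace(time, roi_excess),
    total_trace = intensity_trace(time, total_raw),
    truth = list(total_kbp = total_kbp, t_start = t_start, duration = duration,
                 plateau_kbp = plateau_kbp, noise_sd = noise_sd,
                 frame_interval = frame_interval, n_positions = n_positions,
                 n_frames = n_frames, seed = seed,
                 compaction_time_5_95 = 0.9 * duration,
                 spot_centre_px = spot_centre,
                 clean_kymo = clean)
  )
}

#' Synthetic photobleaching staircase
#'
#' Piecewise-constant decreasing trace: `n_steps` downward steps of size
#' `step_size` with exponentially distributed dwell times (memoryless
#' single-fluorophore bleaching), ending at the baseline.
#'
#' @param n_steps number of bleaching steps (>= 1).
#' @param step_size intensity drop per step, a.u. (3.0 emulates the measured
#'   single-complex step).
#' @param mean_dwell mean plateau duration, s (default 30, tens of seconds
#'   per fluorophore at low excitation power).
#' @param noise_sd additive Gaussian noise, a.u.
#' @param frame_interval sampling interval, s.
#' @param baseline final level, a.u.
#' @param seed RNG seed.
#' @return list with `trace` ([intensity_trace()]) and `truth` (true step
#'   times, sizes, levels).
#' @export
gen_bleach_staircase <- function(n_steps, step_size = 3, mean_dwell = 30,
                                 noise_sd = 0, frame_interval = 0.1,
                                 baseline = 0, seed = 1) {
  stopifnot(n_steps >= 1, step_size > 0, mean_dwell > 0)
  set.seed(seed)
  dwells <- rexp(n_steps, rate = 1 / mean_dwell)
  step_times <- cumsum(dwells)
  t_end <- step_times[n_steps] + mean_dwell
  time <- seq(frame_interval, t_end, by = frame_interval)
  level0 <- baseline + n_steps * step_size
  intensity <- level0 - step_size *
    vapply(time, function(tt) sum(step_times <= tt), numeric(1))
  if (noise_sd > 0) intensity <- intensity + rnorm(length(time), 0, noise_sd)
  list(
    trace = intensity_trace(time, intensity),
    truth = list(n_steps = n_steps, step_size = step_size,
                 step_times = step_times, mean_dwell = mean_dwell,
                 noise_sd = noise_sd, baseline = baseline,
                 frame_interval = frame_interval, seed = seed)
  )
}

#' Synthetic exponential recovery or decay trace
#'
#' FRAP recovery `baseline + amplitude * (1 - exp(-t/tau))` or dissociation
#' decay `baseline + amplitude * exp(-t/tau)`, with additive Gaussian noise.
#'
#' @param kind `"recovery"` or `"decay"`.
#' @param tau time constant, s (> 0).
#' @param amplitude signal amplitude, a.u.
#' @param baseline offset, a.u.
#' @param noise_sd additive Gaussian noise, a.u.
#' @param frame_interval sampling interval, s.
#' @param n_frames number of samples; default spans 5 tau.
#' @param seed RNG seed.
#' @return list with `trace` and `truth`.
#' @export
gen_exponential_trace <- function(kind = c("recovery", "decay"), tau,
                                  amplitude = 1, baseline = 0, noise_sd = 0,
                                  frame_interval = NULL, n_frames = NULL,
                                  seed = 1) {
  kind <- match.arg(kind)
  stopifnot(tau > 0)
  set.seed(seed)
  if (is.null(frame_interval)) frame_interval <- tau / 20
  if (is.null(n_frames)) n_frames <- ceiling(5 * tau / frame_interval)
  time <- seq_len(n_frames) * frame_interval
  t0 <- time - time[1]
  intensity <- if (kind == "decay")
    baseline + amplitude * exp(-t0 / tau) else
    baseline + amplitude * (1 - exp(-t0 / tau))
  if (noise_sd > 0) intensity <- intensity + rnorm(n_frames, 0, noise_sd)
  list(
    trace = intensity_trace(time, intensity),
    truth = list(kind = kind, tau = tau, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd,
                 frame_interval = frame_interval, n_frames = n_frames,
                 seed = seed)
  )
}
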