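# Fluorescence time-series containers and the compaction/cluster-size
# operators: kymograph construction, DNA amount in a cluster (kbp), and the
# 5-95% compaction time on a Savitzky-Golay smoothed trace.

#' Intensity trace container
#'
#' @param time time stamps in seconds (strictly increasing).
#' @param intensity background-subtracted intensity, arbitrary units.
#' @return data.frame of class `intensity_trace`.
#' @export
intensity_trace <- function(time, intensity) {
  stopifnot(length(time) == length(intensity), !is.unsorted(time, strictly = TRUE))
  structure(data.frame(time = time, intensity = intensity),
            class = c("intensity_trace", "data.frame"))
}

#' Kymograph container
#'
#' @param mat position x time matrix of intensities.
#' @param frame_interval seconds between frames (columns).
#' @param pixel_size micrometres per position row.
#' @param background note on how background was removed.
#' @return object of class `bips_kymograph`.
#' @export
kymograph <- function(mat, frame_interval, pixel_size,
                      background = "none") {
  stopifnot(is.matrix(mat), frame_interval > 0, pixel_size > 0)
  structure(list(mat = mat, frame_interval = frame_interval,
                 pixel_size = pixel_size, background = background),
            class = "bips_kymograph")
}

#' @export
print.bips_kymograph <- function(x, ...) {
  cat(sprintf(
    "bips_kymograph: %d positions x %d frames (%.3g um/px, %.3g s/frame, background: %s)\n",
    nrow(x$mat), ncol(x$mat), x$pixel_size, x$frame_interval, x$background))
  invisible(x)
}

#' @export
plot.bips_kymograph <- function(x, ...) {
  graphics::image(seq_len(ncol(x$mat)) * x$frame_interval,
                  seq_len(nrow(x$mat)) * x$pixel_size, t(x$mat),
                  xlab = "time (s)", ylab = "position (um)",
                  col = grDevices::hcl.colors(64, "Viridis"), ...)
  invisible(x)
}

# bilinear sampling of a matrix at fractional (row, col) coordinates
bilinear <- function(m, r, c) {
  r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
  r0 <- pmin(floor(r), nrow(m) - 1); c0 <- pmin(floor(c), ncol(m) - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc + m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# 2-D median smoothing (kernel k x k) used as the background estimate
median_background <- function(m, k = 21) {
  rng <- range(m)
  if (diff(rng) < 1e-12) return(m)
  scaled <- (m - rng[1]) / diff(rng)
  bg <- EBImage::medianFilter(scaled, size = (k - 1) %/% 2)
  as.matrix(bg) * diff(rng) + rng[1]
}

#' Build a kymograph from an image stack
#'
#' For every frame, intensities are summed over a `2 * half_width + 1` pixel
#' span perpendicular to the given line (11 pixels at the default), at unit
#' spacing along the line. Background is removed by subtracting a 2-D
#' median-smoothed copy of the raw kymograph (21 x 21 kernel), and each frame
#' is normalized by its maximum (frames that are all zero are left at zero).
#'
#' @param image_stack 3-D array (rows x cols x frames) or list of matrices.
#' @param line 2 x 2 matrix: endpoints of the line in pixel coordinates
#'   (row, col).
#' @param half_width half the perpendicular summation span in pixels.
#' @param frame_interval seconds per frame.
#' @param pixel_size micrometres per pixel.
#' @param normalize per-frame max normalization (default TRUE).
#' @return a [kymograph()].
#' @export
build_kymograph <- function(image_stack, line, half_width = 5,
                            frame_interval = 1, pixel_size = 0.1,
                            normalize = TRUE) {
  if (is.list(image_stack))
    image_stack <- array(unlist(image_stack),
                         dim = c(dim(image_stack[[1]]), length(image_stack)))
  stopifnot(length(dim(image_stack)) == 3, is.matrix(line), all(dim(line) == 2))
  d <- dim(image_stack)
  if (any(line[, 1] < 1 | line[, 1] > d[1] | line[, 2] < 1 | line[, 2] > d[2]))
    stop("build_kymograph: line endpoints outside the image")
  v <- line[2, ] - line[1, ]
  len <- sqrt(sum(v^2))
  if (len < 1) stop("build_kymograph: degenerate line")
  u <- v / len                      # along the line
  p <- c(-u[2], u[1])               # perpendicular
  n_pos <- floor(len) + 1
  offs <- seq(-half_width, half_width)
  raw <- matrix(0, n_pos, d[3])
  for (f in seq_len(d[3])) {
    fr <- image_stack[, , f]
    for (i in seq_len(n_pos)) {
      base <- line[1, ] + (i - 1) * u
      rr <- base[1] + offs * p[1]
      cc <- base[2] + offs * p[2]
      raw[i, f] <- sum(bilinear(fr, rr, cc))
    }
  }
  bg <- median_background(raw, 21)
  sub <- raw - bg
  if (normalize) {
    mx <- apply(sub, 2, max)
    ok <- mx > 1e-12
    sub[, ok] <- sweep(sub[, ok, drop = FALSE], 2, mx[ok], "/")
    sub[, !ok] <- 0
  }
  kymograph(sub, frame_interval, pixel_size,
            background = "2-D median smoothing (21x21) subtracted")
}

#' DNA amount in a cluster, in kbp
#'
#' Converts background-subtracted intensities to kilobase pairs by
#' normalizing the cluster region-of-interest intensity with the intensity of
#' the entire DNA and multiplying by the genome length (48.5 kbp for lambda
#' DNA).
#'
#' @param roi_trace [intensity_trace()] of the cluster region (background
#'   subtracted).
#' @param total_trace [intensity_trace()] of the whole DNA, time-aligned.
#' @param genome_kbp DNA length represented by the total intensity.
#' @return an `intensity_trace` whose `intensity` column is kbp; frames where
#'   the total is not positive are masked `NA` with a warning.
#' @export
cluster_size_kbp <- function(roi_trace, total_trace, genome_kbp = 48.5) {
  stopifnot(nrow(roi_trace) == nrow(total_trace),
            isTRUE(all.equal(roi_trace$time, total_trace$time)))
  tot <- total_trace$intensity
  bad <- !(tot > 0)
  if (any(bad)) {
    warning("cluster_size_kbp: ", sum(bad),
            " frames with non-positive total intensity masked")
    tot[bad] <- NA_real_
  }
  intensity_trace(roi_trace$time, roi_trace$intensity / tot * genome_kbp)
}

#' Compaction time (5-95%) of a compaction trace
#'
#' Smooths the trace with a Savitzky-Golay filter (order 2, window 250 frames
#' by default, shrunk to the nearest valid odd size when the trace is short),
#' then reports the time between the first crossing of 5% and the first
#' subsequent crossing of 95% of the plateau-minus-baseline amplitude.
#' Baseline is the mean of the first 5% of the smoothed trace; the plateau is
#' the mean of the final 20%. A drift of the final fifth exceeding 20% of the
#' amplitude fails the plateau test and raises an error.
#'
#' @param trace an [intensity_trace()] (typically in kbp).
#' @param savgol_window moving window, frames; values below 3 skip smoothing.
#' @param savgol_order polynomial order.
#' @return compaction time in seconds.
#' @export
compaction_time <- function(trace, savgol_window = 250, savgol_order = 2) {
  y <- trace$intensity
  t <- trace$time
  n <- length(y)
  if (n < 10) stop("compaction_time: trace too short")
  w <- min(savgol_window, n - (1 - n %% 2))
  if (w %% 2 == 0) w <- w - 1
  s <- if (w >= savgol_order + 2 && w >= 3)
    signal::sgolayfilt(y, p = savgol_order, n = w) else y
  baseline <- mean(s[seq_len(max(1, floor(0.05 * n)))])
  plateau_idx <- seq.int(floor(0.8 * n) + 1, n)
  plateau <- mean(s[plateau_idx])
  amp <- plateau - baseline
  if (!(amp > 0)) stop("compaction_time: no rise above baseline")
  drift <- diff(range(s[plateau_idx]))
  if (drift > 0.2 * amp)
    stop("compaction_time: no stable plateau (drift ",
         signif(drift / amp * 100, 3), "% of amplitude)")
  lo <- baseline + 0.05 * amp
  hi <- baseline + 0.95 * amp
  i5 <- which(s >= lo)[1]
  if (is.na(i5)) stop("compaction_time: 5% level never crossed")
  i95 <- which(s[seq.int(i5, n)] >= hi)[1]
  if (is.na(i95)) stop("compaction_time: 95% level never crossed")
  t[i5 + i95 - 1] - t[i5]
}

#' Number of complexes from intensity
#'
#' Divides a cluster intensity by the unit intensity of a single complex (the
#' mean photobleaching step size). When standard deviations are supplied the
#' uncertainty is propagated in quadrature.
#'
#' @param cluster_intensity total cluster intensity, a.u.
#' @param unit_step single-complex intensity, a.u. (> 0).
#' @param cluster_sd,unit_sd optional standard deviations.
#' @return estimated count; propagated SD in `attr(, "sd")` when available.
#' @export
count_complexes <- function(cluster_intensity, unit_step,
                            cluster_sd = NULL, unit_sd = NULL) {
  if (!(unit_step > 0)) stop("count_complexes: unit_step must be positive")
  n <- cluster_intensity / unit_step
  if (!is.null(cluster_sd) || !is.null(unit_sd)) {
    rel2 <- 0
    if (!is.null(cluster_sd) && cluster_intensity != 0)
      rel2 <- rel2 + (cluster_sd / cluster_intensity)^2
    if (!is.null(unit_sd)) rel2 <- rel2 + (unit_sd / unit_step)^2
    attr(n, "sd") <- abs(n) * sqrt(rel2)
  }
  n
}
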