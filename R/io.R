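# External interfaces: traces as two-column TSV, images/kymographs/height
# maps as TIFF with a JSON sidecar carrying physical metadata, ground truth
# and seeds; contact maps as dense TSV.

#' Write / read an intensity trace as TSV
#'
#' Two tab-separated columns, `time_s` and `intensity`.
#'
#' @param trace an [intensity_trace()].
#' @param path file path.
#' @return `read_trace` returns an `intensity_trace`.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time, intensity = trace$intensity)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  intensity_trace(df$time_s, df$intensity)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a matrix-backed image as TIFF with JSON sidecar
#'
#' Intensities are rescaled to [0, 1] for 32-bit float TIFF storage; the
#' original range, pixel size, frame interval, seed and any ground truth are
#' kept in `<path>.json` and restored on read.
#'
#' @param mat numeric matrix.
#' @param path TIFF path (sidecar written next to it).
#' @param meta named list of metadata (pixel sizes, frame interval, truth,
#'   seed, ...).
#' @return `read_image_tiff` returns `list(mat, meta)`.
#' @export
write_image_tiff <- function(mat, path, meta = list()) {
  rng <- range(mat)
  scaled <- if (diff(rng) > 0) (mat - rng[1]) / diff(rng) else mat * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  meta$scale_min <- rng[1]
  meta$scale_max <- rng[2]
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             sidecar_path(path))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  scaled <- tiff::readTIFF(path)
  meta <- jsonlite::fromJSON(readLines(sidecar_path(path), warn = FALSE))
  rng <- c(meta$scale_min, meta$scale_max)
  mat <- if (diff(rng) > 0) scaled * diff(rng) + rng[1] else scaled
  list(mat = mat, meta = meta)
}

#' Write a contact map as dense TSV with a JSON header file
#'
#' @param map a `bips_contact_map`.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(inherits(map, "bips_contact_map"))
  write.table(map$map, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(jsonlite::toJSON(list(r_c_nm = map$r_c_nm,
                                   n_snapshots = map$n_snapshots,
                                   n_beads = nrow(map$map)),
                              auto_unbox = TRUE),
             sidecar_path(path))
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  meta <- jsonlite::fromJSON(readLines(sidecar_path(path), warn = FALSE))
  structure(list(map = m, r_c_nm = meta$r_c_nm,
                 n_snapshots = meta$n_snapshots),
            class = "bips_contact_map")
}

#' Write a trajectory as extended XYZ plus a bond edge-list TSV
#'
#' Each frame's comment line carries the step, box side (nm) and seed; bead
#' rows are typed `D` (DNA) and `B` (bridge). Bonds go to `<path>.bonds.tsv`
#' as (frame, bridge, bead).
#'
#' @param traj a `bips_trajectory`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "bips_trajectory"))
  sig <- traj$chain$sigma_nm
  con <- file(path, "w")
  on.exit(close(con))
  bond_rows <- list()
  for (k in seq_along(traj$snapshots)) {
    sn <- traj$snapshots[[k]]
    n <- nrow(sn$pos)
    writeLines(as.character(n), con)
    writeLines(sprintf("step=%d box_nm=%.6g seed=%d", sn$step,
                       traj$final$box * sig, traj$seed), con)
    typ <- c(rep("D", traj$final$n_beads), rep("B", traj$final$n_bridges))
    writeLines(sprintf("%s %.6f %.6f %.6f", typ, sn$pos[, 1] * sig,
                       sn$pos[, 2] * sig, sn$pos[, 3] * sig), con)
    if (nrow(sn$bonds) > 0)
      bond_rows[[length(bond_rows) + 1]] <-
        data.frame(frame = k, bridge = sn$bonds[, 1], bead = sn$bonds[, 2])
  }
  bonds <- if (length(bond_rows) > 0) do.call(rbind, bond_rows) else
    data.frame(frame = integer(0), bridge = integer(0), bead = integer(0))
  write.table(bonds, paste0(path, ".bonds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
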