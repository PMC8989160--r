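# On-disk formats: depth stacks as 16-bit grayscale TIFF (0.1 mm per
# integer step, 0 = invalid) plus a meta.json sidecar; truth, signal and
# breath tables as CSV/JSON.

DEPTH_SCALE_MM <- 0.1
DEPTH_MAX_MM <- 65535 * DEPTH_SCALE_MM

#' Write a depth sequence to a directory
#'
#' One zero-padded 16-bit grayscale TIFF per frame (integer value =
#' depth / 0.1 mm; 0 marks an invalid pixel) plus `meta.json` with the
#' intrinsics, frame rate, timestamps, depth scale and invalid value.
#'
#' @param seq `depth_sequence`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_depth_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "depth_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_frames <- dim(seq$frames)[3]
  fin <- seq$frames[is.finite(seq$frames)]
  if (length(fin) && max(fin) >= DEPTH_MAX_MM)
    stop(sprintf("depth exceeds the %.1f mm range of the 16-bit format",
                 DEPTH_MAX_MM))
  for (i in seq_len(n_frames)) {
    img <- seq$frames[, , i]
    q <- round(img / DEPTH_SCALE_MM)
    q[!is.finite(q)] <- 0
    tiff::writeTIFF(q / 65535, file.path(dir, sprintf("frame_%06d.tif", i)),
                    bits.per.sample = 16L)
  }
  K <- seq$intrinsics
  meta <- list(format = "depth-tiff16", n_frames = n_frames,
               width = K$width, height = K$height,
               fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
               fps = seq$fps, timestamps = seq$timestamps,
               depth_scale_mm = DEPTH_SCALE_MM, invalid_value = 0)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a depth sequence from a directory
#'
#' @param dir directory written by [write_depth_sequence()]
#' @return `depth_sequence`
#' @export
read_depth_sequence <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path))
    stop(sprintf("input-format error: missing sidecar file '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  K <- camera_intrinsics(meta$fx, meta$fy, meta$cx, meta$cy,
                         meta$width, meta$height)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$",
                           full.names = TRUE))
  if (length(files) != meta$n_frames)
    stop(sprintf("input-format error: %d frame files, meta.json says %d",
                 length(files), meta$n_frames))
  frames <- array(NA_real_, dim = c(meta$height, meta$width, length(files)))
  for (i in seq_along(files)) {
    q <- round(tiff::readTIFF(files[i]) * 65535)
    img <- q * meta$depth_scale_mm
    img[q == meta$invalid_value] <- NA_real_
    frames[, , i] <- img
  }
  depth_sequence(frames, meta$timestamps, K, meta$fps)
}

#' Write phantom ground truth
#'
#' `truth.csv` holds the per-frame analytic membrane displacements;
#' `truth.json` the scalar summary (commanded amplitudes, rate, phase,
#' seed pixels).
#'
#' @param truth `phantom_truth` from [generate_phantom()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_phantom_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(frame = seq_along(truth$t_s), t = truth$t_s,
               rc_true = truth$rc_signal, ab_true = truth$ab_signal),
    file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(true_amp_rc = truth$true_amp_rc, true_amp_ab = truth$true_amp_ab,
         true_rr = truth$true_rr, true_phase = truth$true_phase,
         roi_seed_rc = truth$roi_seed_rc, roi_seed_ab = truth$roi_seed_ab,
         short_recording = truth$short_recording),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a ribcage/abdomen signal pair as CSV
#'
#' Columns: `frame`, `t_s`, `rc_mm`, `ab_mm`, `rc_interp`, `ab_interp`.
#'
#' @param rc_sig,ab_sig `breathing_signal` objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_signals_csv <- function(rc_sig, ab_sig, path) {
  stopifnot(length(rc_sig$values) == length(ab_sig$values),
            rc_sig$fs == ab_sig$fs)
  n <- length(rc_sig$values)
  utils::write.csv(
    data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / rc_sig$fs,
               rc_mm = rc_sig$values, ab_mm = ab_sig$values,
               rc_interp = rc_sig$interpolated_mask,
               ab_interp = ab_sig$interpolated_mask),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a signal-pair CSV
#'
#' @param path file written by [write_signals_csv()]
#' @param fs sampling rate (Hz); inferred from the `t_s` column when `NULL`
#' @return list with `rc` and `ab` [breathing_signal()] objects
#' @export
read_signals_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t_s))
  list(rc = breathing_signal(df$rc_mm, fs, df$rc_interp, source = "rc"),
       ab = breathing_signal(df$ab_mm, fs, df$ab_interp, source = "ab"))
}

#' Write a breath table as CSV
#'
#' Columns: `breath_id`, `t_start_s`, `rr_bpm` (ribcage-based),
#' `a_rc_mm`, `a_ab_mm`, `theta_deg`. Compartments are segmented
#' independently, so abdominal values are aligned by breath order and
#' padded with `NA` when the counts differ.
#'
#' @param bt `breath_table` from [analyze_pair()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_breaths_csv <- function(bt, path) {
  stopifnot(inherits(bt, "breath_table"))
  n <- nrow(bt$rc)
  pad <- function(x) c(x, rep(NA_real_, max(0, n - length(x))))[seq_len(n)]
  utils::write.csv(
    data.frame(breath_id = seq_len(n), t_start_s = bt$rc$t_start_s,
               rr_bpm = bt$rc$rr, a_rc_mm = bt$rc$a,
               a_ab_mm = pad(bt$ab$a), theta_deg = bt$theta$theta),
    path, row.names = FALSE)
  invisible(path)
}
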