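# Breathing-signal extraction: fixed frame-1 ROI tracking, reference-frame
# displacement, outlier/missing handling, smoothing, dual-camera fusion.

#' Breathing signal container
#'
#' @param values per-frame displacement (mm), non-negative
#' @param fs sampling rate (Hz)
#' @param interpolated_mask logical vector marking samples replaced by
#'   interpolation (missing frames or outliers)
#' @param source camera label, or `"fused"`
#' @return object of class `breathing_signal`
#' @export
breathing_signal <- function(values, fs,
                             interpolated_mask = rep(FALSE, length(values)),
                             source = "cam") {
  stopifnot(fs > 0, length(values) == length(interpolated_mask),
            all(is.finite(values)), all(values >= 0))
  structure(list(values = as.numeric(values), fs = fs,
                 interpolated_mask = as.logical(interpolated_mask),
                 source = source),
            class = "breathing_signal")
}

#' @export
print.breathing_signal <- function(x, ...) {
  cat(sprintf(
    "<breathing_signal> %d samples @ %.3g Hz (%s), %.1f%% interpolated\n",
    length(x$values), x$fs, x$source, 100 * mean(x$interpolated_mask)))
  invisible(x)
}

#' Track the frame-1 ROI through a depth sequence
#'
#' Builds the ROI model (sphere seed, regression plane, normal-axis
#' cylinder) on the first frame and applies it unchanged to every frame,
#' computing the ROI centroid and its camera distance P(i). Frames whose
#' cylinder is empty yield missing markers (`NA`).
#'
#' @param seq `depth_sequence`
#' @param spec `roi_spec`
#' @return list with `centroids` (T x 3, mm), `distances` (length-T P(i),
#'   mm) and the frame-1 `model`
#' @export
extract_raw_series <- function(seq, spec) {
  stopifnot(inherits(seq, "depth_sequence"))
  K <- seq$intrinsics
  n_frames <- dim(seq$frames)[3]
  cloud1 <- depth_to_pointcloud(seq$frames[, , 1], K)
  if (nrow(cloud1$points) == 0)
    stop("fatal seed error: first frame has no valid depth")
  roi1 <- select_sphere_roi(cloud1, spec)
  model <- build_cylinder(roi1, spec, K)
  centroids <- matrix(NA_real_, n_frames, 3)
  distances <- rep(NA_real_, n_frames)
  for (i in seq_len(n_frames)) {
    cl <- depth_to_pointcloud(seq$frames[, , i], K)
    member <- points_in_cylinder(cl, model)
    if (nrow(member$points) >= 1) {
      cd <- centroid_and_distance(member)
      centroids[i, ] <- cd$centroid
      distances[i] <- cd$distance
    }
  }
  list(centroids = centroids, distances = distances, model = model)
}

#' Displacement relative to the minimum-distance reference frame
#'
#' The reference frame i* minimises the ROI-camera distance P(i) over
#' non-missing frames (earliest frame on ties). The default `"centroid"`
#' method returns the Euclidean distance between the 3D centroid of frame i
#' and the reference centroid, which captures lateral motion; the
#' `"scalar"` method uses `|P(i) - P(i*)|` instead and discards it.
#' Frames whose distance deviates from the recording median by more than
#' `guard_mm` (e.g. transient occlusions by a near object) are excluded
#' from reference candidacy so a corrupted frame cannot anchor the signal;
#' they are still reported and left to the outlier rule downstream.
#'
#' @param centroids T x 3 centroid matrix from [extract_raw_series()]
#' @param distances length-T P(i) vector
#' @param method `"centroid"` (default) or `"scalar"`
#' @param guard_mm reference-candidacy guard (mm)
#' @return numeric vector of raw displacements (mm, `NA` for missing
#'   frames) with attribute `reference_index`
#' @export
displacement_from_reference <- function(centroids, distances,
                                        method = c("centroid", "scalar"),
                                        guard_mm = 150) {
  method <- match.arg(method)
  valid <- is.finite(distances)
  if (!any(valid)) stop("empty signal: all frames missing")
  med <- stats::median(distances[valid])
  cand <- valid & abs(distances - med) <= guard_mm
  if (!any(cand)) cand <- valid
  ci <- which(cand)
  istar <- ci[which.min(distances[ci])]
  if (method == "centroid") {
    ref <- centroids[istar, ]
    sig <- sqrt((centroids[, 1] - ref[1])^2 +
                (centroids[, 2] - ref[2])^2 +
                (centroids[, 3] - ref[3])^2)
  } else {
    sig <- abs(distances - distances[istar])
  }
  sig[!valid] <- NA_real_
  attr(sig, "reference_index") <- istar
  sig
}

#' Centred moving average with edge-shrinking window
#'
#' At the edges the window shrinks symmetrically so no phase distortion is
#' introduced. Identity for `n = 1`; idempotent on constant signals.
#'
#' @param x numeric vector (no `NA`)
#' @param n odd window length (samples)
#' @return smoothed vector of the same length
#' @export
moving_average <- function(x, n = 5) {
  stopifnot(n >= 1, n %% 2 == 1, all(is.finite(x)))
  len <- length(x)
  hw <- (n - 1) / 2
  k <- pmin(hw, seq_len(len) - 1, len - seq_len(len))
  cs <- cumsum(c(0, x))
  i <- seq_len(len)
  (cs[i + k + 1] - cs[i - k]) / (2 * k + 1)
}

#' Clean a raw displacement signal
#'
#' Displacements above `outlier_mm` (default 150 mm, i.e. 15 cm) and
#' missing samples are replaced by linear interpolation between flanking
#' valid samples (nearest-value extension at the edges), then the signal is
#' smoothed with a centred `smooth_n`-sample moving average. The
#' interpolation mask records every replaced sample.
#'
#' @param raw numeric vector of raw displacements (mm; `NA` = missing)
#' @param fs sampling rate (Hz)
#' @param outlier_mm outlier threshold (mm)
#' @param smooth_n moving-average length (odd; 1 disables smoothing)
#' @param source camera label carried into the result
#' @return [breathing_signal()]
#' @export
clean_signal <- function(raw, fs, outlier_mm = 150, smooth_n = 5,
                         source = "cam") {
  stopifnot(outlier_mm > 0)
  bad <- !is.finite(raw) | raw > outlier_mm
  if (sum(!bad) < 2)
    stop("unrecoverable signal: fewer than 2 valid samples")
  vals <- as.numeric(raw)
  if (any(bad)) {
    ok <- which(!bad)
    vals <- stats::approx(ok, raw[ok], xout = seq_along(raw), rule = 2)$y
  }
  breathing_signal(moving_average(vals, smooth_n), fs,
                   interpolated_mask = bad, source = source)
}

#' Advisory artifact score
#'
#' Fraction of interpolated samples in a signal. Purely advisory: camera
#' clean/dirty flags are supplied by the user (mirroring a manual artefact
#' check) and are never overridden by this score.
#'
#' @param sig `breathing_signal`
#' @return fraction in \[0, 1\]
#' @export
artifact_score <- function(sig) {
  stopifnot(inherits(sig, "breathing_signal"))
  mean(sig$interpolated_mask)
}

#' Fuse the per-compartment signals of two cameras
#'
#' If both signals are flagged clean they are averaged sample-wise; if
#' exactly one is clean it is returned; if neither is clean this is an
#' error.
#'
#' @param sig_a,sig_b `breathing_signal` objects of equal length and rate
#' @param clean_a,clean_b user-supplied artefact flags
#' @return fused [breathing_signal()]
#' @export
fuse_cameras <- function(sig_a, sig_b, clean_a = TRUE, clean_b = TRUE) {
  stopifnot(inherits(sig_a, "breathing_signal"),
            inherits(sig_b, "breathing_signal"))
  if (length(sig_a$values) != length(sig_b$values) || sig_a$fs != sig_b$fs)
    stop("input error: signals differ in length or sampling rate")
  if (!clean_a && !clean_b)
    stop("no valid signal: both cameras flagged as artefacted")
  if (clean_a && clean_b) {
    breathing_signal((sig_a$values + sig_b$values) / 2, sig_a$fs,
                     interpolated_mask = sig_a$interpolated_mask |
                       sig_b$interpolated_mask,
                     source = "fused")
  } else if (clean_a) sig_a else sig_b
}
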