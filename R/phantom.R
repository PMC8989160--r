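# Synthetic bi-compartmental breathing phantom.
#
# Emulates a deformable test object with two adjacent rectangular membranes
# ("ribcage" RC and "abdomen" AB) driven sinusoidally along the surface
# normal, rendered through a pinhole depth camera at an arbitrary pose.
# The analytic membrane displacement plays the role of a reference motion
# capture system for validation.

#' Pinhole camera intrinsics
#'
#' @param fx,fy focal lengths (pixels)
#' @param cx,cy principal point (pixels, zero-based pixel coordinates)
#' @param width,height image size (pixels)
#' @return object of class `camera_intrinsics`
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1,
            cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' Default intrinsics for a close-range depth sensor
#'
#' A 640x480 sensor at roughly 30 cm working distance; the focal length
#' scales with the requested width so lower-resolution variants view the
#' same field.
#'
#' @param width,height image size in pixels
#' @return `camera_intrinsics`
#' @export
default_intrinsics <- function(width = 640, height = 480) {
  f <- 520 * width / 640
  camera_intrinsics(fx = f, fy = f,
                    cx = (width - 1) / 2, cy = (height - 1) / 2,
                    width = width, height = height)
}

#' Rigid camera pose (world to camera)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#' @param translation length-3 vector (mm)
#' @return object of class `camera_pose`
#' @export
camera_pose <- function(rotation, translation) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "camera_pose")
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Camera pose looking at the phantom centre
#'
#' The phantom lies in the world plane z = 0 with its outward normal along
#' +z. The frontal pose places the camera on that normal at
#' `distance_mm`, optical axis towards the membrane; tilts rotate the
#' viewpoint about the phantom centre, so the object stays centred in the
#' image while the motion direction diverges from the optical axis.
#'
#' @param distance_mm camera-to-phantom-centre distance (mm)
#' @param tilt_x_deg,tilt_y_deg viewpoint tilts (degrees)
#' @return `camera_pose`
#' @export
phantom_pose <- function(distance_mm = 300, tilt_x_deg = 0, tilt_y_deg = 0) {
  r0 <- diag(c(1, -1, -1))  # world +z (towards camera) -> camera -z
  r <- rot_x(tilt_x_deg) %*% rot_y(tilt_y_deg) %*% r0
  camera_pose(r, c(0, 0, distance_mm))
}

#' Phantom configuration
#'
#' @param amp_rc,amp_ab peak-to-trough membrane displacement (mm)
#' @param rr breathing rate (breaths per minute)
#' @param phase_deg abdomen-versus-ribcage phase offset (degrees); positive
#'   values mean the abdomen lags the ribcage, negative values that the
#'   outward motion of the abdomen precedes the ribcage
#' @param duration_s recording length (seconds); defaults to 14 full cycles
#' @param fps frame rate (frames per second)
#' @param pose `camera_pose`
#' @param intrinsics `camera_intrinsics`
#' @param noise_sd per-pixel Gaussian depth noise (mm)
#' @param dropout_p per-pixel probability of a missing depth return
#' @param occlusion_windows list of `list(t_start, t_end, compartment)`
#'   entries; during such a window the compartment's pixels are overwritten
#'   by a static near plane (an opaque object between camera and membrane)
#' @param plateau_frac fraction of each compartment over which the
#'   deformation is spatially uniform; the rest tapers to zero at the edges
#'   with a raised-cosine profile
#' @param seed integer seed controlling noise and dropout
#' @param membrane_w,membrane_l overall membrane size (mm); the two
#'   compartments split the length in half
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(amp_rc = 3, amp_ab = 3, rr = 40, phase_deg = 0,
                           duration_s = NULL, fps = 30,
                           pose = phantom_pose(),
                           intrinsics = default_intrinsics(),
                           noise_sd = 0, dropout_p = 0,
                           occlusion_windows = list(),
                           plateau_frac = 0.5, seed = 1L,
                           membrane_w = 120, membrane_l = 160) {
  if (is.null(duration_s)) duration_s <- 14 * 60 / rr
  stopifnot(amp_rc >= 0, amp_ab >= 0, rr > 0, fps > 0, duration_s > 0,
            noise_sd >= 0, dropout_p >= 0, dropout_p < 1,
            plateau_frac > 0, plateau_frac <= 1,
            membrane_w > 0, membrane_l > 0,
            inherits(pose, "camera_pose"),
            inherits(intrinsics, "camera_intrinsics"))
  for (w in occlusion_windows)
    stopifnot(w$t_start < w$t_end, w$compartment %in% c("rc", "ab"))
  structure(list(amp_rc = amp_rc, amp_ab = amp_ab, rr = rr,
                 phase_deg = phase_deg, duration_s = duration_s, fps = fps,
                 pose = pose, intrinsics = intrinsics, noise_sd = noise_sd,
                 dropout_p = dropout_p, occlusion_windows = occlusion_windows,
                 plateau_frac = plateau_frac, seed = as.integer(seed),
                 membrane_w = membrane_w, membrane_l = membrane_l),
            class = "phantom_config")
}

# raised-cosine deformation profile: 1 on the central plateau, tapering to 0
# at +/- half_width
taper_profile <- function(s, half_width, plateau_frac) {
  core <- plateau_frac * half_width
  a <- abs(s)
  w <- as.numeric(a <= core)
  if (plateau_frac < 1) {
    band <- a > core & a < half_width
    w[band] <- 0.5 * (1 + cos(pi * (a[band] - core) / (half_width - core)))
  }
  w
}

project_points <- function(p, intrinsics) {
  # p: 3 x N camera-frame points
  u <- intrinsics$cx + p[1, ] * intrinsics$fx / p[3, ]
  v <- intrinsics$cy + p[2, ] * intrinsics$fy / p[3, ]
  rbind(u, v)
}

#' Depth image sequence
#'
#' @param frames H x W x T array of depths (mm); `NA` marks missing returns
#' @param timestamps length-T vector of frame times (s), strictly increasing
#' @param intrinsics `camera_intrinsics`
#' @param fps nominal frame rate (Hz)
#' @return object of class `depth_sequence`
#' @export
depth_sequence <- function(frames, timestamps, intrinsics, fps) {
  stopifnot(length(dim(frames)) == 3, fps > 0,
            inherits(intrinsics, "camera_intrinsics"),
            dim(frames)[1] == intrinsics$height,
            dim(frames)[2] == intrinsics$width,
            dim(frames)[3] == length(timestamps),
            dim(frames)[3] >= 1)
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  fin <- frames[is.finite(frames)]
  if (length(fin) && any(fin <= 0)) stop("finite depths must be positive")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 intrinsics = intrinsics, fps = fps),
            class = "depth_sequence")
}

#' @export
print.depth_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<depth_sequence> %d frames of %dx%d px, %.3g fps, %.2f s\n",
              d[3], d[2], d[1], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Render a synthetic depth sequence of the bi-compartmental phantom
#'
#' Both membranes are driven along their rest-surface normal by a raised
#' cosine, `d(t) = (amp/2) * (1 + cos(2*pi*(rr/60)*t + phase))`, so the
#' extracted breathing signal (referenced to the minimum camera distance,
#' i.e. peak inflation) starts each condition at a trough and segmentation
#' recovers the nominal cycle count. A positive `phase_deg` delays the
#' abdomen relative to the ribcage. Spatially the deformation is uniform on
#' a central plateau and tapers to zero at the compartment edges.
#'
#' Rendering samples the surface densely (sub-pixel spacing), transforms by
#' the camera pose, projects through the pinhole model and keeps the
#' nearest depth per pixel (z-buffer). Gaussian depth noise, pixel dropout
#' and transient occlusions are applied afterwards; depths are quantised to
#' 0.1 mm, the storage resolution of the on-disk format. Pixels seeing no
#' surface are missing (`NA`). The output is bit-reproducible for a given
#' configuration and seed.
#'
#' @param config `phantom_config`
#' @return list with `sequence` (a [depth_sequence()]) and `truth` (a
#'   `phantom_truth`: analytic per-frame membrane displacements
#'   `rc_signal`/`ab_signal` in mm, the commanded `true_amp_rc`,
#'   `true_amp_ab`, `true_rr`, `true_phase`, and the frame-1 pixel seeds
#'   `roi_seed_rc`, `roi_seed_ab` of the compartment centres)
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  K <- config$intrinsics
  rot <- config$pose$rotation
  tr <- config$pose$translation
  n_frames <- round(config$duration_s * config$fps)
  stopifnot(n_frames >= 1)
  t_s <- (seq_len(n_frames) - 1) / config$fps
  f_hz <- config$rr / 60
  phi <- config$phase_deg * pi / 180
  d_rc <- (config$amp_rc / 2) * (1 + cos(2 * pi * f_hz * t_s))
  d_ab <- (config$amp_ab / 2) * (1 + cos(2 * pi * f_hz * t_s - phi))

  hw <- config$membrane_w / 2
  hl <- config$membrane_l / 2
  qc <- hl / 2  # compartment centres at y = +/- qc

  # frustum check on rest corners and maximally inflated compartment centres
  amp_max <- max(config$amp_rc, config$amp_ab)
  chk <- rbind(c(-hw, -hl, 0), c(hw, -hl, 0), c(-hw, hl, 0), c(hw, hl, 0),
               c(0, qc, amp_max), c(0, -qc, amp_max))
  chk_cam <- rot %*% t(chk) + tr
  if (any(chk_cam[3, ] <= 0))
    stop("configuration error: membrane behind the camera")
  uv <- project_points(chk_cam, K)
  if (any(uv[1, ] < 0 | uv[1, ] > K$width - 1 |
          uv[2, ] < 0 | uv[2, ] > K$height - 1))
    stop("configuration error: membrane does not fit in the camera frustum")

  # surface sampling at <= 0.5 px projected spacing
  z_min <- min(chk_cam[3, ]) - amp_max
  step <- max(0.05, 0.5 * z_min / max(K$fx, K$fy))
  xs <- seq(-hw, hw, by = step)
  ys <- seq(-hl, hl, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  wx <- taper_profile(gx, hw, config$plateau_frac)
  w_rc <- wx * taper_profile(gy - qc, qc, config$plateau_frac) * (gy >= 0)
  w_ab <- wx * taper_profile(gy + qc, qc, config$plateau_frac) * (gy < 0)

  q0 <- rot %*% rbind(gx, gy, 0) + tr       # rest positions, camera frame
  dirv <- as.numeric(rot %*% c(0, 0, 1))    # deformation direction

  H <- K$height
  W <- K$width
  # rest-pose projection masks per compartment, for occlusion overwrite
  uv0 <- round(project_points(q0, K))
  in_img0 <- uv0[1, ] >= 0 & uv0[1, ] < W & uv0[2, ] >= 0 & uv0[2, ] < H
  lin0 <- uv0[1, ] * H + uv0[2, ] + 1
  mask_rc <- unique(lin0[in_img0 & gy >= 0])
  mask_ab <- unique(lin0[in_img0 & gy < 0])

  occluded_lin <- function(i) {
    out <- integer(0)
    for (w in config$occlusion_windows) {
      if (t_s[i] >= w$t_start && t_s[i] < w$t_end)
        out <- c(out, if (w$compartment == "rc") mask_rc else mask_ab)
    }
    unique(out)
  }

  frames <- array(NA_real_, dim = c(H, W, n_frames))
  with_seed(config$seed, {
    for (i in seq_len(n_frames)) {
      cf <- w_rc * d_rc[i] + w_ab * d_ab[i]
      qx <- q0[1, ] + cf * dirv[1]
      qy <- q0[2, ] + cf * dirv[2]
      qz <- q0[3, ] + cf * dirv[3]
      u <- round(K$cx + qx * K$fx / qz)
      v <- round(K$cy + qy * K$fy / qz)
      keep <- which(qz > 0 & u >= 0 & u < W & v >= 0 & v < H)
      lin <- u[keep] * H + v[keep] + 1
      zk <- qz[keep]
      ord <- order(zk, decreasing = TRUE)  # nearest depth written last
      img <- matrix(NA_real_, H, W)
      img[lin[ord]] <- zk[ord]
      valid <- which(!is.na(img))
      if (config$noise_sd > 0)
        img[valid] <- img[valid] + rnorm(length(valid), sd = config$noise_sd)
      if (config$dropout_p > 0) {
        drop <- valid[runif(length(valid)) < config$dropout_p]
        img[drop] <- NA_real_
      }
      occ <- occluded_lin(i)
      if (length(occ)) img[occ] <- 100
      img <- round(img * 10) / 10  # 0.1 mm storage quantisation
      img[!is.na(img) & img <= 0] <- NA_real_
      frames[, , i] <- img
    }
  })

  seed_px <- function(yc, d0) {
    p <- rot %*% c(0, yc, d0) + tr
    as.integer(round(project_points(matrix(p, 3, 1), K)))
  }

  truth <- structure(list(
    rc_signal = d_rc, ab_signal = d_ab,
    true_amp_rc = config$amp_rc, true_amp_ab = config$amp_ab,
    true_rr = config$rr, true_phase = config$phase_deg,
    roi_seed_rc = seed_px(qc, d_rc[1]),
    roi_seed_ab = seed_px(-qc, d_ab[1]),
    t_s = t_s,
    short_recording = config$duration_s < 60 / config$rr
  ), class = "phantom_truth")
  if (truth$short_recording)
    warning("duration shorter than one full breath; truth flagged")

  list(sequence = depth_sequence(frames, t_s, K, config$fps), truth = truth)
}

#' In-vitro protocol presets
#'
#' The validation protocol consists of 13 conditions spanning the ranges
#' expected in neonates: seven amplitude steps (1-7 mm in 1 mm increments
#' at 40 bpm, in phase), three phase steps (0, 45, 90 degrees at 3 mm and
#' 40 bpm) and three rate steps (20, 40, 60 bpm at 3 mm, in phase). Every
#' condition lasts exactly `cycles` full breathing cycles.
#'
#' @param intrinsics,pose camera model shared by all conditions
#' @param noise_sd,dropout_p noise settings applied to every condition
#' @param seed base seed; condition `i` uses `seed + i`
#' @param cycles breathing cycles per condition (protocol value 14)
#' @return named list of [phantom_config()] objects, each carrying `label`
#'   and `sweep` fields
#' @export
protocol_presets <- function(intrinsics = default_intrinsics(),
                             pose = phantom_pose(),
                             noise_sd = 0, dropout_p = 0,
                             seed = 1L, cycles = 14) {
  mk <- function(amp, rr, phase, sweep, label, i) {
    cfg <- phantom_config(amp_rc = amp, amp_ab = amp, rr = rr,
                          phase_deg = phase,
                          duration_s = cycles * 60 / rr,
                          intrinsics = intrinsics, pose = pose,
                          noise_sd = noise_sd, dropout_p = dropout_p,
                          seed = seed + i)
    cfg$label <- label
    cfg$sweep <- sweep
    cfg
  }
  out <- list()
  i <- 0
  for (a in 1:7) {
    i <- i + 1
    out[[sprintf("amp_%dmm", a)]] <-
      mk(a, 40, 0, "amplitude", sprintf("amp_%dmm", a), i)
  }
  for (p in c(0, 45, 90)) {
    i <- i + 1
    out[[sprintf("phase_%ddeg", p)]] <-
      mk(3, 40, p, "phase", sprintf("phase_%ddeg", p), i)
  }
  for (r in c(20, 40, 60)) {
    i <- i + 1
    out[[sprintf("rate_%dbpm", r)]] <-
      mk(3, r, 0, "rate", sprintf("rate_%dbpm", r), i)
  }
  out
}

#' Protocol cycle bookkeeping
#'
#' Counts the cycles and data points each validation analysis draws from a
#' preset list, following the pooling rules of the in-vitro protocol: the
#' amplitude analysis uses every amplitude-sweep cycle plus all 3 mm cycles
#' of the phase and rate sweeps, with two compartments measured per cycle;
#' the phase analysis uses one loop per phase-sweep cycle; the rate
#' analysis uses both compartments of every rate-sweep cycle.
#'
#' @param presets list from [protocol_presets()]
#' @return list with `n_conditions`, `cycles_per_condition`,
#'   `amplitude_cycles`, `amplitude_points`, `phase_points`, `rr_points`,
#'   and `pooled_3mm_cycles` (the pooled middle amplitude step)
#' @export
protocol_cycle_counts <- function(presets) {
  sweep <- vapply(presets,
                  function(p) if (is.null(p$sweep)) NA_character_ else p$sweep,
                  character(1))
  amp <- vapply(presets, function(p) p$amp_rc, numeric(1))
  cyc <- vapply(presets, function(p) round(p$duration_s * p$rr / 60),
                numeric(1))
  amp_cycles <- sum(cyc[sweep %in% "amplitude"]) +
    sum(cyc[!(sweep %in% "amplitude") & amp == 3])
  list(
    n_conditions = length(presets),
    cycles_per_condition = unique(unname(cyc)),
    amplitude_cycles = amp_cycles,
    amplitude_points = 2 * amp_cycles,
    phase_points = sum(cyc[sweep %in% "phase"]),
    rr_points = 2 * sum(cyc[sweep %in% "rate"]),
    pooled_3mm_cycles = sum(cyc[amp == 3])
  )
}
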