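# Shared fixtures: all phantom sequences are generated in code at test
# time. Heavy (14-cycle) conditions are cached across test files.

.sim_cache <- new.env(parent = emptyenv())

# a reduced-resolution camera viewing the same field as the 640x480 default
test_intrinsics <- function(width = 160, height = 120) {
  default_intrinsics(width, height)
}

# full protocol-length condition, pipeline run end to end; cached
run_condition <- function(amp = 3, rr = 40, phase = 0, tilt = 0,
                          cycles = 14, width = 160, height = 120,
                          seed = 11) {
  key <- paste("c", amp, rr, phase, tilt, cycles, width, height, seed,
               sep = "_")
  if (!exists(key, envir = .sim_cache)) {
    cfg <- phantom_config(
      amp_rc = amp, amp_ab = amp, rr = rr, phase_deg = phase,
      duration_s = cycles * 60 / rr,
      intrinsics = test_intrinsics(width, height),
      pose = phantom_pose(tilt_x_deg = tilt), seed = seed)
    ph <- generate_phantom(cfg)
    fs <- cfg$fps
    sig <- lapply(list(rc = ph$truth$roi_seed_rc,
                       ab = ph$truth$roi_seed_ab), function(seed_px) {
      ser <- extract_raw_series(ph$sequence,
                                roi_spec(seed_px[1], seed_px[2]))
      raw <- displacement_from_reference(ser$centroids, ser$distances)
      list(raw = raw, clean = clean_signal(raw, fs))
    })
    bt <- analyze_pair(sig$rc$clean, sig$ab$clean)
    assign(key, list(cfg = cfg, truth = ph$truth, seq = ph$sequence,
                     raw_rc = sig$rc$raw, raw_ab = sig$ab$raw,
                     rc = sig$rc$clean, ab = sig$ab$clean, bt = bt),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# small synthetic point cloud built directly (no rendering)
make_cloud <- function(points, pixel_index = NULL) {
  points <- as.matrix(points)
  if (is.null(pixel_index))
    pixel_index <- cbind(u = seq_len(nrow(points)), v = 0L)
  structure(list(points = points, pixel_index = as.matrix(pixel_index)),
            class = "point_cloud")
}

# independent cross-spectral phase oracle: phase of the cross-spectrum at
# the fundamental frequency (degrees, positive = second signal lags)
cross_spectral_phase <- function(x, y) {
  x <- x - mean(x)
  y <- y - mean(y)
  fx <- stats::fft(x)
  fy <- stats::fft(y)
  k <- which.max(Mod(fx[2:(length(x) %/% 2)])) + 1
  Arg(fx[k] * Conj(fy[k])) * 180 / pi
}
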