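# In-vitro agreement analysis: phantom truth stands in for the reference
# motion-capture system; per-step error tables, Bland-Altman statistics,
# regression agreement.

#' Bland-Altman agreement statistics
#'
#' Differences are `cam - ref`; the limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (sample SD). The regression of
#' `cam` on `ref` and the Pearson correlation complete the agreement
#' summary.
#'
#' @param ref,cam paired measurement vectors (equal length, n >= 2)
#' @return object of class `agreement_stats`: `bias`, `loa_low`,
#'   `loa_high`, `slope`, `intercept`, `r`, `n`
#' @export
bland_altman <- function(ref, cam) {
  stopifnot(length(ref) == length(cam))
  if (length(ref) < 2) stop("insufficient data: need at least 2 pairs")
  d <- cam - ref
  bias <- mean(d)
  sdd <- stats::sd(d)
  fit <- stats::lm(cam ~ ref)
  cf <- stats::coef(fit)
  r <- if (stats::sd(ref) == 0 || stats::sd(cam) == 0) NA_real_
       else stats::cor(ref, cam)
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * sdd,
                 loa_high = bias + 1.96 * sdd,
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 r = r, n = length(ref)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n = %d, bias = %.3g, LoA = [%.3g, %.3g], slope = %.3g, r = %.3g\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$slope, x$r))
  invisible(x)
}

#' Per-step amplitude error table
#'
#' One row per commanded amplitude step with mean (SD) over cycles of the
#' reference and measured amplitudes, the signed error
#' `e = a_ref - a_cam`, the percentage error `100 * e / a_ref`, and their
#' absolute counterparts. Because grouping is by commanded amplitude, the
#' middle (3 mm) step pools the 3 mm cycles contributed by the phase and
#' rate sweeps, as in the validation protocol.
#'
#' @param paired data.frame with columns `amp_cmd`, `a_ref`, `a_cam` and
#'   (optionally) `condition`, `breath` for cycle counting
#' @return data.frame, one row per step, with mean/SD columns and counts
#'   `n_points` (amplitude values) and `n_cycles`
#' @export
error_table <- function(paired) {
  stopifnot(all(c("amp_cmd", "a_ref", "a_cam") %in% names(paired)))
  steps <- sort(unique(paired$amp_cmd))
  out <- lapply(seq_along(steps), function(j) {
    g <- paired[paired$amp_cmd == steps[j], , drop = FALSE]
    e <- g$a_ref - g$a_cam
    pct_ok <- all(g$a_ref != 0)
    e_pct <- if (pct_ok) 100 * e / g$a_ref else rep(NA_real_, length(e))
    n_cycles <- if (all(c("condition", "breath") %in% names(g)))
      nrow(unique(g[, c("condition", "breath")])) else NA_integer_
    msd <- function(x) c(mean(x), if (length(x) > 1) stats::sd(x) else 0)
    data.frame(step = sprintf("S%d", j), amp_cmd = steps[j],
               a_ref_mean = msd(g$a_ref)[1], a_ref_sd = msd(g$a_ref)[2],
               a_cam_mean = msd(g$a_cam)[1], a_cam_sd = msd(g$a_cam)[2],
               e_mean = msd(e)[1], e_sd = msd(e)[2],
               e_pct_mean = msd(e_pct)[1], e_pct_sd = msd(e_pct)[2],
               abs_e_mean = msd(abs(e))[1], abs_e_sd = msd(abs(e))[2],
               abs_e_pct_mean = msd(abs(e_pct))[1],
               abs_e_pct_sd = msd(abs(e_pct))[2],
               pct_defined = pct_ok,
               n_points = nrow(g), n_cycles = n_cycles)
  })
  do.call(rbind, out)
}

# reference-system analysis of an analytic truth signal: displacement from
# the closest-approach (peak inflation) position, then the same cleaning
# and breath analysis applied to camera data
truth_to_signal <- function(d, fs, smooth_n = 5) {
  raw <- abs(d - d[which.max(d)])
  clean_signal(raw, fs, smooth_n = smooth_n, source = "ref")
}

#' Run the in-vitro validation protocol on the synthetic phantom
#'
#' For each protocol condition, renders the phantom, runs the full camera
#' pipeline (ROI tracking, displacement, cleaning, breath analysis) and in
#' parallel applies the breathing-signal and breath-analysis steps to the
#' analytic truth signals, which play the role of the reference motion
#' capture system. Returns paired per-cycle tables following the protocol
#' bookkeeping: amplitudes for every condition and both compartments
#' (pooling the 3 mm cycles of the phase and rate sweeps), rates for the
#' rate sweep, phase shifts for the phase sweep.
#'
#' @param presets list from [protocol_presets()] (or a subset)
#' @param window extremum detection window (samples)
#' @param smooth_n moving-average length (samples)
#' @param radius_px ROI radius (pixels)
#' @param strict when `TRUE`, a noise-free condition segmenting a number of
#'   breaths different from the nominal cycle count raises a protocol
#'   integrity error
#' @return list with data.frames `amplitude` (`condition`, `sweep`,
#'   `amp_cmd`, `compartment`, `breath`, `a_ref`, `a_cam`), `rr`, `phase`,
#'   and `counts` from [protocol_cycle_counts()]
#' @export
run_invitro_protocol <- function(presets, window = 33, smooth_n = 5,
                                 radius_px = 8, strict = TRUE) {
  amp_rows <- list(); rr_rows <- list(); ph_rows <- list()
  if (is.null(names(presets)))
    names(presets) <- sprintf("condition_%d", seq_along(presets))
  for (nm in names(presets)) {
    cfg <- presets[[nm]]
    if (is.null(cfg$sweep)) cfg$sweep <- NA_character_
    ph <- generate_phantom(cfg)
    fs <- cfg$fps
    cam_sig <- lapply(c(rc = "rc", ab = "ab"), function(cmp) {
      seed <- if (cmp == "rc") ph$truth$roi_seed_rc else ph$truth$roi_seed_ab
      ser <- extract_raw_series(ph$sequence,
                                roi_spec(seed[1], seed[2], radius_px))
      raw <- displacement_from_reference(ser$centroids, ser$distances)
      clean_signal(raw, fs, smooth_n = smooth_n, source = "cam")
    })
    ref_sig <- list(rc = truth_to_signal(ph$truth$rc_signal, fs, smooth_n),
                    ab = truth_to_signal(ph$truth$ab_signal, fs, smooth_n))
    cam_bt <- analyze_pair(cam_sig$rc, cam_sig$ab, window)
    ref_bt <- analyze_pair(ref_sig$rc, ref_sig$ab, window)
    nominal <- round(cfg$duration_s * cfg$rr / 60)
    noise_free <- cfg$noise_sd == 0 && cfg$dropout_p == 0 &&
      length(cfg$occlusion_windows) == 0
    if (strict && noise_free &&
        (nrow(cam_bt$rc) != nominal || nrow(cam_bt$ab) != nominal))
      stop(sprintf(
        "protocol integrity error: %s segmented %d/%d breaths, expected %d",
        nm, nrow(cam_bt$rc), nrow(cam_bt$ab), nominal))
    for (cmp in c("rc", "ab")) {
      k <- min(nrow(cam_bt[[cmp]]), nrow(ref_bt[[cmp]]))
      if (k == 0) next
      amp_rows[[length(amp_rows) + 1]] <- data.frame(
        condition = nm, sweep = cfg$sweep, amp_cmd = cfg$amp_rc,
        compartment = cmp, breath = seq_len(k),
        a_ref = ref_bt[[cmp]]$a[seq_len(k)],
        a_cam = cam_bt[[cmp]]$a[seq_len(k)])
      if (identical(cfg$sweep, "rate"))
        rr_rows[[length(rr_rows) + 1]] <- data.frame(
          condition = nm, compartment = cmp, breath = seq_len(k),
          rr_ref = ref_bt[[cmp]]$rr[seq_len(k)],
          rr_cam = cam_bt[[cmp]]$rr[seq_len(k)])
    }
    if (identical(cfg$sweep, "phase")) {
      k <- min(nrow(cam_bt$theta), nrow(ref_bt$theta))
      if (k > 0)
        ph_rows[[length(ph_rows) + 1]] <- data.frame(
          condition = nm, breath = seq_len(k),
          theta_ref = ref_bt$theta$theta[seq_len(k)],
          theta_cam = cam_bt$theta$theta[seq_len(k)])
    }
  }
  bindr <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(amplitude = bindr(amp_rows), rr = bindr(rr_rows),
       phase = bindr(ph_rows), counts = protocol_cycle_counts(presets))
}
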