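# End-to-end pipeline and command-line entry points.

#' Pipeline run configuration
#'
#' Bundles every tunable of the processing chain with its standard default:
#' 8-pixel ROI radius, 15 cm outlier threshold, 5-sample moving average,
#' 33-sample extremum window.
#'
#' @param input directory holding the depth stack of camera A
#' @param rc_seed,ab_seed length-2 pixel seeds `c(u, v)` for camera A
#' @param input_b,rc_seed_b,ab_seed_b optional second camera
#' @param window extremum detection window (samples)
#' @param outlier_mm outlier displacement threshold (mm)
#' @param smooth_n moving-average length (samples)
#' @param radius_px ROI radius (pixels)
#' @param clean_a,clean_b manual artefact flags per camera
#' @param exclude list of `c(t0, t1)` time windows (s) whose breaths are
#'   discarded from the analysis
#' @param out_dir optional output directory for CSV/JSON results
#' @return object of class `run_config`
#' @export
run_config <- function(input, rc_seed, ab_seed,
                       input_b = NULL, rc_seed_b = NULL, ab_seed_b = NULL,
                       window = 33L, outlier_mm = 150, smooth_n = 5,
                       radius_px = 8, clean_a = TRUE, clean_b = TRUE,
                       exclude = list(), out_dir = NULL) {
  stopifnot(length(rc_seed) == 2, length(ab_seed) == 2,
            window > 0, outlier_mm > 0, smooth_n >= 1, radius_px > 0)
  if (!is.null(input_b))
    stopifnot(length(rc_seed_b) == 2, length(ab_seed_b) == 2)
  for (w in exclude) stopifnot(length(w) == 2, w[1] < w[2])
  structure(list(input = input, rc_seed = rc_seed, ab_seed = ab_seed,
                 input_b = input_b, rc_seed_b = rc_seed_b,
                 ab_seed_b = ab_seed_b, window = as.integer(window),
                 outlier_mm = outlier_mm, smooth_n = smooth_n,
                 radius_px = radius_px, clean_a = clean_a,
                 clean_b = clean_b, exclude = exclude, out_dir = out_dir),
            class = "run_config")
}

extract_compartment <- function(seq, seed, config, source) {
  ser <- extract_raw_series(seq, roi_spec(seed[1], seed[2],
                                          config$radius_px))
  raw <- displacement_from_reference(ser$centroids, ser$distances)
  clean_signal(raw, seq$fps, outlier_mm = config$outlier_mm,
               smooth_n = config$smooth_n, source = source)
}

#' Run the full pipeline on one or two recorded depth stacks
#'
#' Extract, clean, (optionally) fuse, segment and summarize: for each
#' compartment the ROI is tracked through the stack, the displacement
#' signal referenced, cleaned and smoothed; with two cameras the
#' per-compartment signals are fused according to the manual clean flags.
#' Breaths overlapping an excluded time window are discarded. Results are
#' written to `out_dir` when configured (`signals.csv`, `breaths.csv`,
#' `summary.csv`, `log.txt`).
#'
#' @param config `run_config`
#' @return list with `rc`, `ab` (fused [breathing_signal()]s), `breaths`
#'   (a `breath_table`), `summary` and `log` (character vector)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  seq_a <- read_depth_sequence(config$input)
  note("camera A: %d frames from %s", dim(seq_a$frames)[3], config$input)
  rc <- extract_compartment(seq_a, config$rc_seed, config, "camA")
  ab <- extract_compartment(seq_a, config$ab_seed, config, "camA")

  if (!is.null(config$input_b)) {
    seq_b <- read_depth_sequence(config$input_b)
    note("camera B: %d frames from %s", dim(seq_b$frames)[3],
         config$input_b)
    rc_b <- extract_compartment(seq_b, config$rc_seed_b, config, "camB")
    ab_b <- extract_compartment(seq_b, config$ab_seed_b, config, "camB")
    rc <- fuse_cameras(rc, rc_b, config$clean_a, config$clean_b)
    ab <- fuse_cameras(ab, ab_b, config$clean_a, config$clean_b)
    note("fused cameras (clean flags: A=%s, B=%s)", config$clean_a,
         config$clean_b)
  }
  note("interpolated samples: rc %.1f%%, ab %.1f%%",
       100 * artifact_score(rc), 100 * artifact_score(ab))

  bt <- analyze_pair(rc, ab, config$window)
  if (length(config$exclude)) {
    drop_rows <- function(df) {
      t1 <- (df$i_min1 - 1) / bt$fs
      t2 <- (df$i_min2 - 1) / bt$fs
      keep <- rep(TRUE, nrow(df))
      for (w in config$exclude) keep <- keep & (t2 < w[1] | t1 > w[2])
      keep
    }
    keep_rc <- drop_rows(bt$rc)
    note("excluded %d ribcage breaths in %d manual windows",
         sum(!keep_rc), length(config$exclude))
    bt$rc <- bt$rc[keep_rc, , drop = FALSE]
    bt$theta <- bt$theta[keep_rc, , drop = FALSE]
    bt$ab <- bt$ab[drop_rows(bt$ab), , drop = FALSE]
  }
  summ <- summarize_recording(bt)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signals_csv(rc, ab, file.path(config$out_dir, "signals.csv"))
    write_breaths_csv(bt, file.path(config$out_dir, "breaths.csv"))
    utils::write.csv(summ, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(config$out_dir, "log.txt"))
  }
  list(rc = rc, ab = ab, breaths = bt, summary = summ, log = log)
}

#' Command-line interface
#'
#' Dispatches the `simulate`, `extract`, `breaths`, `validate` and `run`
#' subcommands used by the `respdepth` executable script. Not intended for
#' interactive use; see the script under `exec/`.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
respdepth_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: respdepth <command> [options]",
    "commands:",
    "  simulate --config cfg.yaml --out DIR     render a phantom sequence",
    "  extract  --in DIR --rc-seed U,V --ab-seed U,V --out signals.csv",
    "  breaths  --in signals.csv --out breaths.csv [--window 33]",
    "  validate --out DIR [--width 160 --height 120]",
    "  run      --in DIR --rc-seed U,V --ab-seed U,V --out DIR",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (!length(i)) return(default)
    rest[i[1] + 1]
  }
  seed_of <- function(s) as.numeric(strsplit(s, ",")[[1]])
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfgf <- opt("config"); out <- opt("out")
        if (is.null(out)) stop("simulate: --out is required")
        y <- if (!is.null(cfgf)) yaml::read_yaml(cfgf) else list()
        K <- default_intrinsics(y$width %||% 640, y$height %||% 480)
        pose <- phantom_pose(y$distance_mm %||% 300,
                             y$tilt_x_deg %||% 0, y$tilt_y_deg %||% 0)
        cfg <- phantom_config(
          amp_rc = y$amp_rc %||% 3, amp_ab = y$amp_ab %||% 3,
          rr = y$rr %||% 40, phase_deg = y$phase_deg %||% 0,
          duration_s = y$duration_s, fps = y$fps %||% 30,
          pose = pose, intrinsics = K, noise_sd = y$noise_sd %||% 0,
          dropout_p = y$dropout_p %||% 0,
          plateau_frac = y$plateau_frac %||% 0.5, seed = y$seed %||% 1)
        ph <- generate_phantom(cfg)
        write_depth_sequence(ph$sequence, out)
        write_phantom_truth(ph$truth, out)
        message(sprintf("wrote %d frames to %s", dim(ph$sequence$frames)[3],
                        out))
        0L
      },
      extract = {
        seq <- read_depth_sequence(opt("in"))
        cfg <- run_config(opt("in"), seed_of(opt("rc-seed")),
                          seed_of(opt("ab-seed")),
                          radius_px = as.numeric(opt("radius-px", "8")),
                          smooth_n = as.numeric(opt("smooth", "5")),
                          outlier_mm = as.numeric(opt("outlier-mm", "150")))
        rc <- extract_compartment(seq, cfg$rc_seed, cfg, "camA")
        ab <- extract_compartment(seq, cfg$ab_seed, cfg, "camA")
        write_signals_csv(rc, ab, opt("out", "signals.csv"))
        0L
      },
      breaths = {
        sigs <- read_signals_csv(opt("in"))
        bt <- analyze_pair(sigs$rc, sigs$ab,
                           as.integer(opt("window", "33")))
        write_breaths_csv(bt, opt("out", "breaths.csv"))
        print(summarize_recording(bt))
        0L
      },
      validate = {
        out <- opt("out", "report")
        K <- default_intrinsics(as.integer(opt("width", "160")),
                                as.integer(opt("height", "120")))
        res <- run_invitro_protocol(protocol_presets(intrinsics = K))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(res$amplitude,
                         file.path(out, "amplitude_pairs.csv"),
                         row.names = FALSE)
        utils::write.csv(error_table(res$amplitude),
                         file.path(out, "error_table.csv"),
                         row.names = FALSE)
        ba <- bland_altman(res$amplitude$a_ref, res$amplitude$a_cam)
        jsonlite::write_json(unclass(ba),
                             file.path(out, "bland_altman_amplitude.json"),
                             auto_unbox = TRUE, digits = NA)
        print(ba)
        0L
      },
      run = {
        cfg <- run_config(opt("in"), seed_of(opt("rc-seed")),
                          seed_of(opt("ab-seed")),
                          window = as.integer(opt("window", "33")),
                          out_dir = opt("out", "out"))
        res <- run_pipeline(cfg)
        print(res$summary)
        0L
      },
      { message(usage); 1L })
  }, error = function(e) {
    message(sprintf("respdepth %s: %s", cmd, conditionMessage(e)))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
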