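# Breath segmentation and breath-by-breath parameters: respiratory rate,
# displacement amplitude, and the Lissajous thoracoabdominal phase shift.

#' Detect alternating local extrema
#'
#' A sample is a maximum (minimum) if it attains the maximum (minimum) of
#' the centred `window`-sample neighbourhood and is the earliest sample in
#' that neighbourhood to do so (plateau tie-break); windows truncate at the
#' signal edges. The returned sequence strictly alternates: when two
#' same-type extrema are adjacent the more extreme one is kept (earliest on
#' ties).
#'
#' @param signal `breathing_signal` or numeric vector
#' @param window neighbourhood length in samples (default 33)
#' @return data.frame with columns `index` and `type` (`"min"`/`"max"`)
#' @export
detect_extrema <- function(signal, window = 33) {
  values <- if (inherits(signal, "breathing_signal")) signal$values
            else as.numeric(signal)
  n <- length(values)
  if (n < window)
    stop("signal shorter than the extremum detection window")
  hw <- (window - 1) %/% 2
  idx <- integer(0)
  typ <- integer(0)
  for (i in seq_len(n)) {
    lo <- max(1, i - hw)
    hi <- min(n, i + hw)
    w <- values[lo:hi]
    mx <- max(w)
    mn <- min(w)
    if (mx == mn) next  # flat neighbourhood: no extremum
    if (values[i] == mx && lo + which.max(w) - 1L == i) {
      idx <- c(idx, i); typ <- c(typ, 1L)
    } else if (values[i] == mn && lo + which.min(w) - 1L == i) {
      idx <- c(idx, i); typ <- c(typ, -1L)
    }
  }
  # enforce strict min/max alternation
  keep <- rep(TRUE, length(idx))
  repeat {
    ki <- which(keep)
    if (length(ki) < 2) break
    dup <- which(typ[ki[-length(ki)]] == typ[ki[-1]])
    if (!length(dup)) break
    j <- dup[1]
    a <- ki[j]; b <- ki[j + 1]
    va <- values[idx[a]]; vb <- values[idx[b]]
    drop_b <- if (typ[a] == 1L) vb <= va else vb >= va
    keep[if (drop_b) b else a] <- FALSE
  }
  data.frame(index = idx[keep],
             type = ifelse(typ[keep] == 1L, "max", "min"),
             stringsAsFactors = FALSE)
}

#' Segment alternating extrema into breaths
#'
#' A breath is a minimum-maximum-minimum triple; consecutive breaths share
#' the boundary minimum.
#'
#' @param extrema data.frame from [detect_extrema()]
#' @return data.frame with columns `i_min1`, `i_max`, `i_min2` (sample
#'   indices); zero rows when fewer than three extrema are available
#' @export
segment_breaths <- function(extrema) {
  idx <- extrema$index
  typ <- extrema$type
  rows <- list()
  if (length(idx) >= 3) {
    for (j in seq_len(length(idx) - 2)) {
      if (typ[j] == "min" && typ[j + 1] == "max" && typ[j + 2] == "min")
        rows[[length(rows) + 1]] <- c(idx[j], idx[j + 1], idx[j + 2])
    }
  }
  if (!length(rows))
    return(data.frame(i_min1 = integer(0), i_max = integer(0),
                      i_min2 = integer(0)))
  m <- do.call(rbind, rows)
  data.frame(i_min1 = m[, 1], i_max = m[, 2], i_min2 = m[, 3])
}

#' Breath-by-breath rate and amplitude
#'
#' Respiratory rate is the inverse of the min-to-min interval,
#' `rr = 60 * fs / (i_min2 - i_min1)` (bpm); amplitude is the difference
#' between the maximum and the following minimum,
#' `a = signal(i_max) - signal(i_min2)` (mm).
#'
#' @param signal `breathing_signal` or numeric vector
#' @param breaths data.frame from [segment_breaths()]
#' @param fs sampling rate (Hz); taken from `signal` when it is a
#'   `breathing_signal`
#' @return `breaths` augmented with `t_start_s`, `rr` and `a`
#' @export
breath_parameters <- function(signal, breaths, fs = NULL) {
  values <- if (inherits(signal, "breathing_signal")) signal$values
            else as.numeric(signal)
  if (is.null(fs)) {
    stopifnot(inherits(signal, "breathing_signal"))
    fs <- signal$fs
  }
  breaths$t_start_s <- (breaths$i_min1 - 1) / fs
  breaths$rr <- 60 * fs / (breaths$i_min2 - breaths$i_min1)
  breaths$a <- values[breaths$i_max] - values[breaths$i_min2]
  breaths
}

#' Lissajous phase shift between ribcage and abdomen over one breath
#'
#' On the loop of ribcage (ordinate) versus abdomen (abscissa) traced over
#' one breath, the loop width `m` is measured along the abdominal axis at
#' the mid-level of the ribcage range (distance between the two crossings,
#' linearly interpolated); `s` is the full abdominal range. The magnitude
#' is `asin(m/s)` when the principal-axis slope (sign of the
#' ribcage-abdomen covariance) is positive and `180 - asin(m/s)` degrees
#' when negative. The sign is the orientation of the loop (signed area):
#' positive when the abdomen lags the ribcage, negative when the outward
#' motion of the abdomen precedes that of the ribcage. A synchronous pair
#' gives a closed loop and 0 degrees; paradoxical motion gives +/-180.
#'
#' @param rc_segment,ab_segment displacement samples of the two
#'   compartments over the same breath
#' @return phase shift in degrees, in \[-180, 180\]; `NA` when either
#'   compartment has a degenerate range or fewer than two mid-level
#'   crossings exist
#' @export
lissajous_phase <- function(rc_segment, ab_segment) {
  stopifnot(length(rc_segment) == length(ab_segment))
  rc <- as.numeric(rc_segment)
  ab <- as.numeric(ab_segment)
  s_rc <- max(rc) - min(rc)
  s_ab <- max(ab) - min(ab)
  tol <- 1e-12
  if (s_rc <= tol || s_ab <= tol) return(NA_real_)
  level <- (max(rc) + min(rc)) / 2
  g <- rc - level
  cross_ab <- numeric(0)
  n <- length(rc)
  for (k in seq_len(n - 1)) {
    if (g[k] == 0) {
      cross_ab <- c(cross_ab, ab[k])
    } else if (g[k] * g[k + 1] < 0) {
      fr <- g[k] / (g[k] - g[k + 1])
      cross_ab <- c(cross_ab, ab[k] + fr * (ab[k + 1] - ab[k]))
    }
  }
  if (g[n] == 0) cross_ab <- c(cross_ab, ab[n])
  if (length(cross_ab) < 2) return(NA_real_)
  m <- max(cross_ab) - min(cross_ab)
  theta <- asin(min(1, m / s_ab)) * 180 / pi
  if (stats::cov(rc, ab) < 0) theta <- 180 - theta
  # loop orientation via the shoelace signed area (loop closed explicitly)
  area <- 0.5 * sum(rc * c(ab[-1], ab[1]) - c(rc[-1], rc[1]) * ab)
  if (area < 0) theta <- -theta
  max(-180, min(180, theta))
}

breaths_of <- function(sig, window = 33) {
  ext <- detect_extrema(sig, window)
  br <- segment_breaths(ext)
  breath_parameters(sig, br)
}

#' Breath-by-breath analysis of a ribcage/abdomen signal pair
#'
#' Segments each compartment's signal into breaths and computes rate and
#' amplitude per breath per compartment; the phase shift is computed once
#' per ribcage breath from the Lissajous loop of the two signals over that
#' breath.
#'
#' @param rc_sig,ab_sig `breathing_signal` objects (equal length and rate)
#' @param window extremum detection window (samples)
#' @return object of class `breath_table`: list with data.frames `rc`,
#'   `ab` (per-breath `t_start_s`, `rr`, `a`) and `theta` (per ribcage
#'   breath), plus `fs`
#' @export
analyze_pair <- function(rc_sig, ab_sig, window = 33) {
  stopifnot(inherits(rc_sig, "breathing_signal"),
            inherits(ab_sig, "breathing_signal"),
            length(rc_sig$values) == length(ab_sig$values),
            rc_sig$fs == ab_sig$fs)
  rc_b <- breaths_of(rc_sig, window)
  ab_b <- breaths_of(ab_sig, window)
  theta <- vapply(seq_len(nrow(rc_b)), function(j) {
    i1 <- rc_b$i_min1[j]; i2 <- rc_b$i_min2[j]
    lissajous_phase(rc_sig$values[i1:i2], ab_sig$values[i1:i2])
  }, numeric(1))
  structure(list(rc = rc_b, ab = ab_b,
                 theta = data.frame(breath = seq_len(nrow(rc_b)),
                                    i_min1 = rc_b$i_min1,
                                    i_min2 = rc_b$i_min2,
                                    theta = theta),
                 fs = rc_sig$fs),
            class = "breath_table")
}

#' @export
print.breath_table <- function(x, ...) {
  cat(sprintf("<breath_table> %d ribcage / %d abdominal breaths @ %.3g Hz\n",
              nrow(x$rc), nrow(x$ab), x$fs))
  invisible(x)
}

#' Recording-level summary of breath parameters
#'
#' Mean and sample standard deviation (n - 1 denominator) of rate,
#' amplitude (per compartment) and phase shift over breaths. With a single
#' breath the SD is undefined and reported as 0 with `sd_defined = FALSE`;
#' undefined phase values are excluded.
#'
#' @param bt `breath_table` from [analyze_pair()]
#' @return data.frame with columns `metric`, `mean`, `sd`, `n`,
#'   `sd_defined`
#' @export
summarize_recording <- function(bt) {
  stopifnot(inherits(bt, "breath_table"))
  row <- function(metric, x) {
    x <- x[is.finite(x)]
    n <- length(x)
    data.frame(metric = metric,
               mean = if (n) mean(x) else NA_real_,
               sd = if (n > 1) stats::sd(x) else 0,
               n = n,
               sd_defined = n > 1)
  }
  do.call(rbind, list(
    row("rr_rc_bpm", bt$rc$rr),
    row("rr_ab_bpm", bt$ab$rr),
    row("a_rc_mm", bt$rc$a),
    row("a_ab_mm", bt$ab$a),
    row("theta_deg", bt$theta$theta)
  ))
}
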