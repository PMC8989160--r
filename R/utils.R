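#' Euclidean norm of a vector
#' @param x numeric vector
#' @return scalar norm
#' @keywords internal
vnorm <- function(x) sqrt(sum(x * x))

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Frequency response of a centred moving-average (boxcar) filter
#'
#' Gain applied to a sinusoid of frequency `f` sampled at `fs` by an
#' `n`-sample moving average: `sin(n*pi*f/fs) / (n*sin(pi*f/fs))`.
#' Used to compensate the documented amplitude attenuation of the
#' five-sample smoother when comparing recovered breath amplitudes with
#' commanded ones.
#'
#' @param f signal frequency (Hz)
#' @param fs sampling rate (Hz)
#' @param n filter length (samples, default 5)
#' @return gain in (0, 1]
#' @export
boxcar_gain <- function(f, fs, n = 5) {
  stopifnot(f >= 0, fs > 0, n >= 1)
  if (f == 0) return(1)
  sin(n * pi * f / fs) / (n * sin(pi * f / fs))
}
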