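# Iterative soft thresholding reconstruction of non-uniformly sampled
# indirect-dimension traces.  Thresholding acts on real spectrum values
# only; imaginaries are regenerated with a Hilbert transform, and measured
# points are restored exactly at the end.

#' A non-uniform sampling schedule
#'
#' The set of acquired increment indices on the full Nyquist grid.
#' @param indices 0-based sampled indices (unique, non-negative).
#' @param grid_size full grid length.
#' @return a `sample_schedule` with fields `indices` (sorted), `grid_size`,
#'   `fraction` and `is_full`.
#' @export
sample_schedule <- function(indices, grid_size) {
  indices <- as.integer(indices)
  grid_size <- as.integer(grid_size)
  if (any(indices < 0)) stop("schedule contains a negative index")
  if (anyDuplicated(indices)) stop("schedule contains duplicate indices")
  if (any(indices >= grid_size)) stop("schedule index beyond the grid")
  indices <- sort(indices)
  structure(list(indices = indices, grid_size = grid_size,
                 fraction = length(indices) / grid_size,
                 is_full = length(indices) == grid_size),
            class = "sample_schedule")
}

#' @export
print.sample_schedule <- function(x, ...) {
  cat(sprintf("<sample_schedule> %d of %d (%.1f%%)%s\n", length(x$indices),
              x$grid_size, 100 * x$fraction,
              if (x$is_full) ", full" else ""))
  invisible(x)
}

#' IST configuration
#'
#' @param iterations number of thresholding iterations (default 500).
#' @param threshold_fraction per-iteration threshold as a fraction of the
#'   current maximum absolute real spectrum value, in (0, 1)
#'   (default 0.98).
#' @param final_hft regenerate the add buffer's imaginaries with a Hilbert
#'   transform before the final inverse transform (default TRUE).
#' @return an `ist_config` object.
#' @export
ist_config <- function(iterations = 500L, threshold_fraction = 0.98,
                       final_hft = TRUE) {
  stopifnot(iterations >= 1, threshold_fraction > 0, threshold_fraction < 1)
  structure(list(iterations = as.integer(iterations),
                 threshold_fraction = threshold_fraction,
                 final_hft = isTRUE(final_hft)), class = "ist_config")
}

# raw (unordered-aware) transforms used inside the IST loop: no
# first-point convention, spectral ordering as in ft()/ift()
raw_ft <- function(x) to_spec_order(stats::fft(x))
raw_ift <- function(s) {
  n <- length(s)
  stats::fft(from_spec_order(s), inverse = TRUE) / n
}

#' Fused Hilbert transform + inverse Fourier transform
#'
#' Equivalent to regenerating the imaginaries of a real spectrum ([hft()])
#' and then inverse transforming, but computed with a single inverse
#' transform followed by the causal time-domain window (the forward
#' transform inside the Hilbert step cancels against the inverse
#' transform that follows it).
#'
#' @param real_spectrum numeric (or complex; only the real part is used)
#'   spectrum in spectral order.
#' @return complex time-domain trace.
#' @export
fused_hilbert_ift <- function(real_spectrum) {
  n <- length(real_spectrum)
  raw_ift(as.complex(Re(real_spectrum))) * hilbert_window(n)
}

#' Reconstruct a non-uniformly sampled trace by iterative soft thresholding
#'
#' The input time-domain trace holds measured values at the schedule's
#' indices and zeros elsewhere.  Each iteration: Fourier transform, take
#' the real part, move the portion of every value exceeding the threshold
#' (`threshold_fraction` times the current maximum magnitude) into an add
#' buffer while clipping the spectrum to the threshold, regenerate
#' imaginaries of the clipped spectrum with a Hilbert transform, inverse
#' transform, and zero the non-sampled time points.  After the last
#' iteration the add buffer is Hilbert transformed, inverse transformed,
#' and the measured values are copied back over the sampled positions --
#' sampled points are returned bit-exactly, only non-sampled points are
#' synthesised.
#'
#' @param v time-domain [nmr_vector()] of length `schedule$grid_size` with
#'   zeros at non-sampled points.
#' @param schedule a [sample_schedule()].
#' @param cfg an [ist_config()].
#' @param reference optional fully sampled time-domain [nmr_vector()]; when
#'   given, the per-iteration normalized RMS spectral error -- the RMS of
#'   the real-spectrum difference divided by the peak height (maximum
#'   absolute value) of the reference real spectrum -- is recorded in the
#'   result's `error` attribute.
#' @param stop_below optional early-exit tolerance: when `reference` is
#'   given, iteration stops once the recorded error drops below this
#'   value.
#' @return the reconstructed time-domain `nmr_vector`.
#' @export
ist_reconstruct <- function(v, schedule, cfg = ist_config(),
                            reference = NULL, stop_below = NULL) {
  stopifnot(inherits(v, "nmr_vector"), inherits(schedule, "sample_schedule"),
            inherits(cfg, "ist_config"))
  n <- length(v$values)
  if (n != schedule$grid_size)
    stop("vector length ", n, " != schedule grid size ",
         schedule$grid_size)
  sampled <- schedule$indices + 1L
  unsampled <- setdiff(seq_len(n), sampled)
  orig <- v$values
  x <- orig
  buf <- numeric(n)
  errors <- NULL
  ref_spec <- NULL
  if (!is.null(reference)) {
    rv <- if (inherits(reference, "nmr_vector")) reference$values
          else as.complex(reference)
    ref_spec <- Re(raw_ft(rv))
    errors <- numeric(cfg$iterations)
  }
  finalize <- function(buf) {
    out <- if (cfg$final_hft) fused_hilbert_ift(buf)
           else raw_ift(as.complex(buf))
    out[sampled] <- orig[sampled]
    out
  }
  for (it in seq_len(cfg$iterations)) {
    r <- Re(raw_ft(x))
    thr <- cfg$threshold_fraction * max(abs(r))
    excess <- sign(r) * pmax(abs(r) - thr, 0)
    buf <- buf + excess
    x <- fused_hilbert_ift(r - excess)
    x[unsampled] <- 0
    if (!is.null(ref_spec)) {
      est <- Re(raw_ft(finalize(buf)))
      errors[it] <- sqrt(mean((est - ref_spec)^2)) / max(abs(ref_spec))
      if (!is.null(stop_below) && errors[it] < stop_below) {
        errors <- errors[seq_len(it)]
        break
      }
    }
  }
  out <- vec_with_values(v, finalize(buf))
  if (!is.null(errors)) attr(out, "error") <- errors
  out
}

#' Place consecutively stored NUS increments onto the full grid
#'
#' Raw NUS acquisitions store only the sampled increments, consecutively.
#' This expands them to the full Nyquist grid: measured values land at the
#' schedule's indices, all other grid points are zero.
#'
#' @param values complex vector of measured increments (one trace), or a
#'   matrix with one column per increment (rows = transformed direct
#'   dimension points).
#' @param schedule a [sample_schedule()]; `length(schedule$indices)` must
#'   match the number of measured increments.
#' @return vector or matrix expanded to `schedule$grid_size` increments.
#' @export
nus_expand <- function(values, schedule) {
  stopifnot(inherits(schedule, "sample_schedule"))
  k <- length(schedule$indices)
  if (is.matrix(values)) {
    if (ncol(values) != k)
      stop("got ", ncol(values), " increments for a schedule of ", k)
    out <- matrix(0i, nrow(values), schedule$grid_size)
    out[, schedule$indices + 1L] <- values
    out
  } else {
    if (length(values) != k)
      stop("got ", length(values), " increments for a schedule of ", k)
    out <- complex(schedule$grid_size)
    out[schedule$indices + 1L] <- values
    out
  }
}
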