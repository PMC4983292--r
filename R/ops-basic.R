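# Per-vector transforms.
#
# Spectral ordering convention: after ft(), index 0 holds the most
# downfield (highest-ppm, highest-frequency-offset) point and the carrier
# sits at ref_point = n/2.  Bin k (0-based) corresponds to the frequency
# offset (n/2 - k) * sw / n Hz.  The forward transform is unnormalized and
# the inverse carries 1/n, so Parseval reads sum|fid|^2 = sum|spec|^2 / n.

# permutation taking fft() bin order to spectral order (1-based indices)
spec_order <- function(n) ((n %/% 2 - (0:(n - 1))) %% n) + 1

to_spec_order <- function(x) x[spec_order(length(x))]

from_spec_order <- function(x) {
  out <- x
  out[spec_order(length(x))] <- x
  out
}

require_domain <- function(v, freq, what) {
  if (v$meta$freq_domain != freq)
    stop(what, " requires a ", if (freq) "frequency" else "time",
         "-domain vector", call. = FALSE)
}

#' Forward Fourier transform of a trace
#'
#' Discrete Fourier transform with the output reordered so that index 0 is
#' the most downfield point and the carrier sits at the centre
#' (`ref_point = n/2`).  By convention the first time-domain point is
#' halved before the transform (the discrete half-weight of the t=0 sample,
#' which otherwise biases the spectrum baseline); this is skipped when the
#' vector carries a digital-filter group delay, which is instead corrected
#' here as a first-order phase ramp and then cleared.
#'
#' @param v time-domain [nmr_vector()].
#' @param fp_half halve the first point before transforming (default TRUE;
#'   ignored when `group_delay > 0`).
#' @return frequency-domain `nmr_vector`.
#' @export
ft <- function(v, fp_half = TRUE) {
  require_domain(v, FALSE, "FT")
  n <- length(v$values)
  y <- v$values
  gd <- v$group_delay
  if (gd == 0 && fp_half) y[1] <- y[1] / 2
  s <- to_spec_order(stats::fft(y))
  if (gd > 0) {
    k <- 0:(n - 1)
    s <- s * exp(2i * pi * gd * (n / 2 - k) / n)
  }
  # the carrier lands at the centre of the ordered spectrum
  v <- vec_with_values(v, s, freq_domain = TRUE, ref_point = n / 2)
  v$group_delay <- 0
  v
}

#' Inverse Fourier transform of a trace
#'
#' Exact inverse of [ft()] (for vectors without group delay), including the
#' reordering and the first-point convention; normalization 1/n.
#' @param v frequency-domain [nmr_vector()].
#' @param fp_half undo the first-point halving of [ft()] (default TRUE).
#' @return time-domain `nmr_vector`.
#' @export
ift <- function(v, fp_half = TRUE) {
  require_domain(v, TRUE, "IFT")
  n <- length(v$values)
  y <- stats::fft(from_spec_order(v$values), inverse = TRUE) / n
  if (fp_half) y[1] <- y[1] * 2
  vec_with_values(v, y, freq_domain = FALSE)
}

# causal-FID time window used by the Hilbert step: keep point 0, double
# points 1..n/2-1, zero the second half (n/2..n-1)
hilbert_window <- function(n) {
  h <- numeric(n)
  h[1] <- 1
  if (n >= 3) h[2:(n %/% 2)] <- 2
  h
}

#' Hilbert transform: regenerate imaginaries of a real spectrum
#'
#' Under the causal-FID assumption (the time signal is zero over the second
#' half of the grid) the imaginary (dispersive) spectrum component is fully
#' determined by the real (absorptive) one.  The input's imaginary part is
#' ignored: the real spectrum is inverse transformed, the second half of
#' the time trace zeroed, points 1..n/2-1 doubled (first point unchanged),
#' and the result forward transformed.  Idempotent.
#'
#' @param v frequency-domain [nmr_vector()]; only `Re(values)` is used.
#' @return frequency-domain `nmr_vector` with regenerated imaginaries.
#' @export
hft <- function(v) {
  require_domain(v, TRUE, "HFT")
  n <- length(v$values)
  t <- stats::fft(from_spec_order(as.complex(Re(v$values))),
                  inverse = TRUE) / n
  s <- to_spec_order(stats::fft(t * hilbert_window(n)))
  vec_with_values(v, s)
}

#' Apodization window specification
#'
#' * `SB`: sine/cosine bell `sin(pi*offset + pi*(1-offset)*i/(end*(n-1)))^power`;
#'   the default `offset = 0.5` gives a cosine window whose first point is 1.
#' * `EXPD`: exponential line broadening `exp(-pi*lb*t)`, `t = i/sw`.
#' * `GM`: Lorentz-to-Gauss `exp(pi*g1*t - g2^2*t^2*pi/(2*ln 2))`.
#'
#' @param kind `"SB"`, `"EXPD"` or `"GM"`.
#' @param offset sine-bell start, as a fraction of pi (default 0.5).
#' @param end sine-bell extent as a fraction of the trace (default 1).
#' @param power sine-bell exponent, 1 or 2.
#' @param lb exponential line broadening in Hz.
#' @param g1 inverse-exponential sharpening in Hz (GM).
#' @param g2 Gaussian broadening in Hz (GM).
#' @return an `apod_spec` object.
#' @export
apod_spec <- function(kind = c("SB", "EXPD", "GM"), offset = 0.5, end = 1.0,
                      power = 1, lb = 0, g1 = 0, g2 = 0) {
  kind <- match.arg(kind)
  stopifnot(is.finite(offset), is.finite(end), end > 0,
            power %in% c(1, 2), is.finite(lb), is.finite(g1), is.finite(g2))
  structure(list(kind = kind, offset = offset, end = end, power = power,
                 lb = lb, g1 = g1, g2 = g2), class = "apod_spec")
}

#' Evaluate an apodization window
#' @param spec an [apod_spec()].
#' @param n number of points.
#' @param sw sweep width in Hz (sets the dwell time for EXPD/GM).
#' @return numeric window of length `n`.
#' @export
apod_window <- function(spec, n, sw) {
  i <- 0:(n - 1)
  t <- i / sw
  w <- switch(spec$kind,
    SB = sin(pi * spec$offset +
               pi * (1 - spec$offset) * i / (spec$end * (n - 1)))^spec$power,
    EXPD = exp(-pi * spec$lb * t),
    GM = exp(pi * spec$g1 * t - spec$g2^2 * t^2 * pi / (2 * log(2))))
  if (!all(is.finite(w))) stop("non-finite apodization window")
  w
}

#' Apodize (window) a time-domain trace
#' @param v time-domain [nmr_vector()].
#' @param spec an [apod_spec()].
#' @return the windowed `nmr_vector`.
#' @export
apodize <- function(v, spec) {
  require_domain(v, FALSE, "apodization")
  w <- apod_window(spec, length(v$values), v$meta$sw)
  vec_with_values(v, v$values * w)
}

next_pow2 <- function(n) 2 ^ ceiling(log2(n))

#' Zero fill a time-domain trace
#'
#' Appends zeros before transforming, interpolating the spectrum.  The
#' default target length is the smallest power of two at least twice the
#' current length; `factor = k` doubles k more times beyond the next power
#' of two; an explicit `size` overrides both.
#'
#' @param v time-domain [nmr_vector()].
#' @param factor number of doublings past the next power of two (default 1).
#' @param size explicit target length (must be >= current length).
#' @return the zero-filled `nmr_vector`.
#' @export
zf <- function(v, factor = 1, size = NULL) {
  require_domain(v, FALSE, "ZF")
  n <- length(v$values)
  target <- if (!is.null(size)) as.integer(size)
            else as.integer(next_pow2(n) * 2 ^ factor)
  if (target < n) stop("zero-fill size ", target, " is smaller than ", n)
  vec_with_values(v, c(v$values, complex(target - n)))
}

#' Phase specification
#'
#' Zeroth-order (`p0`, degrees, frequency independent) and first-order
#' (`p1`, degrees across the full sweep) phase, with `p1` contributing
#' zero at the fractional pivot index `pivot * n`.
#' @param p0,p1 phase in degrees.
#' @param pivot fractional pivot (0..1), default 0.
#' @return a `phase_spec` object.
#' @export
phase_spec <- function(p0 = 0, p1 = 0, pivot = 0) {
  stopifnot(is.finite(p0), is.finite(p1), is.finite(pivot))
  structure(list(p0 = p0, p1 = p1, pivot = pivot), class = "phase_spec")
}

#' Apply zeroth/first-order phase to a trace
#'
#' Multiplies each point by `exp(1i * theta(i))` with
#' `theta(i) = radians(p0 + p1 * (i - pivot*n)/n)`.  Phasing composes
#' additively: applying `a` then `b` equals applying their summed angles.
#' On magnitude-mode (non-complex) data it is a no-op with a warning.
#'
#' @param v an [nmr_vector()] (normally frequency domain).
#' @param p0 zeroth-order phase in degrees, or a [phase_spec()].
#' @param p1 first-order phase in degrees.
#' @param pivot fractional pivot index.
#' @return the phased `nmr_vector`.
#' @export
phase <- function(v, p0 = 0, p1 = 0, pivot = 0) {
  spec <- if (inherits(p0, "phase_spec")) p0 else phase_spec(p0, p1, pivot)
  if (!v$meta$complex) {
    warning("phase applied to magnitude-mode data is a no-op")
    return(v)
  }
  n <- length(v$values)
  i <- 0:(n - 1)
  theta <- (spec$p0 + spec$p1 * (i - spec$pivot * n) / n) * pi / 180
  vec_with_values(v, v$values * exp(1i * theta))
}

#' Extract an inclusive index range of a trace
#'
#' Keeps points `start..end` (0-based, both inclusive).  On
#' frequency-domain data the sweep width and reference are rescaled so
#' every retained point keeps its chemical shift.
#'
#' @param v an [nmr_vector()].
#' @param start,end 0-based inclusive bounds, `0 <= start <= end < n`.
#' @return the extracted `nmr_vector`.
#' @export
extract_range <- function(v, start, end) {
  n <- length(v$values)
  if (start < 0 || end < start || end >= n)
    stop("extract bounds out of range: [", start, ", ", end, "] of ", n)
  if (start == 0 && end == n - 1) return(v)
  vals <- v$values[(start + 1):(end + 1)]
  m <- length(vals)
  meta <- v$meta
  if (meta$freq_domain) {
    ppm0 <- point_to_ppm(meta, start)
    meta$sw <- meta$sw * m / n
    meta$ref_ppm <- ppm0
    meta$ref_point <- 0
  }
  meta$size <- m
  v$values <- vals
  v$meta <- meta
  v
}

#' Magnitude calculation
#'
#' Replaces every sample by its modulus; the result is real (the complex
#' flag is cleared, so later phasing warns and does nothing).
#' @param v an [nmr_vector()].
#' @return the magnitude `nmr_vector`.
#' @export
magnitude <- function(v)
  vec_with_values(v, as.complex(Mod(v$values)), complex = FALSE)

#' Power calculation (squared modulus)
#' @param v an [nmr_vector()].
#' @return the power `nmr_vector` (real valued).
#' @export
power_spectrum <- function(v)
  vec_with_values(v, as.complex(Mod(v$values)^2), complex = FALSE)

#' Keep only the real part of a trace
#'
#' Discards the imaginary component.  Invertible via [hft()] for causal
#' data.
#' @param v an [nmr_vector()].
#' @return the realified `nmr_vector`.
#' @export
real_part <- function(v) vec_with_values(v, as.complex(Re(v$values)))

#' Reverse a spectrum
#'
#' Mirrors the data and moves the reference anchor with its point, so the
#' reference shift stays attached to the sample that carried it.
#' @param v an [nmr_vector()].
#' @return the reversed `nmr_vector`.
#' @export
reverse_spectrum <- function(v) {
  n <- length(v$values)
  meta <- v$meta
  meta$ref_point <- (n - 1) - meta$ref_point
  v$values <- rev(v$values)
  v$meta <- meta
  v
}

#' Circular shift
#' @param v an [nmr_vector()].
#' @param shift points to rotate by (positive moves content to higher
#'   indices); `|shift| < n`.
#' @return the rotated `nmr_vector`.
#' @export
cshift <- function(v, shift) {
  n <- length(v$values)
  if (abs(shift) >= n) stop("cshift by |", shift, "| >= length ", n)
  k <- ((shift %% n) + n) %% n
  if (k == 0) return(v)
  vec_with_values(v, c(v$values[(n - k + 1):n], v$values[1:(n - k)]))
}

#' Baseline correction by linear offset
#'
#' Subtracts the mean of the outer `fraction` of points at both edges
#' (where a spectrum is expected to be pure baseline).
#' @param v an [nmr_vector()].
#' @param fraction fraction of points per edge used for the mean
#'   (default 0.05).
#' @return the offset-corrected `nmr_vector`.
#' @export
dc_correct <- function(v, fraction = 0.05) {
  n <- length(v$values)
  m <- max(1L, round(fraction * n))
  edges <- c(v$values[1:m], v$values[(n - m + 1):n])
  vec_with_values(v, v$values - mean(edges))
}

#' Linear combination of time-domain traces
#'
#' Forms `out_j = sum_k c[j,k] * in_k` with complex coefficients.  `coef`
#' may be a complex (or real) matrix with one column per input, a real
#' matrix with two columns per input (the pair acting on the real and
#' imaginary coefficient parts, i.e. `c = coef[,2k-1] + 1i*coef[,2k]`), or
#' a named preset: `"echo-antiecho"` converts a P/N-type pair into
#' cosine- and sine-modulated traces
#' (`cos = (e + a)/2`, `sin = (a - e)/(2i)`); `"states"` passes the pair
#' through unchanged; `"add-subtract"` forms the sum and difference.
#'
#' @param vs list of [nmr_vector()] of equal length.
#' @param coef coefficient matrix or preset name.
#' @return list of combined `nmr_vector` objects; inputs are not modified.
#' @export
tdcomb <- function(vs, coef = "echo-antiecho") {
  if (inherits(vs, "nmr_vector")) vs <- list(vs)
  nin <- length(vs)
  if (is.character(coef)) {
    coef <- switch(match.arg(coef, c("echo-antiecho", "states",
                                     "add-subtract")),
      `echo-antiecho` = matrix(c(0.5, 0.5i, 0.5, -0.5i), 2, 2),
      states = diag(2) + 0i,
      `add-subtract` = matrix(c(1, 1, 1, -1), 2, 2) + 0i)
  }
  if (!is.matrix(coef)) stop("coef must be a matrix or preset name")
  if (is.numeric(coef) && ncol(coef) == 2 * nin) {
    coef <- coef[, seq(1, 2 * nin, 2), drop = FALSE] +
      1i * coef[, seq(2, 2 * nin, 2), drop = FALSE]
  }
  if (ncol(coef) != nin)
    stop("coefficient matrix has ", ncol(coef), " columns for ", nin,
         " input vectors")
  lens <- vapply(vs, length, integer(1))
  if (length(unique(lens)) != 1) stop("input vectors differ in length")
  vals <- vapply(vs, vec_values, complex(lens[1]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  lapply(seq_len(nrow(coef)), function(j) {
    out <- as.complex(vals %*% coef[j, ])
    vec_with_values(vs[[1]], out)
  })
}

# zero-phase moving average with reflected edges
moving_average_reflect <- function(x, k) {
  n <- length(x)
  m <- (k - 1) %/% 2
  pad <- c(x[(m + 1):2], x, x[(n - 1):(n - m)])
  kern <- rep(1 / k, k)
  as.complex(stats::filter(Re(pad), kern, sides = 2)[(m + 1):(m + n)]) +
    1i * as.complex(stats::filter(Im(pad), kern, sides = 2)[(m + 1):(m + n)])
}

#' Time-domain solvent suppression
#'
#' Subtracts a zero-phase low-pass-filtered copy of the FID (moving-average
#' kernel spanning roughly `n * width / sw` points, edges handled by
#' reflection), removing the slowly varying on-carrier solvent component
#' while leaving off-carrier signals largely intact.
#'
#' @param v time-domain [nmr_vector()].
#' @param width filter band in Hz (default 50); must be `< sw`.
#' @return the suppressed `nmr_vector`.
#' @export
tdss <- function(v, width = 50) {
  require_domain(v, FALSE, "TDSS")
  if (width >= v$meta$sw) stop("TDSS width must be below the sweep width")
  n <- length(v$values)
  k <- max(3L, as.integer(round(n * width / v$meta$sw)))
  if (k %% 2 == 0) k <- k + 1L
  if (k >= n) k <- if (n %% 2 == 0) n - 1L else n - 2L
  low <- moving_average_reflect(v$values, k)
  vec_with_values(v, v$values - low)
}

#' Frequency-domain solvent suppression
#'
#' Multiplies the spectrum by a cosine-tapered notch of the stated width
#' centred on the carrier (the reference point): the attenuation factor is
#' 0 at the notch centre and rises smoothly to 1 at the notch edges.
#'
#' @param v frequency-domain [nmr_vector()].
#' @param width notch width in Hz (default 50); must be `< sw`.
#' @return the notched `nmr_vector`.
#' @export
fdss <- function(v, width = 50) {
  require_domain(v, TRUE, "FDSS")
  if (width >= v$meta$sw) stop("FDSS width must be below the sweep width")
  n <- length(v$values)
  hw <- (width / 2) * n / v$meta$sw
  d <- abs((0:(n - 1)) - v$meta$ref_point)
  factor <- ifelse(d >= hw, 1, 0.5 - 0.5 * cos(pi * d / hw))
  vec_with_values(v, v$values * factor)
}
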