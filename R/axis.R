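#' Axis metadata for one spectral dimension
#'
#' An `axis_meta` object carries everything needed to map point indices to
#' chemical shifts on one dimension: the number of points, the sweep width
#' (Hz), the spectrometer frequency (MHz), and a reference anchor -- the
#' chemical shift `ref_ppm` that applies at the (possibly fractional)
#' 0-based index `ref_point`.  By convention the reference sits at the
#' centre of the axis (`ref_point = size/2`), i.e. the carrier frequency
#' carries the reference shift.
#'
#' Point indices are 0-based throughout the package.  Chemical shift
#' decreases as the point index increases (downfield is to the left, at
#' index 0).
#'
#' @param size number of points (>= 1).
#' @param sw sweep width in Hz (> 0).
#' @param sf spectrometer frequency in MHz (> 0).
#' @param ref_ppm chemical shift (ppm) at `ref_point`.
#' @param ref_point fractional 0-based index where `ref_ppm` applies;
#'   defaults to `size/2`.
#' @param label axis name.
#' @param nucleus one of `"H"`, `"C"`, `"N"`, `"P"`, `"D"`, `"other"`.
#' @param complex logical; do the values along this axis represent
#'   interleaved real/imaginary pairs?
#' @param freq_domain logical; has this axis been Fourier transformed?
#' @return an object of class `axis_meta`.
#' @export
axis_meta <- function(size, sw, sf, ref_ppm = 0, ref_point = size / 2,
                      label = "", nucleus = "H", complex = TRUE,
                      freq_domain = FALSE) {
  size <- as.integer(size)
  stopifnot(length(size) == 1L, size >= 1L, is.finite(sw), sw > 0,
            is.finite(sf), sf > 0, is.finite(ref_ppm), is.finite(ref_point))
  nucleus <- match.arg(nucleus, c("H", "C", "N", "P", "D", "other"))
  structure(list(size = size, sw = as.numeric(sw), sf = as.numeric(sf),
                 ref_ppm = as.numeric(ref_ppm),
                 ref_point = as.numeric(ref_point),
                 label = as.character(label), nucleus = nucleus,
                 complex = isTRUE(complex), freq_domain = isTRUE(freq_domain)),
            class = "axis_meta")
}

#' @export
print.axis_meta <- function(x, ...) {
  cat(sprintf(
    "<axis_meta> %s[%s] %d pts, sw %.6g Hz, sf %.8g MHz, ref %.6g ppm @ %.6g%s%s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)", x$nucleus, x$size,
    x$sw, x$sf, x$ref_ppm, x$ref_point,
    if (x$complex) ", complex" else "",
    if (x$freq_domain) ", freq" else ", time"))
  invisible(x)
}

#' Convert a chemical shift to a fractional point index
#'
#' The axis is linear in frequency: one point spans `sw/size` Hz, i.e.
#' `sw/(sf*size)` ppm.  Shift decreases with increasing index, so
#' `ppm(p) = ref_ppm + (sw/sf) * (ref_point - p) / size`.
#' Out-of-range shifts map to out-of-range fractional indices; no error is
#' raised.
#'
#' @param meta an [axis_meta()].
#' @param shift chemical shift(s) in ppm.
#' @return fractional 0-based point index (vectorised).
#' @seealso [point_to_ppm()]
#' @export
ppm_to_point <- function(meta, shift) {
  stopifnot(inherits(meta, "axis_meta"))
  meta$ref_point + (meta$ref_ppm - shift) * meta$sf * meta$size / meta$sw
}

#' Convert a fractional point index to a chemical shift
#'
#' Inverse of [ppm_to_point()].
#'
#' @param meta an [axis_meta()].
#' @param point fractional 0-based point index (vectorised).
#' @return chemical shift in ppm.
#' @export
point_to_ppm <- function(meta, point) {
  stopifnot(inherits(meta, "axis_meta"))
  meta$ref_ppm + (meta$ref_point - point) * meta$sw / (meta$sf * meta$size)
}

#' Hz offset from the carrier for a point index
#'
#' Frequency offset (Hz) of a point relative to the axis reference point;
#' positive offsets are downfield (towards index 0).
#' @param meta an [axis_meta()].
#' @param point fractional 0-based index.
#' @return offset in Hz.
#' @export
point_to_hz <- function(meta, point) {
  (meta$ref_point - point) * meta$sw / meta$size
}
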