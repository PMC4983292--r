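#' A single NMR trace with axis metadata
#'
#' The unit every processing operation transforms: one ordered sequence of
#' complex samples plus the [axis_meta()] of the dimension it runs along,
#' the integer coordinates of the trace within its parent dataset, and the
#' vendor digital-filter group delay (points; 0 when absent).
#'
#' @param values complex (or numeric, promoted to complex) samples.
#' @param meta an [axis_meta()]; its `size` must equal `length(values)`.
#'   If omitted, a default axis of matching size is constructed.
#' @param location integer coordinates of this trace within its dataset
#'   (one per remaining dimension; empty for standalone vectors).
#' @param group_delay non-negative digital-filter delay in points.
#' @return an object of class `nmr_vector`.
#' @export
nmr_vector <- function(values, meta = NULL, location = integer(),
                       group_delay = 0) {
  values <- as.complex(values)
  if (is.null(meta)) meta <- axis_meta(length(values), sw = 1, sf = 1)
  stopifnot(inherits(meta, "axis_meta"), meta$size == length(values),
            group_delay >= 0)
  structure(list(values = values, meta = meta,
                 location = as.integer(location),
                 group_delay = as.numeric(group_delay)),
            class = "nmr_vector")
}

#' @export
print.nmr_vector <- function(x, ...) {
  cat(sprintf("<nmr_vector> %d pts (%s domain)%s\n", length(x$values),
              if (x$meta$freq_domain) "frequency" else "time",
              if (x$group_delay > 0)
                sprintf(", group delay %.4g", x$group_delay) else ""))
  print(x$meta)
  n <- min(4L, length(x$values))
  cat("  values[1..", n, "]: ", paste(format(x$values[seq_len(n)], digits = 4),
                                      collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.nmr_vector <- function(x) length(x$values)

# internal: replace values, updating the axis size
vec_with_values <- function(v, values, ...) {
  values <- as.complex(values)
  extra <- list(...)
  m <- v$meta
  m$size <- length(values)
  for (nm in names(extra)) m[[nm]] <- extra[[nm]]
  v$values <- values
  v$meta <- m
  v
}

#' Extract the sample values of a trace
#' @param v an [nmr_vector()].
#' @return complex vector of samples.
#' @export
vec_values <- function(v) v$values
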