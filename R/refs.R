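# Chemical-shift referencing: numeric values, symbolic parameter lookup,
# water referencing at the experiment temperature, indirect heteronuclear
# ratios, and anchored "ppm@MHz" references.

#' Indirect referencing frequency ratios
#'
#' Ratios of the zero-ppm frequency of each nucleus to the zero-ppm
#' (DSS) proton frequency, used to reference heteronuclear axes from a
#' correctly referenced proton axis (Wishart et al. 1995 values).
#' @format named numeric vector (`D`, `C`, `N`, `P`).
#' @export
XI_RATIOS <- c(D = 0.153506088, C = 0.251449530, N = 0.101329118,
               P = 0.404808636)

#' Chemical shift of water at a given temperature
#'
#' The widely used linear relation `delta = 7.83 - T / 96.9` with T in
#' kelvin (about 4.75 ppm at 25 C).
#' @param temp_k temperature in kelvin.
#' @return shift in ppm.
#' @export
water_shift <- function(temp_k) 7.83 - temp_k / 96.9

# pull the experiment temperature (kelvin) out of a parameter set
experiment_temperature <- function(params) {
  cand <- c("TE", "temp", "TEMP")
  for (nm in cand) {
    v <- tryCatch(p(params, nm), error = function(e) NULL)
    if (is.numeric(v) && length(v) == 1 && is.finite(v)) {
      # Bruker TE is kelvin; Agilent temp is Celsius.  Values under 150
      # cannot be sample temperatures in kelvin.
      return(if (v < 150) v + 273.15 else v)
    }
  }
  stop("'h2o' referencing requires a temperature parameter ",
       "(TE or temp) in the parameter set")
}

resolve_numeric <- function(x, params, what) {
  if (is.numeric(x)) return(x)
  if (is.character(x)) {
    if (is.null(params))
      stop("symbolic ", what, " '", x, "' needs a parameter set")
    v <- p(params, x)
    if (!is.numeric(v)) stop("parameter '", x, "' is not numeric")
    return(v)
  }
  stop("cannot resolve ", what, " from ", class(x)[1])
}

ref_arg_for_dim <- function(ref_cmd, d) {
  if (is.null(ref_cmd) || length(ref_cmd) < d) NULL else ref_cmd[[d]]
}

#' Resolve referencing commands into axis metadata
#'
#' Applies a plan's `sw`/`sf`/`ref`/`label` commands, in the presence of a
#' vendor parameter set, to produce one [axis_meta()] per dimension:
#'
#' * `sw`/`sf` arguments are numbers or parameter symbols (Bruker
#'   `"name,n"` syntax supported).
#' * `ref` arguments: a number is the carrier shift in ppm; `'h2o'` is the
#'   water shift at the experiment temperature; a nucleus letter
#'   (`'C'`, `'N'`, `'P'`, `'D'`) derives the axis reference from the
#'   proton axis via the indirect ratios [XI_RATIOS]; `"ppm@MHz"` anchors
#'   the stated shift at the stated absolute frequency.
#'
#' The reference point is the centre of each axis (the carrier).
#'
#' @param plan a `process_plan` (or a bare list with a `ref` element).
#' @param params optional `param_set`.
#' @param sizes integer vector of complex points per dimension.
#' @return list of [axis_meta()].
#' @export
resolve_refs <- function(plan, params = NULL, sizes) {
  ndim <- length(sizes)
  refc <- plan$ref
  sw_v <- sf_v <- numeric(ndim)
  for (d in seq_len(ndim)) {
    sw_arg <- ref_arg_for_dim(refc$sw, d)
    sf_arg <- ref_arg_for_dim(refc$sf, d)
    sw_v[d] <- if (is.null(sw_arg)) sizes[d]   # placeholder Hz grid
               else resolve_numeric(sw_arg, params, "sw")
    sf_v[d] <- if (is.null(sf_arg)) 1
               else resolve_numeric(sf_arg, params, "sf")
  }
  ref_ppm <- numeric(ndim)
  nucleus <- rep("other", ndim)
  f0_h <- NULL                     # zero-ppm proton frequency, MHz
  deferred <- integer(0)
  for (d in seq_len(ndim)) {
    r <- ref_arg_for_dim(refc$ref, d)
    if (is.null(r)) { ref_ppm[d] <- 0; next }
    if (is.numeric(r)) {
      ref_ppm[d] <- r
      if (d == 1) nucleus[d] <- "H"
    } else if (identical(r, "h2o")) {
      ref_ppm[d] <- water_shift(experiment_temperature(params))
      nucleus[d] <- "H"
    } else if (grepl("@", r)) {
      parts <- strsplit(r, "@", fixed = TRUE)[[1]]
      delta0 <- as.numeric(parts[1])
      anchor <- as.numeric(parts[2])
      f0 <- anchor / (1 + delta0 * 1e-6)
      ref_ppm[d] <- (sf_v[d] - f0) / f0 * 1e6
      if (d == 1) nucleus[d] <- "H"
    } else if (r %in% names(XI_RATIOS)) {
      deferred <- c(deferred, d)
      nucleus[d] <- r
    } else {
      stop("cannot interpret reference '", r, "' for dimension ", d)
    }
    if (d == 1 && nucleus[1] == "H")
      f0_h <- sf_v[1] / (1 + ref_ppm[1] * 1e-6)
  }
  if (length(deferred)) {
    if (is.null(f0_h))
      stop("nucleus-letter referencing requires a resolved proton axis ",
           "(dimension 1)")
    for (d in deferred) {
      f0_x <- XI_RATIOS[[nucleus[d]]] * f0_h
      ref_ppm[d] <- (sf_v[d] - f0_x) / f0_x * 1e6
    }
  }
  labels <- vapply(seq_len(ndim), function(d) {
    l <- ref_arg_for_dim(refc$label, d)
    if (is.null(l)) paste0("D", d) else as.character(l)
  }, character(1))
  lapply(seq_len(ndim), function(d)
    axis_meta(sizes[d], sw = sw_v[d], sf = sf_v[d], ref_ppm = ref_ppm[d],
              label = labels[d],
              nucleus = if (nucleus[d] %in% c("H", "C", "N", "P", "D"))
                nucleus[d] else "other",
              complex = TRUE, freq_domain = FALSE))
}

#' Which dimensions does a plan skip?
#' @param plan a `process_plan`.
#' @param ndim number of dimensions.
#' @return logical vector, TRUE for skipped dimensions.
#' @export
plan_skip <- function(plan, ndim) {
  sk <- plan$ref$skip
  out <- logical(ndim)
  if (!is.null(sk))
    for (d in seq_len(min(ndim, length(sk)))) out[d] <- sk[[d]] == 1
  out
}
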