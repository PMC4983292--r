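# Model-fitting operations: baseline regions and correction, linear
# prediction, automatic phasing.

#' Baseline region of a trace
#' @param start,end 0-based inclusive point indices, `start <= end`.
#' @return a `region` object.
#' @export
region <- function(start, end) {
  stopifnot(start >= 0, end >= start)
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "region")
}

region_points <- function(r, n) {
  if (r$end >= n) stop("region end ", r$end, " beyond axis size ", n)
  (r$start:r$end) + 1L
}

#' Annotate a spectrum with baseline regions
#'
#' Marks which points the next baseline-correction operation should treat
#' as signal-free.  The data are unchanged.  With an empty region list the
#' baseline is estimated automatically: points whose magnitude is below
#' `median + 3 * MAD` of the magnitude spectrum are taken as baseline.
#'
#' @param v frequency-domain [nmr_vector()].
#' @param regions list of [region()] objects (possibly empty for
#'   auto-estimation).
#' @return `v` with a `baseline_points` attribute (1-based indices).
#' @export
regions <- function(v, regions = list()) {
  require_domain(v, TRUE, "REGIONS")
  if (inherits(regions, "region")) regions <- list(regions)
  n <- length(v$values)
  if (length(regions) == 0) {
    a <- abs(Re(v$values))
    thr <- stats::median(a) + 3 * stats::mad(a)
    pts <- which(a <= thr)
  } else {
    pts <- sort(unlist(lapply(regions, region_points, n = n)))
    if (anyDuplicated(pts)) stop("baseline regions overlap")
  }
  attr(v, "baseline_points") <- pts
  v
}

baseline_pts <- function(v) {
  pts <- attr(v, "baseline_points")
  if (is.null(pts)) {
    v2 <- regions(v)
    pts <- attr(v2, "baseline_points")
  }
  pts
}

#' Polynomial baseline correction
#'
#' Fits a least-squares polynomial of the given order to the real part
#' over the baseline regions (annotated by [regions()] or auto-estimated)
#' and subtracts it from the whole trace.  The imaginary part is left
#' untouched.
#'
#' @param v frequency-domain [nmr_vector()].
#' @param order polynomial order (>= 0); must be below the number of
#'   baseline points.
#' @return the corrected `nmr_vector`.
#' @export
bcpoly <- function(v, order = 2) {
  require_domain(v, TRUE, "BCPOLY")
  n <- length(v$values)
  pts <- baseline_pts(v)
  if (order >= length(pts))
    stop("polynomial order ", order, " too high for ", length(pts),
         " baseline points")
  x <- (pts - 1) / (n - 1)            # scaled abscissa for conditioning
  y <- Re(v$values)[pts]
  X <- outer(x, 0:order, `^`)
  coef <- qr.coef(qr(X), y)
  coef[is.na(coef)] <- 0
  xf <- (seq_len(n) - 1) / (n - 1)
  base <- outer(xf, 0:order, `^`) %*% coef
  vec_with_values(v, complex(real = Re(v$values) - as.numeric(base),
                             imaginary = Im(v$values)))
}

#' Whittaker (asymmetric least squares) baseline correction
#'
#' Estimates a smooth baseline as the minimizer of
#' `sum w_i (y_i - z_i)^2 + lambda * sum (diff(z, 2))^2`, iterating the
#' asymmetric weights (`p` for points above the smooth, `1 - p` below)
#' until the weights change by less than 1e-6 or 50 iterations, then
#' subtracts it.  Peaks, which sit far above the smooth, receive weight
#' `p` (tiny) and so do not drag the baseline up.
#'
#' @param v frequency-domain [nmr_vector()].
#' @param lambda smoothness penalty (> 0); larger is stiffer.
#' @param asymmetry `p` in (0, 1); weight given to points above the
#'   baseline.
#' @param iterations maximum reweighting iterations.
#' @return the corrected `nmr_vector`.
#' @export
bcwhit <- function(v, lambda = 1e7, asymmetry = 0.001, iterations = 50) {
  require_domain(v, TRUE, "BCWHIT")
  if (lambda <= 0) stop("lambda must be positive")
  stopifnot(asymmetry > 0, asymmetry < 1)
  y0 <- Re(v$values)
  mu <- mean(y0)
  y <- y0 - mu          # centring: a flat spectrum is corrected exactly
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iterations)) {
    A <- DtD + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
    if (max(abs(w_new - w)) < 1e-6) { w <- w_new; break }
    w <- w_new
  }
  vec_with_values(v, complex(real = y - z, imaginary = Im(v$values)))
}

#' Linear-prediction model specification
#'
#' @param ncoef autoregressive prediction order.
#' @param fit_range [region()] of points used for coefficient fitting
#'   (default: the whole trace).
#' @param predict_count points to append ([lp_extend()]) or overwrite
#'   ([lp_replace()]).
#' @param direction `"forward"`, `"backward"`, or `"forward-backward"`
#'   (average of coefficients fitted both ways).
#' @param stabilize reflect characteristic roots outside the unit circle
#'   into it, preventing growing predictions (default TRUE).
#' @return an `lp_model` object.
#' @export
lp_model <- function(ncoef = 8, fit_range = NULL, predict_count = NULL,
                     direction = c("forward", "backward",
                                   "forward-backward"),
                     stabilize = TRUE) {
  direction <- match.arg(direction)
  structure(list(ncoef = as.integer(ncoef), fit_range = fit_range,
                 predict_count = predict_count, direction = direction,
                 stabilize = isTRUE(stabilize)), class = "lp_model")
}

# least-squares AR coefficients via SVD with relative truncation 1e-10.
# Predicts x[t] = sum_k a[k] x[t-k] over the fit segment.
ar_fit <- function(x, m) {
  n <- length(x)
  if (m >= n) stop("LP order ", m, " >= ", n, " fit points")
  if (all(x == 0)) return(rep(0i, m))
  rows <- n - m
  A <- matrix(0i, rows, m)
  for (k in seq_len(m)) A[, k] <- x[(m - k + 1):(n - k)]
  b <- x[(m + 1):n]
  sv <- svd(A)
  keep <- sv$d > 1e-10 * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  as.complex(sv$v %*% (dinv * (Conj(t(sv$u)) %*% b)))
}

# reflect roots of z^m - a1 z^(m-1) - ... - am outside the unit circle
stabilize_coef <- function(a) {
  m <- length(a)
  roots <- polyroot(c(-rev(a), 1))
  bad <- Mod(roots) > 1
  if (!any(bad)) return(a)
  roots[bad] <- roots[bad] / Mod(roots[bad])^2   # reflect: 1/conj(r)
  # rebuild monic polynomial z^m - a1 z^(m-1) ... : coefficients from roots
  coef <- 1 + 0i
  for (r in roots) coef <- c(coef, 0i) - c(0i, coef * r)
  # coef = c(1, c1, ..., cm) for z^m + c1 z^(m-1) + ...; a_k = -c_k
  -coef[-1]
}

lp_coefficients <- function(x, model, backward = FALSE) {
  seg <- if (is.null(model$fit_range)) x
         else x[region_points(model$fit_range, length(x))]
  if (all(seg == 0)) return(rep(0i, model$ncoef))
  fit_one <- function(s) {
    a <- ar_fit(s, model$ncoef)
    if (model$stabilize) stabilize_coef(a) else a
  }
  if (backward) fit_one(rev(seg))
  else if (model$direction == "forward-backward")
    (fit_one(seg) + Conj(fit_one(Conj(rev(seg))))) / 2
  else fit_one(seg)
}

ar_predict <- function(x, a, count) {
  m <- length(a)
  buf <- c(x, complex(count))
  n <- length(x)
  for (t in seq_len(count))
    buf[n + t] <- sum(a * buf[(n + t - 1):(n + t - m)])
  buf[(n + 1):(n + count)]
}

#' Extend a time-domain trace by linear prediction
#'
#' Fits autoregressive coefficients by SVD-truncated least squares over
#' the fit range and appends forward-predicted points.  With
#' `stabilize = TRUE` (default) characteristic roots outside the unit
#' circle are reflected inside, so predictions of decaying signals cannot
#' grow.
#'
#' @param v time-domain [nmr_vector()].
#' @param model an [lp_model()]; its `predict_count` defaults to `n/2`.
#' @return the extended `nmr_vector`.
#' @export
lp_extend <- function(v, model = lp_model()) {
  require_domain(v, FALSE, "LP")
  n <- length(v$values)
  count <- if (is.null(model$predict_count)) n %/% 2
           else model$predict_count
  a <- lp_coefficients(v$values, model)
  pred <- ar_predict(v$values, a, count)
  if (!all(is.finite(Re(pred)) & is.finite(Im(pred))))
    stop("linear prediction produced non-finite values")
  vec_with_values(v, c(v$values, pred))
}

#' Replace initial points by backward linear prediction
#'
#' Fits backward AR coefficients (on the reversed trace) and overwrites
#' the first `predict_count` points -- typically corrupted by the
#' receiver -- with backward predictions from the clean interior.
#'
#' @param v time-domain [nmr_vector()].
#' @param model an [lp_model()]; `predict_count` is the number of initial
#'   points to replace (default 2).
#' @return the repaired `nmr_vector`.
#' @export
lp_replace <- function(v, model = lp_model()) {
  require_domain(v, FALSE, "LPR")
  n <- length(v$values)
  count <- if (is.null(model$predict_count)) 2L else model$predict_count
  stopifnot(count < n)
  # fit on the clean interior, excluding the points being replaced
  interior_model <- model
  if (is.null(interior_model$fit_range))
    interior_model$fit_range <- region(count, n - 1)
  seg_pts <- region_points(interior_model$fit_range, n)
  # no root reflection here: on the reversed trace a decaying signal is a
  # growing one, and its characteristic roots legitimately sit outside the
  # unit circle for the few points being re-predicted
  a <- ar_fit(rev(v$values[seg_pts]), model$ncoef)
  pred <- ar_predict(rev(v$values[seg_pts]), a,
                     min(seg_pts) - 1)
  vals <- v$values
  vals[(min(seg_pts) - 1):1] <- pred
  vec_with_values(v, vals)
}

negative_area_penalty <- function(re) {
  base <- stats::median(re)
  r <- re - base
  sum(pmin(r, 0)^2)
}

#' Automatic phasing
#'
#' Finds the phase that minimizes the negative-area penalty
#' `sum(min(Re - median, 0)^2)` of the phased spectrum: an absorption-mode
#' spectrum of positive peaks has essentially no area below the baseline,
#' so dispersive character is penalized.  A coarse 5-degree grid search is
#' refined by golden-section (p0-only) or Nelder-Mead (p0+p1).
#' Deterministic for a fixed input.
#'
#' @param v frequency-domain complex [nmr_vector()].
#' @param mode `"p0"` (zeroth order only) or `"p0p1"`.
#' @return a [phase_spec()] with the correcting phase (apply it with
#'   [phase()] to phase the spectrum).
#' @export
autophase <- function(v, mode = c("p0", "p0p1")) {
  mode <- match.arg(mode)
  require_domain(v, TRUE, "AUTOPHASE")
  if (all(v$values == 0)) stop("cannot autophase an all-zero vector")
  n <- length(v$values)
  i <- 0:(n - 1)
  obj0 <- function(p0) {
    negative_area_penalty(Re(v$values * exp(1i * p0 * pi / 180)))
  }
  grid <- seq(-180, 175, by = 5)
  if (mode == "p0") {
    vals <- vapply(grid, obj0, numeric(1))
    best <- grid[which.min(vals)]
    opt <- stats::optimize(obj0, lower = best - 5, upper = best + 5,
                           tol = 1e-4)
    phase_spec(p0 = opt$minimum)
  } else {
    obj <- function(par) {
      theta <- (par[1] + par[2] * i / n) * pi / 180
      negative_area_penalty(Re(v$values * exp(1i * theta)))
    }
    grid1 <- seq(-90, 90, by = 15)
    combos <- expand.grid(p0 = grid, p1 = grid1)
    vals <- apply(combos, 1, obj)
    start <- as.numeric(combos[which.min(vals), ])
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    phase_spec(p0 = opt$par[1], p1 = opt$par[2])
  }
}
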