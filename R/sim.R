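# Synthetic FID generation and sampling-schedule construction.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' One simulated resonance
#' @param shift chemical shift in ppm.
#' @param amplitude peak amplitude (> 0).
#' @param linewidth Lorentzian full width at half maximum in Hz (> 0).
#' @param phase phase of the resonance in degrees.
#' @return a `sim_peak` object.
#' @export
sim_peak <- function(shift, amplitude = 1, linewidth = 10, phase = 0) {
  stopifnot(amplitude > 0, linewidth > 0)
  structure(list(shift = shift, amplitude = amplitude,
                 linewidth = linewidth, phase = phase), class = "sim_peak")
}

#' Simulated acquisition description
#'
#' Defines a synthetic FID: a sum of exponentially decaying complex
#' sinusoids plus complex Gaussian noise.  The carrier sits at
#' `carrier_ppm` (the centre of the spectrum); each peak's frequency is its
#' offset from the carrier.  Identical specs (including `seed`) produce
#' bit-identical FIDs.
#'
#' @param sf spectrometer frequency in MHz.
#' @param sw sweep width in Hz.
#' @param size number of complex points.
#' @param peaks list of [sim_peak()] objects.
#' @param noise_sigma per-sample Gaussian standard deviation (real and
#'   imaginary channels independently).
#' @param seed RNG seed for the noise.
#' @param carrier_ppm chemical shift of the carrier (default 4.73, the
#'   water resonance region).
#' @return a `sim_spec` object.
#' @export
sim_spec <- function(sf, sw, size, peaks = list(), noise_sigma = 0,
                     seed = 1L, carrier_ppm = 4.73) {
  if (inherits(peaks, "sim_peak")) peaks <- list(peaks)
  stopifnot(sf > 0, sw > 0, size >= 1, noise_sigma >= 0,
            all(vapply(peaks, inherits, logical(1), "sim_peak")))
  for (pk in peaks) {
    if (pk$linewidth >= sw / 2) stop("linewidth must be below sw/2")
    if (abs(pk$shift - carrier_ppm) * sf > sw / 2)
      stop("peak at ", pk$shift, " ppm lies outside the sweep")
  }
  structure(list(sf = sf, sw = sw, size = as.integer(size), peaks = peaks,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 carrier_ppm = carrier_ppm), class = "sim_spec")
}

#' Simulate a free-induction decay
#'
#' `fid(t_i) = sum_k A_k exp(i(2 pi f_k t_i + phi_k)) exp(-pi lw_k t_i)`
#' with `t_i = i/sw` and `f_k` the Hz offset of peak k from the carrier,
#' plus complex Gaussian noise.  The Lorentzian decay `exp(-pi lw t)`
#' makes `lw` the full width at half maximum of the transformed line.
#'
#' @param spec a [sim_spec()].
#' @return a time-domain [nmr_vector()] whose axis carries the
#'   acquisition description's sw/sf and the carrier shift at the centre.
#' @export
simulate_fid <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$size
  t <- (0:(n - 1)) / spec$sw
  vals <- complex(n)
  for (pk in spec$peaks) {
    f <- (pk$shift - spec$carrier_ppm) * spec$sf
    vals <- vals + pk$amplitude *
      exp(1i * (2 * pi * f * t + pk$phase * pi / 180)) *
      exp(-pi * pk$linewidth * t)
  }
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed, complex(
      real = stats::rnorm(n, 0, spec$noise_sigma),
      imaginary = stats::rnorm(n, 0, spec$noise_sigma)))
    vals <- vals + noise
  }
  meta <- axis_meta(n, sw = spec$sw, sf = spec$sf,
                    ref_ppm = spec$carrier_ppm, label = "sim",
                    complex = TRUE, freq_domain = FALSE)
  nmr_vector(vals, meta)
}

#' Generate a non-uniform sampling schedule
#'
#' Selects `round(fraction * grid)` increment indices on the full Nyquist
#' grid.  Index 0 (the first increment) is always included.  `"uniform"`
#' draws uniformly without replacement; `"poisson-gap"` draws inter-sample
#' gaps from sinusoidally weighted Poisson variates (larger gaps in the
#' decayed tail of the FID), retrying the rate parameter until the exact
#' count is hit.  Deterministic for a given seed.
#'
#' @param grid full grid length.
#' @param fraction sampled fraction in (0, 1]; `fraction * grid >= 2`
#'   unless `fraction` is 1 and the grid is a single point.
#' @param mode `"uniform"` or `"poisson-gap"`.
#' @param seed RNG seed.
#' @return a [sample_schedule()].
#' @export
make_schedule <- function(grid, fraction, mode = c("uniform", "poisson-gap"),
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(grid >= 1, fraction > 0, fraction <= 1)
  target <- round(fraction * grid)
  if (target < 2 && grid > 1) stop("fraction * grid must be at least 2")
  if (target >= grid) return(sample_schedule(0:(grid - 1), grid))
  idx <- with_seed(seed, {
    if (mode == "uniform") {
      sort(c(0L, sample(seq_len(grid - 1), target - 1L)))
    } else {
      poisson_gap_indices(grid, target)
    }
  })
  sample_schedule(idx, grid)
}

# sinusoidally weighted poisson-gap schedule; adjusts the rate until the
# draw has exactly `target` indices
poisson_gap_indices <- function(grid, target) {
  lambda <- grid / target - 1
  for (attempt in 1:500) {
    x <- 0
    idx <- integer(0)
    while (x < grid) {
      idx <- c(idx, x)
      g <- stats::rpois(1, lambda * sin((x + 0.5) / grid * pi / 2) * 2)
      x <- x + 1 + g
    }
    k <- length(idx)
    if (k == target) return(as.integer(idx))
    lambda <- lambda * if (k > target) 1.02 else 1 / 1.02
  }
  stop("poisson-gap schedule did not converge to the requested count")
}

#' The teaching scenario: a 600 MHz single-line FID at 20% sampling
#'
#' Simulates a noiseless single-resonance FID as if recorded on a 600 MHz
#' spectrometer with a 4000 Hz sweep width and a 10 Hz linewidth
#' (4096 complex points, peak 1000 Hz downfield of the carrier, amplitude
#' 1), then zeroes 80% of the points according to a seeded uniform random
#' schedule.  Returns both the undersampled trace and the fully sampled
#' reference so reconstruction error can be measured.
#'
#' @param schedule_seed seed for the random schedule (default 1745).
#' @param fraction sampled fraction (default 0.2).
#' @return list with elements `nus` (time-domain [nmr_vector()], zeros at
#'   unsampled points), `schedule` ([sample_schedule()]) and `reference`
#'   (the fully sampled [nmr_vector()]).
#' @export
fig5_scenario <- function(schedule_seed = 1745L, fraction = 0.2) {
  spec <- sim_spec(sf = 600, sw = 4000, size = 4096,
                   peaks = sim_peak(4.73 + 1000 / 600, amplitude = 1,
                                    linewidth = 10),
                   noise_sigma = 0)
  reference <- simulate_fid(spec)
  sched <- make_schedule(spec$size, fraction, "uniform", schedule_seed)
  vals <- reference$values
  keep <- logical(spec$size)
  keep[sched$indices + 1] <- TRUE
  vals[!keep] <- 0
  list(nus = vec_with_values(reference, vals), schedule = sched,
       reference = reference)
}
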