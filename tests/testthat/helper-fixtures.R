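# Shared builders for synthetic data used across the suite.  Everything is
# generated in code; no binary fixtures are stored.

# a standard proton-like axis
h_axis <- function(n = 1024, sw = 4000, sf = 600, ref = 4.73,
                   freq = FALSE) {
  axis_meta(n, sw = sw, sf = sf, ref_ppm = ref, freq_domain = freq)
}

# random complex trace
random_vec <- function(n, meta = h_axis(n), seed = 1) {
  set.seed(seed)
  nmr_vector(complex(real = rnorm(n), imaginary = rnorm(n)), meta)
}

# brute-force DFT in the package's spectral ordering (independent oracle)
naive_dft <- function(y) {
  n <- length(y)
  bins <- vapply(0:(n - 1), function(k)
    sum(y * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
  bins[((n %/% 2 - 0:(n - 1)) %% n) + 1]
}

# hypercomplex 2D FID: one direct resonance amplitude-modulated in t1
# (States-style cos/sin increment pairs); returns n1 x (2*n2) matrix
make_2d_fid <- function(n1 = 64, n2 = 16, sw1 = 4000, sw2 = 2000,
                        f1 = 600, f2 = 150, r1 = 20, r2 = 15,
                        scale = 1e5) {
  t1 <- (0:(n1 - 1)) / sw1
  t2 <- (0:(n2 - 1)) / sw2
  direct <- exp(2i * pi * f1 * t1 - r1 * t1)
  cosm <- cos(2 * pi * f2 * t2) * exp(-r2 * t2)
  sinm <- sin(2 * pi * f2 * t2) * exp(-r2 * t2)
  m <- matrix(0i, n1, 2 * n2)
  for (j in seq_len(n2)) {
    m[, 2 * j - 1] <- direct * cosm[j]
    m[, 2 * j] <- direct * sinm[j]
  }
  round(m * scale)
}

# write a Bruker fixture holding a 2D hypercomplex FID; returns its dir
make_hsqc_dir <- function(dir, n1 = 64, n2 = 16, ...) {
  write_fixture(dir, "bruker", make_2d_fid(n1 = n1, n2 = n2, ...),
                params = list(SW_h = 4000, SFO1 = 600.13),
                params2 = list(SW_h = 2000, SFO1 = 60.81))
  dir
}

# a Fig-2-style two-dimension processing script for such a fixture
hsqc_script <- function(fid_dir, out_path) {
  paste0(
    "FID('", fid_dir, "')\n",
    "CREATE('", out_path, "')\n",
    "sw(p('SW_h,1'), p('SW_h,2'))\n",
    "sf('SFO1,1', 'SFO1,2')\n",
    "ref(4.73, 'N')\n",
    "label('HN', 'N15')\n",
    "DIM(1)\nSB()\nZF()\nFT()\nPHASE(p0=0, p1=0)\n",
    "EXTRACT(start=0, end=63)\n",
    "DIM(2)\nSB(offset=0.45)\nZF()\nFT()\nPHASE(p0=0)\n",
    "run()\n")
}

# noiseless 3D separable hypercomplex FID array
make_3d_fid <- function(n1 = 16, n2 = 8, n3 = 8) {
  t1 <- (0:(n1 - 1)) / 2000
  t2 <- (0:(n2 - 1)) / 1000
  t3 <- (0:(n3 - 1)) / 500
  d1 <- exp(2i * pi * 300 * t1 - 25 * t1)
  c2 <- cos(2 * pi * 120 * t2) * exp(-20 * t2)
  s2 <- sin(2 * pi * 120 * t2) * exp(-20 * t2)
  c3 <- cos(2 * pi * 60 * t3) * exp(-15 * t3)
  s3 <- sin(2 * pi * 60 * t3) * exp(-15 * t3)
  arr <- array(0i, c(n1, 2 * n2, 2 * n3))
  for (j in seq_len(n2)) for (k in seq_len(n3)) {
    arr[, 2 * j - 1, 2 * k - 1] <- d1 * c2[j] * c3[k]
    arr[, 2 * j, 2 * k - 1] <- d1 * s2[j] * c3[k]
    arr[, 2 * j - 1, 2 * k] <- d1 * c2[j] * s3[k]
    arr[, 2 * j, 2 * k] <- d1 * s2[j] * s3[k]
  }
  arr
}

# fit a Lorentzian linewidth (FWHM in Hz) around the tallest bin of a
# real absorption spectrum by nonlinear least squares (independent of the
# simulator's construction)
fit_linewidth <- function(re_spec, hz_per_point) {
  pk <- which.max(re_spec)
  win <- max(1, pk - 30):min(length(re_spec), pk + 30)
  x <- (win - pk) * hz_per_point
  y <- re_spec[win]
  fit <- stats::nls(y ~ a / (1 + (2 * x / w)^2),
                    start = list(a = max(y), w = 4 * hz_per_point),
                    control = stats::nls.control(warnOnly = TRUE))
  abs(coef(fit)[["w"]])
}
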