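test_that("ft matches a brute-force DFT oracle for n <= 256", {
  for (n in c(32, 100, 256)) {
    v <- random_vec(n, h_axis(n), seed = n)
    s <- ft(v, fp_half = FALSE)
    oracle <- naive_dft(v$values)
    expect_lt(max(abs(s$values - oracle)) / max(abs(oracle)), 1e-9)
    expect_true(s$meta$freq_domain)
  }
})

test_that("ft and ift are mutual inverses across power-of-two lengths", {
  for (n in 2^(6:12)) {
    v <- random_vec(n, h_axis(n), seed = n)
    back <- ift(ft(v))
    expect_lt(max(abs(back$values - v$values)), 1e-10)
    back2 <- ift(ft(v, fp_half = FALSE), fp_half = FALSE)
    expect_lt(max(abs(back2$values - v$values)), 1e-10)
  }
  expect_error(ift(random_vec(64)), "frequency")
  expect_error(ft(ft(random_vec(64))), "time")
})

test_that("the carrier sits at the reference point and zeros transform to
          zeros", {
  n <- 256
  m <- h_axis(n)
  on_carrier <- nmr_vector(rep(1 + 0i, n), m)
  s <- ft(on_carrier, fp_half = FALSE)
  expect_identical(which.max(Mod(s$values)) - 1L, as.integer(n %/% 2))
  z <- ft(nmr_vector(complex(n), m))
  expect_true(all(z$values == 0))
})

test_that("Parseval holds under the documented normalization", {
  v <- random_vec(512, seed = 5)
  s <- ft(v, fp_half = FALSE)
  expect_equal(sum(Mod(v$values)^2), sum(Mod(s$values)^2) / 512,
               tolerance = 1e-12)
})

test_that("a group delay is corrected as a first-order phase during ft", {
  n <- 256
  v <- random_vec(n, seed = 8)
  d <- 5L
  shifted <- nmr_vector(c(v$values[(n - d + 1):n], v$values[1:(n - d)]),
                        v$meta, group_delay = d)
  s0 <- ft(v, fp_half = FALSE)
  s1 <- ft(shifted, fp_half = FALSE)
  expect_lt(max(abs(s1$values - s0$values)) / max(abs(s0$values)), 1e-12)
  expect_identical(s1$group_delay, 0)
})

test_that("hft reproduces the full spectrum of a causal FID and is
          idempotent", {
  for (seed in 1:3) {
    n <- 512
    set.seed(seed)
    x <- complex(real = rnorm(n), imaginary = rnorm(n))
    x[(n / 2 + 1):n] <- 0        # causal: second half of the grid empty
    x[1] <- Re(x[1])
    S <- ft(nmr_vector(x, h_axis(n)), fp_half = FALSE)
    H <- hft(nmr_vector(as.complex(Re(S$values)), S$meta))
    expect_lt(max(abs(H$values - S$values)) / max(abs(S$values)), 1e-9)
    expect_lt(max(abs(hft(H)$values - H$values)), 1e-9)
  }
  flat <- nmr_vector(rep(3 + 0i, 64), h_axis(64, freq = TRUE))
  expect_lt(max(abs(Im(hft(flat)$values))), 1e-9)
})

test_that("apodization windows match their closed forms and divide out", {
  n <- 64
  sw <- 4000
  i <- 0:(n - 1)
  t <- i / sw
  cases <- list(
    list(spec = apod_spec("SB", offset = 0.45),
         oracle = sin(pi * 0.45 + pi * 0.55 * i / (n - 1))),
    list(spec = apod_spec("SB", offset = 0.5, power = 2),
         oracle = sin(pi * 0.5 + pi * 0.5 * i / (n - 1))^2),
    list(spec = apod_spec("EXPD", lb = 12),
         oracle = exp(-pi * 12 * t)),
    list(spec = apod_spec("GM", g1 = 15, g2 = 8),
         oracle = exp(pi * 15 * t - 8^2 * t^2 * pi / (2 * log(2)))))
  for (cs in cases) {
    w <- apod_window(cs$spec, n, sw)
    expect_lt(max(abs(w - cs$oracle)), 1e-12)
  }
  # unit windows
  expect_equal(apod_window(apod_spec("EXPD", lb = 0), n, sw), rep(1, n))
  expect_equal(apod_window(apod_spec("SB"), n, sw)[1], 1)
  # multiply then divide restores the trace when the window is nonzero
  v <- random_vec(n, seed = 2)
  sp <- apod_spec("EXPD", lb = 20)
  w <- apod_window(sp, n, sw)
  restored <- apodize(v, sp)$values / w
  expect_lt(max(abs(restored - v$values)), 1e-10)
})

test_that("zero filling follows the power-of-two default and inverts by
          truncation", {
  v <- random_vec(1000, h_axis(1000))
  expect_length(zf(v)$values, 2048)
  expect_length(zf(random_vec(1024))$values, 2048)
  expect_length(zf(v, size = 1500)$values, 1500)
  expect_error(zf(v, size = 10), "smaller")
  z <- zf(v)
  expect_identical(z$values[1:1000], v$values)
  expect_true(all(z$values[1001:2048] == 0))
  expect_identical(z$meta$size, 2048L)
})

test_that("phasing is additive, 180 degrees negates, and magnitude-mode
          data warn", {
  v <- random_vec(128, h_axis(128, freq = TRUE), seed = 4)
  expect_identical(phase(v, 0, 0)$values, v$values)
  expect_lt(max(abs(phase(v, 180)$values + v$values)), 1e-12)
  ab <- phase(phase(v, 30, 40), 10, 20)
  onestep <- phase(v, 40, 60)
  expect_lt(max(abs(ab$values - onestep$values)), 1e-12)
  m <- magnitude(v)
  expect_warning(pm <- phase(m, 90), "no-op")
  expect_identical(pm$values, m$values)
})

test_that("extract keeps inclusive bounds and the ppm of every retained
          point", {
  v <- random_vec(1024, h_axis(1024, freq = TRUE), seed = 6)
  e <- extract_range(v, 100, 500)
  expect_length(e$values, 401)
  expect_identical(e$values, v$values[101:501])
  for (k in c(0, 200, 400))
    expect_lt(abs(point_to_ppm(e$meta, k) - point_to_ppm(v$meta, 100 + k)),
              1e-9)
  idn <- extract_range(v, 0, 1023)
  expect_identical(idn$values, v$values)
  expect_identical(idn$meta, v$meta)
  expect_error(extract_range(v, -1, 10), "out of range")
  expect_error(extract_range(v, 10, 1024), "out of range")
})

test_that("magnitude, power, reverse, cshift and dc behave as defined", {
  m <- h_axis(64, freq = TRUE)
  v345 <- nmr_vector(rep(3 + 4i, 64), m)
  expect_true(all(magnitude(v345)$values == 5))
  expect_false(magnitude(v345)$meta$complex)
  expect_true(all(power_spectrum(v345)$values == 25))
  v <- random_vec(64, m, seed = 9)
  expect_identical(reverse_spectrum(reverse_spectrum(v))$values, v$values)
  rv <- reverse_spectrum(v)
  # the reference anchor follows its data point through the mirror
  expect_identical(rv$meta$ref_point, 63 - v$meta$ref_point)
  expect_identical(point_to_ppm(rv$meta, rv$meta$ref_point),
                   v$meta$ref_ppm)
  expect_identical(cshift(cshift(v, 5), -5)$values, v$values)
  expect_identical(cshift(v, 0)$values, v$values)
  expect_error(cshift(v, 64), ">= length")
  const <- nmr_vector(rep(2.5 + 1i, 64), m)
  expect_lt(max(abs(dc_correct(const)$values)), 1e-12)
})

test_that("tdcomb forms the specified linear combinations", {
  v <- random_vec(32, seed = 10)
  idn <- tdcomb(list(v, v), diag(2))
  expect_identical(idn[[1]]$values, v$values)
  sums <- tdcomb(list(v, v), matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE))
  expect_lt(max(abs(sums[[1]]$values - 2 * v$values)), 1e-12)
  expect_true(all(abs(sums[[2]]$values) < 1e-12))
  # echo/antiecho: e = c(t) exp(-i w t), a = c(t) exp(+i w t)
  t <- (0:31) / 1000
  cmod <- exp(-20 * t)
  w <- 2 * pi * 180
  e <- nmr_vector(cmod * exp(-1i * w * t), h_axis(32))
  a <- nmr_vector(cmod * exp(+1i * w * t), h_axis(32))
  out <- tdcomb(list(e, a), "echo-antiecho")
  expect_lt(max(abs(out[[1]]$values - cmod * cos(w * t))), 1e-9)
  expect_lt(max(abs(out[[2]]$values - cmod * sin(w * t))), 1e-9)
  expect_error(tdcomb(list(v), matrix(1, 2, 3)), "columns")
})

test_that("solvent suppression removes on-carrier signal and spares
          off-carrier signal", {
  n <- 1024
  m <- h_axis(n, sw = 4000)
  t <- (0:(n - 1)) / 4000
  on_c <- nmr_vector(exp(-5 * t) + 0i, m)
  sup <- tdss(on_c, width = 100)
  expect_lt(max(Mod(sup$values)) / max(Mod(on_c$values)), 0.01)
  off <- nmr_vector(exp(2i * pi * 1000 * t - 5 * t), m)
  kept <- tdss(off, width = 100)
  mid <- 100:900   # away from filter edge transients
  expect_lt(max(Mod(kept$values[mid] - off$values[mid])) /
              max(Mod(off$values)), 0.05)
  # FDSS: attenuation factor is exactly 0 at the notch centre
  sp <- ft(off)
  notched <- fdss(nmr_vector(rep(1 + 1i, n),
                             h_axis(n, sw = 4000, freq = TRUE)),
                  width = 200)
  expect_identical(notched$values[n / 2 + 1], 0 + 0i)
  expect_identical(notched$values[1], 1 + 1i)
  expect_error(tdss(on_c, width = 4000), "below the sweep")
})
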