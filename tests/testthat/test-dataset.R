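shapes <- list(`1D` = 61L, `2D` = c(33L, 17L), `3D` = c(24L, 12L, 9L))

test_that("dataset write/read round trip preserves samples and metadata", {
  for (ext in c("nv", "ucsf")) {
    for (nm in names(shapes)) {
      sizes <- shapes[[nm]]
      set.seed(42)
      axes <- lapply(seq_along(sizes), function(d)
        axis_meta(sizes[d], sw = 1000 * d + 0.25, sf = 100 * d + 0.125,
                  ref_ppm = d + 0.5, label = paste0("ax", d),
                  nucleus = c("H", "N", "C")[d], complex = FALSE,
                  freq_domain = d == 1))
      path <- file.path(withr::local_tempdir(), paste0("rt.", ext))
      ds <- dataset_create(axes, path)
      arr <- array(rnorm(prod(sizes)), dim = sizes)
      dataset_write_array(ds, arr)
      ds2 <- dataset_open(path)
      for (d in seq_along(sizes)) {
        a <- ds2$axes[[d]]
        expect_identical(a$size, sizes[d])
        expect_identical(a$sw, axes[[d]]$sw)
        expect_identical(a$sf, axes[[d]]$sf)
        expect_identical(a$ref_ppm, axes[[d]]$ref_ppm)
        expect_identical(a$ref_point, axes[[d]]$ref_point)
        expect_identical(a$label, axes[[d]]$label)
        expect_identical(a$nucleus, axes[[d]]$nucleus)
        expect_identical(a$complex, axes[[d]]$complex)
        expect_identical(a$freq_domain, axes[[d]]$freq_domain)
      }
      back <- dataset_read_array(ds2)
      # float32 storage: 2^-23 relative
      expect_lt(max(abs(back - arr)), 2^-22 * max(abs(arr)))
    }
  }
})

test_that("a fresh dataset is all zeros and traces along any axis match an
          in-memory transpose oracle", {
  set.seed(7)
  sizes <- c(20L, 14L, 6L)
  axes <- lapply(sizes, function(s)
    axis_meta(s, sw = 1000, sf = 500, complex = FALSE))
  path <- file.path(withr::local_tempdir(), "oracle.nv")
  ds <- dataset_create(axes, path, block_sizes = c(8, 4, 4))
  expect_true(all(dataset_read_array(ds) == 0))
  expect_true(all(vapply(dataset_read_vectors(ds, 2, list(c(0L, 0L))),
                         function(v) all(v$values == 0), logical(1))))
  arr <- array(rnorm(prod(sizes)), dim = sizes)
  dataset_write_array(ds, arr)
  for (d in 1:3) {
    others <- setdiff(1:3, d)
    loc <- c(3L, 2L)
    v <- dataset_read_vectors(ds, d, list(loc))[[1]]
    idx <- rep(list(NULL), 3)
    idx[[d]] <- seq_len(sizes[d])
    idx[[others[1]]] <- loc[1] + 1L
    idx[[others[2]]] <- loc[2] + 1L
    oracle <- do.call(`[`, c(list(arr), idx))
    expect_lt(max(abs(Re(v$values) - oracle)), 2^-22 * max(abs(arr)))
  }
})

test_that("trace write then read is float32-exact and respects interleaved
          complex axes", {
  td <- withr::local_tempdir()
  axes <- list(axis_meta(48, sw = 4000, sf = 600, complex = FALSE),
               axis_meta(20, sw = 2000, sf = 61, complex = FALSE))
  ds <- dataset_create(axes, file.path(td, "t.nv"))
  set.seed(3)
  v <- rnorm(48)
  dataset_write_vectors(ds, 1, list(7L), list(v))
  got <- dataset_read_vectors(ds, 1, list(7L))[[1]]
  expect_lt(max(abs(Re(got$values) - v)), 2^-22 * max(abs(v)))
  # complex interleave
  axc <- list(axis_meta(32, sw = 1000, sf = 100, complex = TRUE))
  dsc <- dataset_create(axc, file.path(td, "c.ucsf"))
  z <- complex(real = rnorm(16), imaginary = rnorm(16))
  dataset_write_vectors(dsc, 1, list(integer(0)), list(z))
  zz <- dataset_read_vectors(dsc, 1, list(integer(0)))[[1]]
  expect_length(zz$values, 16)
  expect_lt(max(abs(zz$values - z)), 2^-22 * max(abs(z)))
  # many traces written in one call stay independent
  ds2 <- dataset_create(axes, file.path(td, "many.nv"))
  cols <- lapply(1:20, function(j) rnorm(48) + j)
  dataset_write_vectors(ds2, 1, as.list(0:19), cols)
  for (j in c(1, 10, 20)) {
    got <- dataset_read_vectors(ds2, 1, list(j - 1L))[[1]]
    expect_lt(max(abs(Re(got$values) - cols[[j]])), 1e-5)
  }
})

test_that("the two header dialects carry an identical sample payload", {
  td <- withr::local_tempdir()
  axes <- list(axis_meta(40, sw = 4000, sf = 600, complex = FALSE),
               axis_meta(12, sw = 2000, sf = 61, complex = FALSE))
  set.seed(9)
  arr <- array(rnorm(40 * 12), dim = c(40, 12))
  paths <- c(file.path(td, "a.nv"), file.path(td, "a.ucsf"))
  for (pth in paths) dataset_write_array(dataset_create(axes, pth), arr)
  hdr <- c(nv = 512L, ucsf = 180L + 2L * 128L)
  pay <- lapply(seq_along(paths), function(i) {
    con <- file(paths[i], "rb")
    on.exit(close(con))
    seek(con, hdr[i])
    readBin(con, "raw", file.size(paths[i]) - hdr[i])
  })
  expect_identical(pay[[1]], pay[[2]])
})

test_that("dataset_combine implements elementwise add and subtract", {
  td <- withr::local_tempdir()
  axes <- list(axis_meta(30, sw = 1000, sf = 100, complex = FALSE),
               axis_meta(10, sw = 500, sf = 50, complex = FALSE))
  set.seed(11)
  a <- array(rnorm(300), dim = c(30, 10))
  b <- array(rnorm(300), dim = c(30, 10))
  dsa <- dataset_create(axes, file.path(td, "a.nv"))
  dsb <- dataset_create(axes, file.path(td, "b.nv"))
  dsz <- dataset_create(axes, file.path(td, "z.nv"))   # zeros
  dataset_write_array(dsa, a)
  dataset_write_array(dsb, b)
  sum_ds <- dataset_combine(dsa, dsb, "add", file.path(td, "s.nv"))
  expect_lt(max(abs(dataset_read_array(sum_ds) - (a + b))), 1e-5)
  idn <- dataset_combine(dsa, dsz, "add", file.path(td, "i.nv"))
  expect_equal(dataset_read_array(idn), dataset_read_array(dsa))
  nil <- dataset_combine(dsa, dsa, "subtract", file.path(td, "n.nv"))
  expect_true(all(dataset_read_array(nil) == 0))
  bad <- dataset_create(list(axis_meta(5, sw = 1, sf = 1)),
                        file.path(td, "bad.nv"))
  expect_error(dataset_combine(dsa, bad, "add", file.path(td, "x.nv")),
               "shapes")
})

test_that("dataset paths must use a known extension and coordinates are
          validated", {
  expect_error(dataset_create(list(axis_meta(8, sw = 1, sf = 1)),
                              "out.dat"), "nv or .ucsf")
  td <- withr::local_tempdir()
  ds <- dataset_create(list(axis_meta(8, sw = 1, sf = 1, complex = FALSE),
                            axis_meta(4, sw = 1, sf = 1, complex = FALSE)),
                       file.path(td, "e.nv"))
  expect_error(dataset_read_vectors(ds, 1, list(4L)), "out of range")
})
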