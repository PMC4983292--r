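test_that("a two-dimension processing script parses into the expected
          stages and survives a regeneration round trip", {
  td <- withr::local_tempdir()
  fid <- make_hsqc_dir(file.path(td, "hsqc"))
  script <- hsqc_script(fid, file.path(td, "out.nv"))
  ps <- read_params(fid)
  plan <- parse_script(script, params = ps)
  expect_length(plan$stages, 2)
  expect_identical(vapply(plan$stages[[1]]$ops, `[[`, "", "name"),
                   c("SB", "ZF", "FT", "PHASE", "EXTRACT"))
  expect_length(plan$stages[[2]]$ops, 4)
  expect_identical(plan$ref$ref[[1]], 4.73)
  # parameter symbols resolved at parse time
  expect_identical(plan$ref$sw[[1]], 4000)
  regen <- script_text(plan)
  plan2 <- parse_script(regen, params = ps)
  expect_identical(script_text(plan2), regen)
})

test_that("scripts without run, with unknown commands, or with foreign code
          are rejected", {
  expect_error(parse_script("DIM(1)\nFT()\n"), "must end with run")
  expect_error(parse_script("NOTACOMMAND(3)\nrun()"), "not a processing")
  expect_error(parse_script("system('ls')\nrun()"), "not a processing")
  expect_error(parse_script("FT()\nrun()"), "before any DIM")
})

test_that("heteronuclear axes are referenced by indirect ratios from the
          proton axis", {
  plan <- parse_script("CREATE('x.nv')\nsw(8000,2000,1500)\nsf(600.13,150.9,60.81)\nref(4.73,'C','N')\nDIM(1)\nFT()\nrun()")
  axes <- resolve_refs(plan, NULL, c(512L, 64L, 64L))
  expect_identical(axes[[1]]$ref_ppm, 4.73)
  # hand oracle: zero-ppm proton frequency, scaled by the ratios
  f0h <- 600.13 / (1 + 4.73e-6)
  f0c <- 0.251449530 * f0h
  f0n <- 0.101329118 * f0h
  expect_equal(axes[[2]]$ref_ppm, (150.9 - f0c) / f0c * 1e6,
               tolerance = 1e-12)
  expect_equal(axes[[3]]$ref_ppm, (60.81 - f0n) / f0n * 1e6,
               tolerance = 1e-12)
  expect_identical(axes[[2]]$nucleus, "C")
  # a nucleus letter with no proton reference on axis 1 is an error
  bad <- parse_script("CREATE('x.nv')\nsw(8000,2000)\nsf(600,150)\nref('C','N')\nDIM(1)\nFT()\nrun()")
  expect_error(resolve_refs(bad, NULL, c(64L, 64L)), "proton")
})

test_that("anchored ppm@MHz references resolve to the stated shift at the
          stated frequency", {
  plan <- parse_script("CREATE('x.nv')\nsw(8000)\nsf(800.3174239)\nref('0.0@800.3174239')\nDIM(1)\nFT()\nrun()")
  axes <- resolve_refs(plan, NULL, 512L)
  expect_equal(axes[[1]]$ref_ppm, 0.0, tolerance = 1e-12)
  plan2 <- parse_script("CREATE('x.nv')\nsw(8000)\nsf(800.13)\nref('0.0@800.3174239')\nDIM(1)\nFT()\nrun()")
  ax2 <- resolve_refs(plan2, NULL, 512L)
  expect_equal(ax2[[1]]$ref_ppm,
               (800.13 - 800.3174239) / 800.3174239 * 1e6,
               tolerance = 1e-12)
})

test_that("water referencing uses the experiment temperature", {
  td <- withr::local_tempdir()
  d <- file.path(td, "ag")
  write_fixture(d, "agilent", complex(real = 1:8, imaginary = 8:1),
                params = list(sfrq = 599.87, temp = 25))
  ps <- read_params(d)
  plan <- parse_script("CREATE('x.nv')\nsw(8000)\nsf('sfrq')\nref('h2o')\nDIM(1)\nFT()\nrun()",
                       params = ps)
  axes <- resolve_refs(plan, ps, 8L)
  expect_equal(axes[[1]]$ref_ppm, 7.83 - 298.15 / 96.9, tolerance = 1e-12)
  # no temperature parameter -> error
  d2 <- file.path(td, "ag2")
  write_fixture(d2, "agilent", complex(real = 1:8, imaginary = 8:1),
                params = list(sfrq = 599.87))
  expect_error(resolve_refs(plan, read_params(d2), 8L), "temperature")
})

test_that("running the two-dimension plan produces a referenced
          frequency-domain dataset, independent of thread count", {
  td <- withr::local_tempdir()
  fid <- make_hsqc_dir(file.path(td, "hsqc"), n1 = 64, n2 = 16)
  ps <- read_params(fid)
  plan <- parse_script(hsqc_script(fid, file.path(td, "o1.nv")),
                       params = ps)
  ds1 <- run_plan(plan, params = ps, threads = 1)
  expect_true(all(vapply(ds1$axes, `[[`, logical(1), "freq_domain")))
  a1 <- dataset_read_array(ds1)
  for (nt in c(2, 4)) {
    dsn <- run_plan(plan, params = ps, threads = nt,
                    out_path = file.path(td, paste0("o", nt, ".nv")))
    expect_identical(dataset_read_array(dsn), a1)
  }
  # the processed peak sits at the simulated offsets in both dimensions
  pk <- which(a1 == max(a1), arr.ind = TRUE)
  want1 <- ppm_to_point(dataset_read_vectors(ds1, 1, list(0L))[[1]]$meta,
                        4.73 + 600 / 600.13)
  expect_lt(abs((pk[1] - 1) / 2 - want1), 2)
})

test_that("the default vectors-per-request is total over threads, capped
          at 64", {
  expect_identical(fidproc:::default_vectors_per_request(256, 4), 64L)
  expect_identical(fidproc:::default_vectors_per_request(1000, 4), 64L)
  expect_identical(fidproc:::default_vectors_per_request(100, 4), 25L)
  expect_identical(fidproc:::default_vectors_per_request(3, 8), 1L)
})

test_that("skip leaves the flagged dimension untouched and composes with
          later reprocessing", {
  td <- withr::local_tempdir()
  arr <- make_3d_fid()
  hdr <- function(out) paste0(
    "CREATE('", out, "')\nsw(2000,1000,500)\nsf(600,150,60)\n")
  s_skip <- paste0(hdr(file.path(td, "skip.nv")), "skip(0,1,0)\n",
                   "DIM(1)\nFT()\nDIM(2)\nFT()\nDIM(3)\nFT()\nrun()")
  ds <- run_plan(parse_script(s_skip), raw = fidproc:::raw_fid(arr),
                 threads = 1)
  flags <- vapply(ds$axes, `[[`, logical(1), "freq_domain")
  expect_identical(flags, c(TRUE, FALSE, TRUE))
  # dim 2 holds raw (time-domain) increments: spot-check one trace
  v <- dataset_read_vectors(ds, 2, list(c(0L, 0L)))[[1]]
  expect_length(v$values, 8)
  s_all <- paste0(hdr(file.path(td, "all.nv")),
                  "DIM(1)\nFT()\nDIM(2)\nFT()\nDIM(3)\nFT()\nrun()")
  ds_all <- run_plan(parse_script(s_all), raw = fidproc:::raw_fid(arr),
                     threads = 1)
  a_all <- dataset_read_array(ds_all)
  # the skipped run's processed dims agree with the full run's at the
  # increments that exist before dim-2 processing
  expect_identical(dim(dataset_read_array(ds))[c(1, 3)],
                   dim(a_all)[c(1, 3)])
})

test_that("undoing a dimension restores its pre-processing state through
          the stored dataset", {
  td <- withr::local_tempdir()
  set.seed(8)
  n1 <- 32; n2 <- 8
  dmat <- matrix(complex(real = rnorm(n1 * 2 * n2),
                         imaginary = rnorm(n1 * 2 * n2)), n1, 2 * n2)
  fid <- file.path(td, "a")
  write_fixture(fid, "bruker", round(dmat * 1000),
                params = list(SW_h = 4000, SFO1 = 600),
                params2 = list(SW_h = 2000, SFO1 = 60))
  base <- paste0("FID('", fid, "')\nCREATE('", file.path(td, "u.nv"),
                 "')\nsw(4000,2000)\nsf(600,60)\n")
  undo <- paste0(base, "DIM(1)\nFT()\nDIM(2)\n",
                 "SB(offset=0.45, end=0.98)\nZF()\nFT()\nPHASE(p0=25)\n",
                 "UNDODIM(2)\nrun()")
  ds <- run_plan(parse_script(undo), threads = 1)
  ref <- run_plan(parse_script(paste0(base, "DIM(1)\nFT()\nrun()")),
                  threads = 1, out_path = file.path(td, "r.nv"))
  a <- dataset_read_array(ds)
  a0 <- dataset_read_array(ref)
  expect_lt(max(abs(a[, 1:16] - a0)), 1e-6 * max(abs(a0)))
  expect_true(all(a[, 17:32] == 0))
})

test_that("operation lists invert in reverse order and refuse lossy
          operations", {
  fwd <- list(op_spec("PHASE", list(p0 = 30)))
  inv <- invert_ops(fwd, 64L)
  expect_identical(inv[[1]]$args$p0, -30)
  v <- random_vec(64, h_axis(64, freq = TRUE))
  round <- apply_op(apply_op(v, fwd[[1]]), inv[[1]])
  expect_lt(max(abs(round$values - v$values)), 1e-12)
  # full in-memory forward + inverse chain
  fwd2 <- list(op_spec("SB", list(offset = 0.45, end = 0.98)),
               op_spec("ZF", list()), op_spec("FT", list()),
               op_spec("PHASE", list(p0 = 25)))
  sizes <- fidproc:::plan_sizes(fwd2, 8L)$input_sizes
  inv2 <- invert_ops(fwd2, sizes)
  expect_identical(vapply(inv2, `[[`, "", "name"),
                   c("PHASE", "IFT", "TRUNCATE", "APODDIV"))
  x <- random_vec(8, axis_meta(8, sw = 2000, sf = 60), seed = 3)
  y <- x
  for (o in fwd2) y <- apply_op(y, o)
  for (o in inv2) y <- apply_op(y, o)
  expect_lt(max(abs(y$values - x$values)), 1e-12)
  expect_error(invert_ops(list(op_spec("MAG", list())), 64L),
               "not invertible")
  # REAL inverts to a Hilbert transform
  expect_identical(invert_ops(list(op_spec("REAL", list())),
                              64L)[[1]]$name, "HFT")
})

test_that("the delayed linear-prediction workflow matches direct
          processing order on noiseless data", {
  td <- withr::local_tempdir()
  arr <- make_3d_fid()
  hdr <- function(out) paste0(
    "CREATE('", out, "')\nsw(2000,1000,500)\nsf(600,150,60)\n")
  lp <- "LP(ncoef=4, predict_count=8)\n"
  undo_route <- paste0(hdr(file.path(td, "a.nv")),
                       "DIM(1)\nFT()\nDIM(2)\nZF()\nFT()\nDIM(3)\n", lp,
                       "ZF()\nFT()\nUNDODIM(2)\nDIM(2)\n", lp,
                       "ZF()\nFT()\nrun()")
  direct <- paste0(hdr(file.path(td, "b.nv")),
                   "DIM(1)\nFT()\nDIM(3)\n", lp, "ZF()\nFT()\nDIM(2)\n",
                   lp, "ZF()\nFT()\nrun()")
  dsA <- run_plan(parse_script(undo_route), raw = fidproc:::raw_fid(arr),
                  threads = 1)
  dsB <- run_plan(parse_script(direct), raw = fidproc:::raw_fid(arr),
                  threads = 1)
  aA <- dataset_read_array(dsA)
  aB <- dataset_read_array(dsB)
  expect_lt(max(abs(aA - aB)), 1e-6 * max(abs(aB)))
})

test_that("batch processing writes a manifest and isolates failures", {
  td <- withr::local_tempdir()
  root <- file.path(td, "root")
  dir.create(root)
  for (k in 1:3)
    make_hsqc_dir(file.path(root, paste0("exp", k)), n1 = 32, n2 = 8)
  # symbolic parameter names resolve per entry, against each entry's own
  # parameter files
  template <- paste0(
    "FID('placeholder')\nCREATE('placeholder.nv')\n",
    "sw('SW_h,1', 'SW_h,2')\nsf('SFO1,1', 'SFO1,2')\n",
    "DIM(1)\nZF()\nFT()\nDIM(2)\nZF()\nFT()\nrun()")
  mf <- batch_process(root, template, threads = 1)
  tab <- read.delim(as.character(mf))
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$status == "ok"))
  expect_true(all(file.exists(tab$dataset)))
  expect_identical(tab$index, 1:3)
  # a corrupt directory is recorded as failed, others still process
  root2 <- file.path(td, "root2")
  dir.create(root2)
  make_hsqc_dir(file.path(root2, "good"), n1 = 32, n2 = 8)
  dir.create(file.path(root2, "bad"))
  writeLines("##TITLE= x", file.path(root2, "bad", "acqus"))
  mf2 <- batch_process(root2, template, threads = 1)
  tab2 <- read.delim(as.character(mf2))
  expect_identical(nrow(tab2), 2L)
  expect_identical(sum(tab2$status == "ok"), 1L)
  # empty root: warning and empty manifest
  root3 <- file.path(td, "root3")
  dir.create(root3)
  expect_warning(mf3 <- batch_process(root3, template), "no FID")
  expect_identical(nrow(read.delim(as.character(mf3))), 0L)
})

test_that("scripts can source a simulated FID and reconstruct it after
          scripted undersampling", {
  td <- withr::local_tempdir()
  s <- paste0("SIMFID(sf=600, sw=4000, size=512, shift=5.2, lw=12)\n",
              "CREATE('", file.path(td, "sim.nv"), "')\n",
              "sw(4000)\nsf(600)\nref(4.73)\n",
              "DIM(1)\nNUSSIM(fraction=0.3, seed=11)\n",
              "IST(iterations=100)\nFT()\nrun()")
  ds <- run_plan(parse_script(s), threads = 1)
  a <- dataset_read_array(ds)
  re <- a[seq(1, length(a), 2)]
  spec <- sim_spec(600, 4000, 512, sim_peak(5.2, 1, 12))
  full <- Re(ft(simulate_fid(spec))$values)
  expect_identical(which.max(re), which.max(full))
})

test_that("programmatic insertion places operations at their preferred
          position", {
  plan <- parse_script("CREATE('x.nv')\nsw(4000)\nsf(600)\nDIM(1)\nZF()\nFT()\nPHASE(p0=10)\nrun()")
  plan <- plan_append_op(plan, 1, "SB", list(offset = 0.45))
  names_now <- vapply(plan$stages[[1]]$ops, `[[`, "", "name")
  expect_identical(names_now, c("ZF", "SB", "FT", "PHASE"))
  plan <- plan_append_op(plan, 1, "EXTRACT", list(start = 0, end = 10))
  names_now <- vapply(plan$stages[[1]]$ops, `[[`, "", "name")
  expect_identical(names_now[5], "EXTRACT")
  # a new dimension opens its own stage
  plan <- plan_append_op(plan, 2, "FT")
  expect_identical(plan$stages[[2]]$dim, 2L)
})
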