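#' @section Tiled spectrum files:
#' Processed spectra are stored on disk in a tiled ("sub-matrix") layout so
#' that 1D traces can be read efficiently along any axis.  Two header
#' dialects are supported, selected by filename extension:
#'
#' * `.ucsf` -- the Sparky tile format: a 180-byte file header
#'   (`"UCSF NMR"` magic, dimension count, component count, format
#'   version 2) followed by one 128-byte header per axis (slowest-varying
#'   axis first: 6-byte nucleus name, int32 point count, int32 tile size,
#'   float32 spectrometer frequency / sweep width / centre ppm) and
#'   big-endian float32 tiles.  Unused axis-header bytes (offset 32+) carry
#'   double-precision copies of sf/sw/ref and the complex/frequency-domain
#'   flags so metadata survives a round trip exactly; third-party readers
#'   ignore them.
#' * `.nv` -- this package's documented fixed-size dialect: a 512-byte
#'   big-endian header (`"NVSM"` magic, int32 ndim, then per axis int32
#'   size, int32 block size, float64 sw/sf/ref_ppm/ref_point, complex and
#'   frequency-domain flag bytes, 2-byte nucleus, 16-byte label) followed
#'   by the identical tile payload.
#'
#' In both dialects the payload is a sequence of tiles of
#' `prod(block_sizes)` big-endian float32 samples; the tile grid and the
#' samples within a tile are both ordered with axis 1 fastest.  Partial
#' edge tiles are zero-padded to full size.  Axis sizes count *stored*
#' float samples; an axis flagged `complex` stores real/imaginary
#' interleaved pairs, so it holds `size/2` complex points.
#' @name dataset-format
#' @keywords internal
NULL

NV_HEADER_BYTES <- 512L
UCSF_FILE_HEADER <- 180L
UCSF_AXIS_HEADER <- 128L

ds_dialect_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("nv", "ucsf"))
    stop("dataset path must end in .nv or .ucsf: ", path)
  ext
}

ds_header_bytes <- function(dialect, ndim) {
  if (dialect == "nv") NV_HEADER_BYTES
  else UCSF_FILE_HEADER + UCSF_AXIS_HEADER * ndim
}

# default tile edges: per-axis powers of two, product <= 32768 samples
default_block_sizes <- function(sizes) {
  pow2 <- function(n) 2 ^ ceiling(log2(max(1, n)))
  blocks <- vapply(sizes, pow2, numeric(1))
  while (prod(blocks) > 32768) {
    i <- which.max(blocks)
    if (blocks[i] <= 1) break
    blocks[i] <- blocks[i] / 2
  }
  as.integer(blocks)
}

ucsf_nucleus_name <- function(nucleus) {
  switch(nucleus, H = "1H", C = "13C", N = "15N", P = "31P", D = "2H", "X")
}

nucleus_from_ucsf <- function(name) {
  switch(name, `1H` = "H", `13C` = "C", `15N` = "N", `31P` = "P",
         `2H` = "D", "other")
}

pad_raw <- function(r, len) {
  stopifnot(length(r) <= len)
  c(r, raw(len - length(r)))
}

chars_raw <- function(s, len) pad_raw(charToRaw(substr(s, 1, len)), len)

raw_chars <- function(r) {
  r <- r[r != as.raw(0)]
  rawToChar(r)
}

nv_axis_record <- function(ax, block) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(c(ax$size, as.integer(block)), con, size = 4, endian = "big")
  writeBin(c(ax$sw, ax$sf, ax$ref_ppm, ax$ref_point), con, size = 8,
           endian = "big")
  writeBin(as.integer(c(ax$complex, ax$freq_domain)), con, size = 1)
  writeBin(chars_raw(ax$nucleus, 2L), con)
  writeBin(chars_raw(ax$label, 16L), con)
  pad_raw(rawConnectionValue(con), 60L)
}

nv_header <- function(axes, blocks) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("NVSM"), con)
  writeBin(length(axes), con, size = 4, endian = "big")
  for (i in seq_along(axes))
    writeBin(nv_axis_record(axes[[i]], blocks[i]), con)
  pad_raw(rawConnectionValue(con), NV_HEADER_BYTES)
}

parse_nv_header <- function(hdr) {
  con <- rawConnection(hdr, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "NVSM") stop("not an nv dataset (bad magic)")
  ndim <- readBin(con, "integer", 1, size = 4, endian = "big")
  axes <- vector("list", ndim)
  blocks <- integer(ndim)
  for (i in seq_len(ndim)) {
    ints <- readBin(con, "integer", 2, size = 4, endian = "big")
    dbls <- readBin(con, "numeric", 4, size = 8, endian = "big")
    flags <- readBin(con, "integer", 2, size = 1)
    nuc <- raw_chars(readBin(con, "raw", 2))
    lab <- raw_chars(readBin(con, "raw", 16))
    blocks[i] <- ints[2]
    axes[[i]] <- axis_meta(ints[1], sw = dbls[1], sf = dbls[2],
                           ref_ppm = dbls[3], ref_point = dbls[4],
                           label = lab, nucleus = nuc,
                           complex = flags[1] == 1L,
                           freq_domain = flags[2] == 1L)
  }
  list(axes = axes, blocks = blocks)
}

ucsf_axis_record <- function(ax, block) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(chars_raw(ucsf_nucleus_name(ax$nucleus), 6L), con)
  writeBin(raw(2), con)
  writeBin(c(ax$size, 0L, as.integer(block)), con, size = 4, endian = "big")
  centre_ppm <- point_to_ppm(ax, ax$size / 2)
  writeBin(c(ax$sf, ax$sw, centre_ppm), con, size = 4, endian = "big")
  # extension block (bytes 32+): exact doubles + flags + label
  writeBin(c(ax$sf, ax$sw, ax$ref_ppm, ax$ref_point), con, size = 8,
           endian = "big")
  writeBin(as.integer(c(ax$complex, ax$freq_domain)), con, size = 1)
  writeBin(chars_raw(ax$label, 32L), con)
  pad_raw(rawConnectionValue(con), UCSF_AXIS_HEADER)
}

ucsf_header <- function(axes, blocks) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(chars_raw("UCSF NMR", 10L), con)
  writeBin(as.integer(c(length(axes), 1L, 0L, 2L)), con, size = 1)
  hdr <- pad_raw(rawConnectionValue(con), UCSF_FILE_HEADER)
  # axis order in file: slowest-varying first = our last axis first
  recs <- lapply(rev(seq_along(axes)),
                 function(i) ucsf_axis_record(axes[[i]], blocks[i]))
  c(hdr, do.call(c, recs))
}

parse_ucsf_header <- function(hdr) {
  con <- rawConnection(hdr, "rb")
  on.exit(close(con))
  magic <- raw_chars(readBin(con, "raw", 10))
  if (magic != "UCSF NMR") stop("not a ucsf dataset (bad magic)")
  b <- readBin(con, "integer", 4, size = 1)
  ndim <- b[1]
  seek(con, UCSF_FILE_HEADER)
  axes <- vector("list", ndim)
  blocks <- integer(ndim)
  for (j in seq_len(ndim)) {
    nuc <- raw_chars(readBin(con, "raw", 6))
    readBin(con, "raw", 2)
    ints <- readBin(con, "integer", 3, size = 4, endian = "big")
    readBin(con, "numeric", 3, size = 4, endian = "big")  # float32 sf/sw/ppm
    dbls <- readBin(con, "numeric", 4, size = 8, endian = "big")
    flags <- readBin(con, "integer", 2, size = 1)
    lab <- raw_chars(readBin(con, "raw", 32))
    readBin(con, "raw", UCSF_AXIS_HEADER - 98L)
    i <- ndim - j + 1L          # undo reversed on-disk order
    blocks[i] <- ints[3]
    axes[[i]] <- axis_meta(ints[1], sw = dbls[2], sf = dbls[1],
                           ref_ppm = dbls[3], ref_point = dbls[4],
                           label = lab, nucleus = nucleus_from_ucsf(nuc),
                           complex = flags[1] == 1L,
                           freq_domain = flags[2] == 1L)
  }
  list(axes = axes, blocks = blocks)
}

new_dataset <- function(axes, blocks, path, dialect) {
  sizes <- vapply(axes, `[[`, integer(1), "size")
  structure(list(ndim = length(axes), axes = axes,
                 block_sizes = as.integer(blocks),
                 tile_counts = as.integer(ceiling(sizes / blocks)),
                 storage_path = normalizePath(path, mustWork = FALSE),
                 dialect = dialect),
            class = "nmr_dataset")
}

#' Create a tiled spectrum dataset on disk
#'
#' Writes a zero-initialised dataset file whose dialect is chosen from the
#' filename extension (`.nv` or `.ucsf`); see the package documentation of
#' the on-disk layout.  Axis sizes count stored float32 samples; set an
#' axis's `complex` flag when it will hold interleaved real/imaginary
#' pairs.
#'
#' @param axes list of [axis_meta()] objects, one per dimension (1--4).
#' @param path output file path ending in `.nv` or `.ucsf`.
#' @param block_sizes optional per-axis tile edge lengths; defaults to
#'   powers of two with at most 32768 samples per tile.
#' @return an `nmr_dataset` handle.
#' @export
dataset_create <- function(axes, path, block_sizes = NULL) {
  if (inherits(axes, "axis_meta")) axes <- list(axes)
  stopifnot(length(axes) >= 1, length(axes) <= 4,
            all(vapply(axes, inherits, logical(1), "axis_meta")))
  dialect <- ds_dialect_from_path(path)
  sizes <- vapply(axes, `[[`, integer(1), "size")
  blocks <- if (is.null(block_sizes)) default_block_sizes(sizes)
            else as.integer(block_sizes)
  stopifnot(length(blocks) == length(axes), all(blocks >= 1))
  hdr <- if (dialect == "nv") nv_header(axes, blocks)
         else ucsf_header(axes, blocks)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  ntiles <- prod(ceiling(sizes / blocks))
  tile_n <- prod(blocks)
  zeros <- numeric(tile_n)
  for (t in seq_len(ntiles)) writeBin(zeros, con, size = 4, endian = "big")
  new_dataset(axes, blocks, path, dialect)
}

#' Open an existing dataset file
#' @param path a `.nv` or `.ucsf` file written by [dataset_create()].
#' @return an `nmr_dataset` handle.
#' @export
dataset_open <- function(path) {
  dialect <- ds_dialect_from_path(path)
  if (!file.exists(path)) stop("no such dataset: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (dialect == "nv") {
    parsed <- parse_nv_header(readBin(con, "raw", NV_HEADER_BYTES))
  } else {
    head <- readBin(con, "raw", UCSF_FILE_HEADER)
    ndim <- as.integer(head[11])
    parsed <- parse_ucsf_header(c(head, readBin(con, "raw",
                                                UCSF_AXIS_HEADER * ndim)))
  }
  new_dataset(parsed$axes, parsed$blocks, path, dialect)
}

#' Rewrite the header of a dataset with updated axis metadata
#'
#' Used by the processing engine after each dimension pass; the tile
#' payload is untouched.  Sizes and block sizes must not change.
#' @param ds an `nmr_dataset`.
#' @param axes replacement list of [axis_meta()].
#' @return the updated handle.
#' @export
dataset_update_meta <- function(ds, axes) {
  stopifnot(inherits(ds, "nmr_dataset"), length(axes) == ds$ndim)
  old <- vapply(ds$axes, `[[`, integer(1), "size")
  new <- vapply(axes, `[[`, integer(1), "size")
  if (!identical(old, new)) stop("dataset_update_meta cannot resize axes")
  hdr <- if (ds$dialect == "nv") nv_header(axes, ds$block_sizes)
         else ucsf_header(axes, ds$block_sizes)
  con <- file(ds$storage_path, "r+b")
  on.exit(close(con))
  writeBin(hdr, con)
  ds$axes <- axes
  ds
}

#' @export
print.nmr_dataset <- function(x, ...) {
  cat(sprintf("<nmr_dataset> %dD %s [%s] blocks [%s]\n  %s\n", x$ndim,
              x$dialect,
              paste(vapply(x$axes, `[[`, integer(1), "size"), collapse = "x"),
              paste(x$block_sizes, collapse = "x"), x$storage_path))
  for (ax in x$axes) print(ax)
  invisible(x)
}

# ---- tile geometry -------------------------------------------------------

# 0-based linear tile index from 0-based per-axis tile coords (axis 1 fastest)
tile_linear <- function(tcoords, tile_counts) {
  stride <- cumprod(c(1, tile_counts[-length(tile_counts)]))
  sum(tcoords * stride)
}

tile_bytes <- function(ds) 4 * prod(ds$block_sizes)

# read one whole tile as a numeric vector (length prod(blocks))
read_tile <- function(con, ds, tcoords) {
  off <- ds_header_bytes(ds$dialect, ds$ndim) +
    tile_linear(tcoords, ds$tile_counts) * tile_bytes(ds)
  seek(con, off)
  readBin(con, "numeric", prod(ds$block_sizes), size = 4, endian = "big")
}

write_tile <- function(con, ds, tcoords, values) {
  off <- ds_header_bytes(ds$dialect, ds$ndim) +
    tile_linear(tcoords, ds$tile_counts) * tile_bytes(ds)
  seek(con, off, rw = "write")
  writeBin(as.numeric(values), con, size = 4, endian = "big")
}

# in-tile linear indices (1-based) of a run along `dim` at fixed offsets
tile_run_index <- function(blocks, dim, within, idx_along) {
  stride <- cumprod(c(1, blocks[-length(blocks)]))
  base <- sum(within * stride) - within[dim] * stride[dim]
  base + idx_along * stride[dim] + 1
}

check_coords <- function(ds, dim, loc) {
  sizes <- vapply(ds$axes, `[[`, integer(1), "size")
  others <- setdiff(seq_len(ds$ndim), dim)
  if (length(loc) != length(others))
    stop("trace coordinates must have ", length(others), " entries")
  if (any(loc < 0) || any(loc >= sizes[others]))
    stop("trace coordinates out of range")
}

# read the full stored (real float) trace along `dim` at 0-based coords of
# the other axes
ds_read_trace_raw <- function(con, ds, dim, loc) {
  check_coords(ds, dim, loc)
  n <- ds$axes[[dim]]$size
  blocks <- ds$block_sizes
  full <- integer(ds$ndim)
  full[setdiff(seq_len(ds$ndim), dim)] <- as.integer(loc)
  out <- numeric(n)
  b <- blocks[dim]
  for (t in seq_len(ds$tile_counts[dim]) - 1L) {
    i0 <- t * b
    cnt <- min(b, n - i0)
    if (cnt <= 0) break
    tcoords <- full %/% blocks
    tcoords[dim] <- t
    within <- full %% blocks
    tile <- read_tile(con, ds, tcoords)
    idx <- tile_run_index(blocks, dim, within, seq_len(cnt) - 1L)
    out[(i0 + 1):(i0 + cnt)] <- tile[idx]
  }
  out
}

# Tile cache used while writing: each affected tile is read from disk at
# most once, modified in memory across all traces of the call, and written
# back once.  (Interleaving readBin/writeBin on file connections is
# unreliable in R, and this is also far fewer IO operations.)
ds_write_trace_cached <- function(cache, con_rd, ds, dim, loc, values) {
  check_coords(ds, dim, loc)
  n <- ds$axes[[dim]]$size
  if (length(values) != n)
    stop("trace length ", length(values), " != axis size ", n)
  blocks <- ds$block_sizes
  full <- integer(ds$ndim)
  full[setdiff(seq_len(ds$ndim), dim)] <- as.integer(loc)
  b <- blocks[dim]
  for (t in seq_len(ds$tile_counts[dim]) - 1L) {
    i0 <- t * b
    cnt <- min(b, n - i0)
    if (cnt <= 0) break
    tcoords <- full %/% blocks
    tcoords[dim] <- t
    within <- full %% blocks
    key <- as.character(tile_linear(tcoords, ds$tile_counts))
    if (is.null(cache[[key]]))
      cache[[key]] <- list(tcoords = tcoords,
                           data = read_tile(con_rd, ds, tcoords))
    idx <- tile_run_index(blocks, dim, within, seq_len(cnt) - 1L)
    cache[[key]]$data[idx] <- values[(i0 + 1):(i0 + cnt)]
  }
  invisible(NULL)
}

trace_meta <- function(ds, dim) {
  ax <- ds$axes[[dim]]
  if (ax$complex) {
    ax$size <- ax$size %/% 2L
  }
  ax
}

#' Read 1D traces from a dataset
#'
#' Assembles traces along axis `dim` at the given coordinates of the
#' remaining axes.  If the axis is flagged complex the interleaved stored
#' values are paired into complex samples and the returned vector's axis
#' size is half the stored size.
#'
#' @param ds an `nmr_dataset`.
#' @param dim axis (1-based) the traces run along.
#' @param locations list of integer vectors (or a single vector), each
#'   giving the 0-based coordinates of one trace on the other axes, in
#'   increasing axis order.
#' @return list of [nmr_vector()] objects.
#' @export
dataset_read_vectors <- function(ds, dim, locations) {
  stopifnot(inherits(ds, "nmr_dataset"), dim >= 1, dim <= ds$ndim)
  if (!is.list(locations)) locations <- list(locations)
  ax <- trace_meta(ds, dim)
  con <- file(ds$storage_path, "rb")
  on.exit(close(con))
  lapply(locations, function(loc) {
    raw <- ds_read_trace_raw(con, ds, dim, loc)
    vals <- if (ds$axes[[dim]]$complex)
      complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
    else as.complex(raw)
    nmr_vector(vals, ax, location = loc)
  })
}

#' Write 1D traces into a dataset
#'
#' Inverse of [dataset_read_vectors()]: complex vectors are interleaved
#' into axes flagged complex; for real axes only the real part is stored.
#'
#' @inheritParams dataset_read_vectors
#' @param vectors list of [nmr_vector()] (or bare complex/numeric vectors)
#'   matching `locations`.
#' @return the dataset handle, invisibly.
#' @export
dataset_write_vectors <- function(ds, dim, locations, vectors) {
  stopifnot(inherits(ds, "nmr_dataset"), dim >= 1, dim <= ds$ndim)
  if (!is.list(locations)) locations <- list(locations)
  if (!is.list(vectors) || inherits(vectors, "nmr_vector"))
    vectors <- list(vectors)
  stopifnot(length(locations) == length(vectors))
  cache <- new.env(parent = emptyenv())
  con_rd <- file(ds$storage_path, "rb")
  for (i in seq_along(locations)) {
    v <- vectors[[i]]
    vals <- if (inherits(v, "nmr_vector")) v$values else as.complex(v)
    raw <- if (ds$axes[[dim]]$complex)
      as.numeric(rbind(Re(vals), Im(vals)))
    else Re(vals)
    ds_write_trace_cached(cache, con_rd, ds, dim, locations[[i]], raw)
  }
  close(con_rd)
  con_wr <- file(ds$storage_path, "r+b")
  on.exit(close(con_wr))
  for (key in ls(cache))
    write_tile(con_wr, ds, cache[[key]]$tcoords, cache[[key]]$data)
  invisible(ds)
}

#' Read a whole dataset into an R array
#'
#' Convenience for tests and small datasets: returns the stored float32
#' samples as a base-R array with axis 1 varying fastest.
#' @param ds an `nmr_dataset`.
#' @return numeric array with `dim` equal to the stored axis sizes.
#' @export
dataset_read_array <- function(ds) {
  sizes <- vapply(ds$axes, `[[`, integer(1), "size")
  con <- file(ds$storage_path, "rb")
  on.exit(close(con))
  arr <- array(0, dim = sizes)
  blocks <- ds$block_sizes
  tgrid <- lapply(ds$tile_counts, function(k) seq_len(k) - 1L)
  tcombos <- as.matrix(expand.grid(tgrid))
  for (r in seq_len(nrow(tcombos))) {
    tc <- tcombos[r, ]
    tile <- array(read_tile(con, ds, tc), dim = blocks)
    idx <- lapply(seq_len(ds$ndim), function(d) {
      i0 <- tc[d] * blocks[d]
      seq_len(min(blocks[d], sizes[d] - i0))
    })
    dest <- lapply(seq_len(ds$ndim), function(d)
      tc[d] * blocks[d] + idx[[d]])
    arr <- do.call(`[<-`, c(list(arr), dest,
                            list(do.call(`[`, c(list(tile), idx,
                                                list(drop = FALSE))))))
  }
  arr
}

#' Write an R array as the full dataset payload
#' @param ds an `nmr_dataset`.
#' @param arr numeric array matching the stored axis sizes.
#' @return the handle, invisibly.
#' @export
dataset_write_array <- function(ds, arr) {
  sizes <- vapply(ds$axes, `[[`, integer(1), "size")
  stopifnot(identical(as.integer(dim(arr)), sizes) ||
              (ds$ndim == 1 && length(arr) == sizes))
  if (is.null(dim(arr))) dim(arr) <- sizes
  con <- file(ds$storage_path, "r+b")
  on.exit(close(con))
  blocks <- ds$block_sizes
  tgrid <- lapply(ds$tile_counts, function(k) seq_len(k) - 1L)
  tcombos <- as.matrix(expand.grid(tgrid))
  for (r in seq_len(nrow(tcombos))) {
    tc <- tcombos[r, ]
    tile <- array(0, dim = blocks)
    idx <- lapply(seq_len(ds$ndim), function(d) {
      i0 <- tc[d] * blocks[d]
      seq_len(min(blocks[d], sizes[d] - i0))
    })
    src <- lapply(seq_len(ds$ndim), function(d) tc[d] * blocks[d] + idx[[d]])
    tile <- do.call(`[<-`, c(list(tile), idx,
                             list(do.call(`[`, c(list(arr), src,
                                                 list(drop = FALSE))))))
    write_tile(con, ds, tc, tile)
  }
  invisible(ds)
}

#' Combine two datasets sample-by-sample
#'
#' Creates a third dataset whose every sample is the sum or difference of
#' the corresponding samples of `a` and `b` (vector arithmetic over whole
#' datasets).
#'
#' @param a,b `nmr_dataset` handles with identical shapes.
#' @param op `"add"` or `"subtract"`.
#' @param out_path output path (`.nv` or `.ucsf`).
#' @return the new `nmr_dataset`.
#' @export
dataset_combine <- function(a, b, op = c("add", "subtract"), out_path) {
  op <- match.arg(op)
  sa <- vapply(a$axes, `[[`, integer(1), "size")
  sb <- vapply(b$axes, `[[`, integer(1), "size")
  if (!identical(sa, sb)) stop("dataset shapes differ: cannot combine")
  out <- dataset_create(a$axes, out_path, a$block_sizes)
  arr <- dataset_read_array(a)
  brr <- dataset_read_array(b)
  dataset_write_array(out, if (op == "add") arr + brr else arr - brr)
  out
}
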