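# Plan execution: the first dimension reads raw vendor traces and writes
# the destination dataset; every later dimension reads and writes the
# destination in place.  Data are stored hypercomplex: each processed axis
# keeps real/imaginary interleaved samples so that processing (and
# undoing) of the remaining dimensions stays possible.

default_vectors_per_request <- function(total, threads) {
  max(1L, min(as.integer(ceiling(total / threads)), 64L))
}

#' Default worker count
#'
#' The number of processing threads used when none is given: the detected
#' core count (capped at 8).
#' @return integer.
#' @export
default_threads <- function() {
  n <- tryCatch(parallel::detectCores(logical = FALSE),
                error = function(e) 1L)
  if (is.na(n) || n < 1) n <- 1L
  min(n, 8L)
}

# complex trace values arranged as an n-d array of stored (real) samples:
# axis 1 = complex direct points, higher axes interleave re/im
raw_data_array <- function(raw) raw$data

raw_dims <- function(d) if (is.null(dim(d))) length(d) else dim(d)

# expand NUS increments onto the full grid (2D only): stored columns come
# in re/im pairs per complex increment
nus_expand_matrix <- function(d, schedule) {
  k <- length(schedule$indices)
  if (ncol(d) == k) {                 # plain (non-hypercomplex) increments
    return(nus_expand(d, schedule))
  }
  if (ncol(d) != 2 * k)
    stop("NUS data has ", ncol(d), " increments for a schedule of ", k)
  out <- matrix(0i, nrow(d), 2 * schedule$grid_size)
  for (j in seq_len(k)) {
    g <- schedule$indices[j]
    out[, 2 * g + 1:2] <- d[, 2 * j - 1:0]
  }
  out
}

all_locations <- function(sizes_other) {
  if (length(sizes_other) == 0) return(list(integer(0)))
  grid <- lapply(sizes_other, function(s) 0:(s - 1))
  combos <- as.matrix(expand.grid(grid))
  lapply(seq_len(nrow(combos)), function(r) as.integer(combos[r, ]))
}

# dry-run an op list: returns list(out = final complex size,
# input_sizes = size before each op)
plan_sizes <- function(ops, n) {
  input_sizes <- integer(length(ops))
  for (i in seq_along(ops)) {
    input_sizes[i] <- n
    n <- op_output_size(n, ops[[i]])
  }
  list(out = as.integer(n), input_sizes = input_sizes)
}

stage_error <- function(dim, opi, name, parent) {
  stop(sprintf("dimension %d, operation %d (%s): %s", dim, opi, name,
               conditionMessage(parent)), call. = FALSE)
}

process_trace <- function(v, ops, dim, ctx) {
  for (i in seq_along(ops)) {
    v <- tryCatch(apply_op(v, ops[[i]], ctx),
                  error = function(e) stage_error(dim, i, ops[[i]]$name, e))
  }
  v
}

chunk_list <- function(x, size) {
  if (length(x) == 0) return(list())
  split(x, (seq_along(x) - 1) %/% size)
}

run_batches <- function(items, worker, threads, per_request) {
  batches <- chunk_list(items, per_request)
  results <- if (threads > 1 && .Platform$OS.type != "windows") {
    parallel::mclapply(batches, function(b) lapply(b, worker),
                       mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(batches, function(b) lapply(b, worker))
  }
  unlist(results, recursive = FALSE, use.names = FALSE)
}

#' Execute a processing plan
#'
#' Runs the plan's stages over the raw data: referencing is resolved
#' against the vendor parameters, the destination dataset is created with
#' the final sizes (established by a sizing pass over the operation
#' lists), dimension 1 is processed from the raw traces, and each further
#' dimension is processed in place on the destination.  `UNDODIM` stages
#' execute the inverse of the most recent pass over that dimension;
#' dimensions flagged by `skip` are left untouched.  The result is
#' independent of the thread count.
#'
#' @param plan a `process_plan` from [parse_script()].
#' @param params optional `param_set`; defaults to the parameters read
#'   with the FID.
#' @param raw optional `raw_fid`; defaults to reading `plan$fid_path`.
#' @param threads worker processes (default [default_threads()]).
#' @param vectors_per_request traces handled per work unit; default
#'   `min(total/threads, 64)`.
#' @param out_path override for the plan's CREATE path.
#' @return the processed `nmr_dataset` (invisibly carries the stage
#'   history in attribute `"history"`).
#' @export
run_plan <- function(plan, params = NULL, raw = NULL, threads = 1L,
                     vectors_per_request = NULL, out_path = NULL) {
  stopifnot(inherits(plan, "process_plan"))
  if (is.null(raw)) {
    if (!is.null(plan$fid_path)) {
      raw <- read_fid(plan$fid_path)
    } else if (!is.null(plan$sim)) {
      s <- plan$sim
      spec <- sim_spec(sf = s$sf, sw = s$sw, size = s$size,
                       peaks = sim_peak(s$shift, s$amp, s$lw),
                       noise_sigma = s$noise, seed = s$seed)
      raw <- raw_fid(simulate_fid(spec)$values, params = NULL)
      raw$sim_meta <- simulate_fid(spec)$meta
    } else stop("plan has no FID source")
  }
  if (is.null(params)) params <- raw$params
  out_path <- if (!is.null(out_path)) out_path else plan$create_path
  if (is.null(out_path)) stop("plan has no CREATE path")

  d <- raw_data_array(raw)
  if (!is.null(raw$schedule) && length(dim(d)) == 2)
    d <- nus_expand_matrix(d, raw$schedule)
  stored_raw <- raw_dims(d)            # axis1 complex, others interleaved
  ndim <- length(stored_raw)
  csize_raw <- c(stored_raw[1], stored_raw[-1] %/% 2)
  axes0 <- resolve_refs(plan, params, csize_raw)
  skip <- plan_skip(plan, ndim)

  # ---- sizing pass -------------------------------------------------------
  state_c <- csize_raw
  max_c <- csize_raw
  stage_info <- vector("list", length(plan$stages))
  hist <- list()                       # per executed forward stage
  for (si in seq_along(plan$stages)) {
    st <- plan$stages[[si]]
    if (st$dim > ndim) stop("DIM(", st$dim, ") beyond data with ", ndim,
                            " dimensions")
    if (skip[st$dim]) next
    if (st$undo) {
      prev <- Find(function(h) h$dim == st$dim, rev(hist))
      if (is.null(prev))
        stop("UNDODIM(", st$dim, ") without a prior pass over dimension ",
             st$dim)
      ops <- invert_ops(prev$ops, prev$input_sizes)
      sz <- plan_sizes(ops, state_c[st$dim])
      stage_info[[si]] <- list(ops = ops, input_sizes = sz$input_sizes)
      state_c[st$dim] <- sz$out
      hist <- Filter(function(h) !identical(h, prev), hist)
    } else {
      ops <- Filter(function(o) o$name != "TDCOMB", st$ops)
      sz <- plan_sizes(ops, state_c[st$dim])
      stage_info[[si]] <- list(ops = ops, input_sizes = sz$input_sizes)
      hist <- c(hist, list(list(dim = st$dim, ops = ops,
                                input_sizes = sz$input_sizes)))
      state_c[st$dim] <- sz$out
    }
    max_c[st$dim] <- max(max_c[st$dim], state_c[st$dim])
  }

  # ---- create destination ------------------------------------------------
  stored_final <- c(2L * max_c[1], 2L * max_c[-1])
  create_axes <- lapply(seq_len(ndim), function(k) {
    ax <- axes0[[k]]
    ax$size <- as.integer(stored_final[k])
    ax$complex <- TRUE
    ax
  })
  ds <- dataset_create(create_axes, out_path)

  # ---- execution ---------------------------------------------------------
  # per-dim evolving state: complex size, axis meta (in complex points)
  meta_state <- axes0
  csize <- csize_raw
  ctx <- list(schedule = raw$schedule)
  if (is.null(threads) || threads < 1) threads <- default_threads()
  first_stage <- TRUE
  exec_hist <- list()

  for (si in seq_along(plan$stages)) {
    st <- plan$stages[[si]]
    if (skip[st$dim]) next
    info <- stage_info[[si]]
    ops <- info$ops
    dm <- st$dim
    others <- setdiff(seq_len(ndim), dm)
    pre_meta <- meta_state[[dm]]
    pre_csize <- csize[dm]

    if (first_stage) {
      if (dm != 1) stop("the first processed dimension must be 1")
      # TDCOMB: combine adjacent increment pairs before per-trace work
      tdc <- Filter(function(o) o$name == "TDCOMB", st$ops)
      locs <- all_locations(stored_raw[-1])
      src <- lapply(locs, function(loc) {
        vals <- if (ndim == 1) d
        else do.call(`[`, c(list(d), c(list(TRUE), as.list(loc + 1L))))
        nmr_vector(vals, pre_meta, location = loc,
                   group_delay = raw$group_delay)
      })
      if (length(tdc) && ndim >= 2) {
        coef <- if (!is.null(tdc[[1]]$args$coef)) tdc[[1]]$args$coef
                else "echo-antiecho"
        for (j in seq(1, length(src) - 1, by = 2)) {
          comb <- tdcomb(src[j + 0:1], coef)
          src[[j]]$values <- comb[[1]]$values
          src[[j + 1]]$values <- comb[[2]]$values
        }
      }
      worker <- function(v) process_trace(v, ops, dm, ctx)
      per <- if (is.null(vectors_per_request))
        default_vectors_per_request(length(src), threads)
      else vectors_per_request
      done <- run_batches(src, worker, threads, per)
      out_n <- length(done[[1]]$values)
      pad <- max_c[dm] - out_n
      vecs <- lapply(done, function(v)
        c(v$values, complex(pad)))
      dataset_write_vectors(ds, dm, lapply(done, `[[`, "location"), vecs)
      meta_state[[dm]] <- done[[1]]$meta
      csize[dm] <- out_n
      first_stage <- FALSE
    } else {
      valid_other <- (2L * csize)[others]
      locs <- all_locations(valid_other)
      per <- if (is.null(vectors_per_request))
        default_vectors_per_request(length(locs), threads)
      else vectors_per_request
      nref <- pre_csize
      worker <- function(loc) {
        v <- dataset_read_vectors(ds, dm, list(loc))[[1]]
        m <- pre_meta
        m$size <- nref
        v <- nmr_vector(v$values[seq_len(nref)], m, location = loc)
        process_trace(v, ops, dm, ctx)
      }
      done <- run_batches(locs, worker, threads, per)
      out_n <- length(done[[1]]$values)
      pad <- max_c[dm] - out_n
      vecs <- lapply(done, function(v) c(v$values, complex(pad)))
      dataset_write_vectors(ds, dm, locs, vecs)
      meta_state[[dm]] <- done[[1]]$meta
      csize[dm] <- out_n
    }
    if (st$undo) {
      # restore the pre-pass axis state of that dimension
      fw <- Find(function(h) h$dim == dm, rev(exec_hist))
      if (!is.null(fw)) {
        meta_state[[dm]] <- fw$pre_meta
        csize[dm] <- fw$pre_csize
        exec_hist <- Filter(function(h) !identical(h, fw), exec_hist)
      }
    } else {
      exec_hist <- c(exec_hist, list(list(
        dim = dm, ops = ops, input_sizes = info$input_sizes,
        pre_meta = pre_meta, pre_csize = pre_csize)))
    }
  }

  # ---- final header ------------------------------------------------------
  final_axes <- lapply(seq_len(ndim), function(k) {
    ax <- meta_state[[k]]
    ax$size <- as.integer(stored_final[k])
    ax$complex <- TRUE
    ax
  })
  ds <- dataset_update_meta(ds, final_axes)
  attr(ds, "history") <- exec_hist
  attr(ds, "valid_complex_sizes") <- csize
  plan$executed <- TRUE
  invisible(ds)
}

#' Parse and run a processing script file
#'
#' @param script_path path to a script file.
#' @param ... passed to [run_plan()].
#' @return the processed `nmr_dataset`.
#' @export
process_script <- function(script_path, ...) {
  args <- list(...)
  params <- args$params
  if (is.null(params)) {
    # peek at the FID path so p() lookups resolve during parsing
    txt <- readLines(script_path, warn = FALSE)
    fid_line <- grep("^\\s*FID\\(", txt, value = TRUE)
    if (length(fid_line)) {
      fid_path <- sub("^\\s*FID\\(['\"]([^'\"]+)['\"]\\).*$", "\\1",
                      fid_line[1])
      if (!grepl("^/", fid_path))
        fid_path <- file.path(dirname(script_path), fid_path)
      params <- tryCatch(read_params(fid_path), error = function(e) NULL)
      if (!is.null(params)) args$params <- params
    }
  }
  plan <- parse_script(script_path, params = params, is_file = TRUE)
  if (!is.null(plan$fid_path) && !grepl("^/", plan$fid_path)) {
    plan$fid_path <- file.path(dirname(script_path), plan$fid_path)
  }
  do.call(run_plan, c(list(plan), args))
}

looks_like_fid_dir <- function(path) {
  file.exists(file.path(path, "procpar")) ||
    file.exists(file.path(path, "acqus")) ||
    length(list.files(path, pattern = "\\.(dx|jdx)$")) > 0
}

#' Batch-process every FID directory under a root
#'
#' Scans `root_dir` for recognizable vendor directories, processes each
#' with the template plan (its FID and CREATE commands rewritten per
#' entry), and writes a tab-separated manifest of index, FID path and
#' output dataset path.  A failing entry is recorded and skipped; it does
#' not abort the batch.
#'
#' @param root_dir directory containing FID directories.
#' @param template a `process_plan` (or script text) used for every entry.
#' @param manifest_path where to write the manifest (default
#'   `root_dir/manifest.txt`).
#' @param overwrite replace existing output datasets (default FALSE:
#'   existing outputs fail that entry).
#' @param ... passed to [run_plan()].
#' @return the manifest path, invisibly; the manifest as a data.frame in
#'   attribute `"manifest"`.
#' @export
batch_process <- function(root_dir, template,
                          manifest_path = file.path(root_dir,
                                                    "manifest.txt"),
                          overwrite = FALSE, ...) {
  if (is.character(template)) template <- parse_script(template)
  dirs <- list.dirs(root_dir, recursive = FALSE)
  dirs <- dirs[vapply(dirs, looks_like_fid_dir, logical(1))]
  rows <- list()
  if (length(dirs) == 0)
    warning("no FID directories found under ", root_dir)
  ext <- if (!is.null(template$create_path))
    tools::file_ext(template$create_path) else "nv"
  for (i in seq_along(dirs)) {
    fid_dir <- dirs[i]
    out <- file.path(fid_dir, paste0(basename(fid_dir), ".", ext))
    status <- "ok"
    if (file.exists(out) && !overwrite) {
      status <- "exists (use overwrite)"
    } else {
      plan <- template
      plan$fid_path <- fid_dir
      plan$create_path <- out
      status <- tryCatch({
        run_plan(plan, ...)
        "ok"
      }, error = function(e) paste("failed:", conditionMessage(e)))
    }
    rows[[i]] <- data.frame(index = i, fid = fid_dir,
                            dataset = if (status == "ok") out else "",
                            status = status, stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
  else data.frame(index = integer(), fid = character(),
                  dataset = character(), status = character())
  utils::write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  out <- manifest_path
  attr(out, "manifest") <- manifest
  invisible(out)
}
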