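# Raw FID readers for the supported vendor layouts.

#' Raw time-domain data as stored by the spectrometer
#'
#' @param data complex vector (1D) or matrix with one column per indirect
#'   increment (direct dimension along rows).
#' @param acquisition_order text describing how indirect real/imaginary
#'   components interleave across increments (default `"ri"`: the
#'   hypercomplex convention -- real and imaginary components of each
#'   indirect increment alternate trace by trace).
#' @param group_delay vendor digital-filter delay in points (>= 0).
#' @param schedule optional [sample_schedule()] for NUS acquisitions.
#' @param params the `param_set` the data was read with.
#' @return a `raw_fid` object.
#' @keywords internal
raw_fid <- function(data, acquisition_order = "ri", group_delay = 0,
                    schedule = NULL, params = NULL) {
  stopifnot(group_delay >= 0)
  structure(list(data = data, acquisition_order = acquisition_order,
                 group_delay = as.numeric(group_delay),
                 schedule = schedule, params = params), class = "raw_fid")
}

#' @export
print.raw_fid <- function(x, ...) {
  d <- if (is.matrix(x$data)) dim(x$data) else c(length(x$data), 1L)
  cat(sprintf("<raw_fid> %d complex pts x %d increment(s)%s\n", d[1], d[2],
              if (x$group_delay > 0)
                sprintf(", group delay %.4g", x$group_delay) else ""))
  invisible(x)
}

# Agilent binary file header: 6 int32, 2 int16, 1 int32 (big-endian)
AG_S_FLOAT <- 8L
AG_S_32 <- 4L

read_agilent_fid <- function(dir_path, params) {
  path <- file.path(dir_path, "fid")
  if (!file.exists(path)) stop("no Agilent fid file in ", dir_path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "integer", 6, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 2, endian = "big")  # vers_id, status(hdr)
  nbheaders <- readBin(con, "integer", 1, size = 4, endian = "big")
  nblocks <- h[1]; ntraces <- h[2]; np <- h[3]; ebytes <- h[4]
  expected <- 32 + nblocks * (28 * nbheaders + ntraces * np * ebytes)
  if (file.size(path) != expected)
    stop("Agilent fid size mismatch: expected ", expected, " bytes, found ",
         file.size(path))
  traces <- matrix(0i, np / 2, nblocks * ntraces)
  col <- 0L
  for (b in seq_len(nblocks)) {
    bh <- readBin(con, "integer", 4, size = 2, endian = "big")
    status <- bh[2]
    readBin(con, "integer", 1, size = 4, endian = "big")
    readBin(con, "numeric", 4, size = 4, endian = "big")
    if (nbheaders > 1)
      readBin(con, "raw", 28 * (nbheaders - 1))
    for (tr in seq_len(ntraces)) {
      vals <- if (bitwAnd(status, AG_S_FLOAT) != 0)
        readBin(con, "numeric", np, size = 4, endian = "big")
      else if (ebytes == 4)
        readBin(con, "integer", np, size = 4, endian = "big")
      else
        readBin(con, "integer", np, size = 2, endian = "big")
      col <- col + 1L
      traces[, col] <- complex(real = vals[c(TRUE, FALSE)],
                               imaginary = vals[c(FALSE, TRUE)])
    }
  }
  if (ncol(traces) == 1) traces <- traces[, 1]
  raw_fid(traces, group_delay = 0, params = params)
}

bruker_record_values <- function(td) as.integer(256 * ceiling(td / 256))

read_bruker_fid <- function(dir_path, params) {
  path <- file.path(dir_path, "ser")
  if (!file.exists(path)) path <- file.path(dir_path, "fid")
  if (!file.exists(path)) stop("no Bruker fid/ser file in ", dir_path)
  td1 <- as.integer(p(params, "TD,1"))
  nrec <- if (basename(path) == "ser") {
    td2 <- as.integer(p(params, "TD,2"))
    td2
  } else 1L
  byt <- tryCatch(p(params, "BYTORDA"), error = function(e) 0)
  endian <- if (identical(byt, 1)) "big" else "little"
  dtypa <- tryCatch(p(params, "DTYPA"), error = function(e) 0)
  ebytes <- if (identical(dtypa, 2)) 8L else 4L
  rec <- if (basename(path) == "ser") bruker_record_values(td1) else td1
  expected <- nrec * rec * ebytes
  if (file.size(path) != expected)
    stop("Bruker data size mismatch: expected ", expected, " bytes, found ",
         file.size(path))
  con <- file(path, "rb")
  on.exit(close(con))
  traces <- matrix(0i, td1 / 2, nrec)
  for (r in seq_len(nrec)) {
    vals <- if (ebytes == 8)
      readBin(con, "numeric", rec, size = 8, endian = endian)
    else
      readBin(con, "integer", rec, size = 4, endian = endian)
    vals <- vals[seq_len(td1)]
    traces[, r] <- complex(real = vals[c(TRUE, FALSE)],
                           imaginary = vals[c(FALSE, TRUE)])
  }
  if (ncol(traces) == 1) traces <- traces[, 1]
  gd <- tryCatch(p(params, "GRPDLY"), error = function(e) 0)
  if (!is.numeric(gd) || gd < 0) gd <- 0
  raw_fid(traces, group_delay = gd, params = params)
}

read_jcamp_fid <- function(path, params) {
  lines <- readLines(path, warn = FALSE)
  parse_table <- function(from, to) {
    vals <- numeric(0)
    for (ln in lines[from:to]) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      # first token on each line is the abscissa; the rest are ordinates
      vals <- c(vals, as.numeric(tok[-1]))
    }
    vals
  }
  pages <- grep("^##PAGE=", lines)
  if (length(pages)) {               # complex NTUPLES data, pages N=1 / N=2
    comp <- list()
    for (k in seq_along(pages)) {
      start <- grep("^##DATA TABLE=", lines)[k] + 1L
      end <- if (k < length(pages)) pages[k + 1L] - 1L
             else grep("^##END NTUPLES=", lines)[1] - 1L
      comp[[k]] <- parse_table(start, end)
    }
    vals <- complex(real = comp[[1]], imaginary = comp[[2]])
  } else {
    start <- grep("^##XYDATA=", lines)[1] + 1L
    end <- grep("^##END", lines)[1] - 1L
    vals <- as.complex(parse_table(start, end))
  }
  npts <- tryCatch(p(params, "NPOINTS"), error = function(e) length(vals))
  if (length(vals) != npts)
    stop("JCAMP data size mismatch: NPOINTS=", npts, " but read ",
         length(vals))
  raw_fid(vals, params = params)
}

#' Read raw vendor time-domain data
#'
#' Detects the vendor layout (Agilent `fid`+`procpar`, Bruker `fid`/`ser`
#' + `acqus` family, 1D JCAMP-DX), decodes the binary or numeric-table
#' data with the correct byte order and sample type, and returns complex
#' direct-dimension traces.  The Bruker digital-filter group delay is
#' populated from `GRPDLY`.  A `nuslist` file next to the data, if
#' present, is attached as the sampling schedule.
#'
#' @param dir_path vendor directory (or a JCAMP file path).
#' @return a `raw_fid`.
#' @export
read_fid <- function(dir_path) {
  params <- read_params(dir_path)
  out <- switch(params$dialect,
    agilent = read_agilent_fid(dir_path, params),
    bruker = read_bruker_fid(dir_path, params),
    jcamp = {
      path <- if (dir.exists(dir_path))
        list.files(dir_path, pattern = "\\.(dx|jdx)$", full.names = TRUE)[1]
      else dir_path
      read_jcamp_fid(path, params)
    })
  if (dir.exists(dir_path) && file.exists(file.path(dir_path, "nuslist"))) {
    grid <- if (is.matrix(out$data)) ncol(out$data) else NULL
    sched <- read_schedule(file.path(dir_path, "nuslist"))
    out$schedule <- sched
  }
  out
}
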