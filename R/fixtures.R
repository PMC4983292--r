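# Synthetic vendor-directory writers.  These produce minimal but valid
# Agilent, Bruker and JCAMP-DX layouts that read_params()/read_fid() can
# decode, so tests (and demos) never need spectrometer output.

write_procpar <- function(path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.character(v)) {
      writeLines(sprintf("%s 2 2 0 0 0 1 1 0 1 0", nm), con)
      writeLines(sprintf("1 \"%s\"", v), con)
    } else {
      writeLines(sprintf("%s 1 1 0 0 0 1 1 0 1 0", nm), con)
      writeLines(paste(c(length(v), format(v, digits = 15,
                                           scientific = FALSE)),
                       collapse = " "), con)
    }
    writeLines("0", con)
  }
}

write_agilent_binary <- function(path, data, encoding) {
  if (!is.matrix(data)) data <- matrix(data, ncol = 1)
  np <- 2L * nrow(data)
  nblocks <- ncol(data)
  ebytes <- if (encoding == "int16") 2L else 4L
  status <- bitwOr(1L, bitwOr(16L, if (encoding == "float32") 8L
                              else if (encoding == "int32") 4L else 0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(nblocks, 1L, np, ebytes, np * ebytes,
             np * ebytes + 28L), con, size = 4, endian = "big")
  writeBin(c(0L, status), con, size = 2, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")
  for (b in seq_len(nblocks)) {
    writeBin(c(0L, status, b, 0L), con, size = 2, endian = "big")
    writeBin(1L, con, size = 4, endian = "big")
    writeBin(numeric(4), con, size = 4, endian = "big")
    vals <- as.numeric(rbind(Re(data[, b]), Im(data[, b])))
    if (encoding == "float32")
      writeBin(vals, con, size = 4, endian = "big")
    else
      writeBin(as.integer(round(vals)), con, size = ebytes, endian = "big")
  }
}

write_bruker_file <- function(path, scope_title, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##TITLE= %s", scope_title), con)
  writeLines("##JCAMPDX= 5.0", con)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.character(v)) writeLines(sprintf("##$%s= <%s>", nm, v), con)
    else if (length(v) > 1) {
      writeLines(sprintf("##$%s= (0..%d)", nm, length(v) - 1L), con)
      writeLines(paste(format(v, digits = 15, scientific = FALSE),
                       collapse = " "), con)
    } else
      writeLines(sprintf("##$%s= %s",
                         nm, format(v, digits = 15, scientific = FALSE)),
                 con)
  }
  writeLines("##END=", con)
}

write_bruker_binary <- function(path, data, encoding, endian) {
  is2d <- is.matrix(data)
  if (!is2d) data <- matrix(data, ncol = 1)
  td1 <- 2L * nrow(data)
  rec <- if (is2d) bruker_record_values(td1) else td1
  con <- file(path, "wb")
  on.exit(close(con))
  for (r in seq_len(ncol(data))) {
    vals <- numeric(rec)
    vals[seq_len(td1)] <- as.numeric(rbind(Re(data[, r]), Im(data[, r])))
    if (encoding == "float64")
      writeBin(vals, con, size = 8, endian = endian)
    else
      writeBin(as.integer(round(vals)), con, size = 4, endian = endian)
  }
}

fmt_num <- function(x) format(x, digits = 15, scientific = FALSE)

write_jcamp_file <- function(path, data, params) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(data)
  writeLines(c("##TITLE= synthetic fid",
               "##JCAMP-DX= 5.00",
               "##DATA TYPE= NMR FID",
               sprintf("##NPOINTS= %d", n)), con)
  for (nm in names(params))
    writeLines(sprintf("##$%s= %s", nm, fmt_num(params[[nm]])), con)
  emit_table <- function(vals) {
    per <- 6L
    for (i0 in seq(1, n, per)) {
      i1 <- min(i0 + per - 1L, n)
      writeLines(paste(c(fmt_num(i0 - 1L), fmt_num(vals[i0:i1])),
                       collapse = " "), con)
    }
  }
  if (any(Im(data) != 0)) {
    writeLines("##NTUPLES= NMR FID", con)
    for (pg in 1:2) {
      writeLines(sprintf("##PAGE= N=%d", pg), con)
      writeLines("##DATA TABLE= (X++(R..R)), XYDATA", con)
      emit_table(if (pg == 1) Re(data) else Im(data))
    }
    writeLines("##END NTUPLES= NMR FID", con)
  } else {
    writeLines("##XYDATA= (X++(Y..Y))", con)
    emit_table(Re(data))
  }
  writeLines("##END=", con)
}

#' Write a synthetic vendor raw-data directory
#'
#' Emits a minimal valid vendor layout -- Agilent (`procpar` + `fid`),
#' Bruker (`acqus` family + `fid`/`ser`), or 1D JCAMP-DX -- containing the
#' given complex data, so that [read_params()] and [read_fid()] round-trip
#' it.  All data written by this function is synthetic.
#'
#' @param dir_path directory to create.
#' @param dialect `"agilent"`, `"bruker"` or `"jcamp"`.
#' @param data complex vector, or matrix with one column per indirect
#'   increment.
#' @param params named list of extra parameters for the primary parameter
#'   file (Agilent `procpar` / Bruker `acqus` / JCAMP header).
#' @param params2 named list for the Bruker second-dimension file
#'   (`acqu2s`); written only for matrix data.
#' @param encoding sample encoding: Agilent `"float32"`/`"int32"`, Bruker
#'   `"int32"`/`"float64"`, JCAMP always text.
#' @param endian `"little"` or `"big"` (Bruker only; sets `BYTORDA`).
#' @param group_delay Bruker `GRPDLY` value.
#' @param schedule optional [sample_schedule()]; written as a `nuslist`
#'   file.
#' @return `dir_path`, invisibly.
#' @export
write_fixture <- function(dir_path,
                          dialect = c("agilent", "bruker", "jcamp"),
                          data, params = list(), params2 = list(),
                          encoding = NULL, endian = "little",
                          group_delay = 0, schedule = NULL) {
  dialect <- match.arg(dialect)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  is2d <- is.matrix(data)
  if (dialect == "agilent") {
    encoding <- if (is.null(encoding)) "float32" else encoding
    base <- list(np = 2 * nrow(as.matrix(data)), seqfil = "s2pul")
    write_procpar(file.path(dir_path, "procpar"),
                  utils::modifyList(base, params))
    write_agilent_binary(file.path(dir_path, "fid"), data, encoding)
  } else if (dialect == "bruker") {
    encoding <- if (is.null(encoding)) "int32" else encoding
    base <- list(TD = 2 * nrow(as.matrix(data)),
                 BYTORDA = if (endian == "big") 1 else 0,
                 DTYPA = if (encoding == "float64") 2 else 0)
    if (group_delay > 0) base$GRPDLY <- group_delay
    write_bruker_file(file.path(dir_path, "acqus"), "acqus",
                      utils::modifyList(base, params))
    if (is2d) {
      base2 <- list(TD = ncol(data))
      write_bruker_file(file.path(dir_path, "acqu2s"), "acqu2s",
                        utils::modifyList(base2, params2))
    }
    write_bruker_binary(
      file.path(dir_path, if (is2d) "ser" else "fid"), data, encoding,
      endian)
  } else {
    if (is2d) stop("JCAMP fixtures are 1D only")
    write_jcamp_file(file.path(dir_path, "fid.dx"), data, params)
  }
  if (!is.null(schedule))
    writeLines(as.character(schedule$indices),
               file.path(dir_path, "nuslist"))
  invisible(dir_path)
}
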