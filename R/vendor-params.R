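# Vendor parameter files: Agilent 'procpar', the Bruker acqus family, and
# 1D JCAMP-DX headers, exposed through one typed lookup interface.

#' Typed view of a vendor parameter set
#'
#' Created by [read_params()].  Entries keep their source scope (which
#' file they came from); lookup is case-preserving.
#' @param entries named list of values.
#' @param dialect `"agilent"`, `"bruker"` or `"jcamp"`.
#' @param per_dim_files for Bruker, the ordered parameter-file scopes
#'   (`acqus`, `acqu2s`, ...).
#' @return a `param_set` object.
#' @keywords internal
param_set <- function(entries, dialect, per_dim_files = character()) {
  structure(list(entries = entries, dialect = dialect,
                 per_dim_files = per_dim_files), class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat(sprintf("<param_set> %s, %d parameters", x$dialect,
              length(x$entries)))
  if (length(x$per_dim_files))
    cat(" [", paste(x$per_dim_files, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# --- Agilent procpar ------------------------------------------------------
# Each parameter: a header line (name subtype basictype ... 11 fields),
# a value line starting with the value count (numbers inline; strings
# quoted, one per line after the first), and an enumeration line.
parse_procpar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  i <- 1L
  while (i <= length(lines)) {
    head <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(head) < 3) { i <- i + 1L; next }
    name <- head[1]
    basictype <- suppressWarnings(as.integer(head[3]))
    i <- i + 1L
    val_tokens <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    nvals <- suppressWarnings(as.integer(val_tokens[1]))
    if (is.na(nvals)) stop("malformed procpar value line at line ", i)
    if (!is.na(basictype) && basictype == 2L) {
      vals <- character(nvals)
      first <- sub("^\\s*\\d+\\s+", "", lines[i])
      vals[1] <- gsub("\"", "", first)
      if (nvals > 1) {
        for (k in 2:nvals) {
          i <- i + 1L
          vals[k] <- gsub("\"", "", trimws(lines[i]))
        }
      }
    } else {
      vals <- as.numeric(val_tokens[-1])
      if (length(vals) != nvals) stop("malformed procpar values for ", name)
    }
    i <- i + 1L  # enumeration line
    i <- i + 1L
    entries[[name]] <- list(value = if (length(vals) == 1) vals else vals,
                            scope = "procpar")
  }
  entries
}

# --- Bruker acqus family --------------------------------------------------
# JCAMP-like "##$NAME= value"; array parameters announce their range with
# "(0..n)" and continue on following lines.
parse_bruker_file <- function(path, scope) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^##\\$", ln)) {
      eq <- regmatches(ln, regexec("^##\\$([^=]+)=\\s*(.*)$", ln))[[1]]
      name <- eq[2]
      rest <- eq[3]
      if (grepl("^\\(", rest)) {
        vals <- character(0)
        while (i + 1L <= length(lines) && !grepl("^##", lines[i + 1L])) {
          i <- i + 1L
          vals <- c(vals, strsplit(trimws(lines[i]), "\\s+")[[1]])
        }
        num <- suppressWarnings(as.numeric(vals))
        value <- if (anyNA(num)) vals else num
      } else {
        rest <- trimws(rest)
        num <- suppressWarnings(as.numeric(rest))
        value <- if (is.na(num)) gsub("^<|>$", "", rest) else num
      }
      entries[[paste0(name, ",", scope)]] <- list(value = value,
                                                  scope = scope)
    }
    i <- i + 1L
  }
  entries
}

# --- JCAMP-DX header ------------------------------------------------------
parse_jcamp_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  for (ln in grep("^##", lines, value = TRUE)) {
    eq <- regmatches(ln, regexec("^##\\$?([^=]+)=\\s*(.*)$", ln))[[1]]
    if (length(eq) < 3) next
    name <- trimws(eq[2])
    rest <- trimws(eq[3])
    num <- suppressWarnings(as.numeric(rest))
    entries[[name]] <- list(value = if (is.na(num)) rest else num,
                            scope = "jcamp")
  }
  entries
}

bruker_param_files <- function(dir_path) {
  all <- list.files(dir_path)
  sort(grep("^acqu[0-9]*s$", all, value = TRUE))
}

#' Read vendor parameters from a raw-data directory
#'
#' Recognizes Agilent (`procpar`), Bruker (`acqus`, `acqu2s`, ...) and 1D
#' JCAMP-DX (`*.dx`/`*.jdx`) layouts.  Numeric values are typed as
#' numbers; every entry remembers which file it came from.
#'
#' @param dir_path directory containing the vendor files (or the path of a
#'   JCAMP file itself).
#' @return a `param_set`.
#' @export
read_params <- function(dir_path) {
  if (file.exists(file.path(dir_path, "procpar")))
    return(param_set(parse_procpar(file.path(dir_path, "procpar")),
                     "agilent"))
  bf <- if (dir.exists(dir_path)) bruker_param_files(dir_path) else character()
  if (length(bf)) {
    scopes <- order(nchar(bf), bf)     # acqus, acqu2s, acqu3s, ...
    bf <- bf[scopes]
    entries <- list()
    for (k in seq_along(bf)) {
      dim_scope <- if (bf[k] == "acqus") 1L
                   else as.integer(sub("acqu([0-9]+)s", "\\1", bf[k]))
      entries <- c(entries, parse_bruker_file(file.path(dir_path, bf[k]),
                                              dim_scope))
    }
    return(param_set(entries, "bruker", per_dim_files = bf))
  }
  jc <- if (dir.exists(dir_path))
    list.files(dir_path, pattern = "\\.(dx|jdx)$", full.names = TRUE)
  else if (grepl("\\.(dx|jdx)$", dir_path) && file.exists(dir_path)) dir_path
  else character()
  if (length(jc))
    return(param_set(parse_jcamp_params(jc[1]), "jcamp"))
  stop("no vendor parameters found in ", dir_path)
}

#' Look up a numeric parameter value
#'
#' The symbolic-parameter accessor used in processing scripts.  Agilent and
#' JCAMP parameters are addressed by name (`p("sfrq")`); Bruker parameters
#' use the `"name,n"` form where `n` is the dimension whose parameter file
#' (`acqus` for 1, `acqu2s` for 2, ...) holds the value; a bare Bruker name
#' resolves in dimension 1.
#'
#' @param params a `param_set` from [read_params()].
#' @param name parameter name, optionally `"name,n"` for Bruker.
#' @return the numeric (or character, for text parameters) value.
#' @export
p <- function(params, name) {
  stopifnot(inherits(params, "param_set"))
  key <- name
  if (params$dialect == "bruker" && !grepl(",", name))
    key <- paste0(name, ",1")
  hit <- params$entries[[key]]
  if (is.null(hit))
    stop("parameter '", name, "' not found (searched ",
         if (params$dialect == "bruker")
           paste(params$per_dim_files, collapse = ", ")
         else params$dialect, ")")
  hit$value
}

#' Read a non-uniform sampling schedule file
#'
#' One 0-based increment index per line (the vendor `nuslist` convention).
#' Indices must be unique and non-negative.
#'
#' @param path schedule file.
#' @param grid_size full Nyquist grid length; defaults to
#'   `max(index) + 1`.
#' @return a [sample_schedule()].
#' @export
read_schedule <- function(path, grid_size = NULL) {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt)]
  # tolerate unicode minus from hand-edited files
  txt <- gsub("−", "-", txt)
  idx <- suppressWarnings(as.integer(txt))
  if (anyNA(idx)) stop("malformed schedule line in ", path)
  if (any(idx < 0)) stop("schedule contains a negative index")
  if (is.null(grid_size)) grid_size <- max(idx) + 1L
  sample_schedule(idx, grid_size)
}
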