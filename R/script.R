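# The processing-script dialect: named commands appended to per-dimension
# operation lists, plus file and referencing commands.  Scripts are
# executed, not merely parsed: each command is a function in a locked-down
# interpreter namespace, so arithmetic over parameter lookups
# (p('sfrq') + 5000.0/1.0e6) evaluates naturally while foreign statements
# are rejected.

#' One processing operation in a plan
#' @param name registered command name (e.g. `"SB"`, `"FT"`).
#' @param args named list of argument values.
#' @return an `op_spec`.
#' @keywords internal
op_spec <- function(name, args = list()) {
  if (is.null(op_registry[[name]]))
    stop("unknown operation: ", name)
  structure(list(name = name, args = args), class = "op_spec")
}

# ---- operation registry --------------------------------------------------
# Each entry: apply(v, args, ctx) -> nmr_vector; size(n, args) -> points
# after the op (complex points); invert(args, input_size) -> op_spec of the
# inverse, or NULL if the operation is not invertible.

not_invertible <- function(args, input_size) NULL

op_registry <- list(
  SB = list(
    apply = function(v, a, ctx) apodize(v, do.call(apod_spec, c(list(kind = "SB"), a))),
    size = function(n, a) n,
    invert = function(a, n) op_spec("APODDIV", c(list(kind = "SB"), a))),
  EXPD = list(
    apply = function(v, a, ctx) apodize(v, do.call(apod_spec, c(list(kind = "EXPD"), a))),
    size = function(n, a) n,
    invert = function(a, n) op_spec("APODDIV", c(list(kind = "EXPD"), a))),
  GM = list(
    apply = function(v, a, ctx) apodize(v, do.call(apod_spec, c(list(kind = "GM"), a))),
    size = function(n, a) n,
    invert = function(a, n) op_spec("APODDIV", c(list(kind = "GM"), a))),
  APODDIV = list(                      # inverse apodization (internal)
    apply = function(v, a, ctx) {
      w <- apod_window(do.call(apod_spec, a), length(v$values), v$meta$sw)
      if (min(abs(w)) <= 1e-6)
        stop("cannot invert apodization: window contains a near zero value")
      vec_with_values(v, v$values / w)
    },
    size = function(n, a) n,
    invert = function(a, n) op_spec(a$kind, a[setdiff(names(a), "kind")])),
  ZF = list(
    apply = function(v, a, ctx) do.call(zf, c(list(v), a)),
    size = function(n, a) {
      if (!is.null(a$size)) a$size
      else next_pow2(n) * 2 ^ (if (is.null(a$factor)) 1 else a$factor)
    },
    invert = function(a, n) op_spec("TRUNCATE", list(size = n))),
  TRUNCATE = list(                     # inverse zero fill (internal)
    apply = function(v, a, ctx)
      vec_with_values(v, v$values[seq_len(a$size)]),
    size = function(n, a) a$size,
    invert = function(a, n) op_spec("ZF", list(size = n))),
  FT = list(
    apply = function(v, a, ctx) do.call(ft, c(list(v), a)),
    size = function(n, a) n,
    invert = function(a, n) op_spec("IFT", a)),
  IFT = list(
    apply = function(v, a, ctx) do.call(ift, c(list(v), a)),
    size = function(n, a) n,
    invert = function(a, n) op_spec("FT", a)),
  HFT = list(
    apply = function(v, a, ctx) hft(v),
    size = function(n, a) n,
    invert = not_invertible),
  REAL = list(
    apply = function(v, a, ctx) real_part(v),
    size = function(n, a) n,
    invert = function(a, n) op_spec("HFT")),
  PHASE = list(
    apply = function(v, a, ctx) do.call(phase, c(list(v), a)),
    size = function(n, a) n,
    invert = function(a, n) {
      nm <- names(a)
      if (is.null(nm)) nm <- rep("", length(a))
      for (i in seq_along(a)) {
        # p0/p1 flip sign; the pivot (3rd positional) does not
        if (nm[i] %in% c("p0", "p1") || (nm[i] == "" && i <= 2))
          a[[i]] <- -a[[i]]
      }
      op_spec("PHASE", a)
    }),
  AUTOPHASE = list(
    apply = function(v, a, ctx) phase(v, do.call(autophase, c(list(v), a))),
    size = function(n, a) n,
    invert = not_invertible),
  EXTRACT = list(
    apply = function(v, a, ctx) extract_range(v, a$start, a$end),
    size = function(n, a) a$end - a$start + 1,
    invert = not_invertible),
  MAG = list(
    apply = function(v, a, ctx) magnitude(v),
    size = function(n, a) n,
    invert = not_invertible),
  POWER = list(
    apply = function(v, a, ctx) power_spectrum(v),
    size = function(n, a) n,
    invert = not_invertible),
  REVERSE = list(
    apply = function(v, a, ctx) reverse_spectrum(v),
    size = function(n, a) n,
    invert = not_invertible),
  CSHIFT = list(
    apply = function(v, a, ctx) cshift(v, a$shift),
    size = function(n, a) n,
    invert = not_invertible),
  DC = list(
    apply = function(v, a, ctx) do.call(dc_correct, c(list(v), a)),
    size = function(n, a) n,
    invert = not_invertible),
  TDSS = list(
    apply = function(v, a, ctx) do.call(tdss, c(list(v), a)),
    size = function(n, a) n,
    invert = not_invertible),
  FDSS = list(
    apply = function(v, a, ctx) do.call(fdss, c(list(v), a)),
    size = function(n, a) n,
    invert = not_invertible),
  REGIONS = list(
    apply = function(v, a, ctx) {
      regs <- if (length(a)) lapply(a, function(x) region(x[1], x[2]))
              else list()
      regions(v, regs)
    },
    size = function(n, a) n,
    invert = not_invertible),
  BCPOLY = list(
    apply = function(v, a, ctx) do.call(bcpoly, c(list(v), a)),
    size = function(n, a) n,
    invert = not_invertible),
  BCWHIT = list(
    apply = function(v, a, ctx) do.call(bcwhit, c(list(v), a)),
    size = function(n, a) n,
    invert = not_invertible),
  LP = list(
    apply = function(v, a, ctx) {
      mdl <- do.call(lp_model, a[setdiff(names(a), "predict_count")])
      mdl$predict_count <- a$predict_count
      lp_extend(v, mdl)
    },
    size = function(n, a) n + (if (is.null(a$predict_count)) n %/% 2
                               else a$predict_count),
    invert = not_invertible),
  LPR = list(
    apply = function(v, a, ctx) {
      mdl <- do.call(lp_model, a[setdiff(names(a), "predict_count")])
      mdl$predict_count <- a$predict_count
      lp_replace(v, mdl)
    },
    size = function(n, a) n,
    invert = not_invertible),
  TDCOMB = list(
    apply = function(v, a, ctx) v,    # executed at the batch level
    size = function(n, a) n,
    invert = not_invertible),
  NUSSIM = list(                      # zero points per a simulated schedule
    apply = function(v, a, ctx) {
      fraction <- if (is.null(a$fraction)) 0.2 else a$fraction
      seed <- if (is.null(a$seed)) 1745L else a$seed
      sched <- make_schedule(length(v$values), fraction,
                             if (is.null(a$mode)) "uniform" else a$mode,
                             seed)
      vals <- v$values
      keep <- logical(length(vals))
      keep[sched$indices + 1] <- TRUE
      vals[!keep] <- 0
      out <- vec_with_values(v, vals)
      attr(out, "schedule") <- sched
      out
    },
    size = function(n, a) n,
    invert = not_invertible),
  IST = list(
    apply = function(v, a, ctx) {
      sched <- attr(v, "schedule")
      if (is.null(sched)) sched <- ctx$schedule
      if (is.null(sched))
        stop("IST requires a sampling schedule (nuslist or NUSSIM)")
      cfg <- ist_config(
        iterations = if (is.null(a$iterations)) 500L else a$iterations,
        threshold_fraction = if (is.null(a$threshold)) 0.98 else a$threshold)
      ist_reconstruct(v, sched, cfg)
    },
    size = function(n, a) n,
    invert = not_invertible)
)

#' @export
print.op_spec <- function(x, ...) {
  cat(op_deparse(x), "\n")
  invisible(x)
}

op_deparse <- function(op) {
  fmt <- function(x) {
    if (is.character(x)) paste0("'", x, "'")
    else if (length(x) > 1) paste0("c(", paste(fmt_plain(x), collapse = ","),
                                   ")")
    else fmt_plain(x)
  }
  fmt_plain <- function(x) format(x, digits = 15)
  args <- vapply(seq_along(op$args), function(i) {
    nm <- names(op$args)[i]
    val <- fmt(op$args[[i]])
    if (is.null(nm) || nm == "") val else paste0(nm, "=", val)
  }, character(1))
  paste0(op$name, "(", paste(args, collapse = ", "), ")")
}

# ---- script parsing ------------------------------------------------------

ALLOWED_BUILTINS <- c("+", "-", "*", "/", "^", "(", "c")

check_allowed <- function(expr, commands) {
  if (is.call(expr)) {
    fn <- expr[[1]]
    if (!is.name(fn))
      stop("script error: unsupported construct ", deparse(expr))
    fname <- as.character(fn)
    if (!fname %in% c(commands, "p", ALLOWED_BUILTINS))
      stop("script error: '", fname,
           "' is not a processing command; foreign code is not allowed")
    for (i in seq_along(expr)[-1]) check_allowed(expr[[i]], commands)
  } else if (!(is.numeric(expr) || is.character(expr) || is.name(expr) ||
                 is.null(expr) || is.logical(expr))) {
    stop("script error: unsupported literal ", deparse(expr))
  }
  invisible(TRUE)
}

#' Parse a processing script
#'
#' Scripts consist of file commands (`FID('path')`, `CREATE('out.nv')`),
#' referencing commands (`sw`, `sf`, `ref`, `label`, `skip`), per-dimension
#' operation lists opened by `DIM(n)` (plus `UNDODIM(n)`), and a final
#' `run()`.  Arguments may be positional or named; numeric arguments may
#' be arithmetic expressions over `p('name')` parameter lookups, which are
#' evaluated eagerly against `params`.
#'
#' @param text script text (or a file path when `is_file = TRUE`).
#' @param params optional `param_set` for resolving `p()` lookups at parse
#'   time.
#' @param is_file treat `text` as a path.
#' @return a `process_plan`.
#' @export
parse_script <- function(text, params = NULL, is_file = FALSE) {
  if (is_file) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  exprs <- parse(text = text, keep.source = FALSE)
  plan <- new.env(parent = emptyenv())
  plan$fid_path <- NULL
  plan$sim <- NULL
  plan$create_path <- NULL
  plan$ref <- list()
  plan$stages <- list()
  plan$current <- NULL        # index into stages
  plan$has_run <- FALSE

  add_ref <- function(name, args) {
    plan$ref[[name]] <- args
    invisible(NULL)
  }
  open_dim <- function(d, undo = FALSE) {
    plan$stages <- c(plan$stages,
                     list(list(dim = as.integer(d), ops = list(),
                               undo = undo)))
    plan$current <- length(plan$stages)
  }
  add_op <- function(name, args) {
    if (is.null(plan$current))
      stop("script error: ", name, " before any DIM command")
    st <- plan$stages[[plan$current]]
    st$ops <- c(st$ops, list(op_spec(name, args)))
    plan$stages[[plan$current]] <- st
    invisible(NULL)
  }

  env <- new.env(parent = baseenv())
  cmds <- character(0)
  reg_cmd <- function(nm, fn) {
    assign(nm, fn, envir = env)
    cmds <<- c(cmds, nm)
  }
  reg_cmd("FID", function(path) { plan$fid_path <- path; invisible(NULL) })
  reg_cmd("SIMFID", function(sf = 600, sw = 4000, size = 4096,
                             shift = 4.73, lw = 10, amp = 1,
                             noise = 0, seed = 1) {
    plan$sim <- list(sf = sf, sw = sw, size = size, shift = shift, lw = lw,
                     amp = amp, noise = noise, seed = seed)
    invisible(NULL)
  })
  reg_cmd("CREATE", function(path) {
    plan$create_path <- path
    invisible(NULL)
  })
  for (rn in c("sw", "sf", "ref", "label", "skip")) {
    local({
      nm <- rn
      reg_cmd(nm, function(...) add_ref(nm, list(...)))
    })
  }
  reg_cmd("DIM", function(d) { open_dim(d); invisible(NULL) })
  reg_cmd("UNDODIM", function(d) { open_dim(d, undo = TRUE); invisible(NULL) })
  reg_cmd("run", function() { plan$has_run <- TRUE; invisible(NULL) })
  for (opname in names(op_registry)) {
    if (opname %in% c("APODDIV", "TRUNCATE")) next
    local({
      nm <- opname
      reg_cmd(nm, function(...) add_op(nm, eval_args(list(...))))
    })
  }
  eval_args <- function(a) a
  assign("p", function(name) {
    if (is.null(params))
      stop("script uses p('", name, "') but no parameter set was supplied")
    p(params, name)
  }, envir = env)

  for (e in exprs) {
    check_allowed(e, cmds)
    eval(e, envir = env)
  }
  if (!plan$has_run) stop("script must end with run")
  structure(list(fid_path = plan$fid_path, sim = plan$sim,
                 create_path = plan$create_path,
                 ref = plan$ref, stages = plan$stages, executed = FALSE),
            class = "process_plan")
}

#' Regenerate script text from a plan
#'
#' Produces canonical script text; re-parsing it yields an identical plan
#' (parameter lookups that were already resolved stay resolved).
#' @param plan a `process_plan`.
#' @return a single string of script text.
#' @export
script_text <- function(plan) {
  fmt <- function(x) {
    if (is.character(x)) paste0("'", x, "'")
    else format(x, digits = 15)
  }
  out <- character(0)
  if (!is.null(plan$fid_path))
    out <- c(out, paste0("FID(", fmt(plan$fid_path), ")"))
  if (!is.null(plan$sim))
    out <- c(out, paste0("SIMFID(",
                         paste(names(plan$sim), vapply(plan$sim, fmt,
                                                       character(1)),
                               sep = "=", collapse = ", "), ")"))
  if (!is.null(plan$create_path))
    out <- c(out, paste0("CREATE(", fmt(plan$create_path), ")"))
  for (nm in names(plan$ref)) {
    args <- vapply(plan$ref[[nm]], fmt, character(1))
    out <- c(out, paste0(nm, "(", paste(args, collapse = ", "), ")"))
  }
  for (st in plan$stages) {
    out <- c(out, paste0(if (st$undo) "UNDODIM(" else "DIM(", st$dim, ")"))
    for (op in st$ops) out <- c(out, op_deparse(op))
  }
  out <- c(out, "run()")
  paste(out, collapse = "\n")
}

#' @export
print.process_plan <- function(x, ...) {
  cat("<process_plan>\n")
  cat(script_text(x), "\n")
  invisible(x)
}

apply_op <- function(v, op, ctx = list()) {
  entry <- op_registry[[op$name]]
  if (is.null(entry)) stop("unknown operation: ", op$name)
  entry$apply(v, op$args, ctx)
}

op_output_size <- function(n, op) {
  op_registry[[op$name]]$size(n, op$args)
}

# preferred position classes for interactive insertion: time-domain
# preparation < transform < frequency-domain corrections
op_order_class <- function(name) {
  pre_ft <- c("TDCOMB", "LPR", "TDSS", "NUSSIM", "IST", "LP", "SB",
              "EXPD", "GM", "ZF")
  post_ft <- c("PHASE", "AUTOPHASE", "HFT", "REAL", "EXTRACT", "REGIONS",
               "BCPOLY", "BCWHIT", "FDSS", "MAG", "POWER", "REVERSE",
               "CSHIFT", "DC")
  if (name %in% pre_ft) 1L else if (name == "FT") 2L
  else if (name %in% post_ft) 3L else 2L
}

#' Append an operation to a dimension's list at its preferred position
#'
#' Mirrors interactive insertion: an apodization added after the Fourier
#' transform is placed before it, a phase correction is placed after it.
#' Within an ordering class the operation goes last.  Explicit script
#' order always wins -- this helper is for programmatic plan building.
#'
#' @param plan a `process_plan`.
#' @param dim dimension whose (last) stage receives the operation; a new
#'   stage is opened if none exists.
#' @param name registered operation name.
#' @param args named list of arguments.
#' @return the modified plan.
#' @export
plan_append_op <- function(plan, dim, name, args = list()) {
  stopifnot(inherits(plan, "process_plan"))
  op <- op_spec(name, args)
  idx <- Position(function(st) st$dim == dim && !st$undo, plan$stages,
                  right = TRUE)
  if (is.na(idx)) {
    plan$stages <- c(plan$stages,
                     list(list(dim = as.integer(dim), ops = list(op),
                               undo = FALSE)))
    return(plan)
  }
  ops <- plan$stages[[idx]]$ops
  cls <- op_order_class(name)
  classes <- vapply(ops, function(o) op_order_class(o$name), integer(1))
  pos <- Position(function(c) c > cls, classes)
  if (is.na(pos)) ops <- c(ops, list(op))
  else ops <- append(ops, list(op), after = pos - 1L)
  plan$stages[[idx]]$ops <- ops
  plan
}

#' Build the inverse operation list for a processed dimension
#'
#' Returns the inverses of the given operations in reverse order, so that
#' executing them undoes the original processing.  Only ZF, FT, IFT, REAL,
#' PHASE and the apodization windows are invertible; inverting an
#' apodization later verifies that its window is nowhere near zero.
#'
#' @param ops list of `op_spec` (the forward list).
#' @param input_sizes integer vector: the vector length (complex points)
#'   seen at the input of each forward op.
#' @return list of inverse `op_spec`s.
#' @export
invert_ops <- function(ops, input_sizes) {
  stopifnot(length(ops) == length(input_sizes))
  inv <- list()
  for (i in rev(seq_along(ops))) {
    entry <- op_registry[[ops[[i]]$name]]
    io <- entry$invert(ops[[i]]$args, input_sizes[i])
    if (is.null(io))
      stop(ops[[i]]$name, " is not invertible")
    inv <- c(inv, list(io))
  }
  inv
}
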