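# Solver-agnostic linear/mixed-integer programming layer.
#
# Programs are assembled as sparse equality-constrained specifications and
# solved by the HiGHS solver, reached through SciPy in a persistent Python
# worker process on a localhost socket (one interpreter start per session,
# binary wire format).  `boot::simplex()` offers an independent route for
# cross-checking small programs in the test suite.

.lp_state <- new.env(parent = emptyenv())

#' Specify a linear or mixed-integer program
#'
#' Equality-constrained minimization: `min c'x  s.t.  A x = rhs, lb <= x <= ub`,
#' with optional per-variable integrality.  Variables pinned by `fixed` get
#' equal lower and upper bounds.
#'
#' @param objective numeric vector of nonnegative objective weights.
#' @param a_i,a_j,a_x sparse triplet representation of the constraint matrix.
#' @param rhs right-hand side, one entry per constraint row.
#' @param lb,ub bounds; `-Inf`/`Inf` allowed.
#' @param integrality logical vector marking integer variables.
#' @param fixed optional named list/vector: `fixed[j]` pins variable `j`.
#' @return object of class `"program_spec"`.
#' @export
program_spec <- function(objective, a_i, a_j, a_x, rhs,
                         lb = rep(0, length(objective)),
                         ub = rep(Inf, length(objective)),
                         integrality = rep(FALSE, length(objective)),
                         fixed = NULL) {
  nvar <- length(objective)
  stopifnot(length(lb) == nvar, length(ub) == nvar, length(integrality) == nvar,
            length(a_i) == length(a_j), length(a_j) == length(a_x))
  if (any(objective < 0)) stop("objective weights must be nonnegative")
  if (length(a_j) > 0 && max(a_j) > nvar)
    stop("constraint matrix refers to more variables than the objective has")
  if (!is.null(fixed)) {
    idx <- as.integer(names(fixed))
    lb[idx] <- ub[idx] <- as.numeric(fixed)
  }
  structure(list(objective = as.numeric(objective),
                 a_i = as.integer(a_i), a_j = as.integer(a_j),
                 a_x = as.numeric(a_x), rhs = as.numeric(rhs),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 integrality = as.logical(integrality)),
            class = "program_spec")
}

#' @export
print.program_spec <- function(x, ...) {
  cat(sprintf("<program_spec> %d variables (%d integer), %d constraints, %d nonzeros\n",
              length(x$objective), sum(x$integrality), length(x$rhs), length(x$a_x)))
  invisible(x)
}

.lp_python <- function() {
  getOption("optcycle.python", Sys.getenv("OPTCYCLE_PYTHON", "python"))
}

.lp_worker_script <- function() {
  p <- system.file("python", "lp_worker.py", package = "optcycle")
  if (!nzchar(p)) stop("lp_worker.py not found; is the package installed?")
  p
}

.lp_start <- function() {
  for (attempt in 1:20) {
    port <- 20000L + sample.int(30000L, 1)
    srv <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (!is.null(srv)) break
  }
  if (is.null(srv)) stop("could not open a local port for the solver worker")
  log <- file.path(tempdir(), "optcycle-lp-worker.log")
  system2(.lp_python(), c(.lp_worker_script(), port),
          wait = FALSE, stdout = log, stderr = log)
  con <- tryCatch(socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 60),
                  error = function(e) NULL)
  close(srv)
  if (is.null(con)) {
    msg <- if (file.exists(log)) paste(readLines(log, warn = FALSE), collapse = "\n") else ""
    stop("solver worker failed to start: ", msg)
  }
  .lp_state$con <- con
  invisible(con)
}

.lp_con <- function() {
  con <- .lp_state$con
  if (is.null(con) || !isOpen(con)) .lp_start() else con
  .lp_state$con
}

#' Shut down the solver worker process
#'
#' Called automatically when the package unloads; safe to call at any time.
#' @export
lp_stop <- function() {
  con <- .lp_state$con
  if (!is.null(con) && isOpen(con)) {
    try({
      writeBin(as.integer(c(0L, 0L, 0L, 0L)), con, size = 4L, endian = "little")
      flush(con)
    }, silent = TRUE)
    try(close(con), silent = TRUE)
  }
  .lp_state$con <- NULL
  invisible(NULL)
}

.onUnload <- function(libpath) {
  lp_stop()
}

#' Solve a program
#'
#' Sends the specification to the solver backend and reports the result
#' faithfully: solver failure becomes `status = "failed"`, never a silent
#' fallback.  Values within the integrality tolerance of an integer are
#' rounded in the `values_rounded` field and flagged via `is_integral`.
#'
#' @param spec a `"program_spec"`.
#' @param mip solve with integrality constraints (the specification's `integrality` field
#'   marks which variables).
#' @param method LP algorithm hint: `"simplex"` (HiGHS default) or `"ipm"`
#'   (interior point with crossover; often faster on highly degenerate
#'   uniform-weighted programs).  Ignored for MIPs.
#' @param tol integrality tolerance (default `1e-7`).
#' @param time_limit per-program wall limit in seconds
#'   (option `optcycle.lp_time_limit`, default none).
#' @return object of class `"lp_solution"`: `status` (one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`, `"failed"`), `objective`, `values`,
#'   `values_rounded`, `is_integral`.
#' @export
solve_program <- function(spec, mip = any(spec$integrality),
                          method = getOption("optcycle.lp_method", "simplex"),
                          tol = getOption("optcycle.integrality_tol", 1e-7),
                          time_limit = getOption("optcycle.lp_time_limit", 0)) {
  stopifnot(inherits(spec, "program_spec"))
  con <- .lp_con()
  ptype <- if (mip) 1L else if (identical(method, "ipm")) 2L else 0L
  nvar <- length(spec$objective)
  ncon <- length(spec$rhs)
  lb <- spec$lb; lb[lb == -Inf] <- -1e300
  ub <- spec$ub; ub[ub == Inf] <- 1e300
  # single buffered write: many small TCP segments would stall on Nagle's
  # algorithm and cost tens of milliseconds per program
  msg <- c(writeBin(as.integer(c(1L, ptype, nvar, ncon, length(spec$a_x))),
                    raw(), size = 4L, endian = "little"),
           writeBin(as.numeric(time_limit), raw(), size = 8L, endian = "little"),
           writeBin(spec$objective, raw(), size = 8L, endian = "little"),
           writeBin(spec$a_i, raw(), size = 4L, endian = "little"),
           writeBin(spec$a_j, raw(), size = 4L, endian = "little"),
           writeBin(spec$a_x, raw(), size = 8L, endian = "little"),
           writeBin(spec$rhs, raw(), size = 8L, endian = "little"),
           writeBin(lb, raw(), size = 8L, endian = "little"),
           writeBin(ub, raw(), size = 8L, endian = "little"),
           writeBin(as.integer(spec$integrality), raw(), size = 4L, endian = "little"))
  writeBin(msg, con)
  flush(con)
  t0 <- proc.time()[["elapsed"]]
  status_code <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(status_code) == 0) {
    lp_stop()
    stop("solver worker terminated unexpectedly")
  }
  objective <- readBin(con, "numeric", n = 1L, size = 8L, endian = "little")
  values <- readBin(con, "numeric", n = nvar, size = 8L, endian = "little")
  status <- switch(as.character(status_code),
                   "0" = "optimal", "2" = "infeasible", "3" = "unbounded", "failed")
  # optional structured log: one JSON record per solved program
  log_path <- getOption("optcycle.lp_log", NULL)
  if (!is.null(log_path)) {
    rec <- jsonlite::toJSON(list(
      kind = if (mip) "mip" else paste0("lp-", method),
      n_var = nvar, n_con = ncon, nnz = length(spec$a_x),
      status = status,
      objective = if (status == "optimal") objective else NA,
      seconds = proc.time()[["elapsed"]] - t0), auto_unbox = TRUE, digits = NA)
    cat(rec, "\n", sep = "", file = log_path, append = TRUE)
  }
  rounded <- round(values)
  near_int <- abs(values - rounded) <= tol
  structure(list(status = status,
                 objective = if (status == "optimal") objective else NA_real_,
                 values = values,
                 values_rounded = ifelse(near_int, rounded, values),
                 is_integral = all(near_int),
                 tol = tol),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat(sprintf("<lp_solution> status %s, objective %s, integral: %s\n",
              x$status,
              if (is.na(x$objective)) "NA" else format(x$objective),
              x$is_integral))
  invisible(x)
}
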