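# Triangle-loss (volume-optimal) minimization.
#
# For a finite bar with birth/death pair (sigma, tau) the persistent volume
# program searches over 2-chains v supported on the triangles born in the
# bar's window and no later than tau in the refined order, with v_tau pinned
# to 1 and the boundary required to vanish on every edge after sigma.  The
# boundary of a solution provably has exactly the bar's lifespan, and
# replacing finite-bar representatives with these boundaries (keeping the
# R = DV representatives for essential bars) yields a persistent homology
# cycle basis.  The nonvanishing of the boundary on sigma itself is not
# LP-expressible and is verified on the solution instead: a persistent
# volume always exists, so a vanishing boundary signals a pairing bug.

#' Triangle area from its three edge lengths (Heron's formula)
#'
#' Degenerate triples (triangle inequality violated, as happens for
#' non-metric dissimilarities) get area 0 through a clamped radicand.
#'
#' @param a,b,c edge lengths (vectorized).
#' @return areas; attribute `"clamped"` counts clamped radicands.
#' @export
heron_area <- function(a, b, c) {
  s <- (a + b + c) / 2
  rad <- s * (s - a) * (s - b) * (s - c)
  clamped <- sum(rad < 0)
  rad[rad < 0] <- 0
  structure(sqrt(rad), clamped = clamped)
}

.triangle_weights <- function(filtration, weighting, tri_idx) {
  if (weighting == "uniform") return(rep(1, length(tri_idx)))
  tm <- filtration$simplices[[3]]$vertices[tri_idx, , drop = FALSE]
  d <- filtration$dist
  a <- d[cbind(tm[, 1] + 1L, tm[, 2] + 1L)]
  b <- d[cbind(tm[, 1] + 1L, tm[, 3] + 1L)]
  cc <- d[cbind(tm[, 2] + 1L, tm[, 3] + 1L)]
  w <- heron_area(a, b, cc)
  if (attr(w, "clamped") > 0)
    message(sprintf("%d degenerate triangle(s) received area 0", attr(w, "clamped")))
  as.numeric(w)
}

#' Simplex window of a finite bar
#'
#' The edges born by the bar's death and strictly after the birth edge in
#' the per-dimension order (`Fn`, the rows whose boundary coefficient must
#' vanish), the triangles born within the closed birth window and strictly
#' before the death triangle (`Fn1`), and `Fhat = Fn1 + {tau}`.
#'
#' @param ph a `"ph"` fit.
#' @param k bar index.
#' @return list with `sigma`, `tau`, `Fn`, `Fn1`, `Fhat`.
#' @export
triangle_window <- function(ph, k) {
  bars <- ph$basis$bars
  stopifnot(k >= 1, k <= nrow(bars))
  if (!is.finite(bars$death[k]))
    stop("volume is undefined for an essential bar")
  sigma <- bars$birth_edge[k]
  tau <- bars$death_triangle[k]
  b <- bars$birth[k]; d <- bars$death[k]
  edge_birth <- ph$filtration$simplices[[2]]$birth
  tri_birth <- ph$filtration$simplices[[3]]$birth
  ne_d <- sum(edge_birth <= d)
  Fn <- if (ne_d > sigma) (sigma + 1L):ne_d else integer(0)
  t_lo <- match(TRUE, tri_birth >= b)
  Fn1 <- if (!is.na(t_lo) && t_lo <= tau - 1L) t_lo:(tau - 1L) else integer(0)
  list(sigma = sigma, tau = tau, birth = b, death = d,
       Fn = Fn, Fn1 = Fn1, Fhat = c(Fn1, tau))
}

# boundary triplets of the window triangles, via a precomputed whole matrix
# or built per bar (identical output, different memory profile).  The whole
# matrix is stored column-major (three entries per triangle), so a window --
# always a contiguous run of triangle positions -- is a cheap slice.
.window_boundary <- function(ph, tri_idx, build_mode) {
  if (build_mode == "per_bar")
    return(.tri_boundary_triplets(ph, tri_idx))
  if (is.null(ph$env$b2_rows)) {
    nt <- nrow(ph$filtration$simplices[[3]]$vertices)
    tb <- .tri_boundary_triplets(ph, seq_len(nt))
    o <- order(tb$j)
    ph$env$b2_rows <- matrix(tb$i[o], nrow = 3)   # column t = faces of triangle t
    ph$env$b2_signs <- matrix(tb$x[o], nrow = 3)
  }
  k <- length(tri_idx)
  list(i = as.vector(ph$env$b2_rows[, tri_idx, drop = FALSE]),
       j = rep(seq_len(k), each = 3),
       x = as.vector(ph$env$b2_signs[, tri_idx, drop = FALSE]))
}

#' Build the triangle-loss program for one bar
#'
#' Variables `v+`, `v-` over the window triangles with `v_tau` pinned to 1;
#' one equality row per edge in `Fn` zeroing the boundary there.
#'
#' @param ph a `"ph"` fit.
#' @param window output of [triangle_window()].
#' @param weighting `"uniform"` or `"area"`.
#' @param integral mark `v+`, `v-` integer.
#' @param build_mode `"whole_matrix"` (slice a precomputed full boundary
#'   matrix) or `"per_bar"` (rebuild the needed columns).
#' @return a `"program_spec"`.
#' @export
assemble_triangle_program <- function(ph, window, weighting = c("uniform", "area"),
                                      integral = FALSE,
                                      build_mode = c("whole_matrix", "per_bar")) {
  weighting <- match.arg(weighting)
  build_mode <- match.arg(build_mode)
  fh <- window$Fhat
  nf <- length(fh)
  tb <- .window_boundary(ph, fh, build_mode)
  # Fn is the contiguous run of edge positions (sigma, ne_d]
  lo <- window$sigma
  hi <- if (length(window$Fn)) window$Fn[length(window$Fn)] else window$sigma
  keep <- tb$i > lo & tb$i <= hi
  row_of <- tb$i[keep] - lo
  ncon <- length(window$Fn)
  ai <- c(row_of, row_of)
  aj <- c(tb$j[keep], nf + tb$j[keep])
  ax <- c(tb$x[keep], -tb$x[keep])
  w <- .triangle_weights(ph$filtration, weighting, fh)
  tau_slot <- nf  # tau is last in Fhat
  fixed <- stats::setNames(list(1, 0),
                           c(as.character(tau_slot), as.character(nf + tau_slot)))
  program_spec(objective = c(w, w),
               a_i = ai, a_j = aj, a_x = ax, rhs = numeric(ncon),
               lb = numeric(2 * nf), ub = rep(Inf, 2 * nf),
               integrality = rep(integral, 2 * nf),
               fixed = fixed)
}

# exact boundary of a dimension-2 chain, as a dimension-1 chain
chain_boundary <- function(ph, v) {
  stopifnot(inherits(v, "chain"), v$dim == 2L)
  tb <- .tri_boundary_triplets(ph, v$idx)
  num <- v$num[tb$j] * tb$x
  den <- v$den[tb$j]
  # accumulate per edge exactly
  edges <- sort(unique(tb$i))
  onum <- oden <- numeric(length(edges))
  oden[] <- 1
  pos <- match(tb$i, edges)
  for (t in seq_along(pos)) {
    r <- rat_add(onum[pos[t]], oden[pos[t]], num[t], den[t])
    onum[pos[t]] <- r$num; oden[pos[t]] <- r$den
  }
  chain(1L, edges, onum, oden)
}

#' Volume-optimal cycle basis
#'
#' Solves the triangle-loss program for every finite bar and replaces the
#' bar's representative with the boundary of the optimal volume; essential
#' bars keep their R = DV representatives.  Each solution is verified post
#' hoc: the boundary's coefficient on the birth edge must be nonzero and the
#' recomputed lifespan must equal the bar exactly.
#'
#' @param ph a `"ph"` fit.
#' @param weighting `"uniform"` (triangle count) or `"area"` (Heron area).
#' @param integral solve as mixed-integer programs.
#' @param build_mode see [assemble_triangle_program()].
#' @param var_cap skip bars whose program would exceed this many variables
#'   (logged as a warning; the original representative is kept).
#' @param tol integrality tolerance for lifting solver values to rationals.
#' @param verify_lifespans recompute each output boundary's lifespan by exact
#'   reduction and require it to match the bar (on by default; the
#'   birth-edge nonvanishing check always runs).
#' @return object of class `"tri_opt"`: optimized `basis`, per-bar `report`,
#'   list `volumes` of the optimal 2-chains (NULL for essential/skipped).
#' @export
optimize_volume_basis <- function(ph, weighting = c("uniform", "area"),
                                  integral = FALSE,
                                  build_mode = c("whole_matrix", "per_bar"),
                                  var_cap = 2e7,
                                  tol = getOption("optcycle.integrality_tol", 1e-7),
                                  verify_lifespans = TRUE) {
  weighting <- match.arg(weighting)
  build_mode <- match.arg(build_mode)
  stopifnot(inherits(ph, "ph"))
  basis <- ph$basis
  m <- nrow(basis$bars)
  rows <- vector("list", m)
  volumes <- vector("list", m)
  fin <- which(is.finite(basis$bars$death))
  if (length(fin) > 0)  # expand all baseline volumes in one pass
    .v_columns(ph$dec2, basis$bars$death_triangle[fin])
  for (k in seq_len(m)) {
    if (!is.finite(basis$bars$death[k])) {
      rows[[k]] <- data.frame(bar = k, birth = basis$bars$birth[k], death = Inf,
                              orig_t = NA_real_, objective = NA_real_,
                              opt_t = NA_real_, opt_loss = NA_real_,
                              orig_loss = NA_real_,
                              boundary_l0 = NA_real_, integral_solution = NA,
                              in_pm1 = NA, skipped = FALSE, status = "essential")
      next
    }
    win <- triangle_window(ph, k)
    if (2 * length(win$Fhat) > var_cap) {
      warning(sprintf("bar %d skipped: %d variables exceed the cap of %g",
                      k, 2 * length(win$Fhat), var_cap))
      rows[[k]] <- data.frame(bar = k, birth = win$birth, death = win$death,
                              orig_t = NA_real_, objective = NA_real_,
                              opt_t = NA_real_, opt_loss = NA_real_,
                              orig_loss = NA_real_,
                              boundary_l0 = NA_real_, integral_solution = NA,
                              in_pm1 = NA, skipped = TRUE, status = "skipped")
      next
    }
    spec <- assemble_triangle_program(ph, win, weighting, integral, build_mode)
    sol <- solve_program(spec, mip = integral)
    if (sol$status != "optimal")
      stop(sprintf("triangle program for bar %d returned status '%s'", k, sol$status))
    nf <- length(win$Fhat)
    vvals <- sol$values_rounded[seq_len(nf)] - sol$values_rounded[nf + seq_len(nf)]
    nz <- which(abs(vvals) > tol)
    r <- rat_approx(vvals[nz], tol = tol)
    v <- chain(2L, win$Fhat[nz], r$num, r$den)
    bx <- chain_boundary(ph, v)
    if (!(win$sigma %in% bx$idx))
      stop(sprintf("volume for bar %d has zero boundary on the birth edge; pairing is inconsistent", k))
    if (verify_lifespans) {
      ls <- chain_lifespan(ph, bx)
      if (!isTRUE(all.equal(ls[1], win$birth)) || !isTRUE(all.equal(ls[2], win$death)))
        stop(sprintf("volume boundary for bar %d has lifespan [%g, %g) instead of [%g, %g)",
                     k, ls[1], ls[2], win$birth, win$death))
    }
    w <- .triangle_weights(ph$filtration, weighting, win$Fhat[nz])
    vorig <- original_volume(ph, k)
    worig <- .triangle_weights(ph$filtration, weighting, vorig$idx)
    volumes[[k]] <- v
    basis$reps[[k]] <- bx
    rows[[k]] <- data.frame(
      bar = k, birth = win$birth, death = win$death,
      orig_t = chain_l0(vorig),
      orig_loss = if (weighting == "uniform") chain_l0(vorig) else sum(worig),
      objective = sol$objective,
      opt_t = chain_l0(v),
      opt_loss = if (weighting == "uniform") chain_l0(v) else sum(w),
      boundary_l0 = chain_l0(bx),
      integral_solution = sol$is_integral,
      in_pm1 = all(abs(v$num) == 1 & v$den == 1),
      skipped = FALSE, status = sol$status)
  }
  report <- if (m > 0) do.call(rbind, rows) else
    data.frame(bar = integer(0), birth = numeric(0), death = numeric(0),
               orig_t = numeric(0), orig_loss = numeric(0), objective = numeric(0),
               opt_t = numeric(0), opt_loss = numeric(0), boundary_l0 = numeric(0),
               integral_solution = logical(0), in_pm1 = logical(0),
               skipped = logical(0), status = character(0))
  structure(list(basis = basis,
                 report = report,
                 volumes = volumes, weighting = weighting,
                 integral = integral, build_mode = build_mode),
            class = "tri_opt")
}

#' @export
print.tri_opt <- function(x, ...) {
  done <- x$report[!is.na(x$report$objective), , drop = FALSE]
  cat(sprintf("<tri_opt> %s weights, %s, %s build; %d bars optimized\n",
              x$weighting, if (x$integral) "MIP" else "LP", x$build_mode,
              nrow(done)))
  if (nrow(done) > 0)
    cat(sprintf("  mean volume-loss ratio: %.4f\n",
                mean(done$opt_loss / pmax(done$orig_loss, .Machine$double.eps))))
  invisible(x)
}
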