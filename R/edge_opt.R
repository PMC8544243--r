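# Edge-loss minimization of cycle representatives.
#
# Two program families share the machinery here:
#  * the persistent-basis program: each representative is rewritten as
#    x = xOrig + D2 q + A p, where q ranges over (a column basis of) the
#    triangles born by Birth(xOrig) and p over the other basis cycles born
#    and dying no later than xOrig; solving for minimal weighted l1 of x and
#    replacing the representative in the basis preserves every lifespan and
#    keeps the collection a persistent homology cycle basis;
#  * the filtered-cycle-basis program: x = xOrig + sum w_r g_r + sum v_s f_s
#    over the boundary basis {g_r} and cycle extension {f_s} of the step just
#    before xOrig's birth edge; births are preserved but deaths may grow.
#
# Both are solved in the split form x = x+ - x- with nonnegative parts
# carrying the objective; combination coefficients stay free.

# per-edge weights: 1 (uniform) or the dissimilarity between the endpoints
.edge_weights <- function(filtration, weighting, edge_idx) {
  if (weighting == "uniform") return(rep(1, length(edge_idx)))
  em <- filtration$simplices[[2]]$vertices
  filtration$dist[cbind(em[edge_idx, 1] + 1L, em[edge_idx, 2] + 1L)]
}

# edge-index lookup matrix (0-based vertices -> edge position), built lazily
.edge_index <- function(ph) {
  if (!is.null(ph$env$edge_index)) return(ph$env$edge_index)
  em <- ph$filtration$simplices[[2]]$vertices
  n <- ph$filtration$n_points
  m <- matrix(NA_integer_, n, n)
  m[cbind(em[, 1] + 1L, em[, 2] + 1L)] <- seq_len(nrow(em))
  m[cbind(em[, 2] + 1L, em[, 1] + 1L)] <- seq_len(nrow(em))
  ph$env$edge_index <- m
  m
}

# boundary triplets of the given triangles against the full edge order
.tri_boundary_triplets <- function(ph, tri_idx) {
  if (length(tri_idx) == 0)
    return(list(i = integer(0), j = integer(0), x = numeric(0)))
  tm <- ph$filtration$simplices[[3]]$vertices[tri_idx, , drop = FALSE]
  ei <- .edge_index(ph)
  rows <- c(ei[cbind(tm[, 2] + 1L, tm[, 3] + 1L)],   # drop first vertex: +
            ei[cbind(tm[, 1] + 1L, tm[, 3] + 1L)],   # drop second: -
            ei[cbind(tm[, 1] + 1L, tm[, 2] + 1L)])   # drop third: +
  k <- length(tri_idx)
  list(i = rows, j = rep(seq_len(k), 3), x = rep(c(1, -1, 1), each = k))
}

#' Assemble the context of one persistent-basis edge program
#'
#' Collects the index sets of the edge-loss program for the `j`-th bar of a
#' cycle basis: the edges born by the bar's birth (constraint rows and
#' objective variables), the triangles born by then (optionally reduced to
#' the column basis `ph$rhat`), and the other basis cycles whose birth and
#' death do not exceed the bar's.
#'
#' @param ph a `"ph"` fit.
#' @param basis the current `"cycle_basis"` (representatives may already have
#'   been replaced by earlier optimizations).
#' @param j bar index.
#' @param weighting `"uniform"` or `"length"`.
#' @param use_rhat restrict triangle variables to the column basis.
#' @return a list with the program's ingredients.
#' @export
edge_program_context <- function(ph, basis, j, weighting = c("uniform", "length"),
                                 use_rhat = TRUE) {
  weighting <- match.arg(weighting)
  bars <- basis$bars
  stopifnot(j >= 1, j <= nrow(bars))
  b <- bars$birth[j]; d <- bars$death[j]
  edge_birth <- ph$filtration$simplices[[2]]$birth
  ne <- sum(edge_birth <= b)
  tri_birth <- if (ph$filtration$max_dim >= 2) ph$filtration$simplices[[3]]$birth else numeric(0)
  nt <- sum(tri_birth <= b)
  tri_set <- if (use_rhat) ph$rhat[ph$rhat <= nt] else seq_len(nt)
  Q <- which(bars$birth <= b & bars$death <= d)
  Q <- Q[Q != j]
  xOrig <- basis$reps[[j]]
  if (length(xOrig$idx) > 0 && max(xOrig$idx) > ne)
    stop("representative supported on edges born after its own birth; persistence is inconsistent")
  for (i in Q)
    if (length(basis$reps[[i]]$idx) > 0 && max(basis$reps[[i]]$idx) > ne)
      stop("basis cycle in Q supported outside the program's edge set")
  list(j = j, xOrig = xOrig, edge_set = seq_len(ne), triangle_set = tri_set,
       Q = Q, q_chains = basis$reps[Q],
       weights = .edge_weights(ph$filtration, weighting, seq_len(ne)),
       weighting = weighting)
}

#' Build the persistent-basis edge-loss program
#'
#' Variables are ordered `x+` (edges), `x-` (edges), `q` (triangles, free),
#' `p` (basis cycles, free); one equality row per edge in the window encodes
#' `x+ - x- - D2 q - A p = xOrig`.
#'
#' @param ph a `"ph"` fit.
#' @param ctx output of [edge_program_context()].
#' @param integral mark `x+`, `x-` integer (the combination coefficients stay
#'   continuous).
#' @return a `"program_spec"`.
#' @export
assemble_edge_program <- function(ph, ctx, integral = FALSE) {
  ne <- length(ctx$edge_set)
  ntr <- length(ctx$triangle_set)
  nq <- length(ctx$Q)
  nvar <- 2 * ne + ntr + nq

  tb <- .tri_boundary_triplets(ph, ctx$triangle_set)
  ai <- c(seq_len(ne), seq_len(ne), tb$i)
  aj <- c(seq_len(ne), ne + seq_len(ne), 2 * ne + tb$j)
  ax <- c(rep(1, ne), rep(-1, ne), -tb$x)
  if (nq > 0) {
    for (t in seq_len(nq)) {
      ch <- ctx$q_chains[[t]]
      ai <- c(ai, ch$idx)
      aj <- c(aj, rep(2 * ne + ntr + t, length(ch$idx)))
      ax <- c(ax, -(ch$num / ch$den))
    }
  }
  rhs <- chain_dense(ctx$xOrig, ne)
  program_spec(objective = c(ctx$weights, ctx$weights, numeric(ntr + nq)),
               a_i = ai, a_j = aj, a_x = ax, rhs = rhs,
               lb = c(numeric(2 * ne), rep(-Inf, ntr + nq)),
               ub = rep(Inf, nvar),
               integrality = c(rep(integral, 2 * ne), rep(FALSE, ntr + nq)))
}

# lift a solved split solution back to an exact chain on the edge order
.solution_chain <- function(sol, ne, tol) {
  x <- sol$values_rounded[seq_len(ne)] - sol$values_rounded[ne + seq_len(ne)]
  nz <- which(abs(x) > tol)
  r <- rat_approx(x[nz], tol = tol)
  chain(1L, nz, r$num, r$den)
}

#' Edge-loss optimization of a persistent homology cycle basis
#'
#' Iterates over the bars in order, solves the edge-loss program for each,
#' and (by default) replaces the representative in the basis before moving
#' on, so later programs see the optimized cycles.  Lifespans are preserved
#' exactly; the result is again a persistent homology cycle basis.
#'
#' @param ph a `"ph"` fit.
#' @param weighting `"uniform"` (edge count) or `"length"` (total length).
#' @param integral solve as a mixed-integer program.
#' @param use_rhat use the triangle column basis acceleration.
#' @param replacement replace each representative before optimizing the next
#'   (disable to study the effect; the optimized set may then fail to be a
#'   basis in rare duplicate-bar situations).
#' @param tol integrality tolerance for lifting solver values to rationals.
#' @return object of class `"edge_opt"`: the optimized `basis`, a per-bar
#'   `report` data frame, and the call parameters.
#' @export
optimize_persistent_basis <- function(ph, weighting = c("uniform", "length"),
                                      integral = FALSE, use_rhat = TRUE,
                                      replacement = TRUE,
                                      tol = getOption("optcycle.integrality_tol", 1e-7)) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ph, "ph"))
  basis <- ph$basis
  m <- nrow(basis$bars)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    ctx <- edge_program_context(ph, basis, j, weighting, use_rhat = use_rhat)
    spec <- assemble_edge_program(ph, ctx, integral = integral)
    sol <- solve_program(spec, mip = integral)
    if (sol$status != "optimal")
      stop(sprintf("edge program for bar %d returned status '%s' (xOrig is always feasible)",
                   j, sol$status))
    ne <- length(ctx$edge_set)
    xnew <- .solution_chain(sol, ne, tol)
    w_orig <- sum(ctx$weights[ctx$xOrig$idx])
    w_new <- sum(ctx$weights[xnew$idx])
    rows[[j]] <- data.frame(
      bar = j, birth = basis$bars$birth[j], death = basis$bars$death[j],
      orig_l0 = chain_l0(ctx$xOrig), orig_l1 = chain_l1(ctx$xOrig),
      orig_loss = if (weighting == "uniform") chain_l0(ctx$xOrig) else w_orig,
      objective = sol$objective,
      opt_l0 = chain_l0(xnew),
      opt_loss = if (weighting == "uniform") chain_l0(xnew) else w_new,
      integral_solution = sol$is_integral,
      in_pm1 = all(abs(xnew$num) == 1 & xnew$den == 1) || chain_is_zero(xnew),
      n_var = length(spec$objective), n_con = length(spec$rhs),
      status = sol$status)
    if (replacement) basis$reps[[j]] <- xnew
    else rows[[j]]$opt_chain <- I(list(xnew))
  }
  report <- if (m > 0) do.call(rbind, rows) else
    data.frame(bar = integer(0), birth = numeric(0), death = numeric(0),
               orig_l0 = numeric(0), orig_l1 = numeric(0), orig_loss = numeric(0),
               objective = numeric(0), opt_l0 = numeric(0), opt_loss = numeric(0),
               integral_solution = logical(0), in_pm1 = logical(0),
               n_var = integer(0), n_con = integer(0), status = character(0))
  structure(list(basis = basis, report = report, weighting = weighting,
                 integral = integral, program = "prshcb",
                 replacement = replacement),
            class = "edge_opt")
}

#' @export
print.edge_opt <- function(x, ...) {
  cat(sprintf("<edge_opt> %s program, %s weights, %s; %d bars\n",
              x$program, x$weighting, if (x$integral) "MIP" else "LP",
              nrow(x$report)))
  if (nrow(x$report) > 0)
    cat(sprintf("  mean loss ratio: %.4f\n",
                mean(x$report$opt_loss / pmax(x$report$orig_loss, .Machine$double.eps))))
  invisible(x)
}

# --- filtered cycle basis (per-step) program --------------------------------

#' Assemble the context of one filtered-cycle-basis program
#'
#' For the bar's birth edge `e`, collects the boundary basis `g_r` (reduced
#' dimension-2 columns of triangles born strictly before `e`) and the cycle
#' extension `f_s` (cycles created by earlier edges and not yet killed at the
#' step before `e`), read off the R = DV matrices.
#'
#' @param ph a `"ph"` fit.
#' @param j bar index into `ph$basis`.
#' @param weighting `"uniform"` or `"length"`.
#' @return a list with the program's ingredients.
#' @export
fcb_program_context <- function(ph, j, weighting = c("uniform", "length")) {
  weighting <- match.arg(weighting)
  bars <- ph$basis$bars
  stopifnot(j >= 1, j <= nrow(bars))
  e <- bars$birth_edge[j]
  b <- bars$birth[j]
  tri_birth <- if (ph$filtration$max_dim >= 2) ph$filtration$simplices[[3]]$birth else numeric(0)
  # boundaries present strictly before edge e enters: triangles with smaller
  # birth (equal-birth triangles follow all equal-birth edges in the
  # refinement, faces before cofaces)
  gcols <- which(!is.na(ph$dec2$pivots) & tri_birth < b)
  g_chains <- lapply(gcols, function(k) {
    col <- .csc_col(ph$dec2$R_csc, k)
    chain(1L, col$i, col$num, col$den)
  })
  # cycles created by earlier edges, not yet boundaries at that step
  zero1 <- which(is.na(ph$dec1$pivots))
  zero1 <- zero1[zero1 < e]
  pair_tri <- match(zero1, ph$dec2$pivots)  # column of R2 whose pivot kills it
  alive <- is.na(pair_tri) | tri_birth[pair_tri] >= b
  fedges <- zero1[alive]
  f_chains <- lapply(fedges, function(k) .v_column(ph$dec1, k))
  list(j = j, xOrig = ph$basis$reps[[j]], rows = seq_len(e),
       g_chains = g_chains, f_chains = f_chains,
       weights = .edge_weights(ph$filtration, weighting, seq_len(e)),
       weighting = weighting)
}

#' Build the filtered-cycle-basis edge-loss program
#'
#' @param ph a `"ph"` fit.
#' @param ctx output of [fcb_program_context()].
#' @param integral mark `x+`, `x-` integer.
#' @return a `"program_spec"`.
#' @export
assemble_fcb_program <- function(ph, ctx, integral = FALSE) {
  ne <- length(ctx$rows)
  comb <- c(ctx$g_chains, ctx$f_chains)
  nc <- length(comb)
  ai <- c(seq_len(ne), seq_len(ne))
  aj <- c(seq_len(ne), ne + seq_len(ne))
  ax <- c(rep(1, ne), rep(-1, ne))
  for (t in seq_along(comb)) {
    ch <- comb[[t]]
    if (length(ch$idx) > 0 && max(ch$idx) > ne)
      stop("combination cycle supported outside the program's edge window")
    ai <- c(ai, ch$idx)
    aj <- c(aj, rep(2 * ne + t, length(ch$idx)))
    ax <- c(ax, -(ch$num / ch$den))
  }
  program_spec(objective = c(ctx$weights, ctx$weights, numeric(nc)),
               a_i = ai, a_j = aj, a_x = ax,
               rhs = chain_dense(ctx$xOrig, ne),
               lb = c(numeric(2 * ne), rep(-Inf, nc)),
               ub = rep(Inf, 2 * ne + nc),
               integrality = c(rep(integral, 2 * ne), rep(FALSE, nc)))
}

#' Edge-loss optimization of a filtered cycle basis
#'
#' Applies the per-step program to every representative of the persistent
#' homology cycle basis.  Births are preserved; deaths may exceed the
#' original (reported per bar).  No replacement is involved: each program
#' only uses boundaries and cycles from before the bar's birth step.
#'
#' @inheritParams optimize_persistent_basis
#' @return object of class `"edge_opt"` with `program = "fcb"`; the report
#'   carries the solution lifespans.
#' @export
optimize_filtered_basis <- function(ph, weighting = c("uniform", "length"),
                                    integral = FALSE,
                                    tol = getOption("optcycle.integrality_tol", 1e-7)) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ph, "ph"))
  basis <- ph$basis
  m <- nrow(basis$bars)
  rows <- vector("list", m)
  reps <- vector("list", m)
  for (j in seq_len(m)) {
    ctx <- fcb_program_context(ph, j, weighting)
    spec <- assemble_fcb_program(ph, ctx, integral = integral)
    sol <- solve_program(spec, mip = integral)
    if (sol$status != "optimal")
      stop(sprintf("filtered-basis program for bar %d returned status '%s'", j, sol$status))
    xnew <- .solution_chain(sol, length(ctx$rows), tol)
    ls <- chain_lifespan(ph, xnew)
    w_orig <- sum(ctx$weights[ctx$xOrig$idx])
    w_new <- sum(ctx$weights[xnew$idx])
    reps[[j]] <- xnew
    rows[[j]] <- data.frame(
      bar = j, birth = basis$bars$birth[j], death = basis$bars$death[j],
      sol_birth = ls[1], sol_death = ls[2],
      orig_l0 = chain_l0(ctx$xOrig),
      orig_loss = if (weighting == "uniform") chain_l0(ctx$xOrig) else w_orig,
      objective = sol$objective,
      opt_l0 = chain_l0(xnew),
      opt_loss = if (weighting == "uniform") chain_l0(xnew) else w_new,
      integral_solution = sol$is_integral,
      in_pm1 = all(abs(xnew$num) == 1 & xnew$den == 1) || chain_is_zero(xnew),
      status = sol$status)
  }
  out_basis <- structure(list(bars = basis$bars, reps = reps), class = "cycle_basis")
  report <- if (m > 0) do.call(rbind, rows) else
    data.frame(bar = integer(0), birth = numeric(0), death = numeric(0),
               sol_birth = numeric(0), sol_death = numeric(0),
               orig_l0 = numeric(0), orig_loss = numeric(0),
               objective = numeric(0), opt_l0 = numeric(0), opt_loss = numeric(0),
               integral_solution = logical(0), in_pm1 = logical(0),
               status = character(0))
  structure(list(basis = out_basis,
                 report = report,
                 weighting = weighting, integral = integral, program = "fcb",
                 replacement = FALSE),
            class = "edge_opt")
}
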