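# Persistent homology over the rationals via the R = DV column reduction,
# dimension-1 barcode extraction, and initial cycle representatives.

# --- sparse rational column access ------------------------------------------

.as_csc <- function(tr, ncol) {
  o <- order(tr$j, tr$i)
  p <- c(0L, cumsum(tabulate(tr$j[o], nbins = ncol)))
  list(i = tr$i[o], num = tr$num[o], den = tr$den[o], p = p)
}

.csc_col <- function(csc, j) {
  r <- if (csc$p[j] < csc$p[j + 1]) (csc$p[j] + 1L):csc$p[j + 1L] else integer(0)
  list(i = csc$i[r], num = csc$num[r], den = csc$den[r])
}

# --- decomposition -----------------------------------------------------------

#' Reduce a boundary matrix: R = DV
#'
#' Standard left-to-right column reduction over exact rationals.  `R` is the
#' reduced matrix (no two nonzero columns share a lowest nonzero row) and `V`
#' the unit upper-triangular record of column operations, so that
#' `R = D %*% V` exactly.
#'
#' @param boundary a `"boundary_matrix"` (see [boundary_matrix()]).
#' @param keep_v whether to retain `V` (needed for essential representatives
#'   in dimension 1 and for original bounding volumes in dimension 2; skip to
#'   save memory on large complexes).
#' @return object of class `"rv_decomposition"` with triplet members `R`,
#'   `V` (optional) and the pivot row of every column (`NA` for zero columns).
#' @export
rv_decompose <- function(boundary, keep_v = TRUE, keep_ops = TRUE) {
  stopifnot(inherits(boundary, "boundary_matrix"))
  empty <- list(i = integer(0), j = integer(0), num = numeric(0), den = numeric(0))
  if (boundary$ncol == 0L) {
    out <- list(R = empty, V = if (keep_v) empty else NULL,
                ops = list(j = integer(0), k = integer(0), num = numeric(0), den = numeric(0)),
                pivots = integer(0), nrow = boundary$nrow, ncol = 0L, dim = boundary$dim)
    out$R_csc <- .as_csc(out$R, 0L)
    if (keep_v) out$V_csc <- .as_csc(out$V, 0L)
    out$vcache <- new.env(parent = emptyenv())
    return(structure(out, class = "rv_decomposition"))
  }
  red <- .cpp_reduce(boundary$i, boundary$j, boundary$num, boundary$den,
                     boundary$nrow, boundary$ncol, keep_v, keep_ops || keep_v)
  out <- list(R = red$R, V = red$V, ops = red$ops, pivots = red$pivots,
              nrow = boundary$nrow, ncol = boundary$ncol, dim = boundary$dim)
  out$R_csc <- .as_csc(red$R, boundary$ncol)
  if (keep_v) out$V_csc <- .as_csc(red$V, boundary$ncol)
  out$vcache <- new.env(parent = emptyenv())
  structure(out, class = "rv_decomposition")
}

# V column of a decomposition as a chain of the decomposition's dimension,
# expanded lazily from the operations log and cached.
.v_column <- function(dec, j) {
  if (!is.null(dec$V_csc)) {
    col <- .csc_col(dec$V_csc, j)
    return(chain(dec$dim, col$i, col$num, col$den))
  }
  key <- as.character(j)
  hit <- get0(key, envir = dec$vcache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  .v_columns(dec, j)[[1]]
}

# batch variant: one pass over the operations log for many columns
.v_columns <- function(dec, js) {
  js <- as.integer(js)
  miss <- js[!vapply(as.character(js), exists, TRUE,
                     envir = dec$vcache, inherits = FALSE)]
  if (length(miss) > 0) {
    tr <- .cpp_expand_v(dec$ops$j, dec$ops$k, dec$ops$num, dec$ops$den,
                        dec$ncol, miss)
    csc <- .as_csc(tr, dec$ncol)
    for (j in miss) {
      col <- .csc_col(csc, j)
      assign(as.character(j), chain(dec$dim, col$i, col$num, col$den),
             envir = dec$vcache)
    }
  }
  lapply(as.character(js), get, envir = dec$vcache)
}

#' @export
print.rv_decomposition <- function(x, ...) {
  cat(sprintf("<rv_decomposition> dim %d boundary, %d x %d, %d pivot columns\n",
              x$dim, x$nrow, x$ncol, sum(!is.na(x$pivots))))
  invisible(x)
}

#' Triangle indices forming a column basis of the boundary space
#'
#' The nonzero columns of reduced `D_(n+1)` index a column basis of the full
#' boundary matrix; restricting a program's triangle variables to this set
#' leaves its feasible cycles unchanged while shrinking the variable count.
#'
#' @param dec2 the `"rv_decomposition"` of the dimension-2 boundary matrix.
#' @return integer vector of triangle positions (refined order).
#' @export
triangle_column_basis <- function(dec2) {
  stopifnot(inherits(dec2, "rv_decomposition"))
  which(!is.na(dec2$pivots))
}

# --- barcode and representatives --------------------------------------------

#' Extract the dimension-1 barcode and an initial persistent cycle basis
#'
#' Finite bars come from nonzero columns of reduced `D2`: a column with pivot
#' row `sigma` paired to triangle `tau` yields the interval
#' `[Birth(sigma), Birth(tau))` with the reduced column itself (a cycle) as
#' representative.  Essential bars are unpaired cycle-creating edges; their
#' representatives are the corresponding `V` columns of the dimension-1
#' reduction.  Zero-length intervals are discarded.  Output is ordered by
#' (birth, death).
#'
#' @param dec1,dec2 decompositions of the dimension-1 and dimension-2
#'   boundary matrices on matching orders.
#' @param filtration the underlying `"vr_filtration"`.
#' @return object of class `"cycle_basis"`: a data frame `bars` and a
#'   parallel list `reps` of edge chains.
#' @export
extract_barcode <- function(dec1, dec2, filtration) {
  stopifnot(inherits(dec1, "rv_decomposition"), inherits(dec2, "rv_decomposition"))
  edges <- filtration$simplices[[2]]
  tris <- if (filtration$max_dim >= 2) filtration$simplices[[3]] else NULL
  if (dec1$ncol != nrow(edges$vertices) ||
      (dec2$ncol > 0 && (is.null(tris) || dec2$ncol != nrow(tris$vertices))))
    stop("decomposition orders do not match the filtration")

  birth_e <- edges$birth
  pair_col <- integer(0)
  pair_edge <- integer(0)
  if (dec2$ncol > 0) {
    pair_col <- which(!is.na(dec2$pivots))
    pair_edge <- dec2$pivots[pair_col]
  }

  keep <- if (length(pair_col) > 0) birth_e[pair_edge] < tris$birth[pair_col] else logical(0)
  fin_col <- pair_col[keep]
  fin_edge <- pair_edge[keep]

  # essential classes: cycle-creating edges never used as a pivot row of R2
  ess <- setdiff(which(is.na(dec1$pivots)), pair_edge)

  bars <- data.frame(
    birth = c(birth_e[fin_edge], birth_e[ess]),
    death = c(if (length(fin_col)) tris$birth[fin_col] else numeric(0),
              rep(Inf, length(ess))),
    birth_edge = c(fin_edge, ess),
    death_triangle = c(fin_col, rep(NA_integer_, length(ess))))

  reps <- vector("list", nrow(bars))
  for (k in seq_along(fin_col)) {
    col <- .csc_col(dec2$R_csc, fin_col[k])
    reps[[k]] <- chain(1L, col$i, col$num, col$den)
  }
  if (length(ess) > 0) {
    ess_chains <- .v_columns(dec1, ess)
    for (k in seq_along(ess))
      reps[[length(fin_col) + k]] <- ess_chains[[k]]
  }

  o <- order(bars$birth, bars$death, bars$birth_edge)
  structure(list(bars = bars[o, , drop = FALSE], reps = reps[o]),
            class = "cycle_basis")
}

#' @export
print.cycle_basis <- function(x, ...) {
  cat(sprintf("<cycle_basis> %d dimension-1 bars (%d essential)\n",
              nrow(x$bars), sum(is.infinite(x$bars$death))))
  invisible(x)
}

#' Betti number at a filtration value
#'
#' Counts the bars whose half-open lifespan interval contains `epsilon`.
#'
#' @param basis a `"cycle_basis"`.
#' @param epsilon filtration value.
#' @export
betti_at <- function(basis, epsilon) {
  sum(basis$bars$birth <= epsilon & epsilon < basis$bars$death)
}

# --- the fit -----------------------------------------------------------------

#' Persistent homology of a Vietoris-Rips filtration
#'
#' Computes the dimension-1 persistent homology of a filtration with exact
#' rational coefficients: boundary matrices, their R = DV reductions, the
#' barcode, an initial persistent homology cycle basis, and the triangle
#' column basis used to accelerate the edge-loss programs.
#'
#' @param filtration a `"vr_filtration"`, or a matrix accepted by
#'   [vietoris_rips()] (in which case the filtration is built with defaults).
#' @param volumes record the column-operation log of the dimension-2
#'   reduction, from which original bounding volumes are expanded on demand.
#'   Disable when only the barcode and representatives are needed.
#' @return an object of class `"ph"` with members `filtration`, `dec1`,
#'   `dec2`, `basis` (bars + representatives) and `rhat`.
#' @examples
#' pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' ph <- persistent_homology(vietoris_rips(pts, max_dim = 2))
#' summary(ph)
#' @export
persistent_homology <- function(filtration, volumes = TRUE) {
  if (!inherits(filtration, "vr_filtration"))
    filtration <- vietoris_rips(filtration)
  b1 <- boundary_matrix(filtration, 1)
  b2 <- boundary_matrix(filtration, 2)
  dec1 <- rv_decompose(b1, keep_v = FALSE, keep_ops = TRUE)
  dec2 <- rv_decompose(b2, keep_v = FALSE, keep_ops = volumes)
  basis <- extract_barcode(dec1, dec2, filtration)
  structure(list(filtration = filtration, dec1 = dec1, dec2 = dec2,
                 basis = basis, rhat = triangle_column_basis(dec2),
                 env = new.env(parent = emptyenv())),
            class = "ph")
}

#' @export
print.ph <- function(x, ...) {
  cat(sprintf("<ph> %d points, %d dimension-1 bars (%d essential)\n",
              x$filtration$n_points, nrow(x$basis$bars),
              sum(is.infinite(x$basis$bars$death))))
  invisible(x)
}

#' @export
summary.ph <- function(object, ...) {
  bars <- object$basis$bars
  cnt <- simplex_counts(object$filtration)
  structure(list(n_points = object$filtration$n_points,
                 simplex_counts = cnt,
                 n_bars = nrow(bars),
                 n_essential = sum(is.infinite(bars$death)),
                 bars = bars),
            class = "summary.ph")
}

#' @export
print.summary.ph <- function(x, ...) {
  cat(sprintf("Persistent homology (dimension 1, rational coefficients)\n"))
  cat(sprintf("  points: %d; simplices: %s\n", x$n_points,
              paste(x$simplex_counts, collapse = "/")))
  cat(sprintf("  bars: %d (%d essential)\n", x$n_bars, x$n_essential))
  if (x$n_bars > 0) {
    fin <- x$bars[is.finite(x$bars$death), ]
    if (nrow(fin) > 0)
      cat(sprintf("  finite lifespans: median %.4g, max %.4g\n",
                  stats::median(fin$death - fin$birth), max(fin$death - fin$birth)))
  }
  invisible(x)
}

#' Barcode plot
#'
#' @param x a `"ph"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ph <- function(x, ...) {
  bars <- x$basis$bars
  if (nrow(bars) == 0) {
    graphics::plot(0, 0, type = "n", xlab = "filtration value", ylab = "",
                   main = "dimension-1 barcode (empty)")
    return(invisible(x))
  }
  cap <- max(bars$birth, bars$death[is.finite(bars$death)], x$filtration$scale_cap)
  d <- ifelse(is.finite(bars$death), bars$death, cap * 1.05)
  graphics::plot(NULL, xlim = c(0, cap * 1.05), ylim = c(0, nrow(bars) + 1),
                 xlab = "filtration value", ylab = "bar",
                 main = "dimension-1 barcode", yaxt = "n", ...)
  graphics::segments(bars$birth, seq_len(nrow(bars)), d, seq_len(nrow(bars)),
                     col = ifelse(is.finite(bars$death), "grey25", "firebrick"), lwd = 2)
  invisible(x)
}

# --- chains relative to a ph fit --------------------------------------------

#' Original bounding volume of a finite bar
#'
#' The `V` column of the dimension-2 reduction at the bar's death triangle:
#' the 2-chain whose boundary is the bar's original representative.  This is
#' the unoptimized baseline for the triangle-loss reduction ratios.
#'
#' @param ph a `"ph"` fit.
#' @param k bar index (row of `ph$basis$bars`).
#' @return a dimension-2 chain.
#' @export
original_volume <- function(ph, k) {
  bars <- ph$basis$bars
  stopifnot(k >= 1, k <= nrow(bars))
  if (!is.finite(bars$death[k])) stop("essential bars have no bounding volume")
  .v_column(ph$dec2, bars$death_triangle[k])
}

#' Lifespan of an arbitrary edge chain
#'
#' Birth is the largest birth among supporting edges.  Death is found by
#' expanding the chain in the (pivot-indexed) basis of reduced dimension-2
#' columns: the chain is a boundary from the largest death-triangle birth in
#' its unique expansion onward, or never (`Inf`).
#'
#' @param ph a `"ph"` fit.
#' @param x an edge chain.
#' @return numeric `c(birth, death)`.
#' @export
chain_lifespan <- function(ph, x) {
  stopifnot(inherits(x, "chain"), x$dim == 1L)
  if (chain_is_zero(x)) stop("zero chain has no lifespan")
  birth <- max(ph$filtration$simplices[[2]]$birth[x$idx])
  piv <- ph$dec2$pivots
  tri_birth <- if (ph$filtration$max_dim >= 2) ph$filtration$simplices[[3]]$birth else numeric(0)
  # eliminate against pivot columns
  idx <- x$idx; num <- x$num; den <- x$den
  death <- birth
  repeat {
    if (length(idx) == 0) break
    low <- max(idx)
    j <- which(piv == low)
    if (length(j) == 0) return(c(birth, Inf))
    j <- j[1]
    col <- .csc_col(ph$dec2$R_csc, j)
    k <- length(col$i)  # pivot entry is last (rows sorted)
    cpos <- which(idx == low)
    cf <- rat_div(num[cpos], den[cpos], col$num[k], col$den[k])
    # x <- x - cf * col
    all_idx <- union(idx, col$i)
    nn <- dd <- numeric(length(all_idx)); dd[] <- 1
    m1 <- match(idx, all_idx); nn[m1] <- num; dd[m1] <- den
    m2 <- match(col$i, all_idx)
    for (t in seq_along(m2)) {
      s <- rat_mul(cf$num, cf$den, col$num[t], col$den[t])
      r <- rat_add(nn[m2[t]], dd[m2[t]], -s$num, s$den)
      nn[m2[t]] <- r$num; dd[m2[t]] <- r$den
    }
    keep <- nn != 0
    idx <- all_idx[keep]; num <- nn[keep]; den <- dd[keep]
    death <- max(death, tri_birth[j])
  }
  c(birth, death)
}
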