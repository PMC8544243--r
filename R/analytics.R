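# Descriptive statistics over (optimized) cycle representatives: loop counts,
# coefficient profiles, size-reduction ratios, LP/MIP agreement, duplicate
# intervals, and a brute-force l0 oracle for small windows.

#' Number of loops in a chain's support
#'
#' The nullity of the dimension-1 boundary matrix restricted to the support
#' edges, computed as `E - V + C` on the support graph (edges, touched
#' vertices, connected components).  One loop means the support is a single
#' graph-theoretic cycle.
#'
#' @param x an edge chain with nonempty support.
#' @param filtration the filtration.
#' @return list with `p` (loop count), `E`, `V`, `C`.
#' @export
count_loops <- function(x, filtration) {
  stopifnot(inherits(x, "chain"), x$dim == 1L)
  if (chain_l0(x) == 0) stop("empty support has no loop count")
  em <- filtration$simplices[[2]]$vertices[x$idx, , drop = FALSE]
  verts <- sort(unique(c(em)))
  nv <- length(verts)
  parent <- seq_len(nv)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (r in seq_len(nrow(em))) {
    a <- find(match(em[r, 1], verts)); b <- find(match(em[r, 2], verts))
    if (a != b) parent[a] <- b
  }
  comps <- length(unique(vapply(seq_len(nv), find, 0L)))
  list(p = nrow(em) - nv + comps, E = nrow(em), V = nv, C = comps)
}

#' Coefficient profile of a chain or numeric vector
#'
#' @param x a chain or numeric vector of coefficients.
#' @param tol tolerance applied after rounding.
#' @return list: `in_pm1`, `integral`, `max_abs`, `fractional_values`.
#' @export
coefficient_profile <- function(x, tol = getOption("optcycle.integrality_tol", 1e-7)) {
  vals <- if (inherits(x, "chain")) x$num / x$den else as.numeric(x)
  vals <- vals[vals != 0]
  if (length(vals) == 0)
    return(list(in_pm1 = TRUE, integral = TRUE, max_abs = 0,
                fractional_values = numeric(0)))
  near_int <- abs(vals - round(vals)) <= tol
  integral <- all(near_int)
  in_pm1 <- integral && all(abs(round(vals)) <= 1)
  list(in_pm1 = in_pm1, integral = integral, max_abs = max(abs(vals)),
       fractional_values = sort(unique(vals[!near_int])))
}

#' Size-reduction ratio of an optimization
#'
#' Ratio of the optimized cost to the original loss for a named loss; `NA`
#' when the original loss is zero.
#'
#' @param orig_loss,opt_loss numeric losses (vectorized).
#' @return numeric ratios.
#' @export
reduction_ratio <- function(orig_loss, opt_loss) {
  ifelse(orig_loss == 0, NA_real_, opt_loss / orig_loss)
}

#' LP/MIP agreement summary
#'
#' @param lp_obj,mip_obj paired optimal objective values.
#' @param lp_values,mip_values optional lists of solution vectors for the
#'   solution-identity fraction.
#' @param tol relative tolerance on cost equality.
#' @return list of fractions: `cost_equal`, `solution_equal` (if values
#'   given), `lp_integral` (if values given).
#' @export
lp_mip_agreement <- function(lp_obj, mip_obj, lp_values = NULL, mip_values = NULL,
                             tol = 1e-6) {
  stopifnot(length(lp_obj) == length(mip_obj))
  denom <- pmax(abs(lp_obj), abs(mip_obj), 1)
  out <- list(cost_equal = mean(abs(lp_obj - mip_obj) / denom <= tol),
              n = length(lp_obj))
  if (!is.null(lp_values)) {
    eq <- mapply(function(a, b) isTRUE(max(abs(a - b)) <= 1e-6) || (length(a) == 0 && length(b) == 0),
                 lp_values, mip_values)
    out$solution_equal <- mean(eq)
    out$lp_integral <- mean(vapply(lp_values, function(a)
      all(abs(a - round(a)) <= 1e-6), TRUE))
  }
  out
}

#' Duplicate intervals in a barcode
#'
#' Groups bars by exact (birth, death) equality.
#'
#' @param basis a `"cycle_basis"` (or its `bars` data frame).
#' @return data frame of distinct intervals with multiplicities.
#' @export
duplicate_bars <- function(basis) {
  bars <- if (inherits(basis, "cycle_basis")) basis$bars else basis
  if (nrow(bars) == 0)
    return(data.frame(birth = numeric(0), death = numeric(0), multiplicity = integer(0)))
  key <- paste(format(bars$birth, digits = 17), format(bars$death, digits = 17))
  tab <- table(key)
  first <- !duplicated(key)
  out <- data.frame(birth = bars$birth[first], death = bars$death[first],
                    multiplicity = as.integer(tab[key[first]]))
  out[order(out$birth, out$death), , drop = FALSE]
}

# reduce a rational vector against a set of reduced columns with distinct
# pivots; returns TRUE when it cancels to zero (i.e. lies in their span)
.in_span <- function(target, csc_cols) {
  idx <- target$idx; num <- target$num; den <- target$den
  repeat {
    if (length(idx) == 0) return(TRUE)
    low <- max(idx)
    hit <- csc_cols$pivot_map[[as.character(low)]]
    if (is.null(hit)) return(FALSE)
    col <- csc_cols$cols[[hit]]
    k <- length(col$i)
    cpos <- which(idx == low)
    cf <- rat_div(num[cpos], den[cpos], col$num[k], col$den[k])
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
  }
}

# reduced basis (distinct pivots) of the span of a list of chains
.reduced_span <- function(chains) {
  cols <- list()
  pivot_map <- new.env(parent = emptyenv())
  store <- list(cols = cols, pivot_map = pivot_map)
  for (ch in chains) {
    idx <- ch$idx; num <- ch$num; den <- ch$den
    repeat {
      if (length(idx) == 0) break
      low <- max(idx)
      hit <- pivot_map[[as.character(low)]]
      if (is.null(hit)) {
        store$cols[[length(store$cols) + 1]] <- list(i = idx, num = num, den = den)
        pivot_map[[as.character(low)]] <- length(store$cols)
        break
      }
      col <- store$cols[[hit]]
      k <- length(col$i)
      cpos <- which(idx == low)
      cf <- rat_div(num[cpos], den[cpos], col$num[k], col$den[k])
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
    }
  }
  store
}

#' Brute-force minimal support over {-1, 0, 1} chains
#'
#' Exhaustively searches, in increasing support size, for a chain with
#' coefficients in {-1, 0, 1} supported on `edge_set` that is feasible for
#' the edge-loss program (differs from `xOrig` by an element of the span of
#' `span_chains`).  Independent of the LP path; used to certify l0
#' optimality of LP solutions on small windows.
#'
#' @param xOrig the original representative.
#' @param span_chains list of chains spanning the allowed corrections
#'   (triangle boundaries and eligible basis cycles).
#' @param edge_set candidate support (at most 16 edges).
#' @param max_support stop after this support size.
#' @return smallest support size found, or `Inf` if none within the limit.
#' @export
brute_force_l0 <- function(xOrig, span_chains, edge_set, max_support = length(edge_set)) {
  stopifnot(length(edge_set) <= 16)
  span <- .reduced_span(span_chains)
  for (k in seq_len(max_support)) {
    combos <- utils::combn(edge_set, k)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    for (ci in seq_len(ncol(combos))) {
      for (si in seq_len(nrow(signs))) {
        cand <- chain(1L, combos[, ci], signs[si, ], rep(1, k))
        diffc <- chain_axpy(cand, xOrig, -1, 1)
        if (.in_span(diffc, span)) return(k)
      }
    }
  }
  Inf
}

#' Homology rank of a set of chains modulo boundaries
#'
#' Exact rank of the chains' span modulo the span of the given boundaries;
#' used to verify that optimized representatives still span homology at a
#' parameter.
#'
#' @param chains list of edge chains.
#' @param boundary_chains list of boundary chains (e.g. reduced dimension-2
#'   columns alive at the parameter).
#' @return integer rank.
#' @export
rank_modulo_boundaries <- function(chains, boundary_chains) {
  span <- .reduced_span(boundary_chains)
  rank <- 0L
  for (ch in chains) {
    # reduce against boundaries first, then against previously accepted
    if (!.in_span(ch, span)) {
      rank <- rank + 1L
      # absorb into the span so later chains are tested modulo it
      span <- .reduced_span(c(lapply(span$cols, function(c)
        chain(1L, c$i, c$num, c$den)), list(ch)))
    }
  }
  rank
}
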