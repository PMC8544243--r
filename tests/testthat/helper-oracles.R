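# Shared helpers: small random inputs and an independent persistent-Betti
# oracle built on dense rank computations (base qr), sharing no code with the
# R = DV reduction path.

random_cloud <- function(n, d, seed) {
  set.seed(seed)
  matrix(rnorm(n * d), ncol = d)
}

# dense double matrix from a rational triplet list
triplets_dense <- function(tr, nrow, ncol) {
  m <- matrix(0, nrow, ncol)
  if (length(tr$i) > 0) m[cbind(tr$i, tr$j)] <- tr$num / tr$den
  m
}

qr_rank <- function(m) {
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) return(0L)
  qr(m)$rank
}

# kernel basis of a dense matrix via complete QR
qr_nullspace <- function(m) {
  if (ncol(m) == 0) return(matrix(0, nrow = 0, ncol = 0))
  q <- qr(t(m))
  r <- q$rank
  if (r == ncol(m)) return(matrix(0, nrow = ncol(m), ncol = 0))
  qr.Q(q, complete = TRUE)[, (r + 1):ncol(m), drop = FALSE]
}

# Dimension-1 barcode of a filtration by rank arithmetic alone: persistent
# Betti numbers over all pairs of critical values, then inclusion-exclusion.
# Intended for tiny complexes (tens of simplices).
oracle_barcode <- function(filt) {
  b1 <- boundary_matrix(filt, 1)
  b2 <- boundary_matrix(filt, 2)
  D1 <- triplets_dense(b1, b1$nrow, b1$ncol)
  D2 <- triplets_dense(b2, b2$nrow, b2$ncol)
  eb <- filt$simplices[[2]]$birth
  tb <- if (filt$max_dim >= 2 && !is.null(filt$simplices[[3]]))
    filt$simplices[[3]]$birth else numeric(0)
  crit <- sort(unique(c(eb, tb)))
  Tn <- length(crit)
  # pb[i, j]: classes alive at crit[i] still alive at crit[j] (j >= i)
  zdim <- bdim <- integer(Tn)
  zbases <- vector("list", Tn)
  for (i in seq_len(Tn)) {
    ei <- which(eb <= crit[i])
    zbases[[i]] <- if (length(ei) == 0) matrix(0, 0, 0) else {
      ns <- qr_nullspace(D1[, ei, drop = FALSE])
      full <- matrix(0, ncol(D1), max(0L, ncol(ns)))
      if (ncol(ns) > 0) full[ei, ] <- ns
      full
    }
    zdim[i] <- if (length(zbases[[i]]) == 0) 0L else ncol(zbases[[i]])
  }
  pb <- matrix(0L, Tn, Tn)
  for (i in seq_len(Tn)) {
    Zi <- zbases[[i]]
    for (j in i:Tn) {
      tj <- which(tb <= crit[j])
      Bj <- if (length(tj) == 0) matrix(0, nrow(D2), 0) else D2[, tj, drop = FALSE]
      rB <- qr_rank(Bj)
      if (zdim[i] == 0) { pb[i, j] <- 0L; next }
      joint <- qr_rank(cbind(Bj, Zi))
      dim_cap <- rB + zdim[i] - joint   # dim(B_j  intersect  Z_i)
      pb[i, j] <- zdim[i] - dim_cap
    }
  }
  # multiplicity of interval [crit[i], crit[j+1]) by inclusion-exclusion on
  # the persistent Betti numbers; pb(i, j) counts classes born by crit[i]
  # still alive at crit[j]
  at <- function(i, j) if (i < 1 || j > Tn) 0L else pb[i, j]
  bars <- data.frame(birth = numeric(0), death = numeric(0))
  for (i in seq_len(Tn)) {
    for (j in i:Tn) {
      m <- if (j < Tn)
        (at(i, j) - at(i, j + 1)) - (at(i - 1, j) - at(i - 1, j + 1))
      else
        at(i, j) - at(i - 1, j)
      if (m > 0)
        bars <- rbind(bars, data.frame(
          birth = rep(crit[i], m),
          death = rep(if (j < Tn) crit[j + 1] else Inf, m)))
    }
  }
  bars[order(bars$birth, bars$death), , drop = FALSE]
}

# multiset comparison of barcodes with numeric tolerance
expect_same_barcode <- function(bars_a, bars_b, tol = 1e-9) {
  expect_equal(nrow(bars_a), nrow(bars_b))
  oa <- bars_a[order(bars_a$birth, bars_a$death), c("birth", "death")]
  ob <- bars_b[order(bars_b$birth, bars_b$death), c("birth", "death")]
  expect_equal(unname(as.matrix(oa)), unname(as.matrix(ob)), tolerance = tol)
}

# reduced D2 columns alive at epsilon (boundaries at that parameter)
boundaries_at <- function(ph, epsilon) {
  tb <- ph$filtration$simplices[[3]]$birth
  cols <- which(!is.na(ph$dec2$pivots) & tb <= epsilon)
  lapply(cols, function(k) {
    col <- optcycle:::.csc_col(ph$dec2$R_csc, k)
    chain(1L, col$i, col$num, col$den)
  })
}

# homology rank spanned by the basis representatives alive at epsilon
alive_rank <- function(ph, basis, epsilon) {
  alive <- which(basis$bars$birth <= epsilon & epsilon < basis$bars$death)
  if (length(alive) == 0) return(0L)
  rank_modulo_boundaries(basis$reps[alive], boundaries_at(ph, epsilon))
}
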