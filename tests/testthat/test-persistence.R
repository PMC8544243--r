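test_that("a hollow triangle has one essential cycle and a filled one a single pair", {
  hollow <- filtration_from_simplices(list(c(0, 1), c(0, 2), c(1, 2)),
                                      births = c(1, 1, 1))
  ph <- persistent_homology(hollow)
  expect_equal(nrow(ph$basis$bars), 1)
  expect_equal(ph$basis$bars$death, Inf)
  filled <- filtration_from_simplices(list(c(0, 1), c(0, 2), c(1, 2), c(0, 1, 2)),
                                      births = c(1, 1, 1, 2))
  ph2 <- persistent_homology(filled)
  expect_equal(ph2$basis$bars$birth, 1)
  expect_equal(ph2$basis$bars$death, 2)
})

test_that("three mutually equidistant points leave no dimension-1 bar", {
  d <- matrix(1, 3, 3) - diag(3)
  ph <- persistent_homology(vietoris_rips(d, max_dim = 2, input = "dissimilarity"))
  expect_equal(nrow(ph$basis$bars), 0)   # the zero-length interval is dropped
})

test_that("R = DV holds exactly with unique pivots on random clouds", {
  for (seed in 1:3) {
    f <- vietoris_rips(random_cloud(8, 2, seed), max_dim = 2)
    for (n in 1:2) {
      b <- boundary_matrix(f, n)
      dec <- rv_decompose(b, keep_v = TRUE)
      dv <- optcycle:::.cpp_rat_mult(b$i, b$j, b$num, b$den, b$nrow, b$ncol,
                                     dec$V$i, dec$V$j, dec$V$num, dec$V$den, b$ncol)
      expect_equal(triplets_dense(dv, b$nrow, b$ncol),
                   triplets_dense(dec$R, b$nrow, b$ncol))
      piv <- dec$pivots[!is.na(dec$pivots)]
      expect_equal(anyDuplicated(piv), 0L)
      # V unit upper triangular
      expect_true(all(dec$V$i <= dec$V$j))
      diag_entries <- dec$V$num[dec$V$i == dec$V$j] / dec$V$den[dec$V$i == dec$V$j]
      expect_equal(diag_entries, rep(1, b$ncol))
    }
  }
})

test_that("the unit square yields exactly one bar [1, sqrt(2))", {
  ph <- persistent_homology(make_fixture("square"))
  expect_equal(nrow(ph$basis$bars), 1)
  expect_equal(ph$basis$bars$birth, 1)
  expect_equal(ph$basis$bars$death, sqrt(2))
  expect_equal(sort(ph$basis$reps[[1]]$idx), 1:4)
})

test_that("representatives are cycles born with their bar", {
  ph <- persistent_homology(vietoris_rips(random_cloud(12, 2, 11), max_dim = 2))
  b1 <- boundary_matrix(ph$filtration, 1)
  D1 <- triplets_dense(b1, b1$nrow, b1$ncol)
  eb <- ph$filtration$simplices[[2]]$birth
  for (k in seq_len(nrow(ph$basis$bars))) {
    rep_k <- ph$basis$reps[[k]]
    expect_gt(chain_l0(rep_k), 0)
    dense <- chain_dense(rep_k, b1$ncol)
    expect_equal(max(abs(D1 %*% dense)), 0)
    expect_equal(max(eb[rep_k$idx]), ph$basis$bars$birth[k])
  }
})

test_that("the barcode agrees with an independent rank-based computation", {
  for (seed in 1:20) {
    f <- vietoris_rips(random_cloud(10, 2 + seed %% 3, 100 + seed), max_dim = 2)
    ph <- persistent_homology(f)
    expect_same_barcode(ph$basis$bars, oracle_barcode(f))
  }
})

test_that("the barcode is invariant under relabeling-induced tie-breaks", {
  # an integer grid has many birth ties; relabeling the points permutes the
  # lexicographic blocks without touching the filtration itself
  pts <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  base <- persistent_homology(vietoris_rips(pts, max_dim = 2))$basis$bars
  for (seed in 1:5) {
    set.seed(seed)
    perm <- sample(nrow(pts))
    bars <- persistent_homology(vietoris_rips(pts[perm, ], max_dim = 2))$basis$bars
    expect_same_barcode(bars, base)
  }
})

test_that("finite bars pair an edge with a later-born triangle", {
  ph <- persistent_homology(vietoris_rips(random_cloud(12, 3, 5), max_dim = 2))
  fin <- ph$basis$bars[is.finite(ph$basis$bars$death), ]
  expect_gt(nrow(fin), 0)
  expect_true(all(fin$birth < fin$death))
  expect_true(all(!is.na(fin$death_triangle)))
})

test_that("betti_at counts bars by the half-open convention", {
  ph <- persistent_homology(make_fixture("three_bars"))
  expect_equal(betti_at(ph$basis, 0.5), 0)
  expect_equal(betti_at(ph$basis, 1), 1)
  expect_equal(betti_at(ph$basis, 2), 1)   # [1,2) closed at its death
  expect_equal(betti_at(ph$basis, 3), 2)
})

test_that("the triangle column basis spans the boundary space", {
  f <- vietoris_rips(matrix(c(0, 0, 1, 0, 0.5, 1, 0.5, 0.3), ncol = 2, byrow = TRUE),
                     max_dim = 2)
  b2 <- boundary_matrix(f, 2)
  dec2 <- rv_decompose(b2, keep_v = FALSE)
  rhat <- triangle_column_basis(dec2)
  expect_equal(length(rhat),
               qr_rank(triplets_dense(b2, b2$nrow, b2$ncol)))
  D2 <- triplets_dense(b2, b2$nrow, b2$ncol)
  expect_equal(qr_rank(D2[, rhat, drop = FALSE]), qr_rank(D2))
  # a filled triangle alone has a one-element basis
  filled <- filtration_from_simplices(list(c(0, 1), c(0, 2), c(1, 2), c(0, 1, 2)),
                                      births = c(1, 1, 1, 2))
  dec <- rv_decompose(boundary_matrix(filled, 2), keep_v = FALSE)
  expect_equal(triangle_column_basis(dec), 1L)
  # the tetrahedron boundary has rank 3
  tet <- vietoris_rips(matrix(1, 4, 4) - diag(4), max_dim = 2, input = "dissimilarity")
  dect <- rv_decompose(boundary_matrix(tet, 2), keep_v = FALSE)
  expect_equal(length(triangle_column_basis(dect)), 3L)
})

test_that("original volumes bound their bar's representative", {
  ph <- persistent_homology(vietoris_rips(random_cloud(15, 2, 9), max_dim = 2))
  fin <- which(is.finite(ph$basis$bars$death))
  expect_gt(length(fin), 0)
  for (k in fin) {
    v <- original_volume(ph, k)
    expect_true(chain_equal(optcycle:::chain_boundary(ph, v), ph$basis$reps[[k]]))
    expect_true(ph$basis$bars$death_triangle[k] %in% v$idx)
  }
})

test_that("chain lifespans recompute births and deaths of representatives", {
  ph <- persistent_homology(vietoris_rips(random_cloud(15, 2, 9), max_dim = 2))
  expect_gt(nrow(ph$basis$bars), 0)
  for (k in seq_len(nrow(ph$basis$bars))) {
    ls <- chain_lifespan(ph, ph$basis$reps[[k]])
    expect_equal(ls[1], ph$basis$bars$birth[k])
    expect_equal(ls[2], ph$basis$bars$death[k])
  }
})
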