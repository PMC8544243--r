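test_that("loop counts equal the support graph's cycle-space dimension", {
  f <- make_fixture("bowtie")
  ph <- persistent_homology(f)
  em <- f$simplices[[2]]$vertices
  key <- paste(em[, 1], em[, 2])
  tri1 <- chain(1L, match(c("0 1", "0 2", "1 2"), key), c(1, -1, 1), rep(1, 3))
  expect_equal(count_loops(tri1, f)$p, 1)
  both <- chain(1L, 1:6, c(1, -1, 1, 1, -1, 1), rep(1, 6))
  expect_equal(count_loops(both, f)$p, 2)  # bowtie: 6 - 5 + 1
  expect_error(count_loops(chain(1L), f), "empty")
})

test_that("loop counts agree with a rank-based nullity oracle", {
  for (seed in 1:5) {
    f <- vietoris_rips(random_cloud(12, 2, 40 + seed), max_dim = 2)
    ph <- persistent_homology(f)
    if (nrow(ph$basis$bars) == 0) next
    b1 <- boundary_matrix(f, 1)
    D1 <- triplets_dense(b1, b1$nrow, b1$ncol)
    for (k in seq_len(nrow(ph$basis$bars))) {
      x <- ph$basis$reps[[k]]
      sub <- D1[, x$idx, drop = FALSE]
      nullity <- length(x$idx) - qr_rank(sub)
      expect_equal(count_loops(x, f)$p, nullity)
    }
  }
})

test_that("coefficient profiles classify integral and fractional chains", {
  p1 <- coefficient_profile(c(1, -1, 1))
  expect_true(p1$in_pm1); expect_true(p1$integral)
  p2 <- coefficient_profile(c(0.5, -0.5))
  expect_false(p2$in_pm1); expect_false(p2$integral)
  expect_equal(p2$fractional_values, c(-0.5, 0.5))
  p3 <- coefficient_profile(c(2, -1))
  expect_true(p3$integral); expect_false(p3$in_pm1); expect_equal(p3$max_abs, 2)
  # implication: membership in {-1,0,1} entails integrality
  expect_false(p2$in_pm1 && !p2$integral)
})

test_that("reduction ratios behave at the boundary cases", {
  expect_equal(reduction_ratio(6, 4), 4 / 6)
  expect_equal(reduction_ratio(5, 5), 1)
  expect_true(is.na(reduction_ratio(0, 0)))
})

test_that("LP/MIP agreement summaries are order-independent fractions", {
  lp <- c(1, 2, 3); mip <- c(1, 2, 4)
  a <- lp_mip_agreement(lp, mip)
  expect_equal(a$cost_equal, 2 / 3)
  perm <- c(3, 1, 2)
  expect_equal(lp_mip_agreement(lp[perm], mip[perm])$cost_equal, a$cost_equal)
  ident <- lp_mip_agreement(lp, lp, as.list(lp), as.list(lp))
  expect_equal(ident$cost_equal, 1)
  expect_equal(ident$solution_equal, 1)
})

test_that("duplicate intervals are grouped by exact value equality", {
  ph <- persistent_homology(make_fixture("duplicate_bars"))
  dup <- duplicate_bars(ph$basis)
  expect_equal(nrow(dup), 1)
  expect_equal(dup$multiplicity, 2L)
  ph2 <- persistent_homology(make_fixture("three_bars"))
  dup2 <- duplicate_bars(ph2$basis)
  expect_true(all(dup2$multiplicity == 1))
  expect_equal(sum(dup2$multiplicity), nrow(ph2$basis$bars))
})

test_that("exhaustive search certifies l0 minimality of LP solutions", {
  # six-edge detour: the LP finds 4 edges; brute force over {-1,0,1} chains
  # on the 11-edge window confirms nothing shorter is feasible
  ph <- persistent_homology(make_fixture("six_edge_detour"))
  em <- ph$filtration$simplices[[2]]$vertices
  key <- paste(em[, 1], em[, 2])
  idx <- match(c("0 4", "4 5", "5 6", "2 6", "2 3", "0 3"), key)
  x6 <- chain(1L, idx, c(1, 1, 1, -1, 1, -1), rep(1, 6))
  basis <- ph$basis
  basis$reps[[1]] <- x6
  ctx <- edge_program_context(ph, basis, 1, "uniform")
  lp <- solve_program(assemble_edge_program(ph, ctx))
  tb <- optcycle:::.tri_boundary_triplets(ph, ctx$triangle_set)
  span <- lapply(seq_along(ctx$triangle_set), function(t) {
    sel <- tb$j == t
    chain(1L, tb$i[sel], tb$x[sel], rep(1, sum(sel)))
  })
  best <- brute_force_l0(x6, span, ctx$edge_set, max_support = 4)
  expect_equal(best, 4)
  expect_equal(lp$objective, best)

  # the coned square: LP volume boundary has 5 edges but the edge-loss LP
  # optimum is 4, and brute force confirms 4 is the true l0 minimum
  ph2 <- persistent_homology(make_fixture("volume_vs_edge"))
  ctx2 <- edge_program_context(ph2, ph2$basis, 1, "uniform")
  lp2 <- solve_program(assemble_edge_program(ph2, ctx2))
  tb2 <- optcycle:::.tri_boundary_triplets(ph2, ctx2$triangle_set)
  span2 <- lapply(seq_along(ctx2$triangle_set), function(t) {
    sel <- tb2$j == t
    chain(1L, tb2$i[sel], tb2$x[sel], rep(1, sum(sel)))
  })
  best2 <- brute_force_l0(ctx2$xOrig, span2, ctx2$edge_set, max_support = 4)
  expect_equal(lp2$objective, best2)
})

test_that("homology rank bookkeeping matches betti numbers on a fixture", {
  ph <- persistent_homology(make_fixture("three_bars"))
  expect_equal(alive_rank(ph, ph$basis, 1), 1L)
  expect_equal(alive_rank(ph, ph$basis, 2.5), 1L)
  expect_equal(alive_rank(ph, ph$basis, 3), 2L)
})
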