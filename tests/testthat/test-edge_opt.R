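ph_square <- persistent_homology(make_fixture("square"))

test_that("an already-minimal representative is returned unchanged in cost", {
  eo <- optimize_persistent_basis(ph_square, "uniform")
  expect_equal(eo$report$opt_l0, 4)
  expect_equal(sort(eo$basis$reps[[1]]$idx), 1:4)
  el <- optimize_persistent_basis(ph_square, "length")
  expect_equal(el$report$opt_loss, 4)
})

test_that("a six-edge detour representative shrinks to the four-edge cycle", {
  ph <- persistent_homology(make_fixture("six_edge_detour"))
  expect_equal(nrow(ph$basis$bars), 1)
  em <- ph$filtration$simplices[[2]]$vertices
  key <- paste(em[, 1], em[, 2])
  detour <- c("0 4", "4 5", "5 6", "2 6", "2 3", "0 3")
  idx <- match(detour, key)
  x6 <- chain(1L, idx, c(1, 1, 1, -1, 1, -1), rep(1, 6))
  basis <- ph$basis
  basis$reps[[1]] <- x6
  ctx <- edge_program_context(ph, basis, 1, "uniform")
  sol <- solve_program(assemble_edge_program(ph, ctx))
  expect_equal(sol$objective, 4)
  # the uniform optimum never exceeds the l1 norm of the original
  expect_lte(sol$objective, chain_l1(x6))
})

test_that("lifespans are preserved element-wise by the persistent-basis program", {
  ph <- persistent_homology(vietoris_rips(random_cloud(18, 3, 2), max_dim = 2))
  expect_gt(nrow(ph$basis$bars), 1)
  for (w in c("uniform", "length")) {
    eo <- optimize_persistent_basis(ph, w)
    expect_equal(eo$basis$bars, ph$basis$bars)
    for (k in seq_len(nrow(eo$basis$bars))) {
      ls <- chain_lifespan(ph, eo$basis$reps[[k]])
      expect_equal(ls[1], eo$basis$bars$birth[k])
      expect_equal(ls[2], eo$basis$bars$death[k])
    }
    expect_true(all(eo$report$opt_loss <= eo$report$orig_loss + 1e-9))
  }
})

test_that("optimized bases keep the homology rank at every critical value", {
  ph <- persistent_homology(vietoris_rips(random_cloud(14, 2, 31), max_dim = 2))
  expect_gt(nrow(ph$basis$bars), 0)
  eo <- optimize_persistent_basis(ph, "uniform")
  eps_grid <- sort(unique(c(ph$basis$bars$birth,
                            ph$basis$bars$death[is.finite(ph$basis$bars$death)] - 1e-9)))
  for (eps in eps_grid) {
    expect_equal(alive_rank(ph, eo$basis, eps), betti_at(ph$basis, eps))
  }
})

test_that("dropping the basis-cycle variables cannot improve the optimum", {
  ph <- persistent_homology(vietoris_rips(random_cloud(16, 3, 8), max_dim = 2))
  expect_gt(nrow(ph$basis$bars), 1)
  j <- nrow(ph$basis$bars)
  ctx <- edge_program_context(ph, ph$basis, j, "uniform")
  with_q <- solve_program(assemble_edge_program(ph, ctx))$objective
  ctx0 <- ctx; ctx0$Q <- integer(0); ctx0$q_chains <- list()
  without_q <- solve_program(assemble_edge_program(ph, ctx0))$objective
  expect_gte(without_q, with_q - 1e-9)
})

test_that("the triangle column basis leaves every optimum unchanged", {
  ph <- persistent_homology(vietoris_rips(random_cloud(14, 3, 12), max_dim = 2))
  expect_gt(nrow(ph$basis$bars), 0)
  for (j in seq_len(nrow(ph$basis$bars))) {
    c1 <- edge_program_context(ph, ph$basis, j, "uniform", use_rhat = TRUE)
    c2 <- edge_program_context(ph, ph$basis, j, "uniform", use_rhat = FALSE)
    expect_equal(solve_program(assemble_edge_program(ph, c1))$objective,
                 solve_program(assemble_edge_program(ph, c2))$objective,
                 tolerance = 1e-7)
  }
})

test_that("duplicate bars stay independent after optimization with replacement", {
  ph <- persistent_homology(make_fixture("duplicate_bars"))
  expect_equal(nrow(ph$basis$bars), 2)
  expect_equal(ph$basis$bars$birth, c(1, 1))
  expect_equal(ph$basis$bars$death, rep(sqrt(2), 2))
  eo <- optimize_persistent_basis(ph, "uniform")
  eps <- 1.2
  expect_equal(alive_rank(ph, eo$basis, eps), 2L)
})

test_that("the filtered-basis optimum can outlive its bar but never costs more", {
  ph <- persistent_homology(make_fixture("fcb_extends_death"))
  fo <- optimize_filtered_basis(ph, "uniform")
  bar <- which(is.finite(fo$report$death))
  expect_equal(fo$report$sol_birth[bar], fo$report$birth[bar])
  expect_equal(fo$report$sol_death[bar], Inf)
  expect_equal(fo$report$opt_l0[bar], 3)
  # the per-step program is a relaxation of the persistent-basis program
  eo <- optimize_persistent_basis(ph, "uniform")
  expect_true(all(fo$report$opt_loss <= eo$report$opt_loss + 1e-9))
})

test_that("with no earlier cycles the filtered optimum stays homologous", {
  ph <- persistent_homology(make_fixture("square"))
  ctx <- fcb_program_context(ph, 1, "uniform")
  expect_length(ctx$f_chains, 0)
  fo <- optimize_filtered_basis(ph, "uniform")
  expect_equal(fo$report$sol_death, ph$basis$bars$death)
})

test_that("integral edge programs return integral solutions here", {
  ph <- persistent_homology(vietoris_rips(random_cloud(14, 3, 12), max_dim = 2))
  eo <- optimize_persistent_basis(ph, "length", integral = TRUE)
  expect_true(all(eo$report$integral_solution))
  lp <- optimize_persistent_basis(ph, "length", integral = FALSE)
  expect_true(all(lp$report$objective <= eo$report$objective + 1e-9))
})
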