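test_that("a filled triangle has the minimal window and trivial volume", {
  f <- filtration_from_simplices(list(c(0, 1), c(0, 2), c(1, 2), c(0, 1, 2)),
                                 births = c(1, 1, 1, 2))
  ph <- persistent_homology(f)
  win <- triangle_window(ph, 1)
  expect_length(win$Fn1, 0)
  expect_equal(win$Fhat, win$tau)
  vo <- optimize_volume_basis(ph, "uniform")
  expect_equal(vo$report$opt_t, 1)
  expect_equal(vo$report$objective, 1)
})

test_that("essential bars are rejected by the window construction", {
  hollow <- filtration_from_simplices(list(c(0, 1), c(0, 2), c(1, 2)),
                                      births = c(1, 1, 1))
  ph <- persistent_homology(hollow)
  expect_error(triangle_window(ph, 1), "undefined")
})

test_that("the coned-square fixture separates edge and volume optimality", {
  ph <- persistent_homology(make_fixture("volume_vs_edge"))
  eo <- optimize_persistent_basis(ph, "uniform")
  expect_equal(eo$report$opt_l0, 4)
  vo <- optimize_volume_basis(ph, "uniform")
  expect_equal(vo$report$opt_t, 3)
  expect_equal(vo$report$boundary_l0, 5)
  # uniform optimum never exceeds the window size
  win <- triangle_window(ph, 1)
  expect_lte(vo$report$objective, length(win$Fhat))
})

test_that("the unit square's optimal volume is two triangles", {
  ph <- persistent_homology(make_fixture("square"))
  vo <- optimize_volume_basis(ph, "uniform")
  expect_equal(vo$report$opt_t, 2)
  expect_equal(vo$report$boundary_l0, 4)
  expect_equal(sort(vo$basis$reps[[1]]$idx), 1:4)
})

test_that("both build modes produce identical objectives on a random cloud", {
  ph <- persistent_homology(vietoris_rips(random_cloud(30, 3, 17), max_dim = 2))
  expect_gt(sum(is.finite(ph$basis$bars$death)), 2)
  va <- optimize_volume_basis(ph, "uniform", build_mode = "whole_matrix")
  vb <- optimize_volume_basis(ph, "uniform", build_mode = "per_bar")
  expect_equal(va$report$objective, vb$report$objective)
})

test_that("volume boundaries reproduce their bar's lifespan exactly", {
  ph <- persistent_homology(vietoris_rips(random_cloud(20, 2, 23), max_dim = 2))
  vo <- optimize_volume_basis(ph, "uniform")
  fin <- which(is.finite(vo$report$death))
  expect_gt(length(fin), 0)
  for (k in fin) {
    ls <- chain_lifespan(ph, vo$basis$reps[[k]])
    expect_equal(ls[1], vo$report$birth[k])
    expect_equal(ls[2], vo$report$death[k])
    # boundary nonzero on the birth edge by the post-hoc check having passed
    expect_true(ph$basis$bars$birth_edge[k] %in% vo$basis$reps[[k]]$idx)
  }
  # optimized set (with essentials) spans homology at every parameter
  for (eps in sort(unique(vo$report$birth))) {
    expect_equal(alive_rank(ph, vo$basis, eps), betti_at(ph$basis, eps))
  }
})

test_that("area weighting uses Heron's formula and can change the optimum", {
  ph <- persistent_homology(vietoris_rips(random_cloud(20, 2, 23), max_dim = 2))
  va <- optimize_volume_basis(ph, "area")
  vu <- optimize_volume_basis(ph, "uniform")
  fin <- which(is.finite(va$report$death))
  # area-weighted optima are measured in area units, uniform in counts
  expect_true(all(va$report$opt_loss[fin] >= 0))
  expect_true(all(vu$report$opt_t[fin] >= 1))
})

test_that("a tiny variable cap skips bars with a warning and keeps originals", {
  ph <- persistent_homology(make_fixture("square"))
  expect_warning(vo <- optimize_volume_basis(ph, "uniform", var_cap = 2),
                 "skipped")
  expect_true(vo$report$skipped)
  expect_true(chain_equal(vo$basis$reps[[1]], ph$basis$reps[[1]]))
})
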