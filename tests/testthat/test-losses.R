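test_that("edge losses count support and sum lengths", {
  f <- make_fixture("square")
  ph <- persistent_homology(f)
  el <- edge_losses(ph$basis$reps[[1]], f)
  expect_equal(el$e_unif, 4)
  expect_equal(el$e_len, 4)
  expect_equal(edge_losses(chain(1L), f), list(e_unif = 0, e_len = 0))
  # l0 ignores coefficient magnitude
  big <- chain(1L, 1L, 2, 1)
  expect_equal(edge_losses(big, f)$e_unif, 1)
})

test_that("Heron areas match closed forms and clamp degenerate triples", {
  expect_equal(as.numeric(heron_area(3, 4, 5)), 6)
  expect_equal(as.numeric(heron_area(1, 1, 1)), sqrt(3) / 4)
  expect_equal(as.numeric(heron_area(1, 1, 2)), 0)
  deg <- heron_area(1, 1, 3)   # violates the triangle inequality
  expect_equal(as.numeric(deg), 0)
  expect_equal(attr(deg, "clamped"), 1)
  # symmetry in the three arguments
  expect_equal(as.numeric(heron_area(2, 3, 4)), as.numeric(heron_area(4, 2, 3)))
})

test_that("triangle losses aggregate counts and areas over the support", {
  f <- make_fixture("square")
  ph <- persistent_homology(f)
  v <- original_volume(ph, 1)
  tl <- triangle_losses(v, f)
  expect_equal(tl$t_unif, 2)
  expect_equal(tl$t_area, 1, tolerance = 1e-9)  # two half-unit triangles
})

test_that("the Surveyor area recovers polygon areas in the plane", {
  f <- make_fixture("square")
  ph <- persistent_homology(f)
  sv <- surveyor_area(ph$basis$reps[[1]], f)
  expect_equal(sv$reason, "ok")
  expect_equal(sv$area, 1)
  tri <- vietoris_rips(matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE),
                       max_dim = 2)
  pht <- persistent_homology(tri)
  # build the triangle cycle by hand (no dimension-1 bar survives)
  cyc <- chain(1L, 1:3, c(1, -1, 1), rep(1, 3))
  sv2 <- surveyor_area(cyc, tri)
  expect_equal(sv2$area, 0.5)
})

test_that("ineligible supports return a reason instead of an area", {
  f <- make_fixture("bowtie")
  ph <- persistent_homology(f)
  # figure-eight: both triangle boundaries summed share vertex 2
  x <- chain(1L, 1:6, c(1, -1, 1, 1, -1, 1), rep(1, 6))
  expect_equal(surveyor_area(x, f)$reason, "ambient dimension is not 2")
  # with planar coordinates the same support still fails the cycle condition
  pts <- matrix(c(0, 0, 0, 2, 1, 1, 2, 0, 2, 2), ncol = 2, byrow = TRUE)
  fb <- vietoris_rips(pts, max_dim = 2, scale_cap = sqrt(2))
  em <- fb$simplices[[2]]$vertices
  key <- paste(em[, 1], em[, 2])
  idx <- match(c("0 2", "1 2", "0 1", "2 3", "2 4", "3 4"), key)
  x2 <- chain(1L, idx, c(1, -1, 1, 1, -1, 1), rep(1, 6))
  expect_equal(surveyor_area(x2, fb)$reason, "support is not a single simple cycle")
})

test_that("Surveyor area is invariant under relabeling and reflection", {
  pts <- matrix(c(0, 0, 2, 0, 2, 1, 0, 1), ncol = 2, byrow = TRUE)
  a1 <- surveyor_area(persistent_homology(vietoris_rips(pts, max_dim = 2))$basis$reps[[1]],
                      vietoris_rips(pts, max_dim = 2))$area
  refl <- pts %*% diag(c(-1, 1))
  f2 <- vietoris_rips(refl, max_dim = 2)
  a2 <- surveyor_area(persistent_homology(f2)$basis$reps[[1]], f2)$area
  perm <- pts[c(3, 1, 4, 2), ]
  f3 <- vietoris_rips(perm, max_dim = 2)
  a3 <- surveyor_area(persistent_homology(f3)$basis$reps[[1]], f3)$area
  expect_equal(a1, 2)
  expect_equal(a2, 2)
  expect_equal(a3, 2)
})

test_that("weighted l1 equals weighted l0 on plus-minus-one chains", {
  f <- make_fixture("square")
  x <- chain(1L, 1:4, c(1, -1, -1, 1), rep(1, 4))
  expect_equal(chain_l1(x), chain_l0(x))
  w <- optcycle:::.edge_weights(f, "length", x$idx)
  expect_equal(sum(w * abs(x$num / x$den)), sum(w[seq_along(x$idx)]))
})
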