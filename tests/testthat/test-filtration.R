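test_that("simplex births equal the maximum pairwise dissimilarity", {
  d <- matrix(1, 3, 3) - diag(3)
  f <- vietoris_rips(d, max_dim = 2, input = "dissimilarity")
  expect_equal(simplex_counts(f), c(3L, 3L, 1L))
  expect_equal(f$simplices[[1]]$birth, rep(0, 3))
  expect_equal(f$simplices[[2]]$birth, rep(1, 3))
  expect_equal(f$simplices[[3]]$birth, 1)
})

test_that("the unit square filtration has the hand-enumerated structure", {
  f <- make_fixture("square")
  eb <- f$simplices[[2]]$birth
  expect_equal(sum(eb == 1), 4)
  expect_equal(sum(abs(eb - sqrt(2)) < 1e-12), 2)
  expect_equal(f$simplices[[3]]$birth, rep(sqrt(2), 4))
})

test_that("a complete clique complex has binomial simplex counts", {
  m <- sample_er_dissimilarity(100, seed = 7)
  f <- vietoris_rips(m, max_dim = 2, scale_cap = 1)
  expect_equal(simplex_counts(f), c(100L, choose(100, 2), choose(100, 3)))
})

test_that("invalid dissimilarity input is rejected with index diagnostics", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(vietoris_rips(m, input = "dissimilarity"), "not symmetric")
  m2 <- matrix(c(0.5, 1, 1, 0), 2, 2)
  expect_error(vietoris_rips(m2, input = "dissimilarity"), "diagonal")
  m3 <- matrix(c(0, NaN, NaN, 0), 2, 2)
  expect_error(vietoris_rips(m3, input = "dissimilarity"), "non-finite")
})

test_that("refine_order ties break by dimension then lexicographic tuple", {
  f <- filtration_from_simplices(
    list(c(0, 2), c(0, 1), c(1, 2), c(0, 1, 2)),
    births = c(1, 1, 1, 1))
  em <- f$simplices[[2]]$vertices
  expect_equal(em[1, ], c(0L, 1L))   # (0,1) precedes (0,2)
  expect_equal(em[2, ], c(0L, 2L))
  # all edges precede the equal-birth triangle in the combined refinement:
  # its boundary is fully supported on already-present rows
  b2 <- boundary_matrix(f, 2)
  expect_equal(sort(b2$i), 1:3)
  # idempotent and deterministic
  f2 <- refine_order(f)
  expect_identical(f$simplices, f2$simplices)
})

test_that("a face born after its coface is an invalid filtration", {
  expect_error(
    filtration_from_simplices(list(c(0, 1), c(1, 2), c(0, 2), c(0, 1, 2)),
                              births = c(1, 1, 3, 2)),
    "born at 3 after coface")
})

test_that("boundary columns carry the signed face expansion", {
  f <- make_fixture("two_cycles")
  b2 <- boundary_matrix(f, 2)
  em <- f$simplices[[2]]$vertices
  faces <- em[b2$i, , drop = FALSE]
  got <- data.frame(v1 = faces[, 1], v2 = faces[, 2], sign = b2$num)
  got <- got[order(got$v1, got$v2), ]
  expect_equal(got$sign[got$v1 == 1 & got$v2 == 4], 1)   # +(1,4)
  expect_equal(got$sign[got$v1 == 0 & got$v2 == 4], -1)  # -(0,4)
  expect_equal(got$sign[got$v1 == 0 & got$v2 == 1], 1)   # +(0,1)
})

test_that("the edge boundary is head minus tail and n beyond max_dim is empty", {
  f <- make_fixture("square")
  b1 <- boundary_matrix(f, 1)
  em <- f$simplices[[2]]$vertices
  first <- which(b1$j == 1)
  expect_equal(sort(b1$i[first]), sort(c(em[1, 1] + 1L, em[1, 2] + 1L)))
  expect_equal(b1$num[first][order(b1$i[first])], c(-1, 1))
  b9 <- boundary_matrix(f, 3)
  expect_equal(b9$ncol, 0L)
  expect_equal(b9$nrow, 4L)  # row index over the 2-simplices stays consistent
})

test_that("boundary of boundary vanishes exactly on random clouds", {
  for (seed in 1:3) {
    f <- vietoris_rips(random_cloud(8, 3, seed), max_dim = 2)
    b1 <- boundary_matrix(f, 1)
    b2 <- boundary_matrix(f, 2)
    prod <- optcycle:::.cpp_rat_mult(b1$i, b1$j, b1$num, b1$den, b1$nrow, b1$ncol,
                                     b2$i, b2$j, b2$num, b2$den, b2$ncol)
    expect_length(prod$i, 0)
  }
})

test_that("birth monotonicity holds for every simplex of a VR filtration", {
  f <- vietoris_rips(random_cloud(10, 2, 4), max_dim = 2)
  b2 <- boundary_matrix(f, 2)
  eb <- f$simplices[[2]]$birth
  tb <- f$simplices[[3]]$birth
  expect_true(all(eb[b2$i] <= tb[b2$j] + 1e-12))
})

test_that("point-cloud readers round-trip and the lower-triangle dialect works", {
  pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  tf <- tempfile(fileext = ".csv")
  write.table(pts, tf, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_point_cloud(tf), pts)
  d <- as.matrix(dist(pts)); dimnames(d) <- NULL
  tf2 <- tempfile(fileext = ".csv")
  lines <- vapply(seq_len(nrow(d)), function(r)
    paste(c(d[r, seq_len(r - 1)], 0), collapse = ","), "")
  writeLines(lines, tf2)
  expect_equal(read_dissimilarity(tf2, lower = TRUE), d)
})
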