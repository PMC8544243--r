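# Hand-coded filtered complexes for the worked examples and the test suite.

#' Worked-example fixtures
#'
#' Small filtered complexes with known barcodes and optimization behaviour:
#'
#' * `"two_cycles"`: five vertices on a path 0-1-2-3-4 closed by edges (0,4)
#'   and (1,4), with the triangle (0,1,4); the two printed pentagon/square
#'   cycles differ by exactly the boundary of that triangle.
#' * `"three_bars"`: a filtration whose dimension-1 barcode is
#'   \{[1,2), [2,Inf), [3,Inf)\}: a square hole born at 1 filled at 2, and
#'   two later holes that never fill.
#' * `"fcb_extends_death"`: a theta-like complex where the filtered-basis
#'   optimum of the bar [1,2) is a cheaper cycle whose class never dies, so
#'   its lifespan becomes [1,Inf) and the optimized set is no longer a
#'   persistent homology cycle basis.
#' * `"volume_vs_edge"`: a coned square where the uniform edge-minimal
#'   representative has 4 edges while the optimal volume has 3 triangles and
#'   its boundary cycle 5 edges.
#' * `"square"`: the unit-square point cloud.
#' * `"bowtie"`: two triangles sharing one vertex (loop-count fixture).
#' * `"duplicate_bars"`: two far-apart congruent unit squares producing two
#'   bars with identical birth and death.
#' * `"six_edge_detour"`: a hexagonal detour around a square hole: the
#'   original representative has 6 edges, the optimum 4.
#'
#' @param name fixture name.
#' @return a `"vr_filtration"`.
#' @export
make_fixture <- function(name = c("two_cycles", "three_bars", "fcb_extends_death",
                                  "volume_vs_edge", "square", "bowtie",
                                  "duplicate_bars", "six_edge_detour")) {
  if (is.character(name) && length(name) == 1 && !(name %in% eval(formals(make_fixture)$name)))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(eval(formals(make_fixture)$name), collapse = ", ")))
  name <- match.arg(name)
  switch(name,
    two_cycles = filtration_from_simplices(
      simplices = list(c(0, 1), c(1, 2), c(2, 3), c(3, 4), c(0, 4), c(1, 4),
                       c(0, 1, 4)),
      births = c(1, 1, 1, 1, 1, 1, 1)),
    three_bars = filtration_from_simplices(
      simplices = list(
        c(0, 1), c(1, 2), c(2, 3), c(0, 3),            # square hole, born 1
        c(0, 2), c(0, 1, 2), c(0, 2, 3),               # filled at 2
        c(3, 4), c(4, 5), c(0, 5),                     # second hole, born 2
        c(0, 4)),                                      # third hole, born 3
      births = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 3)),
    fcb_extends_death = filtration_from_simplices(
      # vertices: 0 = a, 1 = n, 2 = b, 3 = m1, 4 = m2
      simplices = list(
        c(0, 1), c(1, 2),                              # short path P1: a-n-b
        c(0, 3), c(3, 4), c(2, 4),                     # long path P2: a-m1-m2-b
        c(0, 2),                                       # chord ab, born 1
        c(0, 4), c(0, 3, 4), c(0, 2, 4)),              # fill ab+P2 at 2
      births = c(0, 0, 0, 0, 0, 1, 2, 2, 2)),
    volume_vs_edge = filtration_from_simplices(
      # square 0123 with apex 4; spokes to 0,1 early so the late window only
      # constrains the spokes of 2 and 3
      simplices = list(
        c(0, 1), c(0, 3), c(0, 4), c(1, 2), c(1, 4), c(2, 3), c(0, 1, 4),
        c(2, 4), c(3, 4), c(1, 2, 4), c(0, 3, 4),
        c(2, 3, 4)),
      births = c(1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3)),
    square = vietoris_rips(matrix(c(0, 0, 1, 0, 1, 1, 0, 1),
                                  ncol = 2, byrow = TRUE), max_dim = 2),
    bowtie = filtration_from_simplices(
      simplices = list(c(0, 1), c(0, 2), c(1, 2), c(2, 3), c(2, 4), c(3, 4)),
      births = rep(1, 6)),
    duplicate_bars = vietoris_rips(
      rbind(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE),
            matrix(c(50, 0, 51, 0, 51, 1, 50, 1), ncol = 2, byrow = TRUE)),
      max_dim = 2, scale_cap = 2),
    six_edge_detour = filtration_from_simplices(
      # square hole 0-1-2-3; the side 0-1-2 is doubled by a detour
      # 0-4-5-6-2 joined by a strip of triangles, so a 6-edge representative
      # (detour + the rest of the square) is homologous to the 4-edge square
      simplices = list(
        c(0, 1), c(1, 2), c(2, 3), c(0, 3),
        c(0, 4), c(4, 5), c(5, 6), c(2, 6),
        c(1, 4), c(1, 5), c(1, 6),
        c(0, 1, 4), c(1, 4, 5), c(1, 5, 6), c(1, 2, 6)),
      births = rep(1, 15))
  )
}
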