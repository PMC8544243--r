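# Loss functions on chains: edge count, total length, triangle count, Heron
# area, and the Surveyor's enclosed area with its eligibility conditions.

#' Edge losses of a 1-chain
#'
#' @param x an edge chain.
#' @param filtration the `"vr_filtration"` supplying edge lengths.
#' @return list with `e_unif` (support size) and `e_len` (total length).
#' @export
edge_losses <- function(x, filtration) {
  stopifnot(inherits(x, "chain"), x$dim == 1L)
  list(e_unif = chain_l0(x),
       e_len = sum(.edge_weights(filtration, "length", x$idx)))
}

#' Triangle losses of a 2-chain
#'
#' @param v a triangle chain.
#' @param filtration the `"vr_filtration"` supplying edge lengths.
#' @return list with `t_unif` (support size) and `t_area` (total Heron area;
#'   degenerate triangles contribute 0).
#' @export
triangle_losses <- function(v, filtration) {
  stopifnot(inherits(v, "chain"), v$dim == 2L)
  if (chain_l0(v) == 0) return(list(t_unif = 0, t_area = 0))
  tm <- filtration$simplices[[3]]$vertices[v$idx, , drop = FALSE]
  d <- filtration$dist
  area <- heron_area(d[cbind(tm[, 1] + 1L, tm[, 2] + 1L)],
                     d[cbind(tm[, 1] + 1L, tm[, 3] + 1L)],
                     d[cbind(tm[, 2] + 1L, tm[, 3] + 1L)])
  list(t_unif = chain_l0(v), t_area = sum(area))
}

# orientation of the triple (p, q, r); exact for rational inputs up to the
# double mantissa, epsilon-guarded otherwise
.orient <- function(p, q, r, eps = 1e-12) {
  v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  if (abs(v) <= eps) 0 else sign(v)
}

# do closed segments a-b and c-d intersect anywhere but a shared endpoint?
.segments_conflict <- function(a, b, c, d, eps = 1e-12) {
  shared <- (all(a == c) || all(a == d) || all(b == c) || all(b == d))
  o1 <- .orient(a, b, c, eps); o2 <- .orient(a, b, d, eps)
  o3 <- .orient(c, d, a, eps); o4 <- .orient(c, d, b, eps)
  if (shared) {
    # adjacent segments conflict only if collinear and overlapping beyond
    # the shared endpoint
    if (o1 == 0 && o2 == 0 && o3 == 0 && o4 == 0) {
      pts <- rbind(a, b, c, d)
      rng <- apply(pts, 2, range)
      # overlap of collinear closed segments longer than a point
      ov <- min(max(a[1], b[1]), max(c[1], d[1])) - max(min(a[1], b[1]), min(c[1], d[1]))
      ov2 <- min(max(a[2], b[2]), max(c[2], d[2])) - max(min(a[2], b[2]), min(c[2], d[2]))
      return(ov > eps || ov2 > eps)
    }
    return(FALSE)
  }
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) - eps <= r[1] && r[1] <= max(p[1], q[1]) + eps &&
      min(p[2], q[2]) - eps <= r[2] && r[2] <= max(p[2], q[2]) + eps
  }
  (o1 == 0 && on_seg(a, b, c)) || (o2 == 0 && on_seg(a, b, d)) ||
    (o3 == 0 && on_seg(c, d, a)) || (o4 == 0 && on_seg(c, d, b))
}

#' Surveyor's (shoelace) area enclosed by a cycle representative
#'
#' Computed only when (i) the ambient point cloud lives in the plane,
#' (ii) the support is a single graph-theoretic cycle, and (iii) no two
#' distinct closed segments intersect except at shared endpoints.  Otherwise
#' the failed condition is reported as the reason; ineligibility is a value,
#' not an error.
#'
#' @param x an edge chain.
#' @param filtration a `"vr_filtration"` built from a point cloud.
#' @return list with `area` (numeric or `NA`) and `reason` (`"ok"` or the
#'   failed condition).
#' @export
surveyor_area <- function(x, filtration) {
  stopifnot(inherits(x, "chain"), x$dim == 1L)
  coords <- filtration$coords
  if (is.null(coords) || ncol(coords) != 2)
    return(list(area = NA_real_, reason = "ambient dimension is not 2"))
  if (chain_l0(x) < 3)
    return(list(area = NA_real_, reason = "support is not a single simple cycle"))
  em <- filtration$simplices[[2]]$vertices[x$idx, , drop = FALSE]
  verts <- sort(unique(c(em)))
  deg <- table(factor(c(em), levels = verts))
  if (any(deg != 2) || length(verts) != nrow(em))
    return(list(area = NA_real_, reason = "support is not a single simple cycle"))
  # walk the cycle
  adj <- split(c(em[, 2], em[, 1]), c(em[, 1], em[, 2]))
  walk <- integer(nrow(em))
  walk[1] <- verts[1]
  prev <- NA_integer_
  for (t in 2:length(walk)) {
    nb <- adj[[as.character(walk[t - 1])]]
    nxt <- nb[is.na(prev) | nb != prev][1]
    prev <- walk[t - 1]
    walk[t] <- nxt
  }
  if (length(unique(walk)) != length(verts))
    return(list(area = NA_real_, reason = "support is not a single simple cycle"))
  # non-adjacent segment intersections
  pts <- coords[walk + 1L, , drop = FALSE]
  nseg <- nrow(pts)
  seg <- cbind(seq_len(nseg), c(seq_len(nseg)[-1], 1L))
  for (s1 in seq_len(nseg - 1)) {
    for (s2 in (s1 + 1):nseg) {
      if (.segments_conflict(pts[seg[s1, 1], ], pts[seg[s1, 2], ],
                             pts[seg[s2, 1], ], pts[seg[s2, 2], ]))
        return(list(area = NA_real_, reason = "segments intersect"))
    }
  }
  p <- pts[, 1]; q <- pts[, 2]
  p2 <- c(p[-1], p[1]); q2 <- c(q[-1], q[1])
  list(area = abs(sum(p * q2 - p2 * q)) / 2, reason = "ok")
}

#' Loss report for one representative (and optional volume)
#'
#' One row with every applicable loss and the Surveyor eligibility code.
#'
#' @param x edge chain (representative).
#' @param filtration the filtration.
#' @param v optional triangle chain (bounding volume).
#' @return one-row data frame.
#' @export
loss_report <- function(x, filtration, v = NULL) {
  el <- edge_losses(x, filtration)
  sv <- surveyor_area(x, filtration)
  tl <- if (!is.null(v)) triangle_losses(v, filtration) else list(t_unif = NA_real_, t_area = NA_real_)
  data.frame(e_unif = el$e_unif, e_len = el$e_len,
             t_unif = tl$t_unif, t_area = tl$t_area,
             sur_area = sv$area, sur_eligibility = sv$reason)
}
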