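# Vietoris-Rips filtrations from point clouds or dissimilarity matrices, plus
# hand-specified filtered complexes for worked examples.

#' Build a Vietoris-Rips filtration
#'
#' A simplex enters the filtration at the maximum pairwise dissimilarity among
#' its vertices; vertices are born at 0.  Within each dimension, simplices are
#' kept in the canonical filtration-preserving order: increasing birth, ties
#' broken lexicographically on the (sorted) vertex tuple.  Interleaving the
#' per-dimension orders by (birth, dimension, lexicographic tuple) gives a
#' simplex-wise refinement in which every face precedes every coface.
#'
#' @param x either an `n x d` coordinate matrix (one point per row) or an
#'   `n x n` symmetric dissimilarity matrix with zero diagonal.  Use `input`
#'   to disambiguate; by default a square symmetric zero-diagonal matrix is
#'   treated as dissimilarities.
#' @param max_dim largest simplex dimension retained (2 suffices for
#'   dimension-1 homology).
#' @param scale_cap largest birth value retained.  The default, the maximum
#'   pairwise dissimilarity, guarantees that every dimension-1 class dies.
#' @param input one of `"auto"`, `"cloud"`, `"dissimilarity"`.
#' @return an object of class `"vr_filtration"`.
#' @examples
#' pts <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' filt <- vietoris_rips(pts, max_dim = 2)
#' filt
#' @export
vietoris_rips <- function(x, max_dim = 2, scale_cap = NULL,
                          input = c("auto", "cloud", "dissimilarity")) {
  input <- match.arg(input)
  x <- as.matrix(x)
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite entry at [%d, %d]", bad[1], bad[2]))
  }
  if (input == "auto") {
    input <- if (nrow(x) == ncol(x) && nrow(x) > 1 &&
                 all(abs(diag(x)) == 0) && isTRUE(all.equal(x, t(x), tolerance = 0)))
      "dissimilarity" else "cloud"
  }
  if (input == "cloud") {
    coords <- x
    dm <- as.matrix(stats::dist(coords))
    dimnames(dm) <- NULL
  } else {
    coords <- NULL
    dm <- .validate_dissimilarity(x)
  }
  if (max_dim < 1) stop("max_dim must be at least 1")
  if (is.null(scale_cap)) scale_cap <- max(dm)
  simp <- .cpp_vr_simplices(dm, as.integer(max_dim), as.numeric(scale_cap))
  filt <- structure(list(n_points = nrow(dm),
                         max_dim = as.integer(max_dim),
                         scale_cap = scale_cap,
                         dist = dm,
                         coords = coords,
                         simplices = simp),
                    class = "vr_filtration")
  # births are maxima of pairwise dissimilarities by construction, so the
  # face-before-coface property holds; no need for the explicit audit
  refine_order(filt, validate = FALSE)
}

.validate_dissimilarity <- function(x) {
  if (nrow(x) != ncol(x)) stop("dissimilarity matrix must be square")
  bad <- which(x != t(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("dissimilarity matrix not symmetric: entry [%d, %d] (%g) != [%d, %d] (%g)",
                 bad[1, 1], bad[1, 2], x[bad[1, , drop = FALSE]],
                 bad[1, 2], bad[1, 1], t(x)[bad[1, , drop = FALSE]]))
  nzd <- which(diag(x) != 0)
  if (length(nzd) > 0)
    stop(sprintf("dissimilarity matrix has nonzero diagonal at index %d", nzd[1]))
  neg <- which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative dissimilarity at [%d, %d]", neg[1, 1], neg[1, 2]))
  x
}

#' Construct a filtered complex from an explicit simplex list
#'
#' Used for hand-specified worked examples where births do not come from a
#' metric.  Faces must be present and born no later than their cofaces; the
#' vertex set is inferred.
#'
#' @param simplices list of integer vectors (0-based vertex ids).
#' @param births numeric vector of birth values, parallel to `simplices`.
#' @param dist optional dissimilarity matrix supplying edge lengths for
#'   length/area weights (defaults to edge births).
#' @return an object of class `"vr_filtration"`.
#' @export
filtration_from_simplices <- function(simplices, births, dist = NULL) {
  stopifnot(length(simplices) == length(births))
  simplices <- lapply(simplices, function(v) sort(as.integer(v)))
  dims <- vapply(simplices, length, 0L) - 1L
  n_points <- max(vapply(simplices, max, 0L)) + 1L
  max_dim <- max(dims)
  out <- vector("list", max_dim + 1)
  # vertices always present at birth 0
  vb <- numeric(n_points)
  explicit_v <- dims == 0L
  if (any(explicit_v)) {
    for (k in which(explicit_v)) vb[simplices[[k]][1] + 1] <- births[k]
  }
  out[[1]] <- list(vertices = matrix(0:(n_points - 1), ncol = 1), birth = vb)
  for (d in seq_len(max_dim)) {
    sel <- which(dims == d)
    if (length(sel) == 0) {
      out[[d + 1]] <- list(vertices = matrix(integer(0), ncol = d + 1),
                           birth = numeric(0))
      next
    }
    m <- do.call(rbind, simplices[sel])
    out[[d + 1]] <- list(vertices = m, birth = births[sel])
  }
  if (is.null(dist)) {
    dist <- matrix(0, n_points, n_points)
    if (max_dim >= 1) {
      em <- out[[2]]$vertices
      for (r in seq_len(nrow(em))) {
        i <- em[r, 1] + 1; j <- em[r, 2] + 1
        dist[i, j] <- dist[j, i] <- out[[2]]$birth[r]
      }
    }
  }
  filt <- structure(list(n_points = n_points,
                         max_dim = max_dim,
                         scale_cap = max(births),
                         dist = dist,
                         coords = NULL,
                         simplices = out),
                    class = "vr_filtration")
  refine_order(filt)
}

#' Impose the canonical simplex-wise refinement order
#'
#' Sorts each dimension by (birth, lexicographic vertex tuple) and verifies
#' birth monotonicity (no face born after a coface).  Idempotent and
#' deterministic; called by the constructors.
#'
#' @param filtration a `"vr_filtration"`.
#' @param validate audit birth monotonicity (face born no later than coface).
#'   On by default; constructors that guarantee monotonicity skip it.
#' @return the filtration with orders fixed.
#' @export
refine_order <- function(filtration, validate = TRUE) {
  stopifnot(inherits(filtration, "vr_filtration"))
  for (d in seq_along(filtration$simplices)) {
    s <- filtration$simplices[[d]]
    if (is.null(s) || nrow(s$vertices) == 0) next
    keys <- c(list(s$birth), lapply(seq_len(ncol(s$vertices)), function(c) s$vertices[, c]))
    o <- do.call(order, keys)
    filtration$simplices[[d]] <- list(vertices = s$vertices[o, , drop = FALSE],
                                      birth = s$birth[o])
  }
  if (validate) .validate_refinement(filtration)
  filtration
}

.validate_refinement <- function(filt) {
  for (d in seq_len(filt$max_dim)) {
    s <- filt$simplices[[d + 1]]
    if (is.null(s) || nrow(s$vertices) == 0) next
    faces <- filt$simplices[[d]]
    key_birth <- .tuple_birth_map(faces$vertices, faces$birth, filt$n_points)
    for (r in seq_len(nrow(s$vertices))) {
      v <- s$vertices[r, ]
      for (omit in seq_along(v)) {
        fk <- .tuple_key(v[-omit], filt$n_points)
        fb <- key_birth[[fk]]
        if (is.null(fb))
          stop(sprintf("invalid filtration: simplex (%s) has a missing face",
                       paste(v, collapse = ",")))
        if (fb > s$birth[r])
          stop(sprintf("invalid filtration: face of (%s) born at %g after coface at %g",
                       paste(v, collapse = ","), fb, s$birth[r]))
      }
    }
  }
  invisible(NULL)
}

.tuple_key <- function(v, n) paste(v, collapse = "_")
.tuple_birth_map <- function(m, births, n) {
  env <- new.env(hash = TRUE, size = max(16L, nrow(m)))
  for (r in seq_len(nrow(m)))
    assign(.tuple_key(m[r, ], n), births[r], envir = env)
  env
}

#' Number of simplices per dimension
#' @param filtration a `"vr_filtration"`.
#' @export
simplex_counts <- function(filtration) {
  vapply(filtration$simplices, function(s) if (is.null(s)) 0L else nrow(s$vertices), 0L)
}

#' Boundary matrix of the n-simplices
#'
#' Returns the signed incidence of n-simplices (columns) on (n-1)-simplices
#' (rows), both in the filtration's refined order, as exact rational triplets.
#' `n` beyond `max_dim` yields an empty matrix with a consistent row index.
#'
#' @param filtration a `"vr_filtration"`.
#' @param n chain dimension (`n >= 1`).
#' @return object of class `"boundary_matrix"`: a triplet list with fields
#'   `i`, `j`, `num`, `den`, `nrow`, `ncol`, `dim`.
#' @export
boundary_matrix <- function(filtration, n) {
  stopifnot(inherits(filtration, "vr_filtration"), n >= 1)
  faces <- filtration$simplices[[n]]
  nrow <- if (is.null(faces)) 0L else nrow(faces$vertices)
  if (n > filtration$max_dim || nrow == 0L ||
      is.null(filtration$simplices[[n + 1]]) ||
      nrow(filtration$simplices[[n + 1]]$vertices) == 0) {
    return(structure(list(i = integer(0), j = integer(0),
                          num = numeric(0), den = numeric(0),
                          nrow = nrow, ncol = 0L, dim = as.integer(n)),
                     class = "boundary_matrix"))
  }
  simp <- filtration$simplices[[n + 1]]
  tr <- .cpp_boundary_triplets(simp$vertices, faces$vertices, filtration$n_points)
  structure(list(i = tr$i, j = tr$j, num = as.numeric(tr$x),
                 den = rep(1, length(tr$x)),
                 nrow = nrow, ncol = nrow(simp$vertices), dim = as.integer(n)),
            class = "boundary_matrix")
}

#' @export
print.vr_filtration <- function(x, ...) {
  cnt <- simplex_counts(x)
  cat(sprintf("<vr_filtration> %d points, max_dim %d, scale cap %g\n",
              x$n_points, x$max_dim, x$scale_cap))
  cat("  simplices:", paste(sprintf("dim %d: %d", seq_along(cnt) - 1, cnt),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Read a point cloud from a delimited text file
#'
#' One point per row, numeric columns, no header required.
#'
#' @param path file path.
#' @param sep field delimiter (`","` by default).
#' @param header whether the first row is a header.
#' @return numeric matrix of coordinates.
#' @export
read_point_cloud <- function(path, sep = ",", header = FALSE) {
  df <- utils::read.table(path, sep = sep, header = header,
                          strip.white = TRUE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop(sprintf("non-numeric values in %s", path))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Read a dissimilarity matrix from a delimited text file
#'
#' Accepts a full square matrix or (with `lower = TRUE`) a lower-triangular
#' listing, one row per point, mirrored to the full symmetric matrix.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @param lower whether the file stores only the lower triangle.
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
read_dissimilarity <- function(path, sep = ",", lower = FALSE) {
  if (!lower) {
    m <- read_point_cloud(path, sep = sep)
    return(.validate_dissimilarity(m))
  }
  rows <- strsplit(trimws(readLines(path)), sep, fixed = TRUE)
  rows <- rows[vapply(rows, function(r) length(r) > 0 && any(nzchar(r)), TRUE)]
  n <- length(rows)
  m <- matrix(0, n, n)
  for (r in seq_len(n)) {
    vals <- as.numeric(rows[[r]])
    if (length(vals) < r - 1)
      stop(sprintf("row %d of %s has %d entries; expected at least %d",
                   r, path, length(vals), r - 1))
    if (r > 1) {
      m[r, 1:(r - 1)] <- vals[1:(r - 1)]
      m[1:(r - 1), r] <- vals[1:(r - 1)]
    }
  }
  .validate_dissimilarity(m)
}
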