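# Synthetic corpora: i.i.d.-coordinate point clouds in ambient dimensions
# 2..10 and Erdos-Renyi dissimilarity matrices with U[0,1] off-diagonal
# entries.  Every draw is seeded; per-replicate seeds derive from the corpus
# seed by a counter so any single input can be regenerated in isolation.

.cloud_families <- c("normal", "gamma", "logistic", "exponential")

#' Sample a synthetic point cloud
#'
#' Coordinates are i.i.d. per axis from the named distribution: standard
#' normal, gamma(shape 2, scale 1), logistic(0, 1), or exponential(rate 1).
#' For the normal, logistic and exponential families the dimension-1 bar
#' count of the Vietoris-Rips filtration is invariant to the (unstated)
#' location/scale, so the defaults are immaterial to those statistics; the
#' gamma shape genuinely matters and is a fixed convention here.
#'
#' @param family one of `"normal"`, `"gamma"`, `"logistic"`, `"exponential"`.
#' @param n number of points (default 100).
#' @param dim ambient dimension.
#' @param seed integer seed; the draw is fully reproducible.
#' @return an `n x dim` coordinate matrix.
#' @export
sample_cloud <- function(family, n = 100, dim = 2, seed = 1) {
  if (!family %in% .cloud_families)
    stop(sprintf("unsupported family '%s'; choose one of: %s",
                 family, paste(.cloud_families, collapse = ", ")))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw <- switch(family,
                 normal = stats::rnorm(n * dim),
                 gamma = stats::rgamma(n * dim, shape = 2, scale = 1),
                 logistic = stats::rlogis(n * dim),
                 exponential = stats::rexp(n * dim))
  matrix(draw, nrow = n, ncol = dim)
}

#' Sample an Erdos-Renyi dissimilarity matrix
#'
#' Symmetric with zero diagonal and the `choose(n, 2)` off-diagonal values
#' i.i.d. uniform on [0, 1]; deliberately non-metric (no triangle
#' inequality), a non-geometric null model for clique-complex filtrations.
#'
#' @param n matrix size (default 100).
#' @param seed integer seed.
#' @return an `n x n` dissimilarity matrix.
#' @export
sample_er_dissimilarity <- function(n = 100, seed = 1) {
  stopifnot(n >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Specify a synthetic corpus
#'
#' @param family distribution family or `"erdos_renyi"`.
#' @param n_points points per cloud / matrix size.
#' @param ambient_dims ambient dimensions (point-cloud families; ignored for
#'   Erdos-Renyi).
#' @param replicates replicates per dimension (point clouds) or number of
#'   matrices (Erdos-Renyi).
#' @param seed corpus seed.
#' @return object of class `"corpus_spec"`.
#' @export
corpus_spec <- function(family, n_points = 100, ambient_dims = 2:10,
                        replicates = if (family == "erdos_renyi") 100 else 10,
                        seed = 1) {
  stopifnot(family %in% c(.cloud_families, "erdos_renyi"), replicates >= 1)
  structure(list(family = family, n_points = n_points,
                 ambient_dims = if (family == "erdos_renyi") NA_integer_ else ambient_dims,
                 replicates = replicates, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Per-item seeds of a corpus
#'
#' Derived from the corpus seed by a counter, so item `k` is regenerable in
#' isolation.  Kept well below 2^31.
#'
#' @param spec a `"corpus_spec"`.
#' @return data frame with one row per corpus item: family, dim, replicate,
#'   seed.
#' @export
corpus_manifest <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (spec$family == "erdos_renyi") {
    k <- seq_len(spec$replicates)
    return(data.frame(family = spec$family, dim = NA_integer_, replicate = k,
                      seed = (spec$seed %% 100000L) * 10000L + k))
  }
  grid <- expand.grid(replicate = seq_len(spec$replicates), dim = spec$ambient_dims)
  data.frame(family = spec$family, dim = grid$dim, replicate = grid$replicate,
             seed = (spec$seed %% 100000L) * 10000L +
               grid$dim * 100L + grid$replicate)
}

#' Materialize one corpus item
#'
#' @param spec a `"corpus_spec"`.
#' @param k item index (row of [corpus_manifest()]).
#' @return coordinate matrix or dissimilarity matrix.
#' @export
corpus_item <- function(spec, k) {
  man <- corpus_manifest(spec)
  stopifnot(k >= 1, k <= nrow(man))
  if (spec$family == "erdos_renyi")
    sample_er_dissimilarity(spec$n_points, seed = man$seed[k])
  else
    sample_cloud(spec$family, n = spec$n_points, dim = man$dim[k],
                 seed = man$seed[k])
}

#' Write a corpus to disk as CSV plus a manifest
#'
#' @param spec a `"corpus_spec"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest with file names.
#' @export
write_corpus <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- corpus_manifest(spec)
  man$file <- sprintf("%s_%s_r%02d.csv", spec$family,
                      ifelse(is.na(man$dim), "na", sprintf("d%02d", man$dim)),
                      man$replicate)
  for (k in seq_len(nrow(man))) {
    utils::write.table(corpus_item(spec, k), file.path(dir, man$file[k]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(list(spec = unclass(spec), items = man),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
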