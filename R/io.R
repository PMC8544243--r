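# Writers for barcodes, cycle representatives, and per-bar reports, plus the
# scripted pipeline behind the command-line interface.

.simplex_label <- function(filtration, dim, idx) {
  if (is.na(idx)) return("")
  paste(filtration$simplices[[dim + 1]]$vertices[idx, ], collapse = " ")
}

#' Write a barcode as CSV
#'
#' Columns: dimension, birth, death (`inf` for essential bars), and the
#' vertex tuples of the birth and death simplices.
#'
#' @param ph a `"ph"` fit.
#' @param path output file.
#' @export
write_barcode <- function(ph, path) {
  bars <- ph$basis$bars
  df <- data.frame(
    dimension = rep(1L, nrow(bars)),
    birth = format(bars$birth, digits = 17, trim = TRUE, scientific = FALSE),
    death = ifelse(is.finite(bars$death),
                   format(bars$death, digits = 17, trim = TRUE, scientific = FALSE),
                   "inf"),
    birth_simplex = vapply(bars$birth_edge, function(i)
      .simplex_label(ph$filtration, 1, i), ""),
    death_simplex = vapply(bars$death_triangle, function(i)
      .simplex_label(ph$filtration, 2, i), ""))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write cycle representatives as JSON
#'
#' One record per bar: a list of `{simplex: [v...], coefficient: "p/q"}`
#' entries.  Rational coefficients are serialized as exact strings, never
#' floats, and round-trip unchanged.
#'
#' @param basis a `"cycle_basis"`.
#' @param filtration the filtration the chains refer to.
#' @param path output file.
#' @export
write_cycles <- function(basis, filtration, path) {
  recs <- lapply(seq_along(basis$reps), function(k) {
    ch <- basis$reps[[k]]
    dimv <- ch$dim
    list(birth = basis$bars$birth[k],
         death = if (is.finite(basis$bars$death[k])) basis$bars$death[k] else "inf",
         chain = lapply(seq_along(ch$idx), function(t) {
           list(simplex = as.integer(filtration$simplices[[dimv + 1]]$vertices[ch$idx[t], ]),
                coefficient = rat_format(ch$num[t], ch$den[t]))
         }))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cycle representatives written by [write_cycles()]
#'
#' @param path JSON file.
#' @param filtration the filtration the chains refer to.
#' @return a list of chains.
#' @export
read_cycles <- function(path, filtration) {
  recs <- jsonlite::read_json(path)
  n <- filtration$n_points
  lapply(recs, function(r) {
    if (length(r$chain) == 0) return(chain(1L))
    verts <- lapply(r$chain, function(e) unlist(e$simplex))
    dimv <- length(verts[[1]]) - 1L
    m <- filtration$simplices[[dimv + 1]]$vertices
    key <- apply(m, 1, paste, collapse = "_")
    idx <- match(vapply(verts, paste, "", collapse = "_"), key)
    if (any(is.na(idx))) stop("cycle refers to a simplex absent from the filtration")
    co <- rat_parse(vapply(r$chain, function(e) e$coefficient, ""))
    chain(dimv, idx, co$num, co$den)
  })
}

#' Run the full pipeline on one input file
#'
#' Reads the input, computes persistent homology, optionally optimizes the
#' representatives, and writes the barcode, cycles, and a per-bar report to
#' `out_dir` together with a manifest of the resolved configuration.
#'
#' @param input path to a CSV point cloud or dissimilarity matrix.
#' @param out_dir output directory.
#' @param kind `"auto"`, `"cloud"` or `"dissimilarity"`.
#' @param method `"none"` (persistence only), `"edge-unif"`, `"edge-len"`,
#'   `"tri-unif"`, `"tri-area"`.
#' @param program `"prshcb"` (persistent basis, with replacement) or `"fcb"`
#'   (filtered basis); edge-loss methods only.
#' @param integral solve mixed-integer programs.
#' @param max_dim,scale_cap filtration parameters.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic given the input).
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(input, out_dir, kind = "auto", method = "none",
                         program = "prshcb", integral = FALSE,
                         max_dim = 2, scale_cap = NULL, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  x <- if (kind == "dissimilarity") read_dissimilarity(input) else read_point_cloud(input)
  filt <- vietoris_rips(x, max_dim = max_dim, scale_cap = scale_cap,
                        input = if (kind == "auto") "auto" else kind)
  ph <- persistent_homology(filt)
  write_barcode(ph, file.path(out_dir, "barcode.csv"))
  write_cycles(ph$basis, filt, file.path(out_dir, "cycles_original.json"))
  report <- NULL
  if (method != "none") {
    opt <- switch(method,
      "edge-unif" = if (program == "fcb") optimize_filtered_basis(ph, "uniform", integral)
                    else optimize_persistent_basis(ph, "uniform", integral),
      "edge-len" = if (program == "fcb") optimize_filtered_basis(ph, "length", integral)
                   else optimize_persistent_basis(ph, "length", integral),
      "tri-unif" = optimize_volume_basis(ph, "uniform", integral),
      "tri-area" = optimize_volume_basis(ph, "area", integral),
      stop(sprintf("unknown method '%s'", method)))
    write_cycles(opt$basis, filt, file.path(out_dir, "cycles_optimized.json"))
    report <- opt$report
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(input = input, kind = kind, method = method, program = program,
         integral = integral, max_dim = max_dim,
         scale_cap = if (is.null(scale_cap)) "enclosing" else scale_cap,
         seed = seed, package_version = as.character(utils::packageVersion("optcycle"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
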