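#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv`. The MTX file is
#' genes x cells (the 10x convention); the result is transposed to the
#' package-internal cells x genes orientation. Duplicate feature names are
#' disambiguated deterministically with suffixes `.1`, `.2`, ...
#'
#' @param dir Directory holding the three files.
#' @param layer Layer tag for the resulting [cell_matrix].
#' @return A [cell_matrix].
#' @export
read_mtx_triplet <- function(dir, layer = "raw_counts") {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing file(s): ", paste(basename(missing), collapse = ", "))
  }
  mm <- Matrix::readMM(paths[1])              # genes x cells
  feats <- utils::read.delim(paths[2], header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(paths[3], header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  if (nrow(mm) != length(feats)) {
    stop(sprintf("matrix declares %d genes but features.tsv lists %d",
                 nrow(mm), length(feats)))
  }
  if (ncol(mm) != length(cells)) {
    stop(sprintf("matrix declares %d cells but barcodes.tsv lists %d",
                 ncol(mm), length(cells)))
  }
  if (layer == "raw_counts" && length(mm@x) && min(mm@x) < 0) {
    stop("negative entries in a counts layer")
  }
  feats <- make.unique(feats, sep = ".")
  m <- Matrix::t(mm)                          # cells x genes
  dimnames(m) <- list(cells, feats)
  cell_matrix(methods::as(m, "CsparseMatrix"), layer = layer)
}

#' Write a [cell_matrix] as a 10x-style MTX triplet
#'
#' Transposes to the genes x cells MTX orientation; round-trips through
#' [read_mtx_triplet()].
#'
#' @param m A [cell_matrix].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(m, dir) {
  stopifnot(inherits(m, "cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- methods::as(Matrix::Matrix(m$values, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(Matrix::t(sp), file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a dense TSV view of a [cell_matrix] (cells in rows)
#' @param m A [cell_matrix].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(cell_id = m$cell_ids, as_dense(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
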