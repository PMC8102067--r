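#' Cell-by-gene expression matrix with per-cell metadata
#'
#' Lightweight container used throughout the package. The internal
#' orientation is always cells x genes; only the Matrix Market (MTX)
#' boundary transposes, because the 10x convention stores genes x cells.
#'
#' @param values Numeric matrix (base or \pkg{Matrix} sparse), cells in rows,
#'   genes in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `colnames(values)`).
#' @param cell_ids Character vector of unique cell barcodes (defaults to
#'   `rownames(values)`).
#' @param layer One of `"raw_counts"`, `"lognorm"`, `"imputed"`. The
#'   `raw_counts` layer must contain non-negative integers.
#' @param cell_meta Optional data.frame of per-cell annotations (condition,
#'   mito fraction, ...) with one row per cell.
#'
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(values,
                        gene_ids = colnames(values),
                        cell_ids = rownames(values),
                        layer = c("raw_counts", "lognorm", "imputed"),
                        cell_meta = NULL) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (supply dimnames or arguments)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != ncol(values) || length(cell_ids) != nrow(values)) {
    stop("id lengths inconsistent with matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  vals <- check_layer_values(values, layer)
  dimnames(vals) <- list(cell_ids, gene_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    if (nrow(cell_meta) != length(cell_ids)) {
      stop("cell_meta must have one row per cell")
    }
    rownames(cell_meta) <- cell_ids
  }
  structure(
    list(values = vals, gene_ids = gene_ids, cell_ids = cell_ids,
         layer = layer, cell_meta = cell_meta),
    class = "cell_matrix"
  )
}

check_layer_values <- function(values, layer) {
  mn <- if (inherits(values, "sparseMatrix")) {
    min(0, values@x)
  } else if (length(values)) {
    min(values)
  } else {
    0
  }
  if (is.na(mn)) stop("matrix contains NA values")
  if (mn < 0) stop(sprintf("%s layer must be non-negative", layer))
  if (layer == "raw_counts") {
    x <- if (inherits(values, "sparseMatrix")) values@x else as.vector(values)
    if (length(x) && any(abs(x - round(x)) > 1e-8)) {
      stop("raw_counts layer must contain integer counts")
    }
  }
  values
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' Number of cells / genes in a `cell_matrix`
#' @param x A `cell_matrix`.
#' @return Integer count.
#' @export
n_cells <- function(x) nrow(x$values)

#' @rdname n_cells
#' @export
n_genes <- function(x) ncol(x$values)

#' Extract the expression values of a `cell_matrix` as a dense base matrix
#' @param x A `cell_matrix`.
#' @return Dense numeric matrix, cells x genes.
#' @export
as_dense <- function(x) {
  stopifnot(inherits(x, "cell_matrix"))
  as.matrix(x$values)
}

#' @export
print.cell_matrix <- function(x, ...) {
  nz <- if (inherits(x$values, "sparseMatrix")) {
    length(x$values@x)
  } else {
    sum(x$values != 0)
  }
  cat(sprintf("<cell_matrix> %d cells x %d genes, layer '%s' (%.1f%% non-zero)\n",
              n_cells(x), n_genes(x), x$layer,
              100 * nz / (as.numeric(nrow(x$values)) * ncol(x$values))))
  if (ncol(x$cell_meta)) {
    cat("  cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.cell_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_cells(x))
  if (missing(j)) j <- seq_len(n_genes(x))
  cell_ids <- stats::setNames(x$cell_ids, x$cell_ids)[i]
  gene_ids <- stats::setNames(x$gene_ids, x$gene_ids)[j]
  cell_matrix(x$values[i, j, drop = FALSE],
              gene_ids = unname(gene_ids), cell_ids = unname(cell_ids),
              layer = x$layer,
              cell_meta = x$cell_meta[i, , drop = FALSE])
}

#' Replace the layer tag after a transformation
#' @noRd
set_layer <- function(x, values, layer) {
  cell_matrix(values, gene_ids = x$gene_ids, cell_ids = x$cell_ids,
              layer = layer, cell_meta = x$cell_meta)
}
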