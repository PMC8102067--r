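#' Quality-control thresholds for cell filtering
#'
#' Defaults follow the common single-cell practice of removing cells with
#' more than 7500 or fewer than 200 detected features, or more than 20%
#' mitochondrial counts. All three rules are strict inequalities, so cells
#' sitting exactly on a boundary (200 or 7500 features, 20% mito) are
#' retained.
#'
#' @param min_features,max_features Detected-feature bounds.
#' @param max_mito Maximum mitochondrial count fraction.
#' @param mito_prefix Prefix identifying mitochondrial genes
#'   (case-insensitive).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200L, max_features = 7500L,
                          max_mito = 0.20, mito_prefix = "mt-") {
  if (min_features >= max_features) stop("min_features must be < max_features")
  if (max_mito < 0 || max_mito > 1) stop("max_mito must lie in [0, 1]")
  structure(list(min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 max_mito = max_mito, mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter cells on detected features and mitochondrial fraction
#'
#' A cell is removed iff `n_features < min_features` OR
#' `n_features > max_features` OR `mito_fraction > max_mito` (strict
#' comparisons). The mitochondrial fraction is computed on raw count mass
#' (not feature counts) over genes matching the mito prefix.
#'
#' @param m A raw-counts [cell_matrix].
#' @param thresholds A [qc_thresholds()].
#' @return List with `matrix` (the retained cells, mito fraction and
#'   feature counts refreshed in `cell_meta`) and `report` (a per-cell
#'   data frame: `cell_id`, `n_features`, `mito_fraction`, `kept`,
#'   `rules_violated`).
#' @export
filter_cells <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "cell_matrix"), inherits(thresholds, "qc_thresholds"))
  if (m$layer != "raw_counts") stop("filter_cells requires the raw_counts layer")
  vals <- m$values
  n_features <- Matrix::rowSums(vals > 0)
  totals <- Matrix::rowSums(vals)
  mito <- grepl(paste0("^", thresholds$mito_prefix), m$gene_ids,
                ignore.case = TRUE)
  mito_frac <- if (any(mito)) {
    ifelse(totals > 0,
           Matrix::rowSums(vals[, mito, drop = FALSE]) / totals, 0)
  } else {
    rep(0, n_cells(m))
  }
  too_few  <- n_features < thresholds$min_features
  too_many <- n_features > thresholds$max_features
  too_mito <- mito_frac > thresholds$max_mito
  kept <- !(too_few | too_many | too_mito)
  rules <- character(n_cells(m))
  rules[too_few]  <- "low_features"
  rules[too_many] <- paste0(rules[too_many],
                            ifelse(nzchar(rules[too_many]), ";", ""),
                            "high_features")
  rules[too_mito] <- paste0(rules[too_mito],
                            ifelse(nzchar(rules[too_mito]), ";", ""),
                            "high_mito")
  report <- data.frame(cell_id = m$cell_ids, n_features = n_features,
                       mito_fraction = mito_frac, kept = kept,
                       rules_violated = rules, stringsAsFactors = FALSE,
                       row.names = NULL)
  out <- m[kept, ]
  out$cell_meta$mito_fraction <- mito_frac[kept]
  out$cell_meta$n_features <- n_features[kept]
  list(matrix = out, report = report)
}

#' Library-size log normalization
#'
#' `value = ln(1 + scale * count / cell_total)` — a per-cell (row)
#' operation that preserves the zero pattern and is invariant to uniform
#' rescaling of a cell's counts.
#'
#' @param m A raw-counts [cell_matrix].
#' @param scale Size-factor target (default `1e4`).
#' @return A [cell_matrix] with layer `lognorm`.
#' @export
normalize_log <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "cell_matrix"))
  if (m$layer != "raw_counts") stop("normalize_log requires the raw_counts layer")
  totals <- Matrix::rowSums(m$values)
  if (any(totals == 0)) {
    stop(sprintf("%d cell(s) with zero total counts; filter them first",
                 sum(totals == 0)))
  }
  sp <- methods::as(Matrix::Matrix(m$values, sparse = TRUE), "CsparseMatrix")
  # operate on the non-zero entries only: log1p(0) = 0 keeps sparsity
  tsp <- Matrix::t(sp)                # work per-cell on columns
  cellidx <- rep(seq_len(ncol(tsp)), diff(tsp@p))
  tsp@x <- log1p(scale * tsp@x / totals[cellidx])
  set_layer(m, Matrix::t(tsp), "lognorm")
}

#' Select highly variable genes
#'
#' Returns the `n` genes of largest across-cell variance on the given layer,
#' with deterministic lexicographic tie-breaking on gene id.
#'
#' @param m A [cell_matrix] (normally lognorm).
#' @param n Number of genes.
#' @return Character vector of gene ids, variance-descending.
#' @export
select_hvg <- function(m, n = 500L) {
  stopifnot(inherits(m, "cell_matrix"))
  if (n > n_genes(m)) stop("n exceeds the number of genes")
  v <- col_vars(m$values)
  ord <- order(-v, m$gene_ids)
  m$gene_ids[ord][seq_len(n)]
}

## column variances without densifying
col_vars <- function(x) {
  n <- nrow(x)
  mu <- Matrix::colMeans(x)
  (Matrix::colSums(x^2) - n * mu^2) / (n - 1)
}
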