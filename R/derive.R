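#' Per-gene two-group Student's t-tests with Bonferroni correction
#'
#' Tests each universe gene for a treated-vs-control difference on the
#' linear normalized scale using a two-sided pooled-variance (equal
#' variance) t-test — Welch available by flag — and Bonferroni-corrects
#' over the number of genes actually tested (the universe intersection,
#' not the whole matrix). Genes with zero pooled variance are flagged and
#' recorded with `p = 1`. Fold change is `mean_treated / mean_control`
#' with a `1e-9` pseudocount guarding zero denominators.
#'
#' @param m A [cell_matrix] or plain numeric matrix (samples x genes) of
#'   normalized expression.
#' @param labels Two-level group labels, one per sample/cell.
#' @param universe Genes to test (absent genes are reported and skipped);
#'   `NULL` tests every gene.
#' @param treated Label of the treated group (default second level).
#' @param var_equal Pooled-variance t-test (`TRUE`, the default) or Welch.
#' @return A data frame of class `de_result`: per gene, group means, fold
#'   change, `t`, `p`, Bonferroni-adjusted `p_adj`, `direction`
#'   (up/down/none, treated-relative) and `flagged` (zero variance).
#'   Attribute `absent` lists requested universe genes not in the matrix.
#' @export
test_genes <- function(m, labels, universe = NULL, treated = NULL,
                       var_equal = TRUE) {
  X <- if (inherits(m, "cell_matrix")) as_dense(m) else as.matrix(m)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (length(labels) != nrow(X)) stop("one label per sample required")
  if (is.null(treated)) treated <- levels(labels)[2]
  control <- setdiff(levels(labels), treated)
  if (min(table(labels)) < 2L) stop("each group needs >= 2 samples")

  all_genes <- colnames(X)
  if (is.null(universe)) universe <- all_genes
  absent <- setdiff(universe, all_genes)
  genes <- intersect(universe, all_genes)
  if (!length(genes)) stop("no universe gene present in the matrix")

  a <- X[labels == treated, genes, drop = FALSE]
  b <- X[labels == control, genes, drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(genes))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  flagged <- se == 0 | !is.finite(se)
  tstat <- ifelse(flagged, NA_real_, (m1 - m2) / se)
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), df))
  n_tested <- length(genes)
  p_adj <- pmin(1, p * n_tested)
  fc <- (m1 + 1e-9) / (m2 + 1e-9)
  direction <- ifelse(m1 > m2, "up", ifelse(m1 < m2, "down", "none"))

  out <- data.frame(gene = genes, mean_control = unname(m2),
                    mean_treated = unname(m1), fold_change = unname(fc),
                    t = unname(tstat), p = unname(p), p_adj = unname(p_adj),
                    direction = unname(direction), flagged = unname(flagged),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "absent") <- absent
  attr(out, "n_tested") <- n_tested
  class(out) <- c("de_result", "data.frame")
  out
}

#' Derive a gene signature from differential-expression results
#'
#' Keeps genes with Bonferroni-adjusted `p < alpha`, fold change strictly
#' greater than `fc_threshold` in the requested direction (for `"down"`,
#' fold change strictly below `1 / fc_threshold`), sorted by fold change
#' (descending for up, ascending for down). An empty result is valid.
#'
#' @param de A `de_result` from [test_genes()].
#' @param alpha Adjusted-p threshold.
#' @param fc_threshold Fold-change threshold (strict; `2` keeps
#'   `fc > 2`, so a gene at exactly 2.0 is excluded).
#' @param direction `"up"` (treated-high, default) or `"down"`.
#' @return Character vector of gene ids with the filtered table attached as
#'   attribute `table`.
#' @export
derive_signature <- function(de, alpha = 0.05, fc_threshold = 2,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(de, "de_result"))
  keep <- de$p_adj < alpha & de$direction == direction
  keep <- keep & if (direction == "up") {
    de$fold_change > fc_threshold
  } else {
    de$fold_change < 1 / fc_threshold
  }
  tab <- de[keep, , drop = FALSE]
  ord <- order(tab$fold_change, decreasing = direction == "up")
  tab <- tab[ord, , drop = FALSE]
  out <- tab$gene
  attr(out, "table") <- tab
  out
}

#' Restrict a gene universe to an ontology-derived list
#'
#' Intersects a user-supplied ontology gene list (e.g. a WNT-signaling
#' annotation export) with the matrix genes by case-sensitive exact match,
#' preserving matrix order. Case-insensitive near-misses are reported in
#' the `fallback` attribute but not matched.
#'
#' @param m A [cell_matrix] or matrix with gene columns.
#' @param ontology_list Character vector of annotated genes.
#' @return Character vector of matched genes (matrix order) with attribute
#'   `fallback` listing case-insensitive-only matches.
#' @export
restrict_universe <- function(m, ontology_list) {
  genes <- if (inherits(m, "cell_matrix")) m$gene_ids else colnames(m)
  hit <- genes[genes %in% ontology_list]
  near <- ontology_list[!(ontology_list %in% genes) &
                          tolower(ontology_list) %in% tolower(genes)]
  if (!length(hit)) {
    stop("empty intersection between ontology list and matrix genes")
  }
  attr(hit, "fallback") <- near
  hit
}
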