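#' Per-cell mean signature score
#'
#' The score of a cell is the mean normalized expression of the signature
#' genes present in the matrix. Genes absent from the matrix are dropped
#' (they shrink the denominator rather than scoring as zero) with a warning;
#' the fraction retained is attached as attribute `coverage`.
#'
#' @param m A lognorm [cell_matrix].
#' @param genes Character vector of signature genes, or a single-signature
#'   entry of a [signature_set].
#' @return Named numeric vector of per-cell scores with attribute
#'   `coverage`.
#' @export
mean_signature_score <- function(m, genes) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
  genes <- as.character(genes)
  present <- intersect(genes, m$gene_ids)
  if (!length(present)) stop("no signature gene present in the matrix")
  coverage <- length(present) / length(genes)
  if (coverage < 1) {
    warning(sprintf("%d/%d signature genes absent from the matrix; scoring on the rest",
                    length(genes) - length(present), length(genes)))
  }
  s <- Matrix::rowMeans(m$values[, present, drop = FALSE])
  s <- stats::setNames(as.numeric(s), m$cell_ids)
  attr(s, "coverage") <- coverage
  s
}

#' Control-bin-corrected module score
#'
#' Genes are binned by their across-cell average expression into `n_bins`
#' equal-frequency bins. For each signature gene, `n_ctrl` control genes are
#' sampled from its bin (excluding all signature genes; with replacement
#' when the bin is small), and the score is the mean expression of the
#' signature genes minus the mean over the pooled control draws. This
#' centres each signature against expression-matched background, so scores
#' near or below zero indicate no enrichment.
#'
#' @param m A lognorm [cell_matrix].
#' @param genes Signature genes (character vector or signature entry).
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes sampled per signature gene.
#' @param seed Optional integer making the control draw reproducible.
#' @param control_pool Optional explicit control gene multiset overriding
#'   the sampling (testing hook).
#' @return Named numeric per-cell score vector with attributes `coverage`
#'   and `control_pool`.
#' @export
module_score <- function(m, genes, n_bins = 24L, n_ctrl = 100L,
                         seed = NULL, control_pool = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.list(genes) && !is.null(genes$genes)) genes <- genes$genes
  genes <- as.character(genes)
  present <- intersect(genes, m$gene_ids)
  if (!length(present)) stop("no signature gene present in the matrix")
  coverage <- length(present) / length(genes)

  if (is.null(control_pool)) {
    avg <- Matrix::colMeans(m$values)
    if (length(unique(avg)) < n_bins) {
      stop("n_bins exceeds the number of distinct average-expression levels")
    }
    bin <- ceiling(n_bins * rank(avg, ties.method = "first") / length(avg))
    names(bin) <- m$gene_ids
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    control_pool <- unlist(lapply(present, function(g) {
      eligible <- m$gene_ids[bin == bin[[g]]]
      eligible <- setdiff(eligible, genes)
      if (!length(eligible)) {
        stop(sprintf("no eligible control genes in the bin of '%s'", g))
      }
      sample(eligible, n_ctrl, replace = length(eligible) < n_ctrl)
    }), use.names = FALSE)
  }
  sig_mean <- Matrix::rowMeans(m$values[, present, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(m$values[, control_pool, drop = FALSE])
  s <- stats::setNames(as.numeric(sig_mean - ctrl_mean), m$cell_ids)
  attr(s, "coverage") <- coverage
  attr(s, "control_pool") <- control_pool
  s
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Assign discrete cell-cycle phases from S and G2M scores
#'
#' Cells whose S and G2M module scores are both at or below zero default to
#' G1 (which here covers the whole non-proliferative G0/G1 side); otherwise
#' the larger score wins, with exact positive ties going to S (documented
#' tie-break).
#'
#' @param s_scores,g2m_scores Equal-length numeric score vectors.
#' @return An object of class `phase_call`: data frame with columns
#'   `phase` (factor G1/S/G2M), `s_score`, `g2m_score`.
#' @export
assign_cycle_phase <- function(s_scores, g2m_scores) {
  if (length(s_scores) != length(g2m_scores)) {
    stop("score vectors must have equal length")
  }
  if (anyNA(s_scores) || anyNA(g2m_scores)) stop("NaN/NA scores")
  phase <- ifelse(pmax(s_scores, g2m_scores) <= 0, "G1",
                  ifelse(s_scores >= g2m_scores, "S", "G2M"))
  out <- data.frame(phase = factor(phase, levels = c("G1", "S", "G2M")),
                    s_score = as.numeric(s_scores),
                    g2m_score = as.numeric(g2m_scores),
                    row.names = names(s_scores))
  class(out) <- c("phase_call", "data.frame")
  out
}

#' Correlate a per-cell score with one gene's expression
#'
#' Spearman rank correlation by default (Pearson optional), with its
#' two-sided p-value. Intended for checks such as relating a pathway
#' activity score to cyclin expression across cells.
#'
#' @param scores Per-cell numeric vector.
#' @param m A lognorm [cell_matrix].
#' @param gene Gene id present in the matrix.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `estimate`, `p.value`, `method`, `n`.
#' @export
correlate_signature_with_gene <- function(scores, m, gene,
                                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "cell_matrix"))
  if (!gene %in% m$gene_ids) stop(sprintf("gene '%s' not in matrix", gene))
  if (length(scores) != n_cells(m)) stop("scores must have one value per cell")
  if (length(scores) < 3L) stop("need at least 3 cells")
  expr <- as.numeric(m$values[, gene])
  if (stats::sd(scores) == 0 || stats::sd(expr) == 0) {
    stop("correlation undefined: constant input vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(scores, expr, method = method, exact = FALSE)
  )
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method, n = length(scores))
}

#' Per-cell score matrix over a set of phased signatures
#'
#' Applies [mean_signature_score()] per signature; columns are z-scored by
#' default (a constant column maps to zeros) before feeding the diffusion
#' map, so each phase signature contributes comparable geometry.
#'
#' @param m A lognorm [cell_matrix].
#' @param phased A [signature_set] (at least two signatures).
#' @param z_score Standardize columns.
#' @return Numeric matrix cells x signatures with attribute `coverage`.
#' @export
phase_signature_matrix <- function(m, phased, z_score = TRUE) {
  stopifnot(inherits(m, "cell_matrix"), inherits(phased, "signature_set"))
  if (length(phased) < 2L) stop("need at least two phased signatures")
  cov <- numeric(length(phased))
  cols <- lapply(seq_along(phased), function(i) {
    s <- mean_signature_score(m, phased[[i]]$genes)
    cov[i] <<- attr(s, "coverage")
    as.numeric(s)
  })
  sm <- do.call(cbind, cols)
  dimnames(sm) <- list(m$cell_ids, names(phased))
  if (z_score) {
    sm <- apply(sm, 2, function(v) {
      sdv <- stats::sd(v)
      if (sdv == 0) rep(0, length(v)) else (v - mean(v)) / sdv
    })
    dimnames(sm) <- list(m$cell_ids, names(phased))
  }
  attr(sm, "coverage") <- stats::setNames(cov, names(phased))
  sm
}
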