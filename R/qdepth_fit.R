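#' Fit the quiescence-depth trajectory model
#'
#' The full Q-depth procedure in one call:
#' \enumerate{
#'   \item score every cell against each phased cell-cycle signature
#'     ([phase_signature_matrix()], columns z-scored by default);
#'   \item call discrete phases from S and G2M control-bin module scores
#'     ([module_score()], [assign_cycle_phase()]) — cells with both scores
#'     at or below zero default to G1;
#'   \item embed the score matrix with a diffusion map and project the
#'     three leading components onto the 2D cycle plane;
#'   \item fit a principal curve through the G0/G1 "box" (by default the
#'     cells called G1, i.e. the non-proliferative side of the graph);
#'   \item orient the curve's arc-length positions (lambdas) so that the
#'     end enriched for the G0 signature is maximal depth, and rescale to
#'     `[0, 1]`.
#' }
#' Cells outside the box receive `qdepth = 0` and are flagged.
#'
#' @param m A lognorm [cell_matrix].
#' @param signatures A [signature_set] of phased cell-cycle signatures.
#'   The signatures whose phase tags equal `s_phase`, `g2m_phase` and
#'   `g0_phase` drive phase calling and orientation.
#' @param s_phase,g2m_phase,g0_phase,g1_phase Phase tags naming the S, G2M,
#'   G0 and G1 signatures within `signatures`.
#' @param z_score Standardize score-matrix columns before embedding.
#' @param k_components,knn,alpha Diffusion-map parameters
#'   (see [diffusion_map()]).
#' @param projection Cycle-plane mode, see [project_cycle_plane()].
#' @param box How the G0/G1 "box" — the region the principal curve is
#'   fitted through — is delineated. `"signature"` (default): cells whose
#'   strongest phased-signature enrichment (argmax over the z-scored score
#'   matrix columns) is the G0 or G1 signature. `"phase"`: cells called G1
#'   by [assign_cycle_phase()] (both module scores at or below zero), a
#'   stricter rule that excludes borderline cells. `"all"`: fit to every
#'   cell.
#' @param smooth_df,tol,max_iter Principal-curve parameters
#'   (see [fit_principal_curve()]).
#' @param n_bins,n_ctrl Module-score parameters.
#' @param seed Seed for the module-score control draw.
#' @param orient_frac Curve-end neighbourhood used for orientation.
#' @return An object of class `qdepth_fit` with per-cell scores, phase
#'   calls, embedding, plane, curve, lambdas and Q-depth.
#' @export
fit_qdepth <- function(m, signatures,
                       s_phase = "S", g2m_phase = "G2M", g0_phase = "G0",
                       g1_phase = "G1",
                       z_score = TRUE,
                       k_components = 3L, knn = 10L, alpha = 1,
                       projection = c("pca", "pair"),
                       box = c("signature", "phase", "all"),
                       smooth_df = NULL, tol = 1e-4, max_iter = 50L,
                       n_bins = 24L, n_ctrl = 100L, seed = NULL,
                       orient_frac = 0.1) {
  projection <- match.arg(projection)
  box <- match.arg(box)
  stopifnot(inherits(m, "cell_matrix"), inherits(signatures, "signature_set"))
  if (m$layer != "lognorm") stop("fit_qdepth expects the lognorm layer")

  phases <- vapply(signatures, function(s) {
    if (is.na(s$phase)) "" else s$phase
  }, character(1))
  find_sig <- function(tag, what) {
    i <- which(phases == tag)
    if (length(i) != 1L) {
      stop(sprintf("need exactly one signature tagged '%s' (%s)", tag, what))
    }
    signatures[[i]]$genes
  }
  s_genes <- find_sig(s_phase, "S-phase scoring")
  g2m_genes <- find_sig(g2m_phase, "G2M scoring")
  g0_genes <- find_sig(g0_phase, "orientation")

  scores <- phase_signature_matrix(m, signatures, z_score = z_score)
  s_ms <- module_score(m, s_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                       seed = if (is.null(seed)) NULL else seed)
  g2m_ms <- module_score(m, g2m_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  phase <- assign_cycle_phase(s_ms, g2m_ms)

  emb <- diffusion_map(scores, k_components = k_components, knn = knn,
                       alpha = alpha)
  plane <- project_cycle_plane(emb, mode = projection)

  in_box <- switch(box,
    signature = {
      g01 <- names(signatures)[phases %in% c(g0_phase, g1_phase)]
      amax <- colnames(scores)[max.col(scores, ties.method = "first")]
      amax %in% g01
    },
    phase = phase$phase == "G1",
    all = rep(TRUE, n_cells(m))
  )
  if (sum(in_box) < 10L) {
    stop(sprintf("only %d cells in the G0/G1 box; cannot fit a curve",
                 sum(in_box)))
  }
  curve <- fit_principal_curve(plane$xy[in_box, , drop = FALSE],
                               smooth_df = smooth_df, tol = tol,
                               max_iter = max_iter)
  g0_scores <- mean_signature_score(m, g0_genes)
  ori <- orient_qdepth(curve$lambda, g0_scores[in_box], frac = orient_frac)

  lambda <- rep(NA_real_, n_cells(m))
  lambda[in_box] <- curve$lambda
  qd <- rep(0, n_cells(m))
  qd[in_box] <- ori$qdepth

  structure(list(
    cell_ids = m$cell_ids,
    scores = scores,
    phase = phase,
    embedding = emb,
    plane = plane,
    curve = curve,
    in_box = in_box,
    lambda = lambda,
    qdepth = qd,
    g0_scores = as.numeric(g0_scores),
    orientation_flipped = ori$orientation_flipped,
    params = list(box = box, projection = projection, z_score = z_score,
                  k_components = k_components, knn = knn, alpha = alpha,
                  smooth_df = smooth_df, tol = tol, max_iter = max_iter,
                  n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
                  orient_frac = orient_frac)
  ), class = "qdepth_fit")
}

#' @export
print.qdepth_fit <- function(x, ...) {
  cat(sprintf("<qdepth_fit> %d cells, %d in the G0/G1 box (%.1f%%)\n",
              length(x$cell_ids), sum(x$in_box),
              100 * mean(x$in_box)))
  cat(sprintf("  diffusion eigenvalues: %s\n",
              paste(sprintf("%.4f", x$embedding$eigenvalues), collapse = ", ")))
  cat(sprintf("  principal curve: %d iteration(s), objective %.4g, orientation %s\n",
              x$curve$iterations, x$curve$total_sqdist,
              if (x$orientation_flipped) "flipped" else "unflipped"))
  invisible(x)
}

#' @export
summary.qdepth_fit <- function(object, ...) {
  tab <- table(object$phase$phase)
  cat("Quiescence-depth trajectory fit\n")
  cat(sprintf("  cells: %d; in G0/G1 box: %d (%.1f%%)\n",
              length(object$cell_ids), sum(object$in_box),
              100 * mean(object$in_box)))
  cat("  phase calls:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat("  Q-depth quartiles (box cells):",
      paste(sprintf("%.3f", stats::quantile(object$qdepth[object$in_box])),
            collapse = " "), "\n")
  invisible(object)
}

#' Per-cell results table of a `qdepth_fit`
#'
#' One row per cell: diffusion components, plane coordinates, lambda,
#' box membership, Q-depth and phase call. This is the table written as
#' `qdepth.tsv` by [run_pipeline()].
#'
#' @param x A `qdepth_fit`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.qdepth_fit <- function(x, ...) {
  data.frame(cell_id = x$cell_ids,
             x$embedding$coords,
             plane_x = x$plane$xy[, 1], plane_y = x$plane$xy[, 2],
             lambda = x$lambda, in_box = x$in_box, qdepth = x$qdepth,
             phase = x$phase$phase,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plot a fitted quiescence-depth trajectory
#'
#' Cycle-plane scatter coloured by Q-depth (grey for out-of-box cells) with
#' the principal curve overlaid.
#'
#' @param x A `qdepth_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qdepth_fit <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
  col <- rep("grey70", length(x$cell_ids))
  qb <- x$qdepth[x$in_box]
  col[x$in_box] <- pal[pmax(1, ceiling(99 * qb) + 1)]
  graphics::plot(x$plane$xy, col = col, pch = 16, cex = 0.5,
                 xlab = "plane x", ylab = "plane y", ...)
  graphics::lines(x$curve$curve_pts, lwd = 2)
  invisible(x)
}
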