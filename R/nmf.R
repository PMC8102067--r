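#' Weighted non-negative matrix factorization
#'
#' Minimizes the weighted Frobenius objective
#' `|| sqrt(M) * (X - W H) ||_F^2` by multiplicative (Lee–Seung style)
#' updates with per-entry weights `M`:
#' `W <- W * ((M*X) H') / ((M*(WH)) H')` and symmetrically for `H`. The
#' default weighting gives observed non-zero entries weight 1 and zeros the
#' smaller weight `w0`, so the factorization is driven by observed signal
#' while zeros (dropout candidates) only weakly pull the reconstruction
#' down. With `w0 = 1` the algorithm reduces exactly to standard
#' unweighted NMF. The objective is non-increasing across iterations (a
#' property of multiplicative updates, asserted on the recorded trace);
#' iteration stops when the relative objective change drops below `tol`.
#'
#' @param x A non-negative [cell_matrix] (lognorm by default use) or plain
#'   matrix, cells x genes.
#' @param rank Factorization rank `r`, `1 <= r < min(dim)`.
#' @param w0 Weight of zero entries in `[0, 1]`.
#' @param max_iter Iteration cap.
#' @param tol Relative objective-change stopping tolerance.
#' @param seed Seed for the uniform random non-negative initialization.
#' @param init Optional list `list(W =, H =)` overriding the random
#'   initialization (e.g. to share a start with a reference run).
#' @return An object of class `nmf_factors`: `W` (cells x rank), `H`
#'   (rank x genes), `rank`, `w0`, `objective` (per-iteration trace),
#'   `iterations`, `converged`.
#' @export
weighted_nmf <- function(x, rank, w0 = 0.1, max_iter = 500L, tol = 1e-5,
                         seed = NULL, init = NULL) {
  X <- if (inherits(x, "cell_matrix")) as_dense(x) else as.matrix(x)
  if (min(X) < 0) stop("negative entries: NMF requires a non-negative matrix")
  n <- nrow(X); p <- ncol(X)
  if (rank < 1L || rank >= min(n, p)) stop("rank out of range [1, min(dim))")
  if (w0 < 0 || w0 > 1) stop("w0 must lie in [0, 1]")
  M <- matrix(1, n, p)
  M[X == 0] <- w0
  eps <- 1e-12

  if (is.null(init)) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    W <- matrix(stats::runif(n * rank), n, rank)
    H <- matrix(stats::runif(rank * p), rank, p)
  } else {
    W <- init$W; H <- init$H
    stopifnot(nrow(W) == n, ncol(W) == rank, nrow(H) == rank, ncol(H) == p)
  }

  MX <- M * X
  obj <- function(W, H) sum(M * (X - W %*% H)^2)
  trace <- obj(W, H)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    W <- W * (MX %*% t(H)) / ((M * WH) %*% t(H) + eps)
    WH <- W %*% H
    H <- H * (t(W) %*% MX) / (t(W) %*% (M * WH) + eps)
    o <- obj(W, H)
    trace <- c(trace, o)
    iterations <- it
    prev <- trace[length(trace) - 1L]
    if (prev - o < tol * max(prev, eps)) { converged <- TRUE; break }
  }
  structure(list(W = W, H = H, rank = as.integer(rank), w0 = w0,
                 objective = trace, iterations = iterations,
                 converged = converged),
            class = "nmf_factors")
}

#' @export
print.nmf_factors <- function(x, ...) {
  cat(sprintf("<nmf_factors> rank %d, w0 = %g, %d iteration(s), objective %.6g%s\n",
              x$rank, x$w0, x$iterations, x$objective[length(x$objective)],
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Reconstruct a completed matrix from NMF factors
#'
#' Under policy `zeros_only` (the default), observed non-zero entries are
#' kept verbatim and only zeros — the dropout candidates — are replaced by
#' the low-rank reconstruction `W H`. Policy `full` replaces the whole
#' matrix by `W H`.
#'
#' @param x The factorized [cell_matrix] (or matrix).
#' @param f An `nmf_factors` from [weighted_nmf()].
#' @param policy `"zeros_only"` or `"full"`.
#' @return A [cell_matrix] with layer `imputed` (or a plain matrix when
#'   `x` is one).
#' @export
impute_matrix <- function(x, f, policy = c("zeros_only", "full")) {
  policy <- match.arg(policy)
  stopifnot(inherits(f, "nmf_factors"))
  X <- if (inherits(x, "cell_matrix")) as_dense(x) else as.matrix(x)
  if (!all(dim(X) == c(nrow(f$W), ncol(f$H)))) {
    stop("factor dimensions do not match the matrix")
  }
  R <- f$W %*% f$H
  out <- if (policy == "zeros_only") {
    Y <- X
    Y[X == 0] <- R[X == 0]
    Y
  } else {
    R
  }
  if (inherits(x, "cell_matrix")) {
    dimnames(out) <- list(x$cell_ids, x$gene_ids)
    set_layer(x, out, "imputed")
  } else {
    out
  }
}

#' Evaluate imputation on artificially masked entries
#'
#' Compares the imputed matrix against the truth on the masked entries,
#' alongside the zero-fill baseline (leaving dropouts at zero).
#'
#' @param x_true Ground-truth matrix.
#' @param x_dropout The observed (masked) matrix.
#' @param x_imputed The imputed matrix.
#' @param mask Logical matrix marking artificially zeroed entries.
#' @return Data frame with rows `imputed` and `zero_fill` and columns
#'   `rmse`, `spearman`.
#' @export
evaluate_imputation <- function(x_true, x_dropout, x_imputed, mask) {
  g <- function(m) if (inherits(m, "cell_matrix")) as_dense(m) else as.matrix(m)
  x_true <- g(x_true); x_dropout <- g(x_dropout); x_imputed <- g(x_imputed)
  mask <- as.matrix(mask)
  if (!any(mask)) stop("empty mask")
  truth <- x_true[mask]
  imp <- x_imputed[mask]
  zf <- x_dropout[mask]
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  sp <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b, method = "spearman")
  }
  data.frame(method = c("imputed", "zero_fill"),
             rmse = c(rmse(imp, truth), rmse(zf, truth)),
             spearman = c(sp(imp, truth), sp(zf, truth)),
             stringsAsFactors = FALSE)
}
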