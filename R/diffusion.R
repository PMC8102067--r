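#' Diffusion-map embedding of a score matrix
#'
#' Builds a Gaussian affinity kernel with locally adaptive bandwidth (the
#' distance to each point's `knn`-th neighbour), applies density
#' normalization with exponent `alpha` (the anisotropic correction that, at
#' `alpha = 1`, removes sampling-density effects), row-normalizes to a
#' Markov transition matrix, and returns the leading non-trivial eigenpairs.
#' Component `k` is the eigenvector `psi_k` scaled by its eigenvalue. The
#' trivial stationary eigenpair (eigenvalue 1, constant eigenvector) is
#' removed. The embedding is fully deterministic: each component's sign is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param s Numeric matrix, cells x features (typically the phased-signature
#'   score matrix from [phase_signature_matrix()]).
#' @param k_components Number of diffusion components to return.
#' @param knn Neighbour index defining the adaptive kernel bandwidth.
#' @param alpha Density-normalization exponent in `[0, 1]`.
#' @return An object of class `diffusion_embedding`: list with `coords`
#'   (cells x `k_components`, columns `DC1..`), `eigenvalues`, and the
#'   kernel parameters.
#' @export
diffusion_map <- function(s, k_components = 3L, knn = 10L, alpha = 1) {
  s <- as.matrix(s)
  if (anyNA(s)) stop("score matrix contains NA/NaN")
  n <- nrow(s)
  if (n < k_components + 2L) stop("need at least k_components + 2 cells")
  if (n < knn + 1L) stop("fewer cells than knn + 1")
  if (all(apply(s, 2, stats::sd) == 0)) stop("zero-variance score matrix")

  d <- as.matrix(stats::dist(s))
  # adaptive bandwidth: distance to the knn-th neighbour (self excluded)
  sigma <- apply(d, 1, function(r) sort(r)[knn + 1L])
  sigma <- pmax(sigma, 1e-12)
  K <- exp(-d^2 / (2 * outer(sigma, sigma)))
  if (alpha > 0) {
    qd <- rowSums(K)
    K <- K / outer(qd^alpha, qd^alpha)
  }
  D <- rowSums(K)
  # symmetric conjugate of the Markov matrix: same spectrum, real eigenpairs
  A <- K / sqrt(outer(D, D))
  eg <- eigen(A, symmetric = TRUE)
  lam <- eg$values
  psi <- eg$vectors / sqrt(D)       # right eigenvectors of P = D^-1 K
  # drop the trivial stationary eigenpair (lambda = 1, constant psi)
  keep <- 2:(k_components + 1L)
  coords <- vapply(keep, function(j) {
    v <- psi[, j] * lam[j]
    if (v[which.max(abs(v))] < 0) v <- -v
    v
  }, numeric(n))
  colnames(coords) <- paste0("DC", seq_len(k_components))
  rownames(coords) <- rownames(s)
  structure(list(coords = coords,
                 eigenvalues = lam[keep],
                 trivial_eigenvalue = lam[1],
                 params = list(k_components = k_components, knn = knn,
                               alpha = alpha)),
            class = "diffusion_embedding")
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat(sprintf("<diffusion_embedding> %d cells, %d components (knn = %d, alpha = %g)\n",
              nrow(x$coords), ncol(x$coords), x$params$knn, x$params$alpha))
  cat("  eigenvalues:", paste(sprintf("%.4f", x$eigenvalues), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project the three leading diffusion components onto the cycle plane
#'
#' The default mode rotates the (DC1, DC2, DC3) cloud onto its two leading
#' principal axes and reports the 3 x 2 combination matrix, making the
#' component combination explicit and reproducible. The alternative
#' `"pair"` mode instead selects the raw component pair whose 2D cloud is
#' most annular (largest `mean(radius)^2 / var(radius)` about its centroid),
#' with ties broken by lowest component indices.
#'
#' @param e A [diffusion_map()] embedding with at least 3 components.
#' @param mode `"pca"` (default) or `"pair"`.
#' @return An object of class `cycle_plane`: list with `xy` (cells x 2),
#'   `combination` (3 x 2 loading matrix), `mode`, and for `"pair"` mode
#'   the chosen pair.
#' @export
project_cycle_plane <- function(e, mode = c("pca", "pair")) {
  mode <- match.arg(mode)
  stopifnot(inherits(e, "diffusion_embedding"))
  if (ncol(e$coords) < 3L) stop("need at least 3 diffusion components")
  X <- e$coords[, 1:3, drop = FALSE]
  if (mode == "pca") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    if (sum(pc$sdev > 1e-12) < 2L) stop("component cloud has rank < 2")
    rot <- pc$rotation[, 1:2, drop = FALSE]
    # deterministic sign: largest-magnitude loading positive per column;
    # ties on sdev are already resolved by prcomp's fixed ordering
    for (j in 1:2) {
      if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
    }
    xy <- sweep(X, 2, colMeans(X)) %*% rot
    pair <- NULL
  } else {
    pairs <- utils::combn(3L, 2L)
    score <- apply(pairs, 2, function(p) {
      xy <- sweep(X[, p, drop = FALSE], 2,
                  colMeans(X[, p, drop = FALSE]))
      r <- sqrt(rowSums(xy^2))
      v <- stats::var(r)
      if (v < 1e-300) Inf else mean(r)^2 / v
    })
    best <- which.max(score)            # ties: first (lowest indices) wins
    pair <- pairs[, best]
    rot <- matrix(0, 3, 2)
    rot[pair[1], 1] <- 1
    rot[pair[2], 2] <- 1
    xy <- X[, pair, drop = FALSE]
  }
  colnames(xy) <- c("plane_x", "plane_y")
  rownames(rot) <- colnames(X)
  colnames(rot) <- c("plane_x", "plane_y")
  structure(list(xy = xy, combination = rot, mode = mode, pair = pair),
            class = "cycle_plane")
}
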