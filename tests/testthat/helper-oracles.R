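# Independent reference implementations used to cross-check the package.
# These are deliberately written as plain, step-by-step code, sharing no
# internals with the implementations they verify.

# brute-force QC: evaluate the three strict rules cell by cell
oracle_qc_keep <- function(counts, min_features, max_features, max_mito,
                           mito_prefix = "mt-") {
  mito <- grepl(paste0("^", mito_prefix), colnames(counts), ignore.case = TRUE)
  vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    nf <- sum(x > 0)
    mf <- if (sum(x) > 0) sum(x[mito]) / sum(x) else 0
    !(nf < min_features || nf > max_features || mf > max_mito)
  }, logical(1))
}

# step-by-step module score with the same documented sampling procedure
oracle_module_score <- function(X, genes, n_bins, n_ctrl, seed) {
  avg <- colMeans(X)
  bin <- ceiling(n_bins * rank(avg, ties.method = "first") / length(avg))
  names(bin) <- colnames(X)
  present <- intersect(genes, colnames(X))
  set.seed(seed)
  pool <- c()
  for (g in present) {
    eligible <- setdiff(names(bin)[bin == bin[[g]]], genes)
    pool <- c(pool, sample(eligible, n_ctrl, replace = length(eligible) < n_ctrl))
  }
  sig <- rowMeans(X[, present, drop = FALSE])
  ctrl <- rowMeans(X[, pool, drop = FALSE])
  sig - ctrl
}

# dense diffusion-map oracle: explicit kernel, explicit Markov matrix,
# general (non-symmetric) eigendecomposition
oracle_diffusion <- function(S, k, knn, alpha) {
  n <- nrow(S)
  d <- as.matrix(dist(S))
  sigma <- apply(d, 1, function(r) sort(r)[knn + 1])
  sigma <- pmax(sigma, 1e-12)
  K <- exp(-d^2 / (2 * outer(sigma, sigma)))
  if (alpha > 0) {
    q <- rowSums(K)
    K <- K / outer(q^alpha, q^alpha)
  }
  P <- K / rowSums(K)
  eg <- eigen(P)
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- Re(eg$values)[ord]
  vecs <- Re(eg$vectors)[, ord, drop = FALSE]
  list(eigenvalues = vals[2:(k + 1)],
       vectors = vecs[, 2:(k + 1), drop = FALSE])
}

# plain unweighted Lee-Seung NMF with the same epsilon guard, for the
# w0 = 1 reduction check (runs from a supplied initialization)
oracle_nmf_trace <- function(X, W, H, n_iter) {
  eps <- 1e-12
  trace <- sum((X - W %*% H)^2)
  for (it in seq_len(n_iter)) {
    WH <- W %*% H
    W <- W * (X %*% t(H)) / (WH %*% t(H) + eps)
    WH <- W %*% H
    H <- H * (t(W) %*% X) / (t(W) %*% WH + eps)
    trace <- c(trace, sum((X - W %*% H)^2))
  }
  trace
}

# exhaustive two-sided rank-sum p-value over all group assignments
oracle_ranksum_exact <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  W_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(r) + 1) / 2
  combos <- utils::combn(length(r), n1)
  W <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(W - mu) >= abs(W_obs - mu) - 1e-9)
}

# small lognormal "bulk" universe with planted treated-up genes
simulate_bulk_universe <- function(n_null = 47, n_planted = 13, fc = 4,
                                   n_per_group = 5, sdlog = 0.15) {
  n_genes <- n_null + n_planted
  genes <- sprintf("u%03d", seq_len(n_genes))
  planted <- genes[seq_len(n_planted)]
  base_mean <- rep(1, n_genes)
  labels <- rep(c("control", "treated"), each = n_per_group)
  X <- t(vapply(seq_len(2 * n_per_group), function(i) {
    mu <- base_mean
    if (labels[i] == "treated") mu[seq_len(n_planted)] <- mu[seq_len(n_planted)] * fc
    mu * exp(rnorm(n_genes, sd = sdlog))
  }, numeric(n_genes)))
  colnames(X) <- genes
  rownames(X) <- sprintf("s%02d", seq_len(nrow(X)))
  list(X = X, labels = labels, planted = planted)
}

# small lognorm cell_matrix fixture built directly from dense values
toy_cell_matrix <- function(values, layer = "lognorm") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("c%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("g%02d", seq_len(ncol(values)))
  }
  cell_matrix(values, layer = layer)
}

# default small simulation shared across tests (kept quick)
small_two_condition <- function(seed = 42, n_per = 200, n_genes = 400,
                                frac_g0 = 0.75) {
  cfg <- sim_config(n_cells = 2 * n_per, n_genes = n_genes, frac_g0 = frac_g0,
                    conditions = default_conditions(n_per), seed = seed)
  generate_two_condition(cfg)
}
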