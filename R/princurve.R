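#' Fit a principal curve by projection–smoothing iteration
#'
#' Hastie–Stuetzle style alternation. The curve is initialized as the first
#' principal-component segment, so after the initial projection the lambdas
#' equal the first-PC arc-length positions. Each iteration then (i) smooths
#' every coordinate against the current lambdas (cubic smoothing spline;
#' generalized cross-validation unless `smooth_df` is fixed), (ii)
#' re-projects all points orthogonally onto the resulting polyline, giving
#' new arc-length lambdas and the total squared projection distance. An
#' iteration is accepted only if it does not increase the objective, so the
#' recorded objective trace is non-increasing by construction; the loop
#' stops when the relative objective change falls below `tol` or at
#' `max_iter` (the latter flagged as non-converged).
#'
#' @param coords Numeric matrix, points x 2.
#' @param smooth_df Fixed spline degrees of freedom (`NULL` = GCV).
#' @param tol Relative objective-change tolerance.
#' @param max_iter Maximum projection–smoothing iterations.
#' @param grid_n Curve evaluation points (polyline resolution).
#' @return An object of class `principal_curve_fit`: list with `curve_pts`
#'   (ordered curve points), `lambda` (per-point arc length), `objective`
#'   (total squared projection distance trace, one entry per accepted
#'   state), `iterations`, `converged`, `total_sqdist`.
#' @export
fit_principal_curve <- function(coords, smooth_df = NULL, tol = 1e-4,
                                max_iter = 50L, grid_n = 200L) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 10L) stop("need at least 10 points")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  n <- nrow(coords)

  # initialization: first principal-component segment
  ctr <- colMeans(coords)
  pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  v1 <- pc$rotation[, 1]
  proj <- as.numeric(sweep(coords, 2, ctr) %*% v1)
  grid <- seq(min(proj), max(proj), length.out = min(grid_n, n))
  curve_pts <- sweep(outer(grid, v1), 2, ctr, `+`)
  pr <- project_polyline(coords, curve_pts)
  lambda <- pr$lambda
  objective <- sum(pr$sqdist)
  trace <- objective

  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    if (objective < 1e-18) { converged <- TRUE; break }
    new_curve <- smooth_curve(coords, lambda, smooth_df, grid_n)
    if (is.null(new_curve)) break       # smoother degenerate; keep current fit
    pr_new <- project_polyline(coords, new_curve)
    obj_new <- sum(pr_new$sqdist)
    if (obj_new > objective) break      # accept only non-increasing steps
    rel <- (objective - obj_new) / max(objective, 1e-300)
    curve_pts <- new_curve
    lambda <- pr_new$lambda
    objective <- obj_new
    trace <- c(trace, objective)
    iterations <- it
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged && iterations < max_iter) converged <- TRUE  # stopped by acceptance rule
  structure(list(curve_pts = curve_pts, lambda = lambda,
                 objective = trace, iterations = iterations,
                 converged = converged, total_sqdist = objective),
            class = "principal_curve_fit")
}

## Smooth each coordinate against lambda, evaluated on a uniform lambda grid.
smooth_curve <- function(coords, lambda, smooth_df, grid_n) {
  n_unique <- length(unique(lambda))
  if (n_unique < 4L) return(NULL)
  grid <- seq(min(lambda), max(lambda), length.out = min(grid_n, nrow(coords)))
  fitted <- try(vapply(seq_len(ncol(coords)), function(j) {
    sm <- if (is.null(smooth_df)) {
      stats::smooth.spline(lambda, coords[, j], cv = FALSE)
    } else {
      stats::smooth.spline(lambda, coords[, j],
                           df = min(smooth_df, n_unique - 1L))
    }
    stats::predict(sm, x = grid)$y
  }, numeric(length(grid))), silent = TRUE)
  if (inherits(fitted, "try-error")) return(NULL)
  fitted
}

## Orthogonal projection of points onto an ordered polyline.
## Returns per-point arc-length position and squared distance.
project_polyline <- function(pts, poly) {
  n <- nrow(pts)
  m <- nrow(poly)
  seg <- diff(poly)                       # (m-1) x d segment vectors
  seglen2 <- rowSums(seg^2)
  seglen <- sqrt(seglen2)
  cum <- c(0, cumsum(seglen))
  best_sq <- rep(Inf, n)
  best_lambda <- numeric(n)
  for (k in seq_len(m - 1L)) {
    if (seglen2[k] < 1e-300) next
    dx <- sweep(pts, 2, poly[k, ])
    t <- pmin(1, pmax(0, (dx %*% seg[k, ]) / seglen2[k]))
    px <- outer(as.numeric(t), seg[k, ])
    sq <- rowSums((dx - px)^2)
    upd <- sq < best_sq
    if (any(upd)) {
      best_sq[upd] <- sq[upd]
      best_lambda[upd] <- cum[k] + t[upd] * seglen[k]
    }
  }
  list(lambda = best_lambda, sqdist = best_sq)
}

#' @export
print.principal_curve_fit <- function(x, ...) {
  cat(sprintf("<principal_curve_fit> %d points, %d iteration(s), objective %.4g%s\n",
              length(x$lambda), x$iterations, x$total_sqdist,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Orient lambdas into a quiescence-depth axis
#'
#' Compares the mean G0-signature score in the two curve-end neighbourhoods
#' (lambda below the `frac` quantile vs. above the `1 - frac` quantile); the
#' end with the higher mean G0 score becomes maximal depth. Lambdas are then
#' rescaled (flipped if needed) to `[0, 1]`.
#'
#' @param lambda Per-cell arc-length positions from
#'   [fit_principal_curve()].
#' @param g0_scores G0-signature scores for the same cells.
#' @param frac End-neighbourhood quantile (default top/bottom decile).
#' @return List with `qdepth` (in `[0, 1]`) and `orientation_flipped`.
#' @export
orient_qdepth <- function(lambda, g0_scores, frac = 0.1) {
  if (length(lambda) != length(g0_scores)) {
    stop("lambda and g0_scores must have equal length")
  }
  lo <- lambda <= stats::quantile(lambda, frac)
  hi <- lambda >= stats::quantile(lambda, 1 - frac)
  m_lo <- mean(g0_scores[lo])
  m_hi <- mean(g0_scores[hi])
  if (isTRUE(all.equal(m_lo, m_hi))) {
    stop("ambiguous orientation: both curve ends have equal mean G0 score; enlarge frac")
  }
  flipped <- m_lo > m_hi
  L <- max(lambda) - min(lambda)
  if (L <= 0) stop("degenerate lambda range")
  q <- (lambda - min(lambda)) / L
  if (flipped) q <- 1 - q
  list(qdepth = q, orientation_flipped = flipped)
}

#' Compare quiescence depth between two conditions
#'
#' Wilcoxon rank-sum test: exact enumeration over all rank assignments
#' (midranks, so tied data are handled) when both groups have at most 10
#' observations, otherwise the normal approximation with tie correction.
#' The shift statistic is `median(treated) - median(control)`, so a
#' positive shift means the treated condition sits deeper in quiescence.
#'
#' @param qdepth Per-cell depth values (or any per-cell statistic).
#' @param labels Two-level condition labels aligned with `qdepth`.
#' @param treated Which label is the treated group (default: the second
#'   level).
#' @return List with `shift`, `p.value`, `method`, group medians and sizes.
#' @export
compare_qdepth <- function(qdepth, labels, treated = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (is.null(treated)) treated <- levels(labels)[2]
  if (!treated %in% levels(labels)) stop("'treated' is not a label level")
  control <- setdiff(levels(labels), treated)
  x <- qdepth[labels == treated]
  y <- qdepth[labels == control]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 cells")
  if (length(x) <= 10L && length(y) <= 10L) {
    p <- exact_ranksum_p(x, y)
    method <- "exact rank-sum enumeration"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    method <- "Wilcoxon rank-sum, normal approximation"
  }
  list(shift = stats::median(x) - stats::median(y),
       p.value = p, method = method,
       median_treated = stats::median(x), median_control = stats::median(y),
       n_treated = length(x), n_control = length(y))
}

## Two-sided exact rank-sum p-value by enumeration of all
## choose(n1+n2, n1) group assignments of the pooled midranks.
exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  W_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  W_all <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}
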