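test_that("diffusion map matches a dense eigendecomposition oracle", {
  set.seed(12)
  for (n in c(30, 50)) {
    S <- cbind(cos(seq(0, 2 * pi, length.out = n)),
               sin(seq(0, 2 * pi, length.out = n))) + matrix(rnorm(2 * n, sd = 0.1), n, 2)
    emb <- diffusion_map(S, k_components = 3, knn = 5, alpha = 1)
    orc <- oracle_diffusion(S, k = 3, knn = 5, alpha = 1)
    expect_equal(emb$eigenvalues, orc$eigenvalues, tolerance = 1e-8)
    for (j in 1:3) {
      a <- emb$coords[, j]
      b <- orc$vectors[, j]
      # same eigenvector up to sign and scaling
      a <- a / sqrt(sum(a^2))
      b <- b / sqrt(sum(b^2))
      if (sum(a * b) < 0) b <- -b
      expect_equal(a, b, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("diffusion map removes the trivial Markov eigenpair", {
  set.seed(4)
  S <- matrix(rnorm(40 * 3), 40, 3)
  emb <- diffusion_map(S, k_components = 3, knn = 6)
  expect_equal(emb$trivial_eigenvalue, 1, tolerance = 1e-10)
  expect_true(all(abs(emb$eigenvalues) <= 1 + 1e-10))
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
})

test_that("duplicated cells share embedding coordinates", {
  set.seed(6)
  S <- matrix(rnorm(25 * 3), 25, 3)
  S <- rbind(S, S[3, ], S[17, ])
  emb <- diffusion_map(S, k_components = 3, knn = 5)
  expect_equal(emb$coords[26, ], emb$coords[3, ], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(emb$coords[27, ], emb$coords[17, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("diffusion map rejects degenerate inputs", {
  S <- matrix(rnorm(30), 10, 3)
  expect_error(diffusion_map(S, knn = 10), "knn")
  expect_error(diffusion_map(matrix(1, 20, 3)), "zero-variance")
  expect_error(diffusion_map(matrix(c(NA, rnorm(59)), 20, 3)), "NA")
})

make_embedding <- function(coords3) {
  structure(list(coords = `colnames<-`(coords3, c("DC1", "DC2", "DC3")),
                 eigenvalues = c(0.9, 0.8, 0.7),
                 params = list(knn = 10, alpha = 1)),
            class = "diffusion_embedding")
}

test_that("cycle-plane projection recovers planar and tilted clouds", {
  set.seed(20)
  th <- runif(300, 0, 2 * pi)
  flat <- cbind(cos(th), sin(th), rnorm(300, sd = 1e-4))
  pl <- project_cycle_plane(make_embedding(flat))
  expect_lt(max(abs(pl$combination[3, ])), 0.01)  # third loading ~ 0

  # circle tilted by a known rotation: recovered plane within 5 degrees
  ang <- 0.6
  R <- rbind(c(1, 0, 0),
             c(0, cos(ang), -sin(ang)),
             c(0, sin(ang), cos(ang)))
  tilted <- cbind(cos(th), sin(th), rnorm(300, sd = 0.02)) %*% t(R)
  pt <- project_cycle_plane(make_embedding(tilted))
  true_normal <- R[, 3]
  fitted_normal <- c(pt$combination[2, 1] * pt$combination[3, 2] -
                       pt$combination[3, 1] * pt$combination[2, 2],
                     pt$combination[3, 1] * pt$combination[1, 2] -
                       pt$combination[1, 1] * pt$combination[3, 2],
                     pt$combination[1, 1] * pt$combination[2, 2] -
                       pt$combination[2, 1] * pt$combination[1, 2])
  cosang <- abs(sum(true_normal * fitted_normal)) /
    sqrt(sum(fitted_normal^2))
  expect_gt(cosang, cos(5 * pi / 180))

  # pair mode picks the annular raw pair deterministically
  pp <- project_cycle_plane(make_embedding(flat), mode = "pair")
  expect_equal(pp$pair, c(1L, 2L))
  pp2 <- project_cycle_plane(make_embedding(flat), mode = "pair")
  expect_identical(pp$xy, pp2$xy)
})

test_that("a straight segment is a principal-curve fixed point", {
  set.seed(2)
  t <- sort(runif(40, -2, 2))
  line <- cbind(1 + 2 * t, -1 + 0.5 * t)
  fit <- fit_principal_curve(line)
  expect_lt(fit$total_sqdist, 1e-9)
  # lambdas are arc lengths along the segment
  want <- (t - min(t)) * sqrt(2^2 + 0.5^2)
  expect_equal(fit$lambda, want, tolerance = 1e-6)
})

test_that("initialization projects onto the first principal component", {
  set.seed(8)
  pts <- matrix(rnorm(60), 30, 2) %*% matrix(c(2, 0.5, 0.3, 1), 2, 2)
  fit <- fit_principal_curve(pts, max_iter = 0)
  pc <- prcomp(pts)
  proj <- pc$x[, 1]
  expect_equal(fit$lambda, proj - min(proj), tolerance = 1e-9)
})

test_that("principal-curve objective is non-increasing on random inputs", {
  set.seed(44)
  for (rep in 1:20) {
    pts <- matrix(rnorm(2 * sample(20:80, 1)), ncol = 2)
    fit <- fit_principal_curve(pts)
    expect_true(all(diff(fit$objective) <= 1e-12))
  }
})

test_that("a noisy quarter circle is recovered in rank order", {
  set.seed(33)
  n <- 500
  a <- sort(runif(n, 0, pi / 2))
  pts <- cbind(cos(a), sin(a)) + matrix(rnorm(2 * n, sd = 0.05), n, 2)
  fit <- fit_principal_curve(pts)
  expect_gt(cor(fit$lambda, a, method = "spearman"), 0.95)
})

test_that("orientation follows the G0-enriched curve end", {
  lam <- seq(0, 5, length.out = 100)
  up <- orient_qdepth(lam, g0_scores = lam + rnorm(100, sd = 0.01))
  expect_false(up$orientation_flipped)
  expect_equal(rank(up$qdepth), rank(lam))
  expect_true(all(up$qdepth >= 0 & up$qdepth <= 1))

  down <- orient_qdepth(lam, g0_scores = -lam)
  expect_true(down$orientation_flipped)
  expect_equal(rank(down$qdepth), rank(-lam))

  expect_error(orient_qdepth(lam, rep(1, 100)), "ambiguous")
})

test_that("condition comparison uses exact enumeration for small groups", {
  same <- compare_qdepth(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$shift, 0)
  expect_equal(same$p.value, 1)

  sep <- compare_qdepth(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                        treated = "b")
  expect_equal(sep$p.value, 0.1)   # 2/20 assignments as extreme
  expect_equal(sep$p.value, oracle_ranksum_exact(c(4, 5, 6), c(1, 2, 3)))
  expect_gt(sep$shift, 0)

  big <- compare_qdepth(rnorm(50), rep(c("a", "b"), each = 25))
  expect_match(big$method, "normal")
  expect_error(compare_qdepth(1:5, c("a", "a", "a", "a", "b")), ">= 2")
})

test_that("the fitted trajectory is invariant to cell order", {
  gen <- small_two_condition(seed = 3, n_per = 150, n_genes = 400)
  mn <- normalize_log(gen$matrix)
  sigs <- truth_signatures(gen$truth)
  fit <- fit_qdepth(mn, sigs, seed = 5)
  set.seed(99)
  perm <- sample(n_cells(mn))
  fitp <- fit_qdepth(mn[perm, ], sigs, seed = 5)
  expect_equal(fitp$qdepth, fit$qdepth[perm], tolerance = 1e-6)
  expect_equal(fitp$in_box, fit$in_box[perm])
  expect_equal(fitp$orientation_flipped, fit$orientation_flipped)
})

test_that("fit_qdepth recovers planted quiescence structure end to end", {
  gen <- small_two_condition(seed = 21, n_per = 300, n_genes = 500)
  mn <- normalize_log(gen$matrix)
  truth <- gen$truth$cells
  fit <- fit_qdepth(mn, truth_signatures(gen$truth), seed = 7)
  g0 <- truth$phase == "G0" & fit$in_box
  expect_gt(cor(truth$q[g0], fit$qdepth[g0], method = "spearman"), 0.75)
  # cyclers sit outside the box / at shallow depth
  cyc <- truth$phase %in% c("S", "G2M")
  expect_lt(mean(fit$in_box[cyc]), 0.1)
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), n_cells(mn))
  expect_true(all(tab$qdepth >= 0 & tab$qdepth <= 1))
})
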