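test_that("mean signature score reduces to the obvious cases", {
  set.seed(3)
  vals <- matrix(runif(12), 3, 4)
  m <- toy_cell_matrix(vals)
  # single-gene signature is that gene's expression
  expect_equal(as.numeric(mean_signature_score(m, "g02")),
               unname(vals[, 2]), tolerance = 1e-15)
  # constant matrix scores the constant
  mc <- toy_cell_matrix(matrix(2.5, 3, 4))
  expect_equal(as.numeric(mean_signature_score(mc, c("g01", "g03"))),
               rep(2.5, 3))
  # two-gene signature: row means of those columns
  expect_equal(as.numeric(mean_signature_score(m, c("g01", "g04"))),
               unname(rowMeans(vals[, c(1, 4)])), tolerance = 1e-15)
})

test_that("absent signature genes shrink the denominator and are reported", {
  m <- toy_cell_matrix(matrix(1:6 / 10, 2, 3))
  expect_warning(s <- mean_signature_score(m, c("g01", "nope")), "absent")
  expect_equal(attr(s, "coverage"), 0.5)
  expect_equal(as.numeric(s), unname(as_dense(m)[, 1]))
  expect_error(mean_signature_score(m, c("zz1", "zz2")), "no signature gene")
})

test_that("mean score of a union of disjoint equal-sized signatures averages", {
  set.seed(9)
  m <- toy_cell_matrix(matrix(runif(40), 4, 10))
  a <- mean_signature_score(m, c("g01", "g02"))
  b <- mean_signature_score(m, c("g05", "g09"))
  u <- mean_signature_score(m, c("g01", "g02", "g05", "g09"))
  expect_equal(as.numeric(u), as.numeric((a + b) / 2), tolerance = 1e-12)
})

test_that("module score matches a step-by-step reimplementation", {
  set.seed(77)
  vals <- matrix(rexp(30 * 50), 30, 50)
  m <- toy_cell_matrix(vals)
  sig <- c("g03", "g17", "g25", "g31", "g48")
  got <- module_score(m, sig, n_bins = 8, n_ctrl = 20, seed = 123)
  want <- oracle_module_score(as_dense(m), sig, n_bins = 8, n_ctrl = 20,
                              seed = 123)
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
})

test_that("module score self-subtracts to zero with a forced control pool", {
  m <- toy_cell_matrix(matrix(runif(60), 6, 10))
  sig <- c("g02", "g07")
  s <- module_score(m, sig, control_pool = sig)
  expect_equal(as.numeric(s), rep(0, 6), tolerance = 1e-15)
})

test_that("module score is invariant to additive constants", {
  set.seed(5)
  vals <- matrix(rexp(20 * 40), 20, 40)
  m1 <- toy_cell_matrix(vals)
  m2 <- toy_cell_matrix(vals + 3)
  sig <- c("g01", "g10", "g39")
  s1 <- module_score(m1, sig, n_bins = 6, n_ctrl = 15, seed = 42)
  s2 <- module_score(m2, sig, n_bins = 6, n_ctrl = 15, seed = 42)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("scores are invariant to cell order", {
  set.seed(31)
  vals <- matrix(rexp(25 * 40), 25, 40)
  m <- toy_cell_matrix(vals)
  perm <- sample(25)
  mp <- m[perm, ]
  sig <- c("g05", "g11", "g33")
  s <- module_score(m, sig, n_bins = 5, n_ctrl = 10, seed = 2)
  sp <- module_score(mp, sig, n_bins = 5, n_ctrl = 10, seed = 2)
  expect_equal(as.numeric(sp), as.numeric(s[perm]), tolerance = 1e-12)
  expect_equal(as.numeric(mean_signature_score(mp, sig)),
               as.numeric(mean_signature_score(m, sig)[perm]), tolerance = 1e-15)
})

test_that("module score needs enough distinct expression levels for binning", {
  m <- toy_cell_matrix(matrix(1, 5, 6))
  expect_error(module_score(m, "g01", n_bins = 24), "distinct")
})

test_that("phase assignment follows the low-scores-default-to-G1 rule", {
  # both scores negative: quiescent side, defaults to G1
  expect_equal(as.character(assign_cycle_phase(-0.2, -0.5)$phase), "G1")
  # zero counts as low
  expect_equal(as.character(assign_cycle_phase(0, -0.1)$phase), "G1")
  expect_equal(as.character(assign_cycle_phase(0, 0)$phase), "G1")
  # argmax when positive
  expect_equal(as.character(assign_cycle_phase(0.5, 0.1)$phase), "S")
  expect_equal(as.character(assign_cycle_phase(0.1, 0.5)$phase), "G2M")
  # documented tie-break: positive tie goes to S
  expect_equal(as.character(assign_cycle_phase(0.3, 0.3)$phase), "S")
  expect_error(assign_cycle_phase(NaN, 0), "NaN")
  expect_error(assign_cycle_phase(c(1, 2), 1), "equal length")
})

test_that("phase calls recover the planted S/G2M cells", {
  gen <- small_two_condition(seed = 19, n_per = 400, n_genes = 600)
  mn <- normalize_log(gen$matrix)
  sigs <- truth_signatures(gen$truth)
  s <- module_score(mn, sigs$S$genes, seed = 1)
  g2m <- module_score(mn, sigs$G2M$genes, seed = 2)
  call <- assign_cycle_phase(s, g2m)
  truth <- gen$truth$cells$phase
  idx <- truth %in% c("S", "G2M")
  acc <- mean(as.character(call$phase)[idx] == truth[idx])
  expect_gt(acc, 0.85)
})

test_that("score-gene correlation equals an independent rank computation", {
  set.seed(11)
  n <- 20
  vals <- matrix(rexp(n * 5), n, 5)
  vals[, 3] <- (1:n) / 10 + rnorm(n, sd = 0.4)   # planted monotone link
  vals <- abs(vals)
  m <- toy_cell_matrix(vals)
  scores <- (1:n) / n
  got <- correlate_signature_with_gene(scores, m, "g03")
  want <- cor(rank(scores), rank(vals[, 3]))
  expect_equal(got$estimate, want, tolerance = 1e-12)

  self <- correlate_signature_with_gene(vals[, 3], m, "g03")
  expect_equal(self$estimate, 1)
  neg <- correlate_signature_with_gene(-vals[, 3], m, "g03")
  expect_equal(neg$estimate, -1)
  expect_error(correlate_signature_with_gene(rep(1, n), m, "g03"), "constant")
})

test_that("phase signature matrix composes mean scores and z-scores columns", {
  set.seed(23)
  vals <- matrix(rexp(50), 5, 10)
  m <- toy_cell_matrix(vals)
  sigs <- signature_set(a = c("g01", "g02"), b = c("g05", "g06"),
                        dup = c("g01", "g02"))
  sm <- phase_signature_matrix(m, sigs, z_score = FALSE)
  expect_equal(unname(sm[, "a"]),
               as.numeric(mean_signature_score(m, c("g01", "g02"))))
  expect_equal(unname(sm[, "a"]), unname(sm[, "dup"]))
  smz <- phase_signature_matrix(m, sigs, z_score = TRUE)
  expect_equal(unname(colMeans(smz)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(smz, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # constant matrix: all-zero columns after z-scoring
  mc <- toy_cell_matrix(matrix(4, 5, 10))
  expect_true(all(phase_signature_matrix(mc, sigs) == 0))
})
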