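test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_cells = 150, n_genes = 300, seed = 11)
  a <- generate_cells(cfg)
  b <- generate_cells(cfg)
  expect_identical(as_dense(a$matrix), as_dense(b$matrix))
  expect_identical(a$truth$cells, b$truth$cells)

  cfg2 <- sim_config(n_cells = 150, n_genes = 300,
                     conditions = default_conditions(75), seed = 11)
  c1 <- generate_two_condition(cfg2)
  c2 <- generate_two_condition(cfg2)
  expect_identical(as_dense(c1$matrix), as_dense(c2$matrix))
})

test_that("frac_g0 = 0 yields only cyclers with defined theta and q = 0", {
  cfg <- sim_config(n_cells = 100, n_genes = 300, frac_g0 = 0, seed = 3)
  g <- generate_cells(cfg)
  expect_false(anyNA(g$truth$cells$theta))
  expect_true(all(g$truth$cells$q == 0))
  expect_false(any(g$truth$cells$phase == "G0"))
})

test_that("counts follow the negative binomial moment targets", {
  # single unregulated gene: mean mu, variance mu + mu^2 / dispersion
  cfg <- sim_config(n_cells = 50000, n_genes = 1, frac_g0 = 0,
                    phase_programs = default_phase_programs()[0, ],
                    baseline_mu = 5, nb_dispersion = 2, dropout_rate = 0,
                    mito_gene_frac = 0, n_mito_genes = 0, seed = 99)
  g <- generate_cells(cfg)
  x <- as_dense(g$matrix)[, 1]
  expect_true(all(x >= 0), info = "counts non-negative")
  expect_true(all(x == round(x)), info = "counts integer")
  expect_lt(abs(mean(x) - 5) / 5, 0.02)
  expect_lt(abs(var(x) - (5 + 25 / 2)) / (5 + 25 / 2), 0.10)
})

test_that("planted DE bookkeeping records exactly the planted genes", {
  gen <- small_two_condition(seed = 5)
  de <- gen$truth$de_genes
  expect_equal(nrow(de), 13)
  expect_true(all(de$fold_change == 4))
  expect_true(all(de$direction == "up"))
  expect_true(all(de$fold_change > 0))
  # planted genes are real, unregulated, non-mito genes
  expect_true(all(de$gene %in% gen$matrix$gene_ids))
  expect_false(any(de$gene %in% gen$truth$signature_membership$gene))
  expect_false(any(grepl("^mt-", de$gene)))
})

test_that("g0_shift moves the expected fraction of cyclers into G0", {
  cfg <- sim_config(
    n_cells = 4000, n_genes = 60, frac_g0 = 0.25,
    phase_programs = default_phase_programs(n_marker_genes = 5L),
    conditions = list(condition_spec("control", 2000),
                      condition_spec("treated", 2000, g0_shift = 0.4)),
    seed = 21
  )
  g <- generate_two_condition(cfg)
  cells <- g$truth$cells
  frac <- tapply(cells$phase == "G0", cells$condition, mean)
  expect_lt(abs(frac[["control"]] - 0.25), 0.04)     # ~4 binomial sd
  expect_lt(abs(frac[["treated"]] - (0.25 + 0.4 * 0.75)), 0.04)
})

test_that("null two-condition design is exchangeable", {
  cfg <- sim_config(n_cells = 400, n_genes = 300,
                    conditions = list(condition_spec("a", 200),
                                      condition_spec("b", 200)),
                    seed = 8)
  g <- generate_two_condition(cfg)
  expect_equal(nrow(g$truth$de_genes), 0)
  tot <- Matrix::rowSums(g$matrix$values)
  cond <- g$truth$cells$condition
  # same generative law: library sizes indistinguishable
  p <- suppressWarnings(stats::ks.test(tot[cond == "a"], tot[cond == "b"])$p.value)
  expect_gt(p, 1e-3)
})

test_that("phase-program expression tracks the latent cycle coordinate", {
  cfg <- sim_config(n_cells = 800, n_genes = 400, frac_g0 = 0, seed = 13)
  g <- generate_cells(cfg)
  mn <- normalize_log(g$matrix)
  sigs <- truth_signatures(g$truth)
  theta <- g$truth$cells$theta
  for (ph in c("G1", "S", "G2M", "M")) {
    sc <- mean_signature_score(mn, sigs[[ph]]$genes)
    ctr <- default_phase_programs()$center[default_phase_programs()$phase == ph]
    bump <- exp(-pmin(abs(theta - ctr), 1 - abs(theta - ctr))^2 / (2 * 0.12^2))
    expect_gt(cor(as.numeric(sc), bump), 0.5)
  }
})

test_that("mito genes carry the configured count fraction in expectation", {
  cfg <- sim_config(n_cells = 2000, n_genes = 200, mito_gene_frac = 0.1,
                    phase_programs = default_phase_programs(n_marker_genes = 10L),
                    dropout_rate = 0, seed = 17)
  g <- generate_cells(cfg)
  expect_lt(abs(mean(g$matrix$cell_meta$mito_fraction) - 0.1), 0.01)
  expect_true(all(grepl("^mt-", g$matrix$gene_ids[191:200])))
})

test_that("truth tables round-trip through TSV", {
  gen <- small_two_condition(seed = 4, n_per = 20, n_genes = 300)
  dir <- withr::local_tempdir()
  write_truth(gen$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$cells, gen$truth$cells)
  expect_equal(back$de_genes, gen$truth$de_genes)
  expect_equal(back$signature_membership, gen$truth$signature_membership)
  expect_equal(nrow(back$cells), 40)

  # empty planted-DE list -> empty DE table with header
  g2 <- generate_cells(sim_config(n_cells = 3, n_genes = 300, seed = 1))
  dir2 <- withr::local_tempdir()
  write_truth(g2$truth, dir2)
  b2 <- read_truth(dir2)
  expect_equal(nrow(b2$de_genes), 0)
  expect_named(b2$de_genes, c("gene", "fold_change", "direction"))
  expect_equal(nrow(b2$cells), 3)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 100), "exceed n_genes")
  expect_error(sim_config(frac_g0 = 1.2), "fractions")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(generate_two_condition(sim_config(n_cells = 50)), "exactly two")
  expect_error(
    generate_two_condition(
      sim_config(n_cells = 50, conditions = list(condition_spec("a", 0),
                                                 condition_spec("b", 0)),
                 seed = 1)),
    "sum to 0")
})
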