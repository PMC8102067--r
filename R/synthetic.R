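#' Configuration for the synthetic single-cell generator
#'
#' The generator plants a cyclic latent cell-cycle coordinate, a graded
#' quiescence (G0) arm, mitochondrial counts, dropout, and optional
#' two-condition structure (quiescence shifts and differentially expressed
#' gene sets), and records the full ground truth so every downstream stage
#' can be validated without external data.
#'
#' Cyclers carry a latent phase `theta` in [0, 1); a phase program's genes
#' have expected expression `baseline_mu * (1 + amplitude * bump(theta -
#' center))` where `bump` is a wrapped Gaussian of the configured width.
#' G0 cells carry a quiescence depth `q ~ Exponential(scale = qdepth_scale)`;
#' their G0-program genes scale as `1 + amplitude * (1 - exp(-q))` while
#' every cycling-program gene decays as `baseline_mu * (1 + amplitude *
#' bump(theta_G1 - center)) * exp(-q)`, mirroring the shutdown of
#' cell-cycle transcription on quiescence entry: shallow G0 cells resemble
#' G1 cells and depth is identifiable and monotone. Counts are negative binomial with the given
#' dispersion (`variance = mu + mu^2 / nb_dispersion`), followed by
#' Bernoulli dropout. Mitochondrial genes (prefix `mt-`) are budgeted so
#' they contribute `mito_gene_frac` of counts in expectation.
#'
#' @param n_cells,n_genes Matrix dimensions (genes include the mito genes).
#' @param frac_g0 Fraction of cells placed on the quiescence arm.
#' @param theta_distribution Distribution of the cyclers' latent phase;
#'   only `"uniform"` is implemented.
#' @param qdepth_scale Scale (mean) of the exponential quiescence depth.
#' @param phase_programs Data frame with columns `phase`, `center` (theta in
#'   [0,1), `NA` for the q-driven G0 program), `amplitude`, `n_genes`,
#'   `width`. Marker sets for distinct phases are disjoint.
#' @param nb_dispersion Negative binomial size parameter (smaller = noisier).
#' @param baseline_mu Expected count of an unregulated gene.
#' @param dropout_rate Zeroing probability after count sampling; under
#'   `dropout_shape = "logistic"` this is the rate at `mu = baseline_mu`
#'   and the rate decreases logistically in `log(mu)`.
#' @param dropout_shape `"constant"` or `"logistic"`.
#' @param mito_gene_frac Expected fraction of each cell's counts carried by
#'   mitochondrial genes.
#' @param n_mito_genes Number of `mt-` prefixed genes.
#' @param conditions Optional list of exactly two condition descriptors for
#'   [generate_two_condition()]; see [condition_spec()].
#' @param seed Integer seed; identical configurations yield bit-identical
#'   output.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000L,
                       n_genes = 1500L,
                       frac_g0 = 0.75,
                       theta_distribution = "uniform",
                       qdepth_scale = 1,
                       phase_programs = default_phase_programs(),
                       nb_dispersion = 2,
                       baseline_mu = 0.5,
                       dropout_rate = 0.2,
                       dropout_shape = c("constant", "logistic"),
                       mito_gene_frac = 0.05,
                       n_mito_genes = 10L,
                       conditions = NULL,
                       seed = 1L) {
  dropout_shape <- match.arg(dropout_shape)
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              frac_g0 = frac_g0, theta_distribution = theta_distribution,
              qdepth_scale = qdepth_scale, phase_programs = phase_programs,
              nb_dispersion = nb_dispersion, baseline_mu = baseline_mu,
              dropout_rate = dropout_rate, dropout_shape = dropout_shape,
              mito_gene_frac = mito_gene_frac,
              n_mito_genes = as.integer(n_mito_genes),
              conditions = conditions, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default phased expression programs
#'
#' Five programs: four cycling phases at fixed positions of the latent cycle
#' plus a quiescence-driven G0 program (`center = NA`).
#'
#' @param n_marker_genes Genes per program.
#' @param amplitude Peak fold activation above baseline.
#' @param width Wrapped-Gaussian bump width on the unit circle.
#' @return Data frame consumed by [sim_config()].
#' @export
default_phase_programs <- function(n_marker_genes = 50L, amplitude = 3,
                                   width = 0.12) {
  data.frame(
    phase = c("G1", "S", "G2M", "M", "G0"),
    center = c(0.10, 0.40, 0.65, 0.90, NA),
    amplitude = amplitude,
    n_genes = as.integer(n_marker_genes),
    width = width,
    stringsAsFactors = FALSE
  )
}

#' Describe one condition of a two-condition design
#'
#' @param label Condition name.
#' @param n_cells Cells drawn for the condition.
#' @param g0_shift Fraction of would-be cyclers moved onto the quiescence arm
#'   in this condition (0 = same cell-cycle structure as the base config).
#' @param de_n,de_fc,de_direction Planted differential expression: vectors
#'   describing gene-set sizes, fold changes (> 0) and directions
#'   (`"up"`/`"down"`, treated-relative) applied to this condition.
#' @return A list consumed by [sim_config()]'s `conditions` field.
#' @export
condition_spec <- function(label, n_cells, g0_shift = 0,
                           de_n = integer(0), de_fc = numeric(0),
                           de_direction = character(0)) {
  stopifnot(length(de_n) == length(de_fc),
            length(de_n) == length(de_direction))
  if (length(de_fc) && any(de_fc <= 0)) stop("planted fold changes must be > 0")
  list(label = label, n_cells = as.integer(n_cells), g0_shift = g0_shift,
       de = data.frame(n = as.integer(de_n), fold_change = de_fc,
                       direction = de_direction, stringsAsFactors = FALSE))
}

#' Default two-condition design: an untreated control arm and a treated arm
#' in which 40% of cyclers exit to quiescence and a 13-gene set is induced
#' four-fold.
#' @param n_per_condition Cells per arm.
#' @param g0_shift Fraction of treated cyclers moved to G0.
#' @return List of two [condition_spec()]s.
#' @export
default_conditions <- function(n_per_condition = 1000L, g0_shift = 0.4) {
  list(condition_spec("control", n_per_condition, g0_shift = 0),
       condition_spec("treated", n_per_condition, g0_shift = g0_shift,
                      de_n = 13L, de_fc = 4, de_direction = "up"))
}

#' Preset two-condition study designs
#'
#' `bp_like_config()` emulates a drug-responsive tumor: the control arm is
#' a proliferating population (half the cells quiescent), and treatment
#' moves 40% of the remaining cyclers into quiescence besides inducing a
#' 13-gene set four-fold. `bpn_like_config()` is the matched null: same
#' base population, no quiescence shift and no induced genes, so the two
#' arms are exchangeable draws from one distribution.
#'
#' @param seed Integer seed.
#' @param n_per_condition Cells per arm.
#' @param n_genes Genes simulated.
#' @param frac_g0 Quiescent fraction of the control arm.
#' @return A [sim_config()].
#' @export
bp_like_config <- function(seed = 1L, n_per_condition = 1000L,
                           n_genes = 1500L, frac_g0 = 0.5) {
  sim_config(n_cells = 2L * n_per_condition, n_genes = n_genes,
             frac_g0 = frac_g0,
             conditions = default_conditions(n_per_condition, g0_shift = 0.4),
             seed = seed)
}

#' @rdname bp_like_config
#' @export
bpn_like_config <- function(seed = 1L, n_per_condition = 1000L,
                            n_genes = 1500L, frac_g0 = 0.5) {
  sim_config(n_cells = 2L * n_per_condition, n_genes = n_genes,
             frac_g0 = frac_g0,
             conditions = list(condition_spec("control", n_per_condition),
                               condition_spec("treated", n_per_condition)),
             seed = seed)
}

validate_sim_config <- function(cfg) {
  frac <- c(frac_g0 = cfg$frac_g0, dropout_rate = cfg$dropout_rate,
            mito_gene_frac = cfg$mito_gene_frac)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_cells < 1L || cfg$n_genes < 1L) stop("counts must be >= 1")
  if (cfg$qdepth_scale <= 0) stop("qdepth_scale must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$baseline_mu <= 0) stop("baseline_mu must be positive")
  pp <- cfg$phase_programs
  if (nrow(pp)) {
    if (any(pp$amplitude < 0)) stop("amplitudes must be >= 0")
    if (anyDuplicated(pp$phase)) stop("phase program labels must be unique")
  }
  if (cfg$mito_gene_frac > 0 && cfg$n_mito_genes < 1L) {
    stop("mito_gene_frac > 0 requires n_mito_genes >= 1")
  }
  n_marker <- if (nrow(pp)) sum(pp$n_genes) else 0L
  if (n_marker + cfg$n_mito_genes > cfg$n_genes) {
    stop("marker and mito gene sets exceed n_genes")
  }
  if (!identical(cfg$theta_distribution, "uniform")) {
    stop("only theta_distribution = 'uniform' is implemented")
  }
  invisible(cfg)
}

## Wrapped Gaussian bump on the unit circle, normalized to bump(0) = 1.
wrapped_bump <- function(d, width) {
  d <- d - floor(d)                     # into [0, 1)
  (exp(-d^2 / (2 * width^2)) +
    exp(-(d - 1)^2 / (2 * width^2)) +
    exp(-(d + 1)^2 / (2 * width^2))) /
    (1 + 2 * exp(-1 / (2 * width^2)))
}

## Gene bookkeeping shared by both generators: marker blocks first, then
## free genes, mito genes ("mt-" prefix) last.
plan_genes <- function(cfg) {
  pp <- cfg$phase_programs
  n_mito <- cfg$n_mito_genes
  if (cfg$mito_gene_frac == 0) n_mito <- 0L
  n_plain <- cfg$n_genes - n_mito
  ids <- sprintf("g%04d", seq_len(n_plain))
  if (n_mito > 0L) ids <- c(ids, sprintf("mt-%02d", seq_len(n_mito)))
  membership <- rep(NA_character_, cfg$n_genes)
  idx <- 1L
  program_idx <- list()
  if (nrow(pp)) {
    for (i in seq_len(nrow(pp))) {
      rng <- idx:(idx + pp$n_genes[i] - 1L)
      membership[rng] <- pp$phase[i]
      program_idx[[pp$phase[i]]] <- rng
      idx <- idx + pp$n_genes[i]
    }
  }
  free_idx <- setdiff(seq_len(n_plain), unlist(program_idx))
  mito_idx <- if (n_mito > 0L) (n_plain + 1L):cfg$n_genes else integer(0)
  list(ids = ids, membership = membership, program_idx = program_idx,
       free_idx = free_idx, mito_idx = mito_idx, n_mito = n_mito)
}

## Latent cell states for one condition arm.
draw_cell_states <- function(n, frac_g0, qdepth_scale, cycling_pp) {
  is_g0 <- stats::runif(n) < frac_g0
  theta <- rep(NA_real_, n)
  q <- rep(0, n)
  theta[!is_g0] <- stats::runif(sum(!is_g0))
  q[is_g0] <- stats::rexp(sum(is_g0), rate = 1 / qdepth_scale)
  phase <- rep("G0", n)
  if (any(!is_g0) && nrow(cycling_pp)) {
    th <- theta[!is_g0]
    dmat <- vapply(cycling_pp$center, function(ctr) {
      d <- abs(th - ctr)
      pmin(d, 1 - d)
    }, numeric(sum(!is_g0)))
    phase[!is_g0] <- cycling_pp$phase[max.col(-dmat, ties.method = "first")]
  }
  list(theta = theta, q = q, phase = phase)
}

## Expected-count matrix for one arm given latent states. `fc` is a
## per-gene multiplier (1 = unregulated).
expected_mu <- function(cfg, plan, st, fc) {
  n <- length(st$q)
  pp <- cfg$phase_programs
  mu <- matrix(cfg$baseline_mu, n, cfg$n_genes)
  g1_center <- if ("G1" %in% pp$phase) pp$center[pp$phase == "G1"] else 0
  is_g0 <- st$phase == "G0"
  for (i in seq_len(nrow(pp))) {
    gidx <- plan$program_idx[[pp$phase[i]]]
    if (!length(gidx)) next
    act <- numeric(n)
    if (is.na(pp$center[i])) {            # quiescence program: rises with q
      act[is_g0] <- 1 - exp(-st$q[is_g0])
      mu[, gidx] <- cfg$baseline_mu * (1 + pp$amplitude[i] * act)
    } else {                              # cycling program
      act[!is_g0] <- wrapped_bump(st$theta[!is_g0] - pp$center[i], pp$width[i])
      act[is_g0] <- wrapped_bump(g1_center - pp$center[i], pp$width[i])
      # G0 cells sit at the G1 exit point and their whole cycling machinery
      # decays with depth, so the program falls below baseline as q grows
      decay <- rep(1, n)
      decay[is_g0] <- exp(-st$q[is_g0])
      mu[, gidx] <- cfg$baseline_mu * (1 + pp$amplitude[i] * act) * decay
    }
  }
  mu <- sweep(mu, 2, fc, `*`)
  if (length(plan$mito_idx)) {
    f <- cfg$mito_gene_frac
    non_mito_total <- rowSums(mu[, -plan$mito_idx, drop = FALSE])
    mu[, plan$mito_idx] <- (f / (1 - f)) * non_mito_total / plan$n_mito
  }
  mu
}

sample_counts <- function(cfg, mu) {
  n <- length(mu)
  counts <- stats::rnbinom(n, size = cfg$nb_dispersion, mu = as.vector(mu))
  if (cfg$dropout_rate > 0) {
    p_drop <- if (cfg$dropout_shape == "constant") {
      rep(cfg$dropout_rate, n)
    } else {
      # logistic in log(mu), anchored so p(baseline_mu) = dropout_rate
      stats::plogis(stats::qlogis(cfg$dropout_rate) -
                      (log(as.vector(mu)) - log(cfg$baseline_mu)))
    }
    counts[stats::runif(n) < p_drop] <- 0L
  }
  matrix(counts, nrow = nrow(mu), ncol = ncol(mu))
}

build_truth <- function(cfg, plan, barcodes, st, condition, de_genes) {
  cells <- data.frame(barcode = barcodes, theta = st$theta, q = st$q,
                      phase = st$phase, condition = condition,
                      stringsAsFactors = FALSE)
  membership <- data.frame(gene = plan$ids[!is.na(plan$membership)],
                           phase = plan$membership[!is.na(plan$membership)],
                           stringsAsFactors = FALSE)
  structure(list(cells = cells, de_genes = de_genes,
                 signature_membership = membership),
            class = "synthetic_truth")
}

empty_de_table <- function() {
  data.frame(gene = character(0), fold_change = numeric(0),
             direction = character(0), stringsAsFactors = FALSE)
}

#' Generate a synthetic single-condition count matrix with ground truth
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (a raw-counts [cell_matrix] with
#'   mito fraction and condition in its `cell_meta`) and `truth` (a
#'   `synthetic_truth`: per-cell `theta`, `q`, phase and condition, the
#'   planted differential-expression table, and gene-to-phase membership).
#' @export
generate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plan <- plan_genes(config)
  cycling_pp <- config$phase_programs[!is.na(config$phase_programs$center), ,
                                      drop = FALSE]
  st <- draw_cell_states(config$n_cells, config$frac_g0,
                         config$qdepth_scale, cycling_pp)
  mu <- expected_mu(config, plan, st, fc = rep(1, config$n_genes))
  counts <- sample_counts(config, mu)
  barcodes <- sprintf("cell%05d", seq_len(config$n_cells))
  m <- finish_matrix(counts, plan, barcodes, "cond1")
  truth <- build_truth(config, plan, barcodes, st, "cond1", empty_de_table())
  list(matrix = m, truth = truth)
}

finish_matrix <- function(counts, plan, barcodes, condition) {
  mito_frac <- if (length(plan$mito_idx)) {
    tot <- rowSums(counts)
    ifelse(tot > 0, rowSums(counts[, plan$mito_idx, drop = FALSE]) / tot, 0)
  } else {
    rep(0, nrow(counts))
  }
  meta <- data.frame(condition = condition,
                     mito_fraction = mito_frac,
                     n_features = rowSums(counts > 0),
                     stringsAsFactors = FALSE)
  cell_matrix(Matrix::Matrix(counts, sparse = TRUE,
                             dimnames = list(barcodes, plan$ids)),
              layer = "raw_counts", cell_meta = meta)
}

#' Generate a two-condition synthetic dataset
#'
#' The second (treated-like) condition applies its `g0_shift` — moving the
#' stated fraction of would-be cyclers onto the quiescence arm — and
#' multiplies the planted differentially expressed genes' expected counts by
#' their fold changes (up) or their reciprocals (down). The returned truth
#' records both the per-cell structure and the planted gene table.
#'
#' @param config A [sim_config()] whose `conditions` field holds exactly two
#'   [condition_spec()]s (see [default_conditions()]).
#' @return As [generate_cells()].
#' @export
generate_two_condition <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  conds <- config$conditions
  if (is.null(conds) || length(conds) != 2L) {
    stop("config$conditions must list exactly two conditions")
  }
  if (sum(vapply(conds, `[[`, integer(1), "n_cells")) == 0L) {
    stop("condition cell counts sum to 0")
  }
  set.seed(config$seed)
  plan <- plan_genes(config)
  cycling_pp <- config$phase_programs[!is.na(config$phase_programs$center), ,
                                      drop = FALSE]

  # plant DE gene sets (disjoint, drawn from unregulated non-mito genes)
  free <- plan$free_idx
  de_tables <- vector("list", 2L)
  for (ci in 1:2) {
    de <- conds[[ci]]$de
    rows <- empty_de_table()
    if (nrow(de)) {
      for (k in seq_len(nrow(de))) {
        if (de$n[k] > length(free)) stop("planted DE set exceeds free genes")
        pick <- sort(sample(free, de$n[k]))
        free <- setdiff(free, pick)
        rows <- rbind(rows, data.frame(gene = plan$ids[pick],
                                       fold_change = de$fold_change[k],
                                       direction = de$direction[k],
                                       stringsAsFactors = FALSE))
      }
    }
    de_tables[[ci]] <- rows
  }

  counts_list <- vector("list", 2L)
  states <- vector("list", 2L)
  for (ci in 1:2) {
    cs <- conds[[ci]]
    frac_g0 <- config$frac_g0 + cs$g0_shift * (1 - config$frac_g0)
    st <- draw_cell_states(cs$n_cells, frac_g0, config$qdepth_scale, cycling_pp)
    fc <- rep(1, config$n_genes)
    det <- de_tables[[ci]]
    if (nrow(det)) {
      gi <- match(det$gene, plan$ids)
      fc[gi] <- ifelse(det$direction == "up", det$fold_change,
                       1 / det$fold_change)
    }
    mu <- expected_mu(config, plan, st, fc)
    counts_list[[ci]] <- sample_counts(config, mu)
    states[[ci]] <- st
  }

  counts <- rbind(counts_list[[1]], counts_list[[2]])
  condition <- rep(c(conds[[1]]$label, conds[[2]]$label),
                   c(conds[[1]]$n_cells, conds[[2]]$n_cells))
  barcodes <- sprintf("cell%05d", seq_len(nrow(counts)))
  st <- list(theta = c(states[[1]]$theta, states[[2]]$theta),
             q = c(states[[1]]$q, states[[2]]$q),
             phase = c(states[[1]]$phase, states[[2]]$phase))
  m <- finish_matrix(counts, plan, barcodes, condition)
  de_all <- rbind(de_tables[[1]], de_tables[[2]])
  de_all <- de_all[order(de_all$gene), , drop = FALSE]
  rownames(de_all) <- NULL
  truth <- build_truth(config, plan, barcodes, st, condition, de_all)
  list(matrix = m, truth = truth)
}

#' Phased signatures implied by a synthetic truth
#'
#' Converts the generator's gene-to-phase membership into a [signature_set]
#' (one signature per planted program, tagged with its phase) for use by the
#' scoring and trajectory stages.
#'
#' @param truth A `synthetic_truth`.
#' @return A [signature_set].
#' @export
truth_signatures <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mem <- truth$signature_membership
  sigs <- split(mem$gene, factor(mem$phase, levels = unique(mem$phase)))
  phases <- stats::setNames(names(sigs), names(sigs))
  signature_set(as.list(sigs), phases = phases)
}

#' Write / read synthetic ground truth as TSV
#'
#' `cells.tsv` holds barcode, theta, q, phase, condition; `genes.tsv` holds
#' the planted DE table and phase membership (full outer join on gene). The
#' pair round-trips losslessly through [read_truth()].
#'
#' @param truth A `synthetic_truth`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(truth$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  genes <- merge(truth$de_genes, truth$signature_membership,
                 by = "gene", all = TRUE)
  colnames(genes) <- c("gene", "fold_change", "direction", "phase_membership")
  genes <- genes[order(genes$gene), , drop = FALSE]
  utils::write.table(genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @return `read_truth` returns the reconstructed `synthetic_truth`.
#' @export
read_truth <- function(dir) {
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             stringsAsFactors = FALSE)
  cells$theta <- as.numeric(cells$theta)
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  de <- genes[!is.na(genes$fold_change),
              c("gene", "fold_change", "direction")]
  rownames(de) <- NULL
  mem <- genes[!is.na(genes$phase_membership), c("gene", "phase_membership")]
  colnames(mem) <- c("gene", "phase")
  # restore generator gene order (marker blocks first): sort by gene id
  mem <- mem[order(mem$gene), , drop = FALSE]
  rownames(mem) <- NULL
  structure(list(cells = cells, de_genes = de, signature_membership = mem),
            class = "synthetic_truth")
}
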