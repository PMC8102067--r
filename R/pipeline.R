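#' Build a validated pipeline run configuration
#'
#' Sections mirror the pipeline stages. Unknown keys — at the top level or
#' inside any section — are rejected, so typos fail loudly instead of
#' silently running with defaults. All randomized stages draw from the
#' single master `seed` through fixed per-stage offsets, recorded in the
#' run log.
#'
#' @param simulate List of [sim_config()] overrides plus `enabled` and
#'   `two_condition` flags; when disabled, `input_dir` must point at an MTX
#'   triplet directory.
#' @param input_dir MTX triplet directory used when simulation is off.
#' @param qc List: `enabled`, `min_features`, `max_features`, `max_mito`,
#'   `mito_prefix`.
#' @param normalize List: `scale`.
#' @param score List: `z_score`, `n_bins`, `n_ctrl`.
#' @param qdepth List: `enabled`, `k_components`, `knn`, `alpha`,
#'   `projection`, `box`, `smooth_df`, `tol`, `max_iter`, `orient_frac`.
#' @param derive List: `enabled`, `alpha`, `fc_threshold`, `direction`,
#'   `universe_size` (synthetic universe: the planted DE genes plus this
#'   many unregulated genes).
#' @param impute List: `enabled`, `rank`, `w0`, `max_iter`, `tol`.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = list(), input_dir = NULL,
                       qc = list(), normalize = list(), score = list(),
                       qdepth = list(), derive = list(), impute = list(),
                       seed = 1L, out_dir = tempfile("qdepth_run")) {
  defaults <- list(
    simulate = list(enabled = TRUE, two_condition = TRUE),
    qc = list(enabled = TRUE, min_features = 200L, max_features = 7500L,
              max_mito = 0.20, mito_prefix = "mt-"),
    normalize = list(scale = 1e4),
    score = list(z_score = TRUE, n_bins = 24L, n_ctrl = 100L),
    qdepth = list(enabled = TRUE, k_components = 3L, knn = 10L, alpha = 1,
                  projection = "pca", box = "signature", smooth_df = NULL,
                  tol = 1e-4, max_iter = 50L, orient_frac = 0.1),
    derive = list(enabled = TRUE, alpha = 0.05, fc_threshold = 2,
                  direction = "up", universe_size = 50L),
    impute = list(enabled = FALSE, rank = 20L, w0 = 0.1, max_iter = 200L,
                  tol = 1e-5)
  )
  merge_section <- function(name, user, extra_ok = character(0)) {
    def <- defaults[[name]]
    bad <- setdiff(names(user), c(names(def), extra_ok))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section '%s': %s", name,
                   paste(bad, collapse = ", ")))
    }
    utils::modifyList(def, user)
  }
  sim_ok <- setdiff(names(formals(sim_config)), "seed")
  cfg <- list(
    simulate = merge_section("simulate", simulate, extra_ok = sim_ok),
    input_dir = input_dir,
    qc = merge_section("qc", qc),
    normalize = merge_section("normalize", normalize),
    score = merge_section("score", score),
    qdepth = merge_section("qdepth", qdepth),
    derive = merge_section("derive", derive),
    impute = merge_section("impute", impute),
    seed = as.integer(seed),
    out_dir = out_dir
  )
  if (!cfg$simulate$enabled && is.null(cfg$input_dir)) {
    stop("either enable simulation or supply input_dir")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose sections mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "...")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, y)
}

## deterministic per-stage streams below 2^31
derive_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) * 1009 + 97 * stage_index) %% 2147483647)
}

#' Execute the full pipeline
#'
#' Runs simulate -> qc -> normalize -> score/phase -> qdepth ->
#' derive-signature -> impute as enabled, writing per-stage TSV/MTX
#' artifacts and a machine-readable JSON run log (parameters, derived
#' seeds, package version, per-stage dimensions) to the output directory.
#' Re-running with the same configuration reproduces identical outputs.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return Invisibly, a list with the principal in-memory results
#'   (`matrix`, `truth`, `qc_report`, `fit`, `de`, `signature`,
#'   `imputed`, `log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log <- list(package_version = as.character(utils::packageVersion("qdepth")),
              seed = config$seed, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate (or load) -------------------------------------------------
  truth <- NULL
  if (config$simulate$enabled) {
    sim_args <- config$simulate
    sim_args$enabled <- NULL
    two <- isTRUE(sim_args$two_condition)
    sim_args$two_condition <- NULL
    if (two && is.null(sim_args$conditions)) {
      sim_args$conditions <- default_conditions()
    }
    sim_args$seed <- derive_seed(config$seed, 1L)
    cfg_sim <- do.call(sim_config, sim_args)
    gen <- stage("simulate", {
      if (two) generate_two_condition(cfg_sim) else generate_cells(cfg_sim)
    })
    m <- gen$matrix
    truth <- gen$truth
    write_mtx_triplet(m, file.path(out, "simulated"))
    write_truth(truth, file.path(out, "simulated"))
    log$stages$simulate <- list(seed = cfg_sim$seed,
                                n_cells = n_cells(m), n_genes = n_genes(m))
  } else {
    m <- stage("load", read_mtx_triplet(config$input_dir))
    log$stages$load <- list(dir = config$input_dir,
                            n_cells = n_cells(m), n_genes = n_genes(m))
  }

  # --- qc -----------------------------------------------------------------
  qc_report <- NULL
  if (config$qc$enabled) {
    th <- qc_thresholds(config$qc$min_features, config$qc$max_features,
                        config$qc$max_mito, config$qc$mito_prefix)
    fl <- stage("qc", filter_cells(m, th))
    qc_report <- fl$report
    utils::write.table(qc_report, file.path(out, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    m <- fl$matrix
    if (!is.null(truth)) {
      truth$cells <- truth$cells[truth$cells$barcode %in% m$cell_ids, ,
                                 drop = FALSE]
    }
    log$stages$qc <- list(kept = n_cells(m), removed = sum(!fl$report$kept))
  } else {
    zero_feat <- sum(Matrix::rowSums(m$values > 0) == 0)
    if (zero_feat > 0) {
      warning(sprintf("qc disabled: %d zero-feature cell(s) passed downstream",
                      zero_feat))
      log$stages$qc <- list(skipped = TRUE, zero_feature_cells = zero_feat)
    }
  }

  # --- normalize ----------------------------------------------------------
  mn <- stage("normalize", normalize_log(m, scale = config$normalize$scale))
  log$stages$normalize <- list(scale = config$normalize$scale)

  # --- score + qdepth -----------------------------------------------------
  fit <- NULL
  if (config$qdepth$enabled) {
    if (is.null(truth)) {
      stop("qdepth stage needs phased signatures; supply synthetic mode ",
           "(real-data runs should call fit_qdepth() directly with their lists)")
    }
    sigs <- truth_signatures(truth)
    qd <- config$qdepth
    fit <- stage("qdepth", fit_qdepth(
      mn, sigs,
      z_score = config$score$z_score,
      k_components = qd$k_components, knn = qd$knn, alpha = qd$alpha,
      projection = qd$projection, box = qd$box, smooth_df = qd$smooth_df,
      tol = qd$tol, max_iter = qd$max_iter,
      n_bins = config$score$n_bins, n_ctrl = config$score$n_ctrl,
      seed = derive_seed(config$seed, 2L), orient_frac = qd$orient_frac
    ))
    tab <- as.data.frame(fit)
    utils::write.table(tab, file.path(out, "qdepth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sc <- data.frame(cell_id = fit$cell_ids, fit$scores,
                     phase = fit$phase$phase, stringsAsFactors = FALSE)
    utils::write.table(sc, file.path(out, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log$stages$qdepth <- list(seed = derive_seed(config$seed, 2L),
                              in_box = sum(fit$in_box),
                              orientation_flipped = fit$orientation_flipped)
  }

  # --- derive-signature ---------------------------------------------------
  de <- NULL; sig <- NULL
  if (config$derive$enabled && !is.null(truth) && nrow(truth$de_genes)) {
    dcfg <- config$derive
    planted <- truth$de_genes$gene
    free <- setdiff(mn$gene_ids,
                    c(planted, truth$signature_membership$gene))
    free <- grep("^mt-", free, value = TRUE, invert = TRUE)
    universe <- c(planted, utils::head(sort(free), dcfg$universe_size))
    de <- stage("derive", test_genes(mn, mn$cell_meta$condition,
                                     universe = universe))
    utils::write.table(de, file.path(out, "de_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sig <- derive_signature(de, alpha = dcfg$alpha,
                            fc_threshold = dcfg$fc_threshold,
                            direction = dcfg$direction)
    if (length(sig)) {
      write_signatures(signature_set(derived = sig),
                       file.path(out, "derived_signature.tsv"))
    }
    log$stages$derive <- list(n_universe = length(universe),
                              n_signature = length(sig))
  }

  # --- impute -------------------------------------------------------------
  imputed <- NULL
  if (config$impute$enabled) {
    icfg <- config$impute
    f <- stage("impute", weighted_nmf(mn, rank = icfg$rank, w0 = icfg$w0,
                                      max_iter = icfg$max_iter,
                                      tol = icfg$tol,
                                      seed = derive_seed(config$seed, 3L)))
    imputed <- impute_matrix(mn, f)
    write_mtx_triplet(imputed, file.path(out, "imputed"))
    log$stages$impute <- list(seed = derive_seed(config$seed, 3L),
                              rank = icfg$rank, w0 = icfg$w0,
                              iterations = f$iterations)
  }

  log$config <- unclass_config(config)
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(matrix = mn, truth = truth, qc_report = qc_report,
                 fit = fit, de = de, signature = as.character(sig),
                 imputed = imputed, log = log, out_dir = out))
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$simulate$phase_programs <- NULL   # data frame; dims logged instead
  cfg
}
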