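# qdepth

Quiescence-depth trajectory analysis for single-cell RNA-seq.

## The problem

Cell-cycle scoring of scRNA-seq data labels cells S or G2/M and defaults
everything else to "G1" — a bucket that silently merges cells traversing G1
with cells that have exited the cycle into quiescence (G0), possibly
deeply. That distinction is the whole question when a therapy is supposed
to drive tumor cells out of the cycle: are the residual cells pausing, or
genuinely dormant?

`qdepth` treats quiescence as a continuous coordinate. Cells are scored
against phased cell-cycle signatures (G0, G1, S, G2/M, M); the cells ×
phases score matrix `S` is embedded with a diffusion map (adaptive
Gaussian kernel `K_ij = exp(-d_ij² / 2σ_i σ_j)`, density normalization
with α = 1, Markov row-normalization, leading non-trivial eigenpairs
`ψ_k λ_k`); the three leading diffusion components are projected onto the
2D cycle plane; a principal curve `f(λ)` is fitted by projection–smoothing
iteration through the G0/G1 region ("box"); and each cell's arc-length
position λ, oriented so the G0-signature-enriched end is maximal and
rescaled to [0, 1], is its **Q-depth**.

Around the core model the package provides QC filtering (strict
feature-count and mitochondrial-fraction rules), log normalization,
control-bin module scoring with discrete phase assignment, derivation of
treatment-response signatures (per-gene Student's t-test, Bonferroni over
the tested universe, strict fold-change threshold), weighted-NMF dropout
imputation, and a negative-binomial synthetic-data generator with complete
ground truth (latent cycle phase θ, quiescence depth q, planted fold
changes) that the entire test suite runs against.

## Worked example

Simulate a drug-responsive two-condition design (a proliferating control
arm; treatment moves 40% of cyclers into quiescence), run QC and
normalization, fit the trajectory, and test the treatment shift:

```r
library(qdepth)

cfg <- bp_like_config(seed = 1, n_per_condition = 500, n_genes = 800)
gen <- generate_two_condition(cfg)
qc  <- filter_cells(gen$matrix)
mat <- normalize_log(qc$matrix)
truth <- gen$truth$cells
truth <- truth[truth$barcode %in% mat$cell_ids, ]

fit <- fit_qdepth(mat, truth_signatures(gen$truth), seed = 2)
print(fit)
#> <qdepth_fit> 961 cells, 599 in the G0/G1 box (62.3%)
#>   diffusion eigenvalues: 0.9753, 0.9211, 0.8644
#>   principal curve: 16 iteration(s), objective 0.006436, orientation unflipped

cmp <- compare_qdepth(fit$qdepth, truth$condition, treated = "treated")
cat(sprintf("median Q-depth shift %.3f, Wilcoxon p = %.3g\n",
            cmp$shift, cmp$p.value))
#> median Q-depth shift 0.208, Wilcoxon p = 2.54e-06

g0 <- truth$phase == "G0" & fit$in_box
cor(truth$q[g0], fit$qdepth[g0], method = "spearman")
#> [1] 0.968
```

Reading the output: 961 of 1,000 simulated cells survive QC; 62% fall in
the G0/G1 box, through which the principal curve is fitted (16
projection–smoothing iterations, final summed squared projection distance
0.006). The treated arm sits a median 0.21 deeper on the [0, 1] Q-depth
axis (Wilcoxon rank-sum p ≈ 3e-6), and recovered Q-depth tracks the
generator's true latent depth q at Spearman ρ = 0.97 among quiescent box
cells. `plot(fit)` draws the cycle plane coloured by depth with the curve
overlaid; `as.data.frame(fit)` gives the per-cell table (diffusion
components, plane coordinates, λ, box flag, Q-depth, phase call).

`run_pipeline(run_config(...))` chains simulate → qc → normalize → score →
qdepth → derive-signature → impute from one configuration (or a YAML
file), writing per-stage TSV/MTX artifacts and a JSON run log with the
derived per-stage seeds.

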