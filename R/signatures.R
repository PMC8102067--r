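#' Named gene-signature collections
#'
#' A `signature_set` maps signature names to gene lists, each optionally
#' tagged with a cell-cycle phase label (G0, G1, S, G2M, M, ...). Phase tags
#' are what let the trajectory stage pick out the S/G2M signatures for phase
#' calling and the G0 signature for orienting the quiescence axis.
#'
#' @param ... Named character vectors of gene identifiers, or a single named
#'   list of them.
#' @param phases Optional named character vector mapping signature names to
#'   phase labels.
#'
#' @return An object of class `signature_set`: a named list with elements
#'   `list(genes = <character>, phase = <character or NA>)`.
#' @export
signature_set <- function(..., phases = NULL) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is.character(args[[1]])) {
    args <- args[[1]]
  }
  if (is.null(names(args)) || any(names(args) == "")) {
    stop("every signature must be named")
  }
  if (anyDuplicated(names(args))) stop("signature names must be unique")
  out <- lapply(names(args), function(nm) {
    g <- args[[nm]]
    if (is.list(g) && !is.null(g$genes)) {
      return(list(genes = as.character(g$genes),
                  phase = if (is.null(g$phase)) NA_character_ else g$phase))
    }
    g <- as.character(g)
    if (!length(g)) stop(sprintf("signature '%s' is empty", nm))
    ph <- if (!is.null(phases) && nm %in% names(phases)) phases[[nm]] else NA_character_
    list(genes = g, phase = ph)
  })
  names(out) <- names(args)
  for (nm in names(out)) {
    if (!length(out[[nm]]$genes)) stop(sprintf("signature '%s' is empty", nm))
  }
  structure(out, class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d signature(s)\n", length(x)))
  for (nm in names(x)) {
    ph <- x[[nm]]$phase
    cat(sprintf("  %s: %d genes%s\n", nm, length(x[[nm]]$genes),
                if (is.na(ph)) "" else sprintf(" [phase %s]", ph)))
  }
  invisible(x)
}

#' Read gene signatures from a TSV file
#'
#' Expects columns `signature`, `gene` and optionally `phase`. File order is
#' preserved within each signature. Genes absent from any particular
#' expression matrix are retained here; they are resolved (dropped with a
#' coverage report) at scoring time.
#'
#' @param path Path to a tab-separated file.
#' @return A [signature_set].
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("signature", "gene") %in% colnames(df))) {
    stop("signature file needs columns 'signature' and 'gene'")
  }
  if (anyDuplicated(df[, c("signature", "gene")])) {
    stop("duplicate (signature, gene) rows in signature file")
  }
  sigs <- split(df$gene, factor(df$signature, levels = unique(df$signature)))
  phases <- NULL
  if ("phase" %in% colnames(df)) {
    ph <- vapply(split(as.character(df$phase),
                       factor(df$signature, levels = unique(df$signature))),
                 function(p) {
                   p <- unique(p[!is.na(p) & p != ""])
                   if (length(p) > 1L) stop("conflicting phase labels within one signature")
                   if (length(p)) p else NA_character_
                 }, character(1))
    phases <- ph
  }
  signature_set(as.list(sigs), phases = phases)
}

#' Write a `signature_set` to TSV
#'
#' The output round-trips through [read_signatures()] and is the format the
#' derivation stage appends to.
#'
#' @param sigs A [signature_set].
#' @param path Output file path.
#' @param append Append to an existing file without rewriting the header.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sigs, path, append = FALSE) {
  stopifnot(inherits(sigs, "signature_set"))
  rows <- do.call(rbind, lapply(names(sigs), function(nm) {
    data.frame(signature = nm, gene = sigs[[nm]]$genes,
               phase = sigs[[nm]]$phase, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !append, append = append)
  invisible(path)
}
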