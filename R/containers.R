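#' Construct a validated panel count matrix
#'
#' A `count_matrix` holds a gene x sample matrix of non-negative counts
#' together with a per-gene housekeeping flag. Housekeeping genes are the
#' designated stable genes whose per-lane geometric mean drives
#' normalization.
#'
#' @param values numeric matrix, genes in rows (rownames required), samples
#'   in columns (colnames required); finite and >= 0.
#' @param housekeeping character vector of gene identifiers to flag as
#'   housekeeping. Genes in the list but absent from `values` trigger a
#'   warning, not an error.
#' @return an object of class `count_matrix`: a list with elements `values`
#'   (the matrix) and `housekeeping` (named logical, one entry per gene).
#' @export
count_matrix <- function(values, housekeeping = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("count matrix requires rownames (genes) and colnames (samples)", call. = FALSE)
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene identifier(s): %s",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")), call. = FALSE)
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample identifier(s): %s",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite or negative count at gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
  missing_hk <- setdiff(housekeeping, genes)
  if (length(missing_hk) > 0)
    warning(sprintf("%d designated housekeeping gene(s) absent from the count matrix: %s",
                    length(missing_hk), paste(missing_hk, collapse = ", ")), call. = FALSE)
  hk <- stats::setNames(genes %in% housekeeping, genes)
  structure(list(values = values, housekeeping = hk), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%d housekeeping)\n",
              nrow(x$values), ncol(x$values), sum(x$housekeeping)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Construct a log-scale expression matrix with provenance
#'
#' @param values numeric matrix of log2-scale normalized expression, finite.
#' @param pseudocount pseudocount recorded from the log transform.
#' @param batch_corrected logical provenance flag.
#' @return object of class `log_matrix` with elements `values` and
#'   `provenance` (list: pseudocount, batch_corrected).
#' @export
log_matrix <- function(values, pseudocount = NA_real_, batch_corrected = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(values)))
    stop("log matrix values must all be finite", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("log matrix requires rownames (genes) and colnames (samples)", call. = FALSE)
  structure(list(values = values,
                 provenance = list(pseudocount = pseudocount,
                                   batch_corrected = batch_corrected)),
            class = "log_matrix")
}

#' @export
print.log_matrix <- function(x, ...) {
  cat(sprintf("<log_matrix> %d genes x %d samples (pseudocount %s, batch-corrected %s)\n",
              nrow(x$values), ncol(x$values),
              format(x$provenance$pseudocount), x$provenance$batch_corrected))
  invisible(x)
}

#' @export
dim.log_matrix <- function(x) dim(x$values)

#' Construct a human co-expression module set
#'
#' Human brain co-expression modules, each annotated with exactly one
#' consensus-cluster label (A-E in the standard annotation) and optionally a
#' brain-region/source label used to pick the matching fold-change context.
#'
#' @param members named list: module id -> character vector of member human
#'   gene symbols (non-empty, unique within a module).
#' @param clusters named character: module id -> consensus cluster label.
#' @param region optional named character: module id -> brain-region or
#'   source annotation.
#' @param cluster_levels allowed cluster labels; labels outside this set are
#'   an error. Default the five consensus clusters `A`-`E`.
#' @return object of class `module_set`.
#' @export
module_set <- function(members, clusters, region = NULL,
                       cluster_levels = LETTERS[1:5]) {
  if (!is.list(members) || is.null(names(members)) || any(names(members) == ""))
    stop("'members' must be a named list of gene vectors", call. = FALSE)
  if (anyDuplicated(names(members)))
    stop("duplicate module identifiers", call. = FALSE)
  empty <- names(members)[lengths(members) == 0]
  if (length(empty) > 0)
    stop(sprintf("module(s) with zero genes: %s", paste(empty, collapse = ", ")), call. = FALSE)
  members <- lapply(members, function(g) unique(as.character(g)))
  clusters <- clusters[names(members)]
  if (any(is.na(clusters)))
    stop("every module needs exactly one consensus cluster label", call. = FALSE)
  bad <- unique(clusters[!clusters %in% cluster_levels])
  if (length(bad) > 0)
    stop(sprintf("unknown consensus cluster label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(cluster_levels, collapse = ", ")),
         call. = FALSE)
  if (!is.null(region)) region <- region[names(members)]
  structure(list(members = members,
                 clusters = stats::setNames(as.character(clusters), names(members)),
                 region = region),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules, sizes %d-%d, clusters {%s}\n",
              length(x$members), min(lengths(x$members)), max(lengths(x$members)),
              paste(sort(unique(x$clusters)), collapse = ", ")))
  invisible(x)
}

#' @export
length.module_set <- function(x) length(x$members)

#' Construct a human log2 fold-change signature table
#'
#' One row per (context, gene): the log2 fold change of AD cases (or a LOAD
#' subtype) versus controls for that human gene symbol, in the named context
#' (a module source study/brain region, or a subtype/cohort).
#'
#' @param context character vector of context ids.
#' @param gene character vector of human gene symbols.
#' @param log2fc numeric vector of finite log2 fold changes.
#' @return tibble of class `human_signature` with columns context, gene,
#'   log2fc.
#' @export
human_signature <- function(context, gene, log2fc) {
  log2fc <- as.numeric(log2fc)
  if (any(!is.finite(log2fc)))
    stop("signature log2fc values must be finite", call. = FALSE)
  out <- tibble::tibble(context = as.character(context),
                        gene = as.character(gene),
                        log2fc = log2fc)
  if (anyDuplicated(out[c("context", "gene")]))
    stop("duplicate (context, gene) rows in signature", call. = FALSE)
  class(out) <- c("human_signature", class(out))
  out
}

#' Construct a one-to-one human-mouse homolog map
#'
#' Many-to-many rows (a symbol appearing more than once on either side) are
#' dropped with a warning so that the retained pairs are strictly one-to-one.
#' Matching elsewhere in the package is case-insensitive.
#'
#' @param human,mouse character vectors of equal length.
#' @return tibble of class `homolog_map` with columns human, mouse.
#' @export
homolog_map <- function(human, mouse) {
  out <- tibble::tibble(human = as.character(human), mouse = as.character(mouse))
  out <- out[!duplicated(out), , drop = FALSE]
  dup_h <- toupper(out$human) %in% toupper(out$human)[duplicated(toupper(out$human))]
  dup_m <- toupper(out$mouse) %in% toupper(out$mouse)[duplicated(toupper(out$mouse))]
  n_multi <- sum(dup_h | dup_m)
  if (n_multi > 0) {
    n_h <- length(unique(out$human[dup_h]))
    warning(sprintf("%d human symbol(s) multi-mapped; %d homolog row(s) dropped to keep the map one-to-one",
                    n_h, n_multi), call. = FALSE)
    out <- out[!(dup_h | dup_m), , drop = FALSE]
  }
  class(out) <- c("homolog_map", class(out))
  out
}
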