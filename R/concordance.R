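#' Pearson correlation with significance
#'
#' Sample Pearson r with the two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom (the
#' standard `cor.test` result). A perfect `|r| = 1` is reported with
#' p = 1e-300 (effectively zero, kept positive for downstream logs).
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("pearson_with_p requires n >= 3 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_with_p requires non-constant vectors", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 1e-300 else max(ct$p.value, 1e-300)
  list(r = r, p = p, n = n)
}

new_concordance_table <- function(df) {
  class(df) <- c("concordance_table", class(df))
  df
}

# resolve human module genes to mouse beta values through the homolog map
map_module_to_mouse <- function(genes_human, homologs, beta) {
  lut <- stats::setNames(homologs$mouse, toupper(homologs$human))
  mouse <- unname(lut[toupper(genes_human)])
  beta_lut <- stats::setNames(beta, toupper(names(beta)))
  b <- unname(beta_lut[toupper(mouse)])
  tibble::tibble(human = genes_human, mouse = mouse, beta = b)
}

#' Concordance of a mouse perturbation with human co-expression modules
#'
#' For every module: intersect the module's human genes with homolog-mapped
#' panel genes, then correlate the human log2 fold change (AD vs control)
#' against the mouse effect vector `beta(term)` over that intersection.
#' Modules whose intersection falls below `min_overlap` are reported with a
#' missing correlation and a reason code rather than silently dropped. Genes with mouse
#' beta exactly 0 (unfitted) or missing human log2FC are excluded pairwise;
#' `n_genes` records the final count used.
#'
#' @param effects an `effect_table`.
#' @param term perturbation term to score.
#' @param signature a [human_signature()].
#' @param modules a [module_set()].
#' @param homologs a [homolog_map()].
#' @param context signature context to use; default the single context
#'   present (per-module `region` annotations matching a context override
#'   this).
#' @param min_overlap minimum genes required for a correlation (default 5).
#' @return `concordance_table` tibble: term, context, kind = "module",
#'   cluster, r, p, n_genes, note.
#' @export
module_concordance <- function(effects, term, signature, modules, homologs,
                               context = NULL, min_overlap = 5) {
  stopifnot(inherits(modules, "module_set"))
  beta <- effect_vector(effects, term)
  contexts <- unique(signature$context)
  if (is.null(context)) {
    if (length(contexts) == 1) context <- contexts
    else if (is.null(modules$region))
      stop("signature has multiple contexts; supply 'context' or module regions",
           call. = FALSE)
  }
  rows <- lapply(names(modules$members), function(m) {
    ctx <- if (!is.null(modules$region) && modules$region[[m]] %in% contexts)
      modules$region[[m]] else context
    sig <- signature[signature$context == ctx, , drop = FALSE]
    sig_lut <- stats::setNames(sig$log2fc, toupper(sig$gene))
    mapped <- map_module_to_mouse(modules$members[[m]], homologs, beta)
    fc <- unname(sig_lut[toupper(mapped$human)])
    ok <- !is.na(mapped$beta) & mapped$beta != 0 & !is.na(fc)
    base <- tibble::tibble(term = term, context = m, kind = "module",
                           cluster = modules$clusters[[m]],
                           r = NA_real_, p = NA_real_,
                           n_genes = sum(ok), note = NA_character_)
    if (sum(ok) < min_overlap) {
      base$note <- "insufficient_overlap"
    } else if (stats::sd(mapped$beta[ok]) == 0 || stats::sd(fc[ok]) == 0) {
      base$note <- "constant_vector"
    } else {
      res <- pearson_with_p(fc[ok], mapped$beta[ok])
      base$r <- res$r; base$p <- res$p; base$n_genes <- res$n
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$r)))
    stop("no module had sufficient homolog overlap with the panel", call. = FALSE)
  new_concordance_table(out)
}

#' Concordance of a mouse perturbation with human disease-subtype signatures
#'
#' Identical to [module_concordance()] but with no module restriction: for
#' each subtype/cohort context the correlation spans all homolog-mapped
#' panel genes with a fitted mouse effect and a human log2 fold change.
#'
#' @inheritParams module_concordance
#' @param subtype_sigs a [human_signature()] with one context per
#'   subtype/cohort.
#' @return `concordance_table` tibble with kind = "subtype".
#' @export
subtype_concordance <- function(effects, term, subtype_sigs, homologs,
                                min_overlap = 5) {
  beta <- effect_vector(effects, term)
  lut <- stats::setNames(homologs$human, toupper(homologs$mouse))
  human_of_panel <- unname(lut[toupper(names(beta))])
  rows <- lapply(unique(subtype_sigs$context), function(ctx) {
    sig <- subtype_sigs[subtype_sigs$context == ctx, , drop = FALSE]
    sig_lut <- stats::setNames(sig$log2fc, toupper(sig$gene))
    fc <- unname(sig_lut[toupper(human_of_panel)])
    ok <- !is.na(fc) & !is.na(human_of_panel) & beta != 0
    base <- tibble::tibble(term = term, context = ctx, kind = "subtype",
                           cluster = NA_character_,
                           r = NA_real_, p = NA_real_,
                           n_genes = sum(ok), note = NA_character_)
    if (sum(ok) < min_overlap) {
      base$note <- "insufficient_overlap"
    } else {
      res <- pearson_with_p(fc[ok], unname(beta)[ok])
      base$r <- res$r; base$p <- res$p; base$n_genes <- res$n
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  if (all(is.na(out$r)))
    stop("no subtype context had sufficient homolog overlap with the panel", call. = FALSE)
  new_concordance_table(out)
}

#' Pairwise correlation between perturbation effect vectors
#'
#' Pearson correlation (with significance) between every pair of term
#' coefficient vectors over all panel genes — how similar two genetic
#' perturbations' transcriptomic fingerprints are.
#'
#' @param effects an `effect_table`.
#' @param terms terms to include; default every non-intercept term.
#' @return list with `r` and `p` (symmetric term x term matrices, unit
#'   diagonal) and `table` (a long-format `concordance_table`).
#' @export
cross_perturbation_correlation <- function(effects, terms = NULL) {
  terms <- terms %||% setdiff(unique(effects$term), "(Intercept)")
  if (length(terms) < 2)
    stop("cross-perturbation correlation requires >= 2 terms", call. = FALSE)
  vecs <- sapply(terms, function(tm) effect_vector(effects, tm))
  r_mat <- diag(1, length(terms)); dimnames(r_mat) <- list(terms, terms)
  p_mat <- matrix(NA_real_, length(terms), length(terms), dimnames = list(terms, terms))
  diag(p_mat) <- 1e-300
  rows <- list()
  for (i in seq_along(terms)) for (j in seq_along(terms)) {
    if (j <= i) next
    res <- pearson_with_p(vecs[, i], vecs[, j])
    r_mat[i, j] <- r_mat[j, i] <- res$r
    p_mat[i, j] <- p_mat[j, i] <- res$p
    rows[[length(rows) + 1]] <- tibble::tibble(
      term = terms[i], context = terms[j], kind = "perturbation",
      cluster = NA_character_, r = res$r, p = res$p, n_genes = res$n,
      note = NA_character_)
  }
  list(r = r_mat, p = p_mat, table = new_concordance_table(dplyr::bind_rows(rows)))
}
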