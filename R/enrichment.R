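#' Build a ranked gene list from an effect table
#'
#' Panel genes ranked by a factor's regression coefficients, descending.
#' Ties are broken by gene symbol order (recorded so rankings are
#' reproducible).
#'
#' @param effects an `effect_table`.
#' @param term factor whose coefficients provide the ranking scores.
#' @return named numeric vector of class `ranked_list`, sorted descending;
#'   attribute `tie_break = "gene_symbol"`.
#' @export
rank_genes <- function(effects, term) {
  beta <- effect_vector(effects, term)
  if (anyDuplicated(names(beta))) stop("duplicate genes in ranking", call. = FALSE)
  if (any(!is.finite(beta))) stop("ranking scores must be finite", call. = FALSE)
  ord <- order(-beta, names(beta))
  structure(beta[ord], class = "ranked_list", tie_break = "gene_symbol")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The running sum walks the ranked list: a hit adds `|score|^exponent`
#' normalized by the set's total weight, a miss subtracts `1/(N - k)` where
#' N is the list length and k the set size. The enrichment score is the
#' running-sum value of maximal absolute deviation from zero. Exponent 0
#' gives the classic (unweighted) Kolmogorov-Smirnov statistic.
#'
#' @param ranked a `ranked_list` (named scores, sorted descending) or any
#'   named numeric vector already in rank order.
#' @param gene_set character vector of gene symbols.
#' @param exponent weight exponent >= 0 (default 1, the standard weighting).
#' @return list with `es` and `profile` (the running sum, length N).
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  scores <- as.numeric(ranked)
  genes <- names(ranked)
  if (is.null(genes)) stop("ranked list must be named by gene", call. = FALSE)
  exponent <- check_nonneg(exponent, "exponent")
  hit <- genes %in% gene_set
  k <- sum(hit)
  N <- length(genes)
  if (k == 0) stop("gene set has no genes in the ranked list", call. = FALSE)
  if (k == N) stop("gene set equals the entire ranked list", call. = FALSE)
  w <- abs(scores)^exponent
  w_hit <- sum(w[hit])
  if (w_hit == 0) {            # all hit scores are zero: fall back to equal weights
    inc <- hit / k
  } else {
    inc <- ifelse(hit, w / w_hit, 0)
  }
  dec <- ifelse(hit, 0, 1 / (N - k))
  profile <- cumsum(inc - dec)
  es <- profile[which.max(abs(profile))]
  list(es = es, profile = profile)
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' For each set, the observed enrichment score is compared with a null built
#' by drawing `nperm` random same-size gene sets from the ranked list
#' (gene-label permutation; there are no sample phenotypes to permute in
#' preranked mode). The permutation p uses the same-signed null:
#' `p = (1 + #\{|null| >= |ES|\}) / (1 + #null)` over null scores sharing the
#' observed sign; NES is ES divided by the mean |null ES| of that sign.
#' Benjamini-Hochberg adjustment is applied across sets.
#'
#' @param ranked a `ranked_list`.
#' @param gene_sets named list of gene-symbol vectors.
#' @param nperm number of permutations (>= 100; default 10000 for analysis).
#' @param exponent weight exponent (default 1).
#' @param seed integer seed; identical seed gives an identical table.
#' @return tibble of class `enrichment_table`: set, size, es, nes, p, padj,
#'   leading_edge (comma-separated), note (reason for skipped sets).
#' @export
gsea_preranked <- function(ranked, gene_sets, nperm = 10000, exponent = 1,
                           seed = 1L) {
  nperm <- check_count(nperm, "nperm", min = 100L)
  genes <- names(ranked)
  N <- length(genes)
  rows <- vector("list", length(gene_sets))
  with_seed(seed, {
    for (i in seq_along(gene_sets)) {
      set_name <- names(gene_sets)[i]
      members <- intersect(gene_sets[[i]], genes)
      k <- length(members)
      if (k == 0 || k == N) {
        rows[[i]] <- tibble::tibble(set = set_name, size = k, es = NA_real_,
                                    nes = NA_real_, p = NA_real_, padj = NA_real_,
                                    leading_edge = NA_character_,
                                    note = if (k == 0) "no_overlap" else "set_equals_universe")
        next
      }
      obs <- enrichment_score(ranked, members, exponent)
      null_es <- vapply(seq_len(nperm), function(b) {
        enrichment_score(ranked, genes[sample.int(N, k)], exponent)$es
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(obs$es)]
      p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      nes <- if (length(same) > 0 && mean(abs(same)) > 0)
        obs$es / mean(abs(same)) else NA_real_
      peak <- which.max(abs(obs$profile))
      le <- if (obs$es >= 0) genes[seq_len(peak)] else genes[peak:N]
      le <- intersect(le, members)
      rows[[i]] <- tibble::tibble(set = set_name, size = k, es = obs$es,
                                  nes = nes, p = p, padj = NA_real_,
                                  leading_edge = paste(le, collapse = ","),
                                  note = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p)
  out$padj[ok] <- bh_adjust(out$p[ok])
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Directionally coherent genes per module
#'
#' For each module, the homolog-mapped genes whose mouse perturbation effect
#' and human log2 fold change share the same (non-zero) sign — the genes
#' driving a positive concordance.
#'
#' @inheritParams module_concordance
#' @return named list: module id -> tibble (human, mouse, beta, log2fc) of
#'   coherent genes (possibly zero rows).
#' @export
directional_coherent_genes <- function(effects, term, signature, modules,
                                       homologs, context = NULL) {
  stopifnot(inherits(modules, "module_set"))
  beta <- effect_vector(effects, term)
  contexts <- unique(signature$context)
  if (is.null(context) && length(contexts) == 1) context <- contexts
  out <- lapply(names(modules$members), function(m) {
    ctx <- if (!is.null(modules$region) && modules$region[[m]] %in% contexts)
      modules$region[[m]] else context
    sig <- signature[signature$context == ctx, , drop = FALSE]
    sig_lut <- stats::setNames(sig$log2fc, toupper(sig$gene))
    mapped <- map_module_to_mouse(modules$members[[m]], homologs, beta)
    mapped$log2fc <- unname(sig_lut[toupper(mapped$human)])
    keep <- !is.na(mapped$beta) & !is.na(mapped$log2fc) &
      mapped$beta != 0 & mapped$log2fc != 0 &
      sign(mapped$beta) == sign(mapped$log2fc)
    mapped[keep, , drop = FALSE]
  })
  stats::setNames(out, names(modules$members))
}

#' Hypergeometric overrepresentation test
#'
#' One-sided upper-tail hypergeometric p for the overlap of a gene subset
#' with each term set, relative to a finite universe, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param subset character vector of selected genes (must lie in `universe`).
#' @param universe character vector, the finite gene universe.
#' @param term_sets named list of gene sets (intersected with the universe).
#' @return tibble: set, set_size, overlap, p, padj.
#' @export
overrepresentation_test <- function(subset, universe, term_sets) {
  universe <- unique(universe)
  subset <- unique(subset)
  if (length(subset) == 0) stop("subset is empty", call. = FALSE)
  if (length(setdiff(subset, universe)) > 0)
    stop("subset must be contained in the universe", call. = FALSE)
  rows <- lapply(names(term_sets), function(nm) {
    set <- intersect(unique(term_sets[[nm]]), universe)
    ov <- length(intersect(subset, set))
    p <- stats::phyper(ov - 1, length(set), length(universe) - length(set),
                       length(subset), lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = length(set), overlap = ov, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$padj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1. Inputs
#' must lie in (0, 1].
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}
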