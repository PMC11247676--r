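# Independent oracles, written before the implementations they check and
# kept free of package internals.

# textbook Pearson r and t-based two-sided p, computed from first principles
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p = p)
}

# brute-force unweighted (exponent 0) KS running sum: explicit loop over
# positions using hit/miss fractions, no cumsum, no shared code
oracle_es_unweighted <- function(genes_ranked, gene_set) {
  k <- sum(genes_ranked %in% gene_set)
  N <- length(genes_ranked)
  running <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (genes_ranked[i] %in% gene_set) running <- running + 1 / k
    else running <- running - 1 / (N - k)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# small synthetic experiment used across tests; arguments override defaults
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60, n_housekeeping = 6,
         genotype_factors = c("5xFAD", "LOAD1", "Abca7", "Plcg2"),
         animals_per_group_per_sex = 3, ages = 4, n_batches = 2),
    list(...))
  do.call(sim_config, args)
}

# effect table wrapping a known coefficient vector, for concordance tests
truth_effect_table <- function(beta, term = "Abca7") {
  out <- tibble::tibble(gene = names(beta), term = term, beta = unname(beta),
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        df = NA_integer_, resid_sd = NA_real_)
  class(out) <- c("effect_table", class(out))
  out
}
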