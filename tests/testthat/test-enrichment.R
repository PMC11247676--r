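ranked_fixture <- function(n = 20, seed = 1) {
  set.seed(seed)
  scores <- sort(rnorm(n), decreasing = TRUE)
  names(scores) <- sprintf("g%02d", seq_len(n))
  structure(scores, class = "ranked_list")
}

test_that("enrichment score hits the closed-form extremes and worked example", {
  ranked <- ranked_fixture(10)
  expect_equal(enrichment_score(ranked, names(ranked)[1:3], exponent = 0)$es, 1.0)
  expect_equal(enrichment_score(ranked, names(ranked)[8:10], exponent = 0)$es, -1.0)

  # N = 5, hits at positions 1 and 4, exponent 0
  r5 <- structure(c(5, 4, 3, 2, 1), names = paste0("g", 1:5), class = "ranked_list")
  res <- enrichment_score(r5, c("g1", "g4"), exponent = 0)
  expect_equal(res$profile, c(1/2, 1/6, -1/6, 1/3, 0), tolerance = 1e-12)
  expect_equal(res$es, 0.5)

  expect_error(enrichment_score(ranked, "absent"), "no genes")
  expect_error(enrichment_score(ranked, names(ranked)), "entire")
})

test_that("unweighted score matches the brute-force oracle on short lists", {
  set.seed(101)
  for (i in 1:200) {
    N <- sample(3:12, 1)
    genes <- sprintf("x%02d", 1:N)
    scores <- structure(sort(rnorm(N), decreasing = TRUE), names = genes,
                        class = "ranked_list")
    k <- sample(seq_len(N - 1), 1)
    set <- sample(genes, k)
    expect_equal(enrichment_score(scores, set, exponent = 0)$es,
                 oracle_es_unweighted(genes, set), tolerance = 1e-12)
  }
})

test_that("list reversal mirrors the unweighted score", {
  # reversal always preserves |ES|; it negates the sign whenever the maximal
  # absolute deviation is attained with a unique sign (a palindromic hit
  # pattern is its own reversal, so a +max/-min tie cannot flip sign)
  set.seed(102)
  for (i in 1:100) {
    N <- sample(6:12, 1)
    genes <- sprintf("x%02d", 1:N)
    scores <- structure(sort(rnorm(N), decreasing = TRUE), names = genes,
                        class = "ranked_list")
    rev_scores <- structure(rev(unclass(scores)), class = "ranked_list")
    set <- sample(genes, sample(seq_len(N - 1), 1))
    fwd <- enrichment_score(scores, set, exponent = 0)
    bwd <- enrichment_score(rev_scores, set, exponent = 0)
    expect_equal(abs(bwd$es), abs(fwd$es), tolerance = 1e-12)
    sign_unique <- abs(max(fwd$profile) + min(fwd$profile)) > 1e-12
    if (sign_unique)
      expect_equal(bwd$es, -fwd$es, tolerance = 1e-12)
  }
})

test_that("weighted score agrees with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(103)
  for (i in 1:25) {
    N <- 50
    scores <- structure(sort(rnorm(N, sd = 2), decreasing = TRUE),
                        names = sprintf("x%02d", 1:N), class = "ranked_list")
    set <- sample(names(scores), 8)
    ours <- enrichment_score(scores, set, exponent = 1)$es
    ref <- fgsea::calcGseaStat(unclass(scores),
                               selectedStats = which(names(scores) %in% set),
                               gseaParam = 1, scoreType = "std")
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("preranked GSEA flags extreme sets and is seed-deterministic", {
  set.seed(104)
  scores <- structure(sort(rnorm(200), decreasing = TRUE),
                      names = sprintf("g%03d", 1:200), class = "ranked_list")
  sets <- list(top = names(scores)[1:10],
               random = sample(names(scores), 15),
               none = c("absent1", "absent2"))
  tab <- gsea_preranked(scores, sets, nperm = 1000, seed = 5)
  top <- tab[tab$set == "top", ]
  expect_lt(top$p, 5e-3)
  expect_gt(top$nes, 1)
  expect_gt(top$es, 0)
  expect_identical(tab$note[tab$set == "none"], "no_overlap")
  expect_true(all(tab$padj >= tab$p, na.rm = TRUE))
  expect_true(all(tab$p >= 1 / 1001, na.rm = TRUE))
  expect_true(all(sign(tab$nes) == sign(tab$es), na.rm = TRUE))
  tab2 <- gsea_preranked(scores, sets, nperm = 1000, seed = 5)
  expect_identical(tab, tab2)
  expect_false(identical(tab, gsea_preranked(scores, sets, nperm = 1000, seed = 6)))
})

test_that("GSEA p-values ignore the labels of genes outside every set", {
  set.seed(105)
  scores <- structure(sort(rnorm(100), decreasing = TRUE),
                      names = sprintf("g%03d", 1:100), class = "ranked_list")
  sets <- list(s1 = names(scores)[seq(5, 60, by = 5)])
  tab1 <- gsea_preranked(scores, sets, nperm = 500, seed = 9)
  relabel <- names(scores)
  outside <- !relabel %in% sets$s1
  relabel[outside] <- paste0("renamed_", relabel[outside])
  scores2 <- structure(unclass(scores), names = relabel, class = "ranked_list")
  tab2 <- gsea_preranked(scores2, sets, nperm = 500, seed = 9)
  expect_equal(tab2$es, tab1$es)
  expect_equal(tab2$p, tab1$p)
  expect_equal(tab2$nes, tab1$nes)
})

test_that("leading edge collects the set genes up to the score peak", {
  scores <- structure(c(3, 2.5, 2, 1, 0.5, -0.5, -1, -2),
                      names = paste0("g", 1:8), class = "ranked_list")
  tab <- gsea_preranked(scores, list(s = c("g1", "g3", "g8")), nperm = 200, seed = 2)
  le <- strsplit(tab$leading_edge, ",")[[1]]
  expect_true(all(le %in% c("g1", "g3", "g8")))
  expect_gt(length(le), 0)
})

test_that("directional coherence applies the sign rule", {
  genes <- c("Up", "Down", "Mixed", "Zerob", "Zeroh")
  beta <- stats::setNames(c(0.5, -0.4, 0.3, 0, 0.2), genes)
  eff <- truth_effect_table(beta, term = "T")
  ms <- module_set(list(M = toupper(genes)), c(M = "A"))
  sig <- human_signature(context = "ctx", gene = toupper(genes),
                         log2fc = c(0.7, -0.2, -0.6, 0.4, 0))
  hm <- synthetic_homolog_map(genes)
  coh <- directional_coherent_genes(eff, "T", sig, ms, hm)
  expect_setequal(coh$M$mouse, c("Up", "Down"))
})

test_that("overrepresentation test reproduces exact hypergeometric values", {
  universe4 <- c("a", "b", "c", "d")
  tab <- overrepresentation_test(c("a", "b"), universe4, list(s = c("a", "b")))
  expect_equal(tab$p, 1 / 6)

  universe10 <- letters[1:10]
  tab2 <- overrepresentation_test(letters[1:5], universe10,
                                  list(s = letters[1:5]))
  expect_equal(tab2$p, 1 / choose(10, 5))

  tab3 <- overrepresentation_test(c("a", "b"), universe4, list(s = c("c", "d")))
  expect_equal(tab3$p, 1.0)

  expect_error(overrepresentation_test(character(), universe4, list(s = "a")),
               "empty")
  expect_error(overrepresentation_test("z", universe4, list(s = "a")),
               "universe")
})

test_that("BH adjustment reproduces step-up values and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(106)
  p <- sort(runif(50))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj) >= -1e-15))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
})

test_that("gene ranking sorts by coefficient with symbol tie-break", {
  eff <- truth_effect_table(stats::setNames(c(1, 2, 2, -1), c("d", "b", "a", "c")),
                            term = "T")
  ranked <- rank_genes(eff, "T")
  expect_equal(names(ranked), c("a", "b", "d", "c"))
  expect_identical(attr(ranked, "tie_break"), "gene_symbol")
})
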