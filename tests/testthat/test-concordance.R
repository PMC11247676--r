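test_that("pearson_with_p matches closed forms and the textbook oracle", {
  expect_equal(pearson_with_p(1:4, 1:4)$r, 1.0)
  expect_equal(pearson_with_p(1:4, 1:4)$p, 1e-300)
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1.0)

  res <- pearson_with_p(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  ora <- oracle_pearson(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$r, ora$r, tolerance = 1e-12)
  expect_equal(res$p, ora$p, tolerance = 1e-12)

  set.seed(91)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_with_p(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate correlation inputs raise distinguishable errors", {
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")
  expect_error(pearson_with_p(c(1, 1, 1), 1:3), "non-constant")
  expect_error(pearson_with_p(1:3, 1:4), "equal length")
})

sim_fixture <- function() {
  cfg <- sim_config(n_genes = 200, n_housekeeping = 6,
                    genotype_factors = c("5xFAD", "LOAD1", "Abca7"),
                    animals_per_group_per_sex = 3, ages = 4, n_batches = 2,
                    effect_sparsity = 1, seed = 92)
  sim <- simulate_experiment(cfg)
  panel <- rownames(sim$truth$beta_true)[!sim$counts$housekeeping]
  list(sim = sim, panel = panel,
       homologs = synthetic_homolog_map(rownames(sim$truth$beta_true)),
       eff = truth_effect_table(sim$truth$beta_true[, "Abca7"]))
}

test_that("module concordance recovers an exactly planted signature", {
  fx <- sim_fixture()
  ms <- make_module_set(6, toupper(fx$panel), seed = 5, size_range = c(15, 30),
                        overlap = FALSE)
  sig <- plant_human_signature(fx$sim$truth, "Abca7", ms, target_r = 1,
                               noise_sd = 0, seed = 1)
  conc <- module_concordance(fx$eff, "Abca7", sig, ms, fx$homologs)
  expect_equal(nrow(conc), 6)
  expect_true(all(abs(conc$r - 1) < 1e-12))
  expect_true(all(conc$p < 1e-6))
  expect_identical(unname(conc$cluster), unname(ms$clusters[conc$context]))
})

test_that("modules without homologs are flagged, not dropped", {
  fx <- sim_fixture()
  ms_members <- list(M1 = toupper(fx$panel[1:20]),
                     M2 = sprintf("NOHOM%02d", 1:15))
  ms <- module_set(ms_members, c(M1 = "A", M2 = "B"))
  sig <- human_signature(context = "ctx",
                         gene = c(toupper(fx$panel[1:20]), sprintf("NOHOM%02d", 1:15)),
                         log2fc = rnorm(35))
  conc <- module_concordance(fx$eff, "Abca7", sig, ms, fx$homologs)
  expect_equal(nrow(conc), 2)
  expect_identical(conc$note[conc$context == "M2"], "insufficient_overlap")
  expect_true(is.na(conc$r[conc$context == "M2"]))
  expect_false(is.na(conc$r[conc$context == "M1"]))
})

test_that("planted module concordance is recovered on average", {
  fx <- sim_fixture()
  ms <- make_module_set(3, toupper(fx$panel), seed = 6, size_range = c(50, 50),
                        overlap = FALSE)
  rs <- vapply(1:100, function(s) {
    sig <- plant_human_signature(fx$sim$truth, "Abca7", ms, target_r = 0.6,
                                 noise_sd = 1, seed = s)
    mean(module_concordance(fx$eff, "Abca7", sig, ms, fx$homologs)$r)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.1)
})

test_that("affine maps of the human signature transform r as expected", {
  fx <- sim_fixture()
  ms <- make_module_set(4, toupper(fx$panel), seed = 7, size_range = c(20, 20),
                        overlap = FALSE)
  sig <- plant_human_signature(fx$sim$truth, "Abca7", ms, target_r = 0.6,
                               noise_sd = 1, seed = 3)
  pos <- sig; pos$log2fc <- 2.5 * pos$log2fc + 0.7
  neg <- sig; neg$log2fc <- -1.5 * neg$log2fc + 0.2
  base <- module_concordance(fx$eff, "Abca7", sig, ms, fx$homologs)
  up <- module_concordance(fx$eff, "Abca7", pos, ms, fx$homologs)
  dn <- module_concordance(fx$eff, "Abca7", neg, ms, fx$homologs)
  expect_equal(up$r, base$r, tolerance = 1e-12)
  expect_equal(dn$r, -base$r, tolerance = 1e-12)
})

test_that("module concordance equals a direct correlation on the intersection", {
  fx <- sim_fixture()
  ms <- make_module_set(1, toupper(fx$panel), seed = 8, size_range = c(25, 25))
  sig <- plant_human_signature(fx$sim$truth, "Abca7", ms, target_r = 0.4,
                               noise_sd = 1, seed = 4)
  conc <- module_concordance(fx$eff, "Abca7", sig, ms, fx$homologs)
  genes_h <- ms$members[[1]]
  beta <- fx$sim$truth$beta_true[, "Abca7"]
  b <- beta[match(genes_h, toupper(names(beta)))]
  fc <- sig$log2fc[match(genes_h, sig$gene)]
  direct <- pearson_with_p(fc, unname(b))
  expect_equal(conc$r, direct$r, tolerance = 1e-12)
  expect_equal(conc$p, direct$p, tolerance = 1e-12)
  expect_equal(conc$n_genes, direct$n)
})

test_that("subtype concordance spans the panel and mirrors rescaled signatures", {
  fx <- sim_fixture()
  beta <- fx$sim$truth$beta_true[, "Abca7"]
  sig <- human_signature(context = rep(c("subA", "subB"), each = length(beta)),
                         gene = rep(toupper(names(beta)), 2),
                         log2fc = c(3 * unname(beta), 3 * unname(beta)))
  conc <- subtype_concordance(fx$eff, "Abca7", sig, fx$homologs)
  expect_equal(nrow(conc), 2)
  expect_true(all(abs(conc$r - 1) < 1e-12))
  # both contexts share one signature: identical rows
  expect_equal(conc$r[1], conc$r[2])
  expect_equal(conc$n_genes[1], conc$n_genes[2])
})

test_that("independent subtype signatures correlate near zero on large panels", {
  cfg <- sim_config(n_genes = 500, n_housekeeping = 6,
                    genotype_factors = c("5xFAD", "LOAD1", "Abca7"),
                    animals_per_group_per_sex = 3, ages = 4, n_batches = 2,
                    effect_sparsity = 1, seed = 93)
  sim <- simulate_experiment(cfg)
  homologs <- synthetic_homolog_map(rownames(sim$truth$beta_true))
  eff <- truth_effect_table(sim$truth$beta_true[, "Abca7"])
  hits <- vapply(1:100, function(s) {
    sig <- make_subtype_signatures(sim$truth, "Abca7", c(null = 0),
                                   noise_sd = 1, seed = 1000 + s)
    abs(subtype_concordance(eff, "Abca7", sig, homologs)$r) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cross-perturbation correlation is symmetric with unit diagonal", {
  set.seed(95)
  genes <- sprintf("Gene%03d", 1:500)
  eff <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(tm)
    truth_effect_table(stats::setNames(rnorm(500), genes), term = tm)))
  class(eff) <- c("effect_table", class(eff))
  cp <- cross_perturbation_correlation(eff, terms = c("A", "B", "C"))
  expect_equal(cp$r, t(cp$r))
  expect_equal(unname(diag(cp$r)), rep(1, 3))
  expect_true(all(abs(cp$r[upper.tri(cp$r)]) < 0.15))
  # duplicated term vectors correlate exactly
  eff2 <- dplyr::bind_rows(eff, truth_effect_table(
    stats::setNames(eff$beta[eff$term == "A"], genes), term = "A2"))
  cp2 <- cross_perturbation_correlation(eff2, terms = c("A", "A2"))
  expect_equal(cp2$r["A", "A2"], 1.0)
  expect_error(cross_perturbation_correlation(eff, terms = "A"), ">= 2 terms")
})

test_that("independent effect vectors have small mean absolute correlation", {
  set.seed(96)
  mean_abs <- vapply(1:100, function(i) {
    eff <- dplyr::bind_rows(lapply(c("A", "B"), function(tm)
      truth_effect_table(stats::setNames(rnorm(500), sprintf("G%03d", 1:500)),
                         term = tm)))
    abs(cross_perturbation_correlation(eff, terms = c("A", "B"))$r["A", "B"])
  }, numeric(1))
  expect_lt(mean(mean_abs), 0.1)
})
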