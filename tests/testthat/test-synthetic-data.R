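test_that("config validation names the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(effect_sparsity = 1.5), "effect_sparsity")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_housekeeping = 770), "n_housekeeping")
})

test_that("simulation is a pure function of (config, seed)", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$beta_true, b$truth$beta_true)
  c <- simulate_experiment(tiny_config(seed = 12))
  expect_false(identical(a$counts$values, c$counts$values))
})

test_that("housekeeping genes carry zero planted effects and unit cross-group ratios", {
  sim <- simulate_experiment(tiny_config(seed = 3))
  hk <- names(sim$counts$housekeeping)[sim$counts$housekeeping]
  expect_length(hk, 6)
  expect_true(all(sim$truth$beta_true[hk, ] == 0))
  expect_true(all(sim$truth$batch_shifts[hk, ] == 0))
  expect_true(all(sim$truth$sex_effects[hk] == 0))
})

test_that("sample grid has the configured cell counts and metadata fields", {
  cfg <- tiny_config(seed = 5)
  sim <- simulate_experiment(cfg)
  cells <- table(sim$meta$strain, sim$meta$sex)
  expect_true(all(cells == cfg$animals_per_group_per_sex))
  expect_setequal(unique(sim$meta$strain),
                  c("B6J", "5xFAD", "LOAD1", "LOAD1.Abca7", "LOAD1.Plcg2"))
  expect_setequal(unique(sim$meta$sex), c("female", "male"))
  expect_true(all(sim$meta$age_months == 4))
  expect_length(unique(sim$meta$batch), cfg$n_batches)
})

test_that("zero planted effects leave genotype group means equal up to noise", {
  cfg <- sim_config(n_genes = 120, n_housekeeping = 6,
                    genotype_factors = c("5xFAD", "LOAD1"),
                    animals_per_group_per_sex = 6, ages = 4, n_batches = 1,
                    effect_scale = 0, batch_shift_scale = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  logc <- log2(sim$counts$values + 1)
  g1 <- sim$meta$sample[sim$meta$strain == "B6J"]
  g2 <- sim$meta$sample[sim$meta$strain == "LOAD1"]
  pvals <- apply(logc, 1, function(v) stats::t.test(v[g1], v[g2])$p.value)
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("large cohorts at near-Poisson dispersion recover planted fold changes", {
  # 50 animals/group/sex, strong effects, tiny dispersion: the sample log2
  # fold change of each affected gene should sit within +/-0.2 of truth
  cfg <- sim_config(n_genes = 200, n_housekeeping = 6,
                    genotype_factors = c("5xFAD", "LOAD1"),
                    animals_per_group_per_sex = 50, ages = 4, n_batches = 1,
                    effect_sparsity = 0.3, effect_scale = 1,
                    batch_shift_scale = 0, dispersion = 1e-4, seed = 31)
  sim <- simulate_experiment(cfg)
  logc <- log2(sim$counts$values)
  ctrl <- sim$meta$sample[sim$meta$strain == "B6J"]
  trt <- sim$meta$sample[sim$meta$strain == "LOAD1"]
  lfc <- rowMeans(logc[, trt]) - rowMeans(logc[, ctrl])
  affected <- sim$truth$beta_true[, "LOAD1"] != 0
  err <- abs(lfc[affected] - sim$truth$beta_true[affected, "LOAD1"])
  expect_gte(mean(err <= 0.2), 0.90)
})

test_that("planted-effect recovery improves with cohort size", {
  rmse_at <- function(n, seed) {
    cfg <- sim_config(n_genes = 100, n_housekeeping = 6,
                      genotype_factors = c("5xFAD", "LOAD1"),
                      animals_per_group_per_sex = n, ages = 4, n_batches = 1,
                      effect_sparsity = 0.3, effect_scale = 0.5,
                      batch_shift_scale = 0, seed = seed)
    sim <- simulate_experiment(cfg)
    lm2 <- normalize_experiment(sim$counts, sim$meta, correct_batch = FALSE)
    fit <- fit_gene_effects(lm2, build_design(sim$meta, default_background_map(cfg$genotype_factors)))
    bhat <- fit$beta[fit$term == "LOAD1"][match(rownames(sim$truth$beta_true),
                                                fit$gene[fit$term == "LOAD1"])]
    sqrt(mean((bhat - sim$truth$beta_true[, "LOAD1"])^2))
  }
  seeds <- 101:120
  rmse6 <- mean(vapply(seeds, function(s) rmse_at(6, s), numeric(1)))
  rmse24 <- mean(vapply(seeds, function(s) rmse_at(24, s), numeric(1)))
  expect_lt(rmse24, rmse6)
})

test_that("module sets respect sizes, labels, and seeded determinism", {
  genes <- sprintf("GENE%03d", 1:300)
  ms <- make_module_set(30, genes, clusters = LETTERS[1:5], seed = 9)
  expect_length(ms, 30)
  expect_true(all(lengths(ms$members) >= 10 & lengths(ms$members) <= 100))
  expect_setequal(unique(ms$clusters), LETTERS[1:5])
  expect_true(all(vapply(ms$members, anyDuplicated, integer(1)) == 0))
  ms2 <- make_module_set(30, genes, clusters = LETTERS[1:5], seed = 9)
  expect_identical(ms$members, ms2$members)
  # degenerate: module equals the whole universe
  one <- make_module_set(1, genes[1:10], clusters = "A", seed = 1,
                         size_range = c(10, 10))
  expect_setequal(one$members[[1]], genes[1:10])
  expect_error(make_module_set(2, genes[1:5], seed = 1, size_range = c(10, 10)),
               "larger than gene universe")
})

test_that("planted signatures hit their target correlation in expectation", {
  cfg <- sim_config(n_genes = 400, n_housekeeping = 6,
                    genotype_factors = c("5xFAD", "LOAD1", "Abca7"),
                    animals_per_group_per_sex = 3, ages = 4, n_batches = 2,
                    effect_sparsity = 1, seed = 41)
  sim <- simulate_experiment(cfg)
  panel <- rownames(sim$truth$beta_true)[!sim$counts$housekeeping]
  homologs <- synthetic_homolog_map(rownames(sim$truth$beta_true))
  beta <- sim$truth$beta_true[, "Abca7"]

  # zero-noise limit: exact positive affine image, r = 1
  ms <- make_module_set(5, toupper(panel), seed = 7, size_range = c(30, 30),
                        overlap = FALSE)
  sig <- plant_human_signature(sim$truth, "Abca7", ms, target_r = 1,
                               noise_sd = 0, seed = 1)
  eff <- truth_effect_table(beta)
  conc <- module_concordance(eff, "Abca7", sig, ms, homologs)
  expect_true(all(abs(conc$r - 1) < 1e-12))

  # calibration: mean measured r over 200 seeds near 0 and near 0.6
  measure <- function(target, size, seeds) {
    ms <- make_module_set(3, toupper(panel), seed = 13,
                          size_range = c(size, size), overlap = FALSE)
    mean(vapply(seeds, function(s) {
      sig <- plant_human_signature(sim$truth, "Abca7", ms, target_r = target,
                                   noise_sd = 1, seed = s)
      mean(module_concordance(eff, "Abca7", sig, ms, homologs)$r)
    }, numeric(1)))
  }
  expect_lt(abs(measure(0, 30, 1:200)), 0.05)
  expect_lt(abs(measure(0.6, 50, 1:200) - 0.6), 0.05)
})

test_that("target_r outside [-1,1] and degenerate noise are rejected", {
  sim <- simulate_experiment(tiny_config(seed = 2, effect_sparsity = 1))
  ms <- make_module_set(2, toupper(rownames(sim$truth$beta_true)), seed = 1,
                        size_range = c(10, 10))
  expect_error(plant_human_signature(sim$truth, "Abca7", ms, target_r = 1.2),
               "\\[-1, 1\\]")
  expect_error(plant_human_signature(sim$truth, "Abca7", ms, target_r = 0.5,
                                     noise_sd = 0), "noise_sd")
  expect_error(plant_human_signature(sim$truth, "NoSuch", ms, target_r = 0.5),
               "NoSuch")
})
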