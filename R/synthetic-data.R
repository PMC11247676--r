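#' Default genotype factors of the panel study design
#'
#' Two whole-model factors carried on the B6J background (the amyloidogenic
#' 5xFAD transgene and the sensitized LOAD1 background, i.e. humanized APOE4
#' plus Trem2*R47H) and eleven candidate-variant factors carried on the LOAD1
#' background.
#'
#' @return character vector of 13 factor names.
#' @export
default_genotype_factors <- function() {
  c("5xFAD", "LOAD1",
    "Abca7", "Ceacam1", "Mthfr", "Shc2", "Slc6a17", "Clasp2",
    "Sorl1", "Meox2", "Snx1", "Plcg2", "Mtmr4")
}

#' Default strain-to-background control hierarchy
#'
#' B6J is the baseline; 5xFAD and LOAD1 are compared against B6J; each
#' variant strain (named `LOAD1.<factor>`) is compared against LOAD1, so a
#' variant coefficient estimates the deviation from its sensitized
#' background.
#'
#' @param factors genotype factor names (default [default_genotype_factors()]).
#' @return named character vector: strain -> background strain, with the
#'   baseline strain mapping to `NA`.
#' @export
default_background_map <- function(factors = default_genotype_factors()) {
  variants <- setdiff(factors, c("5xFAD", "LOAD1"))
  strains <- c("B6J", intersect(c("5xFAD", "LOAD1"), factors),
               if (length(variants)) paste0("LOAD1.", variants))
  bg <- c(NA_character_,
          rep("B6J", length(intersect(c("5xFAD", "LOAD1"), factors))),
          rep("LOAD1", length(variants)))
  stats::setNames(bg, strains)
}

#' Simulation configuration for a synthetic panel experiment
#'
#' Defines the generative model: negative-binomial counts whose log2 mean is
#' baseline + design effects + sex effect + lane batch shift. Defaults mirror
#' the panel study design: a ~770-gene panel with 10 housekeeping genes, 13
#' genotype factors plus sex, two age cohorts (4 and 12 months) and about six
#' animals per group per sex.
#'
#' @param n_genes total number of panel genes (housekeeping included).
#' @param n_housekeeping number of designated housekeeping genes; these
#'   receive zero planted effects of any kind by construction.
#' @param genotype_factors character vector of factor names; `5xFAD` and
#'   `LOAD1` ride on the B6J background, all others on LOAD1.
#' @param animals_per_group_per_sex animals per (strain, sex, age) cell.
#' @param ages age cohorts in months (the 8-month cohort can be generated
#'   but is excluded from the default).
#' @param n_batches number of lane/run batches per age cohort.
#' @param effect_sparsity fraction of non-housekeeping genes affected by each
#'   factor (and by sex).
#' @param effect_scale standard deviation of planted effects, log2 units.
#' @param batch_shift_scale standard deviation of per-gene batch shifts,
#'   log2 units.
#' @param dispersion negative-binomial dispersion (1/size); variance is
#'   mu + dispersion * mu^2. The default 0.02 (biological CV ~14%) reflects
#'   the low replicate variability of inbred mice under controlled housing.
#' @param baseline_log2_mean_range range of per-gene baseline log2 means.
#' @param seed integer seed; identical (config, seed) gives identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 770,
                       n_housekeeping = 10,
                       genotype_factors = default_genotype_factors(),
                       animals_per_group_per_sex = 6,
                       ages = c(4, 12),
                       n_batches = 4,
                       effect_sparsity = 0.1,
                       effect_scale = 0.5,
                       batch_shift_scale = 0.25,
                       dispersion = 0.02,
                       baseline_log2_mean_range = c(5, 10),
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_housekeeping = check_count(n_housekeeping, "n_housekeeping"),
    genotype_factors = as.character(genotype_factors),
    animals_per_group_per_sex = check_count(animals_per_group_per_sex,
                                            "animals_per_group_per_sex"),
    ages = as.numeric(ages),
    n_batches = check_count(n_batches, "n_batches"),
    effect_sparsity = check_fraction(effect_sparsity, "effect_sparsity"),
    effect_scale = check_nonneg(effect_scale, "effect_scale"),
    batch_shift_scale = check_nonneg(batch_shift_scale, "batch_shift_scale"),
    dispersion = check_positive(dispersion, "dispersion"),
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$genotype_factors) < 1 || anyDuplicated(cfg$genotype_factors))
    abort_cfg("genotype_factors", "must be a non-empty vector of unique factor names")
  if (cfg$n_housekeeping >= cfg$n_genes)
    abort_cfg("n_housekeeping", "must be smaller than n_genes")
  if (length(cfg$ages) < 1 || any(!is.finite(cfg$ages)) || any(cfg$ages <= 0))
    abort_cfg("ages", "must be positive ages in months")
  if (length(cfg$baseline_log2_mean_range) != 2 ||
      any(!is.finite(cfg$baseline_log2_mean_range)) ||
      diff(cfg$baseline_log2_mean_range) < 0)
    abort_cfg("baseline_log2_mean_range", "must be a non-decreasing interval c(lo, hi)")
  structure(cfg, class = "sim_config")
}

sim_gene_names <- function(cfg) {
  n_target <- cfg$n_genes - cfg$n_housekeeping
  c(sprintf("Gene%04d", seq_len(n_target)),
    sprintf("Hkg%02d", seq_len(cfg$n_housekeeping)))
}

sim_strains <- function(cfg) names(default_background_map(cfg$genotype_factors))

#' Simulate a panel count experiment with known ground truth
#'
#' Draws negative-binomial counts whose log2 mean is
#' `baseline + design %*% beta_true + male * sex_effect + batch_shift`, for a
#' fully crossed (strain x sex x age) design with the configured number of
#' animals per cell and random lane assignment within each age cohort.
#' Housekeeping genes receive no genotype, sex, or batch effects, so their
#' expected cross-group ratios are 1.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]), `meta` (tibble:
#'   sample, strain, sex, age_months, batch), and `truth` (class `sim_truth`:
#'   `beta_true` gene x factor matrix, `sex_effects` gene vector,
#'   `batch_shifts` gene x batch matrix, `baseline` gene vector).
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sim_gene_names(cfg)
    is_hk <- grepl("^Hkg", genes)
    n_genes <- cfg$n_genes
    strains <- sim_strains(cfg)
    bg_map <- default_background_map(cfg$genotype_factors)

    # ground truth: sparse, symmetric-around-zero planted effects
    baseline <- stats::runif(n_genes, cfg$baseline_log2_mean_range[1],
                             cfg$baseline_log2_mean_range[2])
    beta_true <- matrix(0, n_genes, length(cfg$genotype_factors),
                        dimnames = list(genes, cfg$genotype_factors))
    for (f in cfg$genotype_factors) {
      hit <- !is_hk & stats::runif(n_genes) < cfg$effect_sparsity
      beta_true[hit, f] <- stats::rnorm(sum(hit), 0, cfg$effect_scale)
    }
    sex_effects <- numeric(n_genes)
    hit <- !is_hk & stats::runif(n_genes) < cfg$effect_sparsity
    sex_effects[hit] <- stats::rnorm(sum(hit), 0, cfg$effect_scale)
    names(sex_effects) <- genes
    batch_names <- sprintf("batch%02d", seq_len(cfg$n_batches))
    batch_shifts <- matrix(0, n_genes, cfg$n_batches,
                           dimnames = list(genes, batch_names))
    if (cfg$batch_shift_scale > 0)
      batch_shifts[!is_hk, ] <- stats::rnorm(sum(!is_hk) * cfg$n_batches,
                                             0, cfg$batch_shift_scale)
    names(baseline) <- genes

    # sample grid: strain x sex x age, n animals per cell
    grid <- expand.grid(animal = seq_len(cfg$animals_per_group_per_sex),
                        sex = c("female", "male"),
                        strain = strains,
                        age_months = cfg$ages,
                        stringsAsFactors = FALSE)
    n_samp <- nrow(grid)
    meta <- tibble::tibble(
      sample = sprintf("S%04d", seq_len(n_samp)),
      strain = as.character(grid$strain),
      sex = as.character(grid$sex),
      age_months = as.numeric(grid$age_months),
      batch = NA_character_
    )
    # lanes assigned at random within each age cohort
    for (a in cfg$ages) {
      idx <- which(meta$age_months == a)
      meta$batch[idx] <- sample(rep_len(batch_names, length(idx)))
    }

    # per-sample factor loadings from the control hierarchy
    term_mat <- matrix(0, n_samp, length(cfg$genotype_factors),
                       dimnames = list(meta$sample, cfg$genotype_factors))
    for (i in seq_len(n_samp)) {
      s <- meta$strain[i]
      while (!is.na(s) && s != "B6J") {
        term <- sub("^LOAD1\\.", "", s)
        term_mat[i, term] <- 1
        s <- bg_map[[s]]
      }
    }

    log2mu <- baseline +
      beta_true %*% t(term_mat) +
      outer(sex_effects, as.numeric(meta$sex == "male")) +
      batch_shifts[, match(meta$batch, batch_names), drop = FALSE]
    mu <- 2^log2mu
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                     n_genes, n_samp, dimnames = list(genes, meta$sample))

    truth <- structure(list(beta_true = beta_true,
                            sex_effects = sex_effects,
                            batch_shifts = batch_shifts,
                            baseline = baseline),
                       class = "sim_truth")
    list(counts = count_matrix(counts, housekeeping = genes[is_hk]),
         meta = meta,
         truth = truth)
  })
}

#' Generate a synthetic human co-expression module set
#'
#' Samples modules of 10-100 member genes (without replacement within a
#' module; overlap across modules optional) from a human gene universe and
#' assigns each module one consensus-cluster label.
#'
#' @param n_modules number of modules (30 in the standard human annotation).
#' @param genes human gene-symbol universe to draw members from.
#' @param clusters cluster labels to assign (recycled across modules so each
#'   label is used about equally); default the five consensus clusters A-E.
#' @param seed integer seed.
#' @param size_range inclusive range of module sizes.
#' @param overlap if `FALSE`, modules partition disjoint genes (sizes are
#'   drawn so the total fits the universe).
#' @return a [module_set()].
#' @export
make_module_set <- function(n_modules, genes, clusters = LETTERS[1:5],
                            seed = 1L, size_range = c(10, 100),
                            overlap = TRUE) {
  n_modules <- check_count(n_modules, "n_modules")
  if (length(genes) == 0) abort_cfg("genes", "gene universe must be non-empty")
  genes <- unique(as.character(genes))
  if (size_range[1] > length(genes))
    stop(sprintf("module size %d larger than gene universe (%d genes)",
                 size_range[1], length(genes)), call. = FALSE)
  with_seed(seed, {
    size_choices <- seq(size_range[1], min(size_range[2], length(genes)))
    sizes <- size_choices[sample.int(length(size_choices), n_modules, replace = TRUE)]
    if (!overlap && sum(sizes) > length(genes))
      stop(sprintf("disjoint modules need %d genes but universe has %d",
                   sum(sizes), length(genes)), call. = FALSE)
    pool <- if (overlap) NULL else sample(genes)
    members <- vector("list", n_modules)
    offset <- 0
    for (m in seq_len(n_modules)) {
      if (overlap) {
        members[[m]] <- sample(genes, sizes[m])
      } else {
        members[[m]] <- pool[(offset + 1):(offset + sizes[m])]
        offset <- offset + sizes[m]
      }
    }
    names(members) <- sprintf("M%02d", seq_len(n_modules))
    labels <- sample(rep_len(clusters, n_modules))
    module_set(members, stats::setNames(labels, names(members)),
               cluster_levels = unique(c(clusters, labels)))
  })
}

#' Plant a human fold-change signature with a target per-module concordance
#'
#' The generative inverse of the concordance measurement: for each module the
#' human log2 fold change over member genes is `a * beta + e` with
#' `e ~ N(0, noise_sd^2)` and the gain `a` calibrated so the expected Pearson
#' correlation with the mouse truth effect `beta_true[, factor]` equals
#' `target_r`. The calibration targets the expected (not the realized)
#' correlation: the measured r of any single draw varies by sampling.
#' Genes outside all modules receive pure noise. Genes shared between
#' modules keep the value from the first module that assigned them.
#'
#' @param truth `sim_truth` from [simulate_experiment()].
#' @param factor factor name whose planted effect vector anchors the
#'   signature.
#' @param modules a [module_set()] over human symbols.
#' @param target_r single value in \[-1, 1\], or named per-module vector.
#' @param noise_sd standard deviation of the independent noise, log2 units.
#'   `|target_r| < 1` requires `noise_sd > 0`; `|target_r| = 1` plants an
#'   exact (sign-matched) copy of the truth vector.
#' @param seed integer seed.
#' @param homologs optional [homolog_map()]; by default human symbols are
#'   matched to mouse truth genes case-insensitively.
#' @param context context id recorded in the output signature.
#' @return a [human_signature()] over the module gene universe.
#' @export
plant_human_signature <- function(truth, factor, modules, target_r,
                                  noise_sd = 1, seed = 1L, homologs = NULL,
                                  context = "AD_vs_control") {
  stopifnot(inherits(truth, "sim_truth"), inherits(modules, "module_set"))
  if (!factor %in% colnames(truth$beta_true))
    stop(sprintf("factor '%s' not present in truth", factor), call. = FALSE)
  mods <- names(modules$members)
  r_vec <- if (length(target_r) == 1) stats::setNames(rep(as.numeric(target_r), length(mods)), mods)
           else target_r[mods]
  if (any(is.na(r_vec)) || any(abs(r_vec) > 1))
    stop("target_r must lie in [-1, 1] (one value, or one per module)", call. = FALSE)
  noise_sd <- check_nonneg(noise_sd, "noise_sd")
  if (noise_sd == 0 && any(abs(r_vec) < 1 & r_vec != 0))
    stop("planting |target_r| < 1 requires noise_sd > 0", call. = FALSE)

  beta <- truth$beta_true[, factor]
  mouse_upper <- stats::setNames(beta, toupper(names(beta)))
  human_to_mouse <- if (is.null(homologs)) {
    function(h) unname(mouse_upper[toupper(h)])
  } else {
    lut <- stats::setNames(homologs$mouse, toupper(homologs$human))
    function(h) unname(mouse_upper[toupper(lut[toupper(h)])])
  }

  universe <- unique(unlist(modules$members, use.names = FALSE))
  with_seed(seed, {
    value <- stats::setNames(rep(NA_real_, length(universe)), universe)
    for (m in mods) {
      g <- modules$members[[m]]
      free <- g[is.na(value[g])]
      if (length(free) == 0) next
      b <- human_to_mouse(free)
      r <- r_vec[[m]]
      e <- stats::rnorm(length(free), 0, noise_sd)
      ok <- !is.na(b)
      h <- e
      if (abs(r) == 1) {
        h[ok] <- sign(r) * b[ok]
        h[!ok] <- 0
      } else if (r != 0 && sum(ok) >= 2 && stats::sd(b[ok]) > 0) {
        gain <- sign(r) * sqrt(r^2 / (1 - r^2)) * noise_sd / stats::sd(b[ok])
        h[ok] <- gain * b[ok] + e[ok]
      }
      value[free] <- h
    }
    value[is.na(value)] <- stats::rnorm(sum(is.na(value)), 0, noise_sd)
    human_signature(context = context, gene = toupper(universe), log2fc = unname(value))
  })
}
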