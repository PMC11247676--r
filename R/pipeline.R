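#' Plant panel-wide disease-subtype signatures
#'
#' Builds one human log2 fold-change vector per subtype context spanning the
#' whole panel (no module restriction), each calibrated so its expected
#' Pearson correlation with the truth effect vector of `factor` equals the
#' context's target.
#'
#' @param truth `sim_truth` from [simulate_experiment()].
#' @param factor anchoring factor name.
#' @param targets named numeric vector: context id -> target correlation in
#'   \[-1, 1\].
#' @param noise_sd independent noise standard deviation (> 0 unless every
#'   target is 0 or +/-1).
#' @param seed integer seed.
#' @return a [human_signature()] over all panel genes (human symbols).
#' @export
make_subtype_signatures <- function(truth, factor, targets, noise_sd = 1,
                                    seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!factor %in% colnames(truth$beta_true))
    stop(sprintf("factor '%s' not present in truth", factor), call. = FALSE)
  if (any(abs(targets) > 1)) stop("targets must lie in [-1, 1]", call. = FALSE)
  beta <- truth$beta_true[, factor]
  sdb <- stats::sd(beta)
  with_seed(seed, {
    rows <- lapply(names(targets), function(ctx) {
      r <- targets[[ctx]]
      e <- stats::rnorm(length(beta), 0, noise_sd)
      if (abs(r) == 1) {
        fc <- sign(r) * beta
      } else if (r == 0 || sdb == 0) {
        fc <- e
      } else {
        gain <- sign(r) * sqrt(r^2 / (1 - r^2)) * noise_sd / sdb
        fc <- gain * beta + e
      }
      tibble::tibble(context = ctx, gene = toupper(names(beta)), log2fc = fc)
    })
    df <- dplyr::bind_rows(rows)
    human_signature(df$context, df$gene, df$log2fc)
  })
}

#' Identity homolog map for a synthetic mouse gene universe
#'
#' Human symbols are the upper-cased mouse symbols, the convention the
#' synthetic generator uses for its one-to-one homologs.
#'
#' @param mouse_genes character vector of mouse gene symbols.
#' @return a [homolog_map()].
#' @export
synthetic_homolog_map <- function(mouse_genes) {
  homolog_map(toupper(mouse_genes), mouse_genes)
}

default_pipeline_config <- function() {
  list(
    sim = list(),
    modules = list(n_modules = 30, size_range = c(10, 50), overlap = TRUE),
    plant = list(factor = "Abca7", target_r = 0.6, noise_sd = 1),
    subtypes = list(factor = "Abca7", noise_sd = 1,
                    targets = c(ROSMAP.A = 0.5, ROSMAP.B = -0.3,
                                Mayo.A = 0.5, Mayo.B = 0.1, Mayo.C = -0.3,
                                MSBB.A = 0.5, MSBB.B = -0.3)),
    enrich = list(terms = c("Abca7", "5xFAD"), nperm = 1000, exponent = 1),
    concord = list(min_overlap = 5),
    report = list(alpha = 0.05)
  )
}

#' Run the full synthetic concordance pipeline
#'
#' Executes the whole analysis chain deterministically from a configuration
#' and a seed: simulate the panel experiment; housekeeping-normalize, log2
#' transform and batch-correct per age; fit the per-gene additive regression
#' per age cohort; build the synthetic human module set, module signature
#' and subtype signatures; score module, subtype and cross-perturbation
#' concordance; run preranked GSEA plus directional-coherence
#' overrepresentation for the configured terms; and write all tables, the
#' module dot-plot (SVG) and a manifest under `out_dir`. Identical
#' (config, seed) inputs reproduce every output byte-for-byte.
#'
#' @param config configuration list (see `concordAD:::default_pipeline_config()`
#'   for the stage keys); missing entries take the defaults. May also be a
#'   YAML path readable by [read_config()].
#' @param out_dir output directory; `NULL` skips file output.
#' @param seed master integer seed for every stochastic stage.
#' @param force overwrite existing outputs.
#' @return list with the intermediate and final objects: `cfg`, `sim`,
#'   `logmat`, `effects` (per age), `modules`, `homologs`, `signature`,
#'   `subtype_sigs`, `concordance`, `subtype`, `cross`, `enrichment`,
#'   `coherence`, `overrepresentation`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = 1L,
                         force = FALSE) {
  if (is.character(config)) config <- read_config(config)
  defaults <- default_pipeline_config()
  config <- utils::modifyList(defaults, config)
  seed <- check_count(seed, "seed", min = 0L)

  cfg <- do.call(sim_config, c(config$sim, list(seed = seed)))
  sim <- simulate_experiment(cfg)
  logmat <- normalize_experiment(sim$counts, sim$meta)
  effects <- fit_all_ages(logmat, sim$meta)

  genes <- rownames(sim$counts$values)
  panel_genes <- genes[!sim$counts$housekeeping]
  homologs <- synthetic_homolog_map(genes)
  modules <- do.call(make_module_set,
                     c(list(genes = toupper(panel_genes), seed = seed + 101),
                       config$modules))
  signature <- plant_human_signature(sim$truth, config$plant$factor, modules,
                                     target_r = config$plant$target_r,
                                     noise_sd = config$plant$noise_sd,
                                     seed = seed + 202, homologs = homologs)
  subtype_sigs <- make_subtype_signatures(sim$truth, config$subtypes$factor,
                                          targets = config$subtypes$targets,
                                          noise_sd = config$subtypes$noise_sd,
                                          seed = seed + 303)

  all_terms <- function(eff) setdiff(unique(eff$term), "(Intercept)")
  concordance <- dplyr::bind_rows(lapply(names(effects), function(age) {
    dplyr::bind_rows(lapply(all_terms(effects[[age]]), function(tm) {
      out <- module_concordance(effects[[age]], tm, signature, modules, homologs,
                                min_overlap = config$concord$min_overlap)
      out$age <- as.numeric(age)
      out
    }))
  }))
  subtype <- dplyr::bind_rows(lapply(names(effects), function(age) {
    dplyr::bind_rows(lapply(all_terms(effects[[age]]), function(tm) {
      out <- subtype_concordance(effects[[age]], tm, subtype_sigs, homologs,
                                 min_overlap = config$concord$min_overlap)
      out$age <- as.numeric(age)
      out
    }))
  }))
  cross <- lapply(effects, cross_perturbation_correlation)

  # GSEA gene sets: module membership translated to mouse panel symbols
  mouse_sets <- lapply(modules$members, function(g) {
    lut <- stats::setNames(homologs$mouse, toupper(homologs$human))
    unname(stats::na.omit(lut[toupper(g)]))
  })
  first_age <- names(effects)[1]
  enrichment <- dplyr::bind_rows(lapply(config$enrich$terms, function(tm) {
    ranked <- rank_genes(effects[[first_age]], tm)
    ranked <- ranked[!grepl("^Hkg", names(ranked))]
    class(ranked) <- "ranked_list"
    tab <- gsea_preranked(ranked, mouse_sets, nperm = config$enrich$nperm,
                          exponent = config$enrich$exponent, seed = seed + 404)
    tab$term <- tm
    tab
  }))

  coherence <- directional_coherent_genes(effects[[first_age]],
                                          config$plant$factor, signature,
                                          modules, homologs)
  coherent_all <- unique(unlist(lapply(coherence, function(x) x$mouse)))
  overrep <- if (length(coherent_all) > 0) {
    overrepresentation_test(coherent_all, panel_genes, mouse_sets)
  } else NULL

  result <- list(cfg = cfg, sim = sim, logmat = logmat, effects = effects,
                 modules = modules, homologs = homologs, signature = signature,
                 subtype_sigs = subtype_sigs, concordance = concordance,
                 subtype = subtype, cross = cross, enrichment = enrichment,
                 coherence = coherence, overrepresentation = overrep)

  if (!is.null(out_dir)) {
    export_results(list(counts = sim$counts, metadata = sim$meta,
                        logmat = logmat, effects = effects,
                        modules = modules, homologs = homologs,
                        signature = signature, subtype = subtype,
                        concordance = concordance, enrichment = enrichment,
                        overrepresentation = overrep),
                   out_dir, seed = seed, params = config, force = force)
    for (age in names(effects)) {
      sub <- concordance[concordance$age == as.numeric(age), , drop = FALSE]
      correlation_dotplot(sub, file.path(out_dir, sprintf("dotplot_age%s.svg", age)),
                          alpha = config$report$alpha,
                          title = sprintf("Perturbation-module concordance, %s months", age))
    }
  }
  result
}
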