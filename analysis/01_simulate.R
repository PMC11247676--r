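#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study: a NanoString-style brain panel
# experiment (13 genotype factors + sex, two age cohorts, ~6 animals per
# group per sex, lane batches) plus the human-side inputs: 30 co-expression
# modules with consensus clusters, a module fold-change signature planted
# against the Abca7 variant effect, subtype signatures for three cohorts,
# and the one-to-one homolog map.

suppressMessages(library(concordAD))

seed <- 2026
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_experiment(cfg)
cat(sprintf("simulated %d genes x %d samples (%d housekeeping, %d strains, ages %s)\n",
            nrow(sim$counts$values), ncol(sim$counts$values),
            sum(sim$counts$housekeeping), length(unique(sim$meta$strain)),
            paste(unique(sim$meta$age_months), collapse = "/")))

genes <- rownames(sim$counts$values)
panel <- genes[!sim$counts$housekeeping]
homologs <- synthetic_homolog_map(genes)
modules <- make_module_set(30, toupper(panel), seed = seed + 101,
                           size_range = c(10, 50))
signature <- plant_human_signature(sim$truth, "Abca7", modules,
                                   target_r = 0.6, noise_sd = 1,
                                   seed = seed + 202, homologs = homologs)
subtypes <- make_subtype_signatures(sim$truth, "Abca7",
                                    targets = c(ROSMAP.A = 0.5, ROSMAP.B = -0.3,
                                                Mayo.A = 0.5, Mayo.B = 0.1,
                                                Mayo.C = -0.3,
                                                MSBB.A = 0.5, MSBB.B = -0.3),
                                    noise_sd = 1, seed = seed + 303)

write_counts(sim$counts, file.path(out, "counts.tsv"))
write_metadata(sim$meta, file.path(out, "metadata.tsv"))
write_sim_truth(sim$truth, file.path(out, "truth.tsv"))
writeLines(genes[sim$counts$housekeeping], file.path(out, "housekeeping.txt"))
write_modules_gmt(modules, file.path(out, "modules.gmt"))
write_signature(signature, file.path(out, "signature_modules.tsv"))
write_signature(subtypes, file.path(out, "signature_subtypes.tsv"))
write_homolog_map(homologs, file.path(out, "homologs.tsv"))
cat(sprintf("inputs written under %s (module sizes %d-%d; planted module r = 0.6 for Abca7)\n",
            out, min(lengths(modules$members)), max(lengths(modules$members))))
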