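#!/usr/bin/env Rscript
# Stage 5 — functional enrichment: preranked GSEA of coefficient-ranked
# panel genes against the module gene sets, directional-coherence gene
# extraction for the planted factor, and hypergeometric overrepresentation
# of the coherent genes with BH-FDR control.

suppressMessages(library(concordAD))

dat <- "results/data"
seed <- 2026
modules <- read_modules(file.path(dat, "modules.gmt"))
signature <- read_signature(file.path(dat, "signature_modules.tsv"))
homologs <- read_homolog_map(file.path(dat, "homologs.tsv"))
eff <- tibble::as_tibble(utils::read.table(file.path(dat, "effects_age4.tsv"),
                                           header = TRUE, sep = "\t"))
class(eff) <- c("effect_table", class(eff))

lut <- stats::setNames(homologs$mouse, toupper(homologs$human))
mouse_sets <- lapply(modules$members, function(g)
  unname(stats::na.omit(lut[toupper(g)])))

tabs <- lapply(c("Abca7", "5xFAD"), function(tm) {
  ranked <- rank_genes(eff, tm)
  ranked <- structure(ranked[!grepl("^Hkg", names(ranked))], class = "ranked_list")
  tab <- gsea_preranked(ranked, mouse_sets, nperm = 5000, exponent = 1,
                        seed = seed + 404)
  tab$term <- tm
  tab
})
enr <- dplyr::bind_rows(tabs)
utils::write.table(enr, file.path(dat, "enrichment_gsea.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
hits <- enr[!is.na(enr$padj) & enr$padj < 0.05, ]
cat(sprintf("GSEA: %d set-term pairs tested, %d with BH-adjusted p < 0.05\n",
            sum(!is.na(enr$p)), nrow(hits)))
if (nrow(hits) > 0)
  print(as.data.frame(hits[order(hits$padj), c("term", "set", "size", "es", "nes", "p", "padj")]))

coh <- directional_coherent_genes(eff, "Abca7", signature, modules, homologs)
coh_genes <- unique(unlist(lapply(coh, function(x) x$mouse)))
cat(sprintf("directional coherence (Abca7): %d genes share sign between mouse effect and human log2FC across %d modules\n",
            length(coh_genes), sum(lengths(lapply(coh, nrow)) > 0)))
panel <- unique(eff$gene[!grepl("^Hkg", eff$gene)])
ora <- overrepresentation_test(coh_genes, panel, mouse_sets)
utils::write.table(ora, file.path(dat, "overrepresentation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("overrepresentation: %d/%d module sets at BH q < 0.05\n",
            sum(ora$padj < 0.05), nrow(ora)))
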