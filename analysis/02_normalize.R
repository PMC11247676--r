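#!/usr/bin/env Rscript
# Stage 2 — housekeeping normalization, log2 transform, and per-age
# empirical-Bayes batch correction of the panel counts.

suppressMessages(library(concordAD))

dat <- "results/data"
hk <- readLines(file.path(dat, "housekeeping.txt"))
counts <- read_counts(file.path(dat, "counts.tsv"), housekeeping = hk)
meta <- read_metadata(file.path(dat, "metadata.tsv"))

logmat <- normalize_experiment(counts, meta, pseudocount = 1)
write_counts(logmat, file.path(dat, "logmat.tsv"))
cat(sprintf("normalized %d x %d counts: housekeeping geometric-mean division, log2(x+1 ratio), ComBat per age cohort preserving sex + genotype\n",
            nrow(logmat$values), ncol(logmat$values)))

# sanity: per-lane housekeeping geometric mean is 1 after division
norm <- housekeeping_normalize(counts, pseudocount = 1)
gm <- apply(norm$values[hk, ], 2, geometric_mean)
cat(sprintf("post-normalization housekeeping geometric mean per lane: %.6f-%.6f\n",
            min(gm), max(gm)))
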