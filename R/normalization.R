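#' Geometric mean of positive values
#'
#' `exp(mean(log(x)))`, the center used for housekeeping-based lane
#' normalization.
#'
#' @param values numeric vector, all strictly positive.
#' @return the geometric mean.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0 || any(!is.finite(values)) || any(values <= 0))
    stop("geometric mean requires finite values > 0", call. = FALSE)
  exp(mean(log(values)))
}

#' Housekeeping normalization of a panel count matrix
#'
#' Divides every count within a lane (sample column) by the geometric mean of
#' the designated housekeeping genes from that same lane, so lane-to-lane
#' differences in input amount and hybridization efficiency cancel. After
#' normalization, the housekeeping geometric mean is 1 in every lane; the
#' transform is idempotent and invariant to rescaling a whole lane.
#'
#' @param counts a [count_matrix()] with >= 2 housekeeping genes flagged.
#' @param pseudocount value >= 0 added to every count before the division
#'   (default 0), so that lanes with zero housekeeping counts keep a defined
#'   divisor and the subsequent log of a ratio stays linear in log2 counts.
#' @return a [count_matrix()] of normalized values (housekeeping flags kept).
#' @export
housekeeping_normalize <- function(counts, pseudocount = 0) {
  stopifnot(inherits(counts, "count_matrix"))
  pseudocount <- check_nonneg(pseudocount, "pseudocount")
  hk <- names(counts$housekeeping)[counts$housekeeping]
  if (length(hk) == 0)
    stop("no housekeeping genes flagged; normalization requires designated housekeeping genes",
         call. = FALSE)
  if (length(hk) < 2)
    stop("housekeeping normalization requires >= 2 flagged housekeeping genes", call. = FALSE)
  vals <- counts$values + pseudocount
  hk_counts <- vals[hk, , drop = FALSE]
  if (any(hk_counts <= 0))
    stop("housekeeping counts must be positive; set a pseudocount > 0", call. = FALSE)
  gm <- apply(hk_counts, 2, geometric_mean)
  out <- sweep(vals, 2, gm, "/")
  count_matrix(out, housekeeping = hk)
}

#' Log2 transform of normalized counts
#'
#' Elementwise `log2(value + pseudocount)`. The pseudocount is recorded in
#' the output's provenance.
#'
#' @param counts a [count_matrix()] (typically housekeeping-normalized).
#' @param pseudocount value >= 0 added before the log (default 1).
#' @return a [log_matrix()].
#' @export
log_transform <- function(counts, pseudocount = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  pseudocount <- check_nonneg(pseudocount, "pseudocount")
  if (any(counts$values + pseudocount <= 0))
    stop("zero values present: set a positive pseudocount before the log transform",
         call. = FALSE)
  log_matrix(log2(counts$values + pseudocount), pseudocount = pseudocount)
}

#' Empirical-Bayes batch correction of a log expression matrix
#'
#' Parametric empirical-Bayes location/scale adjustment (ComBat): per-gene
#' batch effects are estimated after adjusting for preserved biological
#' covariates, shrunk toward pooled priors, and removed; preserved covariate
#' effects are retained. A single batch is a no-op.
#'
#' @param logmat a [log_matrix()].
#' @param batches character/factor batch label per sample (>= 2 samples per
#'   batch).
#' @param preserve optional numeric design matrix (samples x terms) of
#'   biological covariates to protect from removal; an intercept is not
#'   needed. Must not be confounded with batch.
#' @return a [log_matrix()] with `batch_corrected = TRUE` provenance.
#' @export
batch_correct <- function(logmat, batches, preserve = NULL) {
  stopifnot(inherits(logmat, "log_matrix"))
  batches <- as.character(batches)
  if (length(batches) != ncol(logmat$values))
    stop("one batch label required per sample", call. = FALSE)
  tab <- table(batches)
  if (length(tab) == 1) {
    out <- logmat
    out$provenance$batch_corrected <- TRUE
    return(out)
  }
  small <- names(tab)[tab < 2]
  if (length(small) > 0)
    stop(sprintf("batch(es) with a single sample cannot be corrected: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  mod <- NULL
  if (!is.null(preserve)) {
    preserve <- as.matrix(preserve)
    if (nrow(preserve) != ncol(logmat$values))
      stop("preserve design must have one row per sample", call. = FALSE)
    # drop any intercept column; ComBat supplies its own
    keep <- apply(preserve, 2, function(x) stats::sd(x) > 0)
    preserve <- preserve[, keep, drop = FALSE]
    if (ncol(preserve) > 0) {
      full <- cbind(1, preserve, stats::model.matrix(~ factor(batches))[, -1, drop = FALSE])
      if (qr(full)$rank < ncol(full)) {
        stop(sprintf("batch is confounded with preserved covariate(s): %s",
                     paste(colnames(preserve), collapse = ", ")), call. = FALSE)
      }
      mod <- stats::model.matrix(~ preserve)
    }
  }
  corrected <- suppressMessages(
    sva::ComBat(dat = logmat$values, batch = factor(batches), mod = mod,
                par.prior = TRUE, prior.plots = FALSE)
  )
  out <- log_matrix(corrected,
                    pseudocount = logmat$provenance$pseudocount,
                    batch_corrected = TRUE)
  out
}

#' Full normalization chain for one experiment
#'
#' Housekeeping normalization, log2 transform, then (optionally) batch
#' correction applied independently within each age cohort, mirroring the
#' per-age regression models downstream.
#'
#' The pseudocount is applied to the raw counts before the housekeeping
#' division; the log is then taken on the ratio directly, keeping the
#' transform linear in log2 counts.
#'
#' @param counts a [count_matrix()].
#' @param meta sample metadata tibble (columns sample, strain, sex,
#'   age_months, batch) aligned with `counts` columns.
#' @param pseudocount pseudocount added to raw counts before division
#'   (default 1).
#' @param correct_batch apply per-age ComBat (default TRUE), preserving the
#'   sex + genotype design.
#' @param background_map strain -> background map used to build the
#'   preserved design (default [default_background_map()]).
#' @return a [log_matrix()] over all samples.
#' @export
normalize_experiment <- function(counts, meta, pseudocount = 1,
                                 correct_batch = TRUE,
                                 background_map = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!setequal(meta$sample, colnames(counts$values)) ||
      anyDuplicated(meta$sample))
    stop("metadata must contain exactly one row per count-matrix sample", call. = FALSE)
  meta <- meta[match(colnames(counts$values), meta$sample), , drop = FALSE]
  normed <- housekeeping_normalize(counts, pseudocount)
  logmat <- log_matrix(log_transform(normed, pseudocount = 0)$values,
                       pseudocount = pseudocount)
  if (!correct_batch) return(logmat)
  if (is.null(background_map))
    background_map <- infer_background_map(meta$strain)
  out <- logmat$values
  for (a in sort(unique(meta$age_months))) {
    idx <- which(meta$age_months == a)
    sub <- log_matrix(logmat$values[, idx, drop = FALSE],
                      pseudocount = pseudocount)
    design <- build_design(meta[idx, , drop = FALSE], background_map)
    corrected <- batch_correct(sub, meta$batch[idx],
                               preserve = design[, setdiff(colnames(design), "(Intercept)"),
                                                 drop = FALSE])
    out[, idx] <- corrected$values
  }
  log_matrix(out, pseudocount = pseudocount, batch_corrected = TRUE)
}

#' Infer the background map from strain naming conventions
#'
#' Strains named `LOAD1.<x>` sit on the LOAD1 background; `5xFAD` and
#' `LOAD1` sit on B6J; `B6J` is the baseline.
#'
#' @param strains character vector of strain labels.
#' @return named character vector usable as a `background_map`.
#' @export
infer_background_map <- function(strains) {
  strains <- unique(strains)
  bg <- ifelse(strains == "B6J", NA_character_,
               ifelse(grepl("^LOAD1\\.", strains), "LOAD1", "B6J"))
  stats::setNames(bg, strains)
}
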