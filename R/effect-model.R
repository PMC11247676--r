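#' Build the additive design matrix with the nested control hierarchy
#'
#' Encodes `log expr = b0 + sum_i b_i + e`: an intercept (the B6J baseline),
#' a male indicator (female = reference), and one 0/1 indicator per genotype
#' factor. A strain contributes the indicator of its own factor plus those of
#' every background strain above it, so a variant strain carried on LOAD1 has
#' both its variant term and the LOAD1 term set; the variant coefficient then
#' estimates the deviation from LOAD1, and LOAD1's the deviation from B6J.
#'
#' @param meta metadata tibble with columns sample, strain, sex.
#' @param background_map named character: strain -> background strain, `NA`
#'   for the baseline strain. Every strain in `meta` must appear.
#' @return numeric samples x terms matrix (rownames = samples) with columns
#'   `(Intercept)`, `male` (if both sexes present), and one per factor
#'   observed; guaranteed full column rank.
#' @export
build_design <- function(meta, background_map) {
  missing <- setdiff(unique(meta$strain), names(background_map))
  if (length(missing) > 0)
    stop(sprintf("strain(s) absent from background map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  strain_terms <- function(strain) {
    terms <- character()
    s <- strain
    repeat {
      bg <- background_map[[s]]
      if (is.na(bg)) break   # baseline strain contributes no factor term
      terms <- c(terms, sub("^LOAD1\\.", "", s))
      s <- bg
      if (!s %in% names(background_map))
        stop(sprintf("background strain '%s' absent from background map", s), call. = FALSE)
    }
    terms
  }
  term_lists <- lapply(meta$strain, strain_terms)
  factors <- unique(unlist(term_lists))
  X <- matrix(0, nrow(meta), length(factors) + 1,
              dimnames = list(meta$sample, c("(Intercept)", factors)))
  X[, "(Intercept)"] <- 1
  for (i in seq_along(term_lists)) X[i, term_lists[[i]]] <- 1
  if (length(unique(meta$sex)) > 1) {
    X <- cbind(X[, 1, drop = FALSE],
               male = as.numeric(meta$sex == "male"),
               X[, -1, drop = FALSE])
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("design is rank deficient; aliased term(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  X
}

#' Per-gene ordinary least squares over a shared design
#'
#' Fits the additive multiple regression independently for every gene and
#' returns the perturbation effect vectors: coefficient (log2 units),
#' standard error from `(X'X)^-1 * sigma^2`, t statistic, and two-sided p
#' from the t distribution on the residual degrees of freedom.
#'
#' @param logmat a [log_matrix()] (genes x samples).
#' @param design design matrix from [build_design()], rows aligned with (or
#'   a permutation of) `logmat` samples.
#' @return tibble of class `effect_table`: gene, term, beta, se, t, p, df,
#'   resid_sd (per-gene residual standard deviation, repeated across terms).
#' @export
fit_gene_effects <- function(logmat, design) {
  stopifnot(inherits(logmat, "log_matrix"))
  if (!setequal(rownames(design), colnames(logmat$values)))
    stop("design rows and expression samples must match", call. = FALSE)
  design <- design[colnames(logmat$values), , drop = FALSE]
  n <- nrow(design); p <- ncol(design)
  df <- n - p
  if (df < 1) stop("residual degrees of freedom < 1; more samples than terms required",
                   call. = FALSE)
  Y <- t(logmat$values)                     # samples x genes
  qr_x <- qr(design)
  coef <- qr.coef(qr_x, Y)                  # terms x genes
  resid <- qr.resid(qr_x, Y)
  sigma2 <- colSums(resid^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qr_x)))[order(qr_x$pivot)]
  se <- sqrt(outer(xtx_inv_diag, sigma2))   # terms x genes
  tstat <- coef / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  genes <- colnames(Y)
  terms <- colnames(design)
  out <- tibble::tibble(
    gene = rep(genes, each = length(terms)),
    term = rep(terms, times = length(genes)),
    beta = as.vector(coef),
    se = as.vector(se),
    t = as.vector(tstat),
    p = as.vector(pval),
    df = df,
    resid_sd = rep(sqrt(sigma2), each = length(terms))
  )
  class(out) <- c("effect_table", class(out))
  out
}

#' Fit one independent per-gene model per age cohort
#'
#' @param logmat a [log_matrix()] over all samples.
#' @param meta metadata tibble aligned with `logmat` samples.
#' @param background_map strain -> background map (default inferred from
#'   strain names).
#' @param ages ages to fit (default all present); cohorts with samples from
#'   fewer than 2 strains are skipped with a warning.
#' @return named list, one `effect_table` per age (names are the ages).
#' @export
fit_all_ages <- function(logmat, meta, background_map = NULL, ages = NULL) {
  stopifnot(inherits(logmat, "log_matrix"))
  meta <- meta[match(colnames(logmat$values), meta$sample), , drop = FALSE]
  if (is.null(background_map)) background_map <- infer_background_map(meta$strain)
  ages <- ages %||% sort(unique(meta$age_months))
  out <- list()
  for (a in ages) {
    idx <- which(meta$age_months == a)
    if (length(idx) == 0 || length(unique(meta$strain[idx])) < 2) {
      warning(sprintf("age cohort %s skipped: fewer than 2 strains with samples", a),
              call. = FALSE)
      next
    }
    sub <- log_matrix(logmat$values[, idx, drop = FALSE],
                      pseudocount = logmat$provenance$pseudocount,
                      batch_corrected = logmat$provenance$batch_corrected)
    design <- build_design(meta[idx, , drop = FALSE], background_map)
    fit <- fit_gene_effects(sub, design)
    fit$age <- a
    out[[as.character(a)]] <- fit
  }
  out
}

#' Extract one term's effect vector from an effect table
#'
#' @param effects an `effect_table` from [fit_gene_effects()].
#' @param term term name (e.g. a genotype factor).
#' @return named numeric vector of coefficients, names = mouse gene symbols.
#' @export
effect_vector <- function(effects, term) {
  sub <- effects[effects$term == term, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("term '%s' not present in effect table", term), call. = FALSE)
  stats::setNames(sub$beta, sub$gene)
}
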