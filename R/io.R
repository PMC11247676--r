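read_table_checked <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (nrow(df) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
  df
}

#' Read a gene x sample count table
#'
#' First column gene identifiers, remaining columns numeric counts, one per
#' sample. Parse failures report the offending row/column.
#'
#' @param path TSV (or CSV with `sep=","`) path.
#' @param housekeeping character vector of designated housekeeping gene ids;
#'   listed genes absent from the file produce a warning, not an error.
#' @param sep field separator.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, housekeeping = character(), sep = "\t") {
  df <- read_table_checked(path, sep)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicated gene row '%s' in %s",
                 genes[duplicated(genes)][1], path), call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric count at row %d (gene '%s'), column '%s'",
                   bad[1], genes[bad[1]], names(vals)[j]), call. = FALSE)
    neg <- which(v < 0)
    if (length(neg) > 0)
      stop(sprintf("negative count at row %d (gene '%s'), column '%s'",
                   neg[1], genes[neg[1]], names(vals)[j]), call. = FALSE)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  count_matrix(m, housekeeping = housekeeping)
}

#' Write a count matrix as TSV
#' @param counts a [count_matrix()] or [log_matrix()].
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  vals <- counts$values
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample, strain, sex, age_months, batch)
#' @param path TSV path.
#' @return tibble with the five standard columns.
#' @export
read_metadata <- function(path) {
  df <- read_table_checked(path)
  need <- c("sample", "strain", "sex", "age_months", "batch")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  bad_sex <- setdiff(unique(df$sex), c("male", "female"))
  if (length(bad_sex) > 0)
    stop(sprintf("sex must be male/female; found: %s", paste(bad_sex, collapse = ", ")),
         call. = FALSE)
  tibble::as_tibble(df[need])
}

#' Write sample metadata as TSV
#' @param meta metadata tibble.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module set (GMT or 3-column TSV dialect)
#'
#' GMT dialect: one module per line, `module<TAB>cluster<TAB>gene1<TAB>...`
#' (the description field carries the consensus-cluster label). TSV dialect:
#' header `module  gene  cluster`, one gene per row. Both produce the same
#' `module_set`.
#'
#' @param path file path; dialect inferred from the `.gmt` extension unless
#'   `dialect` is given.
#' @param dialect `"gmt"` or `"tsv"`.
#' @param cluster_levels allowed cluster labels (default A-E).
#' @return a [module_set()].
#' @export
read_modules <- function(path, dialect = NULL,
                         cluster_levels = LETTERS[1:5]) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dialect <- dialect %||% if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (dialect == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop(sprintf("empty file: %s", path), call. = FALSE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(parts, length, integer(1)) < 3
    if (any(short))
      stop(sprintf("module '%s' has zero genes or missing cluster label",
                   parts[[which(short)[1]]][1]), call. = FALSE)
    members <- lapply(parts, function(p) p[-(1:2)])
    names(members) <- vapply(parts, `[[`, character(1), 1)
    clusters <- stats::setNames(vapply(parts, `[[`, character(1), 2), names(members))
  } else {
    df <- read_table_checked(path)
    need <- c("module", "gene", "cluster")
    if (length(setdiff(need, names(df))) > 0)
      stop("module TSV needs columns: module, gene, cluster", call. = FALSE)
    members <- split(as.character(df$gene), df$module)
    cl <- tapply(as.character(df$cluster), df$module, unique)
    multi <- names(cl)[lengths(cl) > 1]
    if (length(multi) > 0)
      stop(sprintf("module(s) with more than one cluster label: %s",
                   paste(multi, collapse = ", ")), call. = FALSE)
    clusters <- stats::setNames(vapply(cl, `[[`, character(1), 1), names(cl))
  }
  module_set(members, clusters, cluster_levels = cluster_levels)
}

#' Write a module set in GMT dialect
#' @param modules a [module_set()].
#' @param path output path (.gmt).
#' @export
write_modules_gmt <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  lines <- vapply(names(modules$members), function(m) {
    paste(c(m, modules$clusters[[m]], modules$members[[m]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a homolog map (2-column TSV: human, mouse)
#'
#' Many-to-many rows are dropped with a warning so the returned map is
#' one-to-one.
#'
#' @param path TSV path with columns `human` and `mouse`.
#' @return a [homolog_map()].
#' @export
read_homolog_map <- function(path) {
  df <- read_table_checked(path)
  if (length(setdiff(c("human", "mouse"), names(df))) > 0)
    stop("homolog map needs columns: human, mouse", call. = FALSE)
  homolog_map(df$human, df$mouse)
}

#' Write a homolog map as TSV
#' @param homologs a [homolog_map()].
#' @param path output path.
#' @export
write_homolog_map <- function(homologs, path) {
  utils::write.table(homologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a human fold-change signature (TSV: context, gene, log2fc)
#' @param path TSV path.
#' @return a [human_signature()].
#' @export
read_signature <- function(path) {
  df <- read_table_checked(path)
  if (length(setdiff(c("context", "gene", "log2fc"), names(df))) > 0)
    stop("signature needs columns: context, gene, log2fc", call. = FALSE)
  v <- suppressWarnings(as.numeric(df$log2fc))
  bad <- which(is.na(v))
  if (length(bad) > 0)
    stop(sprintf("non-numeric log2fc at row %d (gene '%s')", bad[1], df$gene[bad[1]]),
         call. = FALSE)
  human_signature(df$context, df$gene, v)
}

#' Write a human signature as TSV
#' @param signature a [human_signature()].
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(signature, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration (YAML)
#'
#' One YAML file mapping each pipeline stage to its parameters; see
#' [run_pipeline()] for the recognized keys.
#'
#' @param path YAML path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}

#' Write a simulation ground-truth bundle as a long TSV
#'
#' One row per (component, gene, name, value): planted genotype effects
#' (`beta_true`), batch shifts, sex effects and baselines, in a single
#' round-trippable table.
#'
#' @param truth `sim_truth` from [simulate_experiment()].
#' @param path output TSV path.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  long <- function(m, comp) {
    tibble::tibble(component = comp,
                   gene = rep(rownames(m), ncol(m)),
                   name = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
  }
  df <- dplyr::bind_rows(
    long(truth$beta_true, "beta_true"),
    long(truth$batch_shifts, "batch_shift"),
    tibble::tibble(component = "sex_effect", gene = names(truth$sex_effects),
                   name = "male", value = unname(truth$sex_effects)),
    tibble::tibble(component = "baseline", gene = names(truth$baseline),
                   name = "intercept", value = unname(truth$baseline)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation ground-truth bundle written by [write_sim_truth()]
#' @param path TSV path.
#' @return a `sim_truth` object.
#' @export
read_sim_truth <- function(path) {
  df <- read_table_checked(path)
  wide <- function(comp) {
    sub <- df[df$component == comp, , drop = FALSE]
    genes <- unique(sub$gene); cols <- unique(sub$name)
    m <- matrix(NA_real_, length(genes), length(cols),
                dimnames = list(genes, cols))
    m[cbind(sub$gene, sub$name)] <- sub$value
    m
  }
  beta <- wide("beta_true")
  batch <- wide("batch_shift")
  sexm <- wide("sex_effect")
  basem <- wide("baseline")
  structure(list(beta_true = beta, batch_shifts = batch,
                 sex_effects = sexm[, 1], baseline = basem[, 1]),
            class = "sim_truth")
}

#' Read a log-scale expression matrix TSV (first column gene ids)
#'
#' Unlike [read_counts()], values may be negative (log2 scale).
#'
#' @param path TSV path.
#' @param pseudocount,batch_corrected provenance to record.
#' @return a [log_matrix()].
#' @export
read_log_matrix <- function(path, pseudocount = NA_real_, batch_corrected = FALSE) {
  df <- read_table_checked(path)
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicated gene row '%s' in %s",
                 genes[duplicated(genes)][1], path), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("log matrix values must be numeric", call. = FALSE)
  rownames(m) <- genes
  log_matrix(m, pseudocount = pseudocount, batch_corrected = batch_corrected)
}
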