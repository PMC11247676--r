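#' Correlation dot-plot matrix
#'
#' The standard cross-species concordance display: one circle per
#' (perturbation, context) cell, with circle area and color intensity
#' proportional to |r| — blue for positive, red for negative — and a black
#' frame around cells whose correlation is significant (p below the
#' threshold). Columns are grouped by consensus cluster when module rows
#' carry cluster annotations. Every row of the input table produces a cell;
#' nothing is silently dropped.
#'
#' @param table a `concordance_table`.
#' @param path output file path (`.svg` default, `.png` supported).
#' @param alpha significance threshold for framing (default 0.05).
#' @param title optional plot title.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly; the file is written as a side
#'   effect.
#' @export
correlation_dotplot <- function(table, path, alpha = 0.05, title = NULL,
                                width = 8, height = 5) {
  if (nrow(table) == 0) stop("concordance table is empty", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  df <- tibble::as_tibble(table)
  df$r_plot <- ifelse(is.na(df$r), 0, df$r)
  df$framed <- !is.na(df$p) & df$p < alpha
  if (!all(is.na(df$cluster))) {
    ord <- order(df$cluster, df$context)
    df$context <- factor(df$context, levels = unique(df$context[ord]))
    df$col_group <- df$cluster
  } else {
    df$context <- factor(df$context, levels = unique(df$context))
    df$col_group <- ""
  }
  lim <- max(abs(df$r_plot), 0.1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$context, y = .data$term)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$r_plot), fill = .data$r_plot,
                                     colour = .data$framed),
                        shape = 21, stroke = 0.9) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, lim), name = "|r|") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                                  limits = c(-lim, lim), name = "Pearson r",
                                  # rectangle-drawn colourbar keeps the SVG free
                                  # of raster images, so output is byte-stable
                                  guide = ggplot2::guide_colourbar(display = "rectangles")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey85"),
                                 labels = c(`TRUE` = sprintf("p < %g", alpha),
                                            `FALSE` = "n.s."),
                                 name = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.title = ggplot2::element_blank()) +
    ggplot2::ggtitle(title %||% "")
  if (any(df$col_group != ""))
    p <- p + ggplot2::facet_grid(. ~ col_group, scales = "free_x", space = "free_x")
  fmt <- tolower(tools::file_ext(path))
  if (!dir.exists(dirname(path)))
    stop(sprintf("output directory does not exist: %s", dirname(path)), call. = FALSE)
  if (fmt == "png") {
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  print(p)
  grDevices::dev.off()
  invisible(p)
}

#' Export pipeline result tables with a reproducibility manifest
#'
#' Writes every supplied table as TSV under `out_dir` plus a JSON manifest
#' recording the seed, stage parameters, package version, and which stages
#' are present. Existing files are an error unless `force = TRUE`; a missing
#' table is recorded as absent in the manifest rather than failing.
#'
#' @param tables named list; recognized names: `counts`, `metadata`,
#'   `logmat`, `effects` (one table or a per-age list), `concordance`,
#'   `subtype`, `cross`, `enrichment`, `overrepresentation`, `signature`,
#'   `modules` (a `module_set`), `homologs`.
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @param params stage parameters recorded in the manifest.
#' @param force overwrite existing files.
#' @return path of the manifest JSON, invisibly.
#' @export
export_results <- function(tables, out_dir, seed = NA_integer_,
                           params = list(), force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(obj, file, writer) {
    dest <- file.path(out_dir, file)
    if (file.exists(dest) && !force)
      stop(sprintf("output exists (use force = TRUE to overwrite): %s", dest),
           call. = FALSE)
    writer(obj, dest)
    written <<- c(written, file)
  }
  write_tsv <- function(obj, dest)
    utils::write.table(tibble::as_tibble(obj), dest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  stages <- list()
  for (nm in names(tables)) {
    obj <- tables[[nm]]
    if (is.null(obj)) { stages[[nm]] <- "absent"; next }
    if (nm == "counts" || nm == "logmat") {
      emit(obj, paste0(nm, ".tsv"), write_counts)
    } else if (nm == "modules") {
      emit(obj, "modules.gmt", write_modules_gmt)
    } else if (nm == "effects" && is.list(obj) && !tibble::is_tibble(obj)) {
      for (age in names(obj))
        emit(obj[[age]], sprintf("effects_age%s.tsv", age), write_tsv)
    } else {
      emit(obj, paste0(nm, ".tsv"), write_tsv)
    }
    stages[[nm]] <- "present"
  }
  manifest <- list(seed = seed, params = params,
                   package = as.character(utils::packageVersion("concordAD")),
                   stages = stages, files = written)
  dest <- file.path(out_dir, "manifest.json")
  if (file.exists(dest) && !force)
    stop(sprintf("output exists (use force = TRUE to overwrite): %s", dest), call. = FALSE)
  jsonlite::write_json(manifest, dest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dest)
}
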