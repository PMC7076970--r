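utils::globalVariables(c("term_label", "neglog_q", "category", "x_value",
                         "k", "q_value"))

Q_FLOOR <- 1e-300  # q-values are floored here so -log10 stays finite

#' Bar plot of top enriched terms
#'
#' Horizontal bars for the top `top_n` terms by `rank_by`, bar length
#' -log10(q) (q floored at 1e-300), labels the term names (truncated at
#' 60 characters). Ordering is deterministic: rank value, then term id.
#'
#' @param table an `enrich_table` from [enrich()].
#' @param path optional output file (`.png`, `.pdf` or `.svg`); when
#'   `NULL` the ggplot object is returned unrendered.
#' @param top_n number of terms to draw (default 20); a larger value
#'   than the table has draws all rows with a warning.
#' @param rank_by `"q_value"` (default) or `"p_value"`.
#' @param category_facet facet by category (e.g. GO namespace)?
#' @param width,height device size in inches.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
enrich_barplot <- function(table, path = NULL, top_n = 20,
                           rank_by = c("q_value", "p_value"),
                           category_facet = FALSE, width = 7, height = 5) {
  rank_by <- match.arg(rank_by)
  df <- plot_frame(table, top_n, rank_by)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = neglog_q, y = term_label)) +
    ggplot2::geom_col(ggplot2::aes(fill = category), show.legend = category_facet) +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL,
                  title = "Enriched terms") +
    ggplot2::theme_bw(base_size = 10)
  if (category_facet) {
    p <- p + ggplot2::facet_grid(category ~ ., scales = "free_y",
                                 space = "free_y")
  }
  if (!is.null(path)) {
    save_plot(p, path, width, height)
    return(invisible(p))
  }
  p
}

#' Bubble plot of top enriched terms
#'
#' x is the fold enrichment (or the gene ratio k/n), y the ranked term
#' names, bubble area proportional to the overlap count k, colour
#' mapped to the q-value on a reversed scale (small q = warm).
#'
#' @inheritParams enrich_barplot
#' @param x_var `"fold_enrichment"` (default) or `"gene_ratio"`.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
enrich_bubbleplot <- function(table, path = NULL, top_n = 20,
                              rank_by = c("q_value", "p_value"),
                              x_var = c("fold_enrichment", "gene_ratio"),
                              category_facet = FALSE, width = 7, height = 5) {
  rank_by <- match.arg(rank_by)
  x_var <- match.arg(x_var)
  df <- plot_frame(table, top_n, rank_by)
  df$x_value <- if (x_var == "fold_enrichment") df$fold_enrichment
                else df$k / df$n
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x_value, y = term_label)) +
    ggplot2::geom_point(ggplot2::aes(size = k, colour = q_value)) +
    ggplot2::scale_colour_gradient(low = "#d73027", high = "#4575b4",
                                   trans = "log10",
                                   guide = ggplot2::guide_colourbar(reverse = TRUE)) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = if (x_var == "fold_enrichment") "Fold enrichment"
                  else "Gene ratio (k/n)",
                  y = NULL, colour = "q-value", size = "genes",
                  title = "Enriched terms") +
    ggplot2::theme_bw(base_size = 10)
  if (category_facet) {
    p <- p + ggplot2::facet_grid(category ~ ., scales = "free_y",
                                 space = "free_y")
  }
  if (!is.null(path)) {
    save_plot(p, path, width, height)
    return(invisible(p))
  }
  p
}

# top-n selection + deterministic ordering + label truncation;
# never mutates the input table
plot_frame <- function(table, top_n, rank_by) {
  stopifnot(inherits(table, "enrich_table"), nrow(table) >= 1, top_n >= 1)
  df <- as.data.frame(table)
  df <- df[order(df[[rank_by]], df$term_id), , drop = FALSE]
  if (top_n > nrow(df)) {
    warning(sprintf("top_n = %d exceeds the %d available terms; drawing all",
                    top_n, nrow(df)), call. = FALSE)
    top_n <- nrow(df)
  }
  df <- df[seq_len(top_n), , drop = FALSE]
  lab <- ifelse(nchar(df$term_name) > 60,
                paste0(substr(df$term_name, 1, 59), "…"), df$term_name)
  lab <- make.unique(lab)
  df$term_label <- factor(lab, levels = rev(lab))
  df$neglog_q <- -log10(pmax(df$q_value, Q_FLOOR))
  df
}

save_plot <- function(p, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg" && !capabilities("cairo")) {
    stop("svg output needs cairo support in this R build; use png or pdf",
         call. = FALSE)
  }
  dev <- switch(ext,
                png = function(f, ...) grDevices::png(f, width = width,
                                                      height = height,
                                                      units = "in", res = 150),
                pdf = function(f, ...) grDevices::pdf(f, width = width,
                                                      height = height),
                svg = function(f, ...) grDevices::svg(f, width = width,
                                                      height = height),
                stop(sprintf("unsupported plot format '%s' (png, pdf, svg)",
                             ext), call. = FALSE))
  dev(path)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
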