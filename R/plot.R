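#' Expression-curve plot for one locus
#'
#' Overlays per-sample expression curves along the exonic coordinates of a
#' locus (introns removed), in the standard visual idiom of per-base
#' isoform-usage analysis: red curves for low-expression samples, green and
#' blue for the two clusters, bold per-cluster median curves, and
#' alternating orange/blue shading marking union-exon boundaries.
#'
#' @param m A [coverage_matrix()] or wide data frame.
#' @param model Optional [gene_model()]; enables exon shading (the matrix
#'   columns must tile its union exons).
#' @param labels Named character vector (or tibble with `sample_id`,
#'   `label`) assigning each sample `"low"`, `"cluster1"` or `"cluster2"`;
#'   defaults to `"cluster1"` for all.  Unknown labels are an error.
#' @param scale `"log"` (log2 of count + 1, default) or `"raw"`.
#' @param show_medians Draw bold per-cluster median curves (default TRUE;
#'   clusters with no samples are silently omitted).
#' @param out_path Optional file path; the figure is also written with
#'   [ggplot2::ggsave()] (format from the extension).
#' @return A ggplot object.
#' @export
plot_expression <- function(m, model = NULL, labels = NULL,
                            scale = c("log", "raw"), show_medians = TRUE,
                            out_path = NULL) {
  m <- as_coverage_matrix(m)
  scale <- match.arg(scale)
  if (is.null(labels)) {
    labels <- stats::setNames(rep("cluster1", length(m$sample_ids)), m$sample_ids)
  } else if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$sample_id)
  }
  known <- c("low", "cluster1", "cluster2")
  if (!all(labels %in% known))
    abort(sprintf("unknown label(s): %s",
                  paste(setdiff(unique(labels), known), collapse = ", ")))
  missing <- setdiff(m$sample_ids, names(labels))
  if (length(missing) > 0)
    abort(sprintf("labels missing for sample(s): %s",
                  paste(missing, collapse = ", ")))

  vals <- m$counts
  storage.mode(vals) <- "double"
  if (scale == "log") vals <- log2(vals + 1)
  d <- ncol(vals)
  long <- tibble::tibble(
    sample_id = rep(m$sample_ids, each = d),
    index = rep(seq_len(d), times = nrow(vals)),
    value = as.vector(t(vals))
  )
  long$label <- unname(labels[long$sample_id])

  pal <- c(low = "#d62728", cluster1 = "#2ca02c", cluster2 = "#1f77b4")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value))

  if (!is.null(model)) {
    stopifnot(inherits(model, "gene_model"))
    if (model$length_d != d)
      abort("model exonic length does not match the matrix columns")
    widths <- model$union_exons$end - model$union_exons$start
    ends <- cumsum(widths)
    shade <- tibble::tibble(
      xmin = c(0, utils::head(ends, -1)) + 0.5, xmax = ends + 0.5,
      fill = rep(c("a", "b"), length.out = length(ends))
    )
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$fill),
      ymin = -Inf, ymax = Inf, alpha = 0.12, show.legend = FALSE
    ) +
      ggplot2::scale_fill_manual(values = c(a = "#ff7f0e", b = "#1f77b4"))
  }

  p <- p + ggplot2::geom_line(
    ggplot2::aes(group = .data$sample_id, color = .data$label),
    linewidth = 0.3, alpha = 0.6
  )
  if (show_medians) {
    med <- dplyr::summarise(
      dplyr::group_by(long, .data$label, .data$index),
      value = median(.data$value), .groups = "drop"
    )
    p <- p + ggplot2::geom_line(
      data = med,
      ggplot2::aes(group = .data$label, color = .data$label),
      linewidth = 1.1
    )
  }
  p <- p +
    ggplot2::scale_color_manual(values = pal, name = NULL) +
    ggplot2::labs(
      x = "exonic position (bp, introns removed)",
      y = if (scale == "log") "log2(coverage + 1)" else "coverage",
      title = m$gene_id
    ) +
    ggplot2::theme_minimal()

  if (!is.null(out_path)) ggplot2::ggsave(out_path, p, width = 8, height = 4.5)
  p
}

#' @param object A `sigfuge_result` with attached curves.
#' @param m Coverage matrix the result was computed from.
#' @param ... Passed to [plot_expression()].
#' @rdname plot_expression
#' @export
autoplot.sigfuge_result <- function(object, m, ...) {
  plot_expression(m, labels = object$labels, ...)
}
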