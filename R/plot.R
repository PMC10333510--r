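#' Confusion-matrix heatmap
#' @param cm an `mcr_confusion`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(cm$table)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_gradient(low = "grey25", high = "firebrick") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Subject-level accuracy %.1f%%",
                                  100 * cm$accuracy)) +
    ggplot2::theme_minimal()
}

#' Topographic map of channel importance
#'
#' Scatter of occlusion scores on the schematic 10/20 head (nose up), with
#' the highest-ranked channels labelled.
#'
#' @param imp an `mcr_importance` (from [occlusion_importance()]).
#' @param top number of channels to label (default 8).
#' @return A ggplot object.
#' @export
plot_topomap <- function(imp, top = 8) {
  mon <- montage_1020()
  df <- merge(mon, as.data.frame(imp), by.x = "name", by.y = "channel")
  lab <- df[df$rank <= top, ]
  circ <- data.frame(x = cos(seq(0, 2 * pi, length.out = 181)) * 1.25,
                     y = sin(seq(0, 2 * pi, length.out = 181)) * 1.25)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circ, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE) +
    ggplot2::annotate("polygon", x = c(-0.12, 0, 0.12), y = c(1.24, 1.4, 1.24),
                      fill = NA, color = "black") +
    ggplot2::geom_point(ggplot2::aes(size = pmax(.data$score, 0),
                                     color = .data$score)) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_color_gradient2(low = "steelblue", mid = "grey80",
                                   high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Occlusion channel importance", size = "drop",
                  color = "drop") +
    ggplot2::theme_void()
}

#' Scatter plot of a 2-D embedding
#'
#' Colors epochs by class; optionally overlays one subject's epochs in
#' black to locate an individual on the disease spectrum.
#'
#' @param emb an `mcr_embedding` carrying `class_label` (and `subject_id`
#'   when `highlight_subject` is used).
#' @param highlight_subject optional subject id to overlay.
#' @return A ggplot object.
#' @export
plot_embedding <- function(emb, highlight_subject = NULL) {
  p <- ggplot2::ggplot(emb, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                         color = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", color = "class") +
    ggplot2::theme_minimal()
  if (!is.null(highlight_subject)) {
    sel <- emb[emb$subject_id == highlight_subject, ]
    p <- p + ggplot2::geom_point(data = sel, color = "black", size = 1.5)
  }
  p
}
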