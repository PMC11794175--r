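# Figure helpers (ggplot2 when available, base graphics otherwise).

#' Violin/box plot of DLi-ASc by true stage
#'
#' @param scores Numeric DLi-ASc values.
#' @param stages Character true stages.
#' @return A ggplot object, or (base fallback) draws and returns `NULL`.
#' @export
plot_dli_by_stage <- function(scores, stages) {
  df <- data.frame(stage = factor(stages, AS_STAGES), dli = scores)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$dli)) +
             ggplot2::geom_violin(fill = "grey85") +
             ggplot2::geom_boxplot(width = 0.12, outlier.shape = NA) +
             ggplot2::labs(x = NULL, y = "DLi-ASc (0-100)") +
             ggplot2::theme_minimal())
  }
  boxplot(dli ~ stage, df, ylab = "DLi-ASc (0-100)")
  invisible(NULL)
}

#' Scatter plot of a 2-D embedding coloured by stage
#'
#' @param embedding n x 2 matrix from [embed_features()].
#' @param stages Character stages.
#' @return ggplot object or `NULL` (base fallback).
#' @export
plot_embedding <- function(embedding, stages) {
  df <- data.frame(x = embedding[, 1], y = embedding[, 2],
                   stage = factor(stages, AS_STAGES))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    return(ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                            colour = .data$stage)) +
             ggplot2::geom_point(size = 1.6) +
             ggplot2::labs(x = "dim 1", y = "dim 2", colour = "stage") +
             ggplot2::theme_minimal())
  }
  plot(df$x, df$y, col = as.integer(df$stage), pch = 19,
       xlab = "dim 1", ylab = "dim 2")
  invisible(NULL)
}
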