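#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a terminal damage profile
#'
#' 5' C->T and 3' G->A mismatch frequencies by distance from the fragment
#' end, the standard visual authenticity check for ancient DNA.
#'
#' @param object A [mismatch_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.damage_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("offset", "f5", "f3")],
    c("f5", "f3"),
    names_to = "end", values_to = "frequency"
  )
  long$end <- ifelse(long$end == "f5", "5' C>T", "3' G>A")
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$offset, .data$frequency, colour = .data$end)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "distance from fragment end (bp)",
      y = "mismatch frequency", colour = NULL,
      title = "Terminal deamination profile"
    ) +
    ggplot2::theme_minimal()
}

#' Plot reference PCA with projected ancient samples
#'
#' @param object An `adna_pca` from [reference_pca()].
#' @param projections Optional tibble from [project_ancient()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adna_pca <- function(object, projections = NULL, ...) {
  p <- ggplot2::ggplot(
    object$coordinates,
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$population)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(title = "Reference PCA") +
    ggplot2::theme_minimal()
  if (!is.null(projections)) {
    pr <- projections[projections$projected, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = pr,
      ggplot2::aes(.data$PC1, .data$PC2),
      colour = "black", shape = 18, size = 3, inherit.aes = FALSE
    ) +
      ggplot2::geom_text(
        data = pr,
        ggplot2::aes(.data$PC1, .data$PC2, label = .data$sample_id),
        colour = "black", vjust = -1, size = 3, inherit.aes = FALSE
      )
  }
  p
}

#' Stacked-bar admixture plot
#'
#' @param object An `admixture_fit` or `cluster_alignment`.
#' @param populations Optional per-individual population labels used to
#'   order the bars.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.admixture_fit <- function(object, populations = NULL, ...) {
  plot_q_matrix(object$Q, populations)
}

#' @rdname autoplot.admixture_fit
#' @export
autoplot.cluster_alignment <- function(object, populations = NULL, ...) {
  plot_q_matrix(object$Q_mean, populations)
}

plot_q_matrix <- function(q, populations = NULL) {
  ids <- rownames(q) %||% sprintf("ind%d", seq_len(nrow(q)))
  ord <- if (!is.null(populations)) order(populations, ids) else seq_along(ids)
  long <- tibble(
    id = factor(rep(ids[ord], ncol(q)), levels = ids[ord]),
    cluster = factor(rep(seq_len(ncol(q)), each = nrow(q))),
    proportion = as.vector(q[ord, , drop = FALSE])
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$id, .data$proportion, fill = .data$cluster)
  ) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
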