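#' Plot a recoding scan
#'
#' Scatter of per-contig coding fraction under table 11 against table 4.
#' Recoded genomes sit far above the diagonal; the dashed lines show the
#' candidate thresholds.
#'
#' @param reports Tibble from [scan_contigs()].
#' @param d4_min,delta_min Thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_recoding_scan <- function(reports, d4_min = 0.85, delta_min = 0.10) {
  df <- reports[reports$evaluable, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d11, y = .data$d4,
                                   colour = .data$candidate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = delta_min,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = d4_min, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "coding fraction, table 11",
                  y = "coding fraction, table 4 (TGA = Trp)",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' Plot SparCC correlations
#'
#' With a `target_bin`, a ranked lollipop of every other bin's basis
#' correlation with the target (the host-attribution view); otherwise a
#' correlation heatmap.
#'
#' @param object A [sparcc()] fit.
#' @param target_bin Optional target bin.
#' @param rho_min Threshold drawn as a guide in the target view.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sparcc_fit <- function(object, target_bin = NULL, rho_min = 0.8,
                                ...) {
  if (!is.null(target_bin)) {
    others <- setdiff(rownames(object$rho), target_bin)
    df <- tibble::tibble(bin_id = others,
                         rho = object$rho[target_bin, others])
    df$bin_id <- stats::reorder(df$bin_id, df$rho)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$bin_id)) +
        ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$rho,
                                           yend = .data$bin_id),
                              colour = "grey70") +
        ggplot2::geom_point() +
        ggplot2::geom_vline(xintercept = rho_min, linetype = "dashed",
                            colour = "grey40") +
        ggplot2::labs(x = paste("basis correlation with", target_bin),
                      y = NULL) +
        ggplot2::theme_minimal()
    )
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_a, y = .data$bin_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Paired abundance profiles across samples
#'
#' Co-occurrence view for two bins: per-sample length-weighted abundances
#' on a log scale, samples ordered by the first bin's abundance.
#'
#' @param A Abundance matrix from [bin_abundance()].
#' @param bin_a,bin_b Bin ids to compare.
#' @return A ggplot object.
#' @export
plot_abundance_pair <- function(A, bin_a, bin_b) {
  stopifnot(bin_a %in% rownames(A), bin_b %in% rownames(A))
  ord <- order(A[bin_a, ])
  lev <- colnames(A)[ord]
  df <- tibble::tibble(
    sample_id = factor(rep(lev, 2), levels = lev),
    bin_id = rep(c(bin_a, bin_b), each = length(lev)),
    abundance = c(A[bin_a, ord], A[bin_b, ord])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$abundance,
                                   colour = .data$bin_id,
                                   group = .data$bin_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample", y = "length-weighted abundance",
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}
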