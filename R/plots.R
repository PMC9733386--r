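# ggplot2 views of the main result types.

#' Cis-window plot of an allele-specific or mixed-model scan
#'
#' Distance from the feature midpoint against -log10 p (first-test p for
#' allele-specific scans, Wald p for mixed-model scans), significant pairs
#' highlighted.
#'
#' @param scan An `asqtl_as_scan` or `asqtl_mlm_scan`.
#' @param features Optional character vector restricting the features shown.
#' @return A ggplot.
#' @export
plot_scan <- function(scan, features = NULL) {
  p_col <- if ("p1" %in% names(scan)) "p1" else "p"
  d <- as_tibble(scan)
  if (!is.null(features)) d <- d |> filter(.data$feature_id %in% features)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$distance_bp / 1e3,
    y = -log10(.data[[p_col]]),
    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "distance from feature midpoint (kb)",
                  y = expression(-log[10](p)), colour = "significant") +
    ggplot2::theme_minimal()
}

#' Sequence-logo-style view of a motif cluster PFM
#'
#' Per-position stacked base frequencies scaled by information content
#' (2 - entropy, bits).
#'
#' @param pfm A 4 x width count matrix (rows A, C, G, T).
#' @return A ggplot.
#' @export
plot_pfm <- function(pfm) {
  freq <- sweep(pfm, 2, colSums(pfm), "/")
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    2 + sum(f * log2(f))
  })
  colnames(freq) <- sprintf("pos%d", seq_len(ncol(freq)))
  d <- as_tibble(freq, rownames = "base") |>
    tidyr::pivot_longer(-"base", names_to = "col", values_to = "freq") |>
    mutate(position = as.integer(gsub("\\D", "", .data$col)),
           bits = .data$freq * ic[.data$position])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$bits,
                                  fill = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(x = "position", y = "information (bits)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.asqtl_as_scan <- function(object, ...) plot_scan(object)

#' @export
autoplot.asqtl_mlm_scan <- function(object, ...) plot_scan(object)

#' Enrichment overview of a motif set
#'
#' Observed/expected genomic enrichment per retained cluster, on a log
#' scale, sized by cluster membership.
#'
#' @param object An `asqtl_motif_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asqtl_motif_set <- function(object, ...) {
  d <- object$clusters |> filter(!is.na(.data$enrichment))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$iupac, .data$enrichment),
                                  y = .data$enrichment, size = .data$size)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "observed / expected", size = "sequences") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
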