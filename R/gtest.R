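# Within-feature heterogeneity of maternal:paternal ratios (G-test).

#' G-test of allelic-ratio heterogeneity across sites in a feature
#'
#' For s heterozygous sites in a feature with maternal/paternal counts
#' `n_ij`, tests the null that the maternal:paternal ratio is shared across
#' sites, using
#' `G = 2(sum n_ij ln n_ij + n.. ln n.. - sum n.j ln n.j - sum n_i. ln n_i.)`
#' with the convention `0 ln 0 = 0`, against chi-squared on `s - 1` degrees
#' of freedom. A single-site table is degenerate: G = 0, df = 0, p = 1.
#'
#' @param table Numeric matrix or data frame with s rows (sites) and 2
#'   columns (maternal, paternal counts).
#' @return Tibble with `G`, `df`, `p`, `s`, `degenerate`.
#' @export
#' @examples
#' heterogeneity_g_test(rbind(c(30, 10), c(10, 30)))
heterogeneity_g_test <- function(table) {
  tab <- as.matrix(table)
  stopifnot(ncol(tab) == 2, all(tab >= 0))
  s <- nrow(tab)
  if (s == 1) {
    return(tibble(G = 0, df = 0L, p = 1, s = 1L, degenerate = TRUE))
  }
  row_tot <- rowSums(tab)
  col_tot <- colSums(tab)
  grand <- sum(tab)
  G <- 2 * (sum(xlogx(tab)) + xlogx(grand) - sum(xlogx(col_tot)) -
              sum(xlogx(row_tot)))
  # numerically zero under identical ratios; snap fp residue so p is exact
  G <- max(G, 0)
  if (G < 1e-9) G <- 0
  df <- s - 1L
  tibble(G = G, df = as.integer(df), p = pchisq(G, df, lower.tail = FALSE),
         s = as.integer(s), degenerate = FALSE)
}

#' Heterogeneity G-tests for every multi-site animal-feature table
#'
#' Builds, per feature, the s x 2 table of summed maternal/paternal counts
#' per site (summing across animals heterozygous at that site) and applies
#' [heterogeneity_g_test()].
#'
#' @param allele_counts Tibble (animal_id, snp_id, maternal_count,
#'   paternal_count) of retained heterozygous sites.
#' @param features An `asqtl_features`.
#' @return Tibble: feature_id, type, G, df, p, s, degenerate.
#' @export
feature_heterogeneity <- function(allele_counts, features) {
  per_site <- allele_counts |>
    group_by(.data$snp_id) |>
    summarise(maternal = sum(.data$maternal_count),
              paternal = sum(.data$paternal_count), .groups = "drop")
  sm <- features$snp_map |>
    inner_join(per_site, by = "snp_id") |>
    left_join(features$features[, c("feature_id", "type")], by = "feature_id")
  sm |>
    group_by(.data$feature_id, .data$type) |>
    dplyr::group_modify(function(d, key) {
      heterogeneity_g_test(cbind(d$maternal, d$paternal))
    }) |>
    ungroup()
}

#' Fraction of multi-site features with heterogeneous allelic ratios
#'
#' Per feature class, the fraction of features with at least two sites whose
#' G-test p falls below `alpha`. Classes with no multi-site features report
#' 0 of 0.
#'
#' @param het_table Output of [feature_heterogeneity()].
#' @param alpha Flag level (default 0.05).
#' @return Tibble: type, n_multi_site, n_heterogeneous, fraction.
#' @export
summarize_heterogeneity <- function(het_table, alpha = 0.05) {
  het_table |>
    filter(.data$s >= 2) |>
    group_by(.data$type) |>
    summarise(n_multi_site = n(),
              n_heterogeneous = sum(.data$p < alpha), .groups = "drop") |>
    mutate(fraction = ifelse(.data$n_multi_site > 0,
                             .data$n_heterogeneous / .data$n_multi_site, 0))
}
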