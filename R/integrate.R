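# Intersection of the four QTL result sets: overlap odds ratios, direction
# concordance, enrichment under peaks, peak-exon linking, p-value
# combination and causal-candidate selection.

#' Overlap odds ratio between two significant-feature sets
#'
#' From a tested universe of size `n_tested` and two hit sets, forms the
#' 2x2 table `a = |A and B|`, `b = |A| - a`, `c = |B| - a`,
#' `d = n_tested - |A| - |B| + a` and reports the sample cross-product odds
#' ratio `a d / (b c)`. Marginals may be given directly (counts) instead of
#' sets.
#'
#' @param n_tested Size of the tested universe.
#' @param set_a,set_b Character vectors of hits, or single counts when
#'   `n_both` is supplied.
#' @param n_both Overlap count, only when marginals are passed as counts.
#' @return Tibble: n_tested, n_a, n_b, n_both, a, b, c, d, odds_ratio,
#'   infinite (flag for a zero `b c`).
#' @export
#' @examples
#' overlap_odds_ratio(48456, 15308, 25163, n_both = 10678)
overlap_odds_ratio <- function(n_tested, set_a, set_b, n_both = NULL) {
  if (is.null(n_both)) {
    n_a <- length(unique(set_a)); n_b <- length(unique(set_b))
    n_both <- length(intersect(unique(set_a), unique(set_b)))
  } else {
    n_a <- as.numeric(set_a); n_b <- as.numeric(set_b)
  }
  a <- n_both; b <- n_a - n_both; c <- n_b - n_both
  d <- n_tested - n_a - n_b + n_both
  assert_that(all(c(a, b, c, d) >= 0), "inconsistent overlap marginals")
  inf <- b * c == 0
  tibble(n_tested = n_tested, n_a = n_a, n_b = n_b, n_both = n_both,
         a = a, b = b, c = c, d = d,
         odds_ratio = if (inf) Inf else a * d / (b * c),
         infinite = inf)
}

#' Direction concordance of shared significant dSNPs
#'
#' Intersects two result sets on (feature_id, dsnp/snp id), keeping rows
#' significant in both, and reports the fraction of shared pairs whose
#' effect signs agree. Both inputs must use the alternate-allele sign
#' convention (allele-specific slope with alt-maternal coded +1; dosage beta
#' of the alternate-allele count). Zero-effect entries are excluded from the
#' fraction and counted separately.
#'
#' @param results_a,results_b Tibbles with `feature_id`, a SNP id column
#'   (`dsnp_id` or `snp_id`), an effect column (`b` or `beta`) and
#'   `significant`.
#' @return Tibble: n_shared, n_same_sign, n_zero, fraction_same_sign.
#' @export
direction_concordance <- function(results_a, results_b) {
  std <- function(r) {
    sid <- if ("dsnp_id" %in% names(r)) "dsnp_id" else "snp_id"
    eff <- if ("b" %in% names(r)) "b" else "beta"
    r |>
      filter(.data$significant) |>
      select(feature_id = "feature_id", snp = dplyr::all_of(sid),
             effect = dplyr::all_of(eff))
  }
  shared <- inner_join(std(results_a), std(results_b),
                       by = c("feature_id", "snp"), suffix = c("_a", "_b"))
  zero <- shared$effect_a == 0 | shared$effect_b == 0
  nonzero <- shared[!zero, , drop = FALSE]
  tibble(
    n_shared = nrow(shared),
    n_same_sign = sum(sign(nonzero$effect_a) == sign(nonzero$effect_b)),
    n_zero = sum(zero),
    fraction_same_sign = if (nrow(nonzero) > 0) {
      sum(sign(nonzero$effect_a) == sign(nonzero$effect_b)) / nrow(nonzero)
    } else {
      NA_real_
    })
}

#' Enrichment of QTL under peaks
#'
#' `Enrichment = (C/A) / (B/D)`: values above 1 indicate enrichment, below 1
#' depletion. In the default `"sites"` convention, A is the number of tested
#' positions under (merged) peaks, B the number of QTL positions, C the
#' number of QTL under peaks and D the number of tested positions. In the
#' `"bp"` convention A is merged peak base pairs and D genome base pairs
#' (B, C stay QTL site counts).
#'
#' @param qtl_positions Tibble (chrom, pos) of QTL sites.
#' @param peak_intervals Tibble (chrom, start, end), 0-based half-open;
#'   overlaps are merged before counting.
#' @param all_positions Tibble (chrom, pos) of every tested site (required
#'   for `mode = "sites"`).
#' @param genome_size Total genome length in bp (required for
#'   `mode = "bp"`).
#' @param mode `"sites"` (default) or `"bp"`.
#' @return Tibble: A, B, C, D, enrichment.
#' @export
enrichment_under_peaks <- function(qtl_positions, peak_intervals,
                                   all_positions = NULL, genome_size = NULL,
                                   mode = c("sites", "bp")) {
  mode <- match.arg(mode)
  peaks <- GenomicRanges::reduce(GenomicRanges::GRanges(
    peak_intervals$chrom,
    IRanges::IRanges(start = peak_intervals$start + 1, end = peak_intervals$end)))
  count_under <- function(pos_tbl) {
    gr <- GenomicRanges::GRanges(pos_tbl$chrom,
                                 IRanges::IRanges(pos_tbl$pos + 1, pos_tbl$pos + 1))
    sum(IRanges::overlapsAny(gr, peaks))
  }
  B <- nrow(qtl_positions)
  C <- count_under(qtl_positions)
  if (mode == "sites") {
    assert_that(!is.null(all_positions), "mode 'sites' needs all_positions")
    A <- count_under(all_positions)
    D <- nrow(all_positions)
  } else {
    assert_that(!is.null(genome_size), "mode 'bp' needs genome_size")
    A <- sum(IRanges::width(peaks))
    D <- genome_size
  }
  assert_that(A > 0 && B > 0 && D > 0, "enrichment undefined: A, B or D is 0")
  tibble(A = A, B = B, C = C, D = D, enrichment = (C / A) / (B / D))
}

#' Link peaks to exons through shared significant dSNPs
#'
#' Every (peak, exon) pair sharing at least one significant dSNP is
#' reported with the number of shared dSNPs and the midpoint distance.
#'
#' @param peak_results,exon_results Scan tibbles with `feature_id`,
#'   `dsnp_id`/`snp_id` and `significant`.
#' @param features An `asqtl_features` (midpoints).
#' @return List: `pairs` tibble (peak_id, exon_id, n_shared_dsnps,
#'   distance_bp) and `summary` tibble (n_pairs, median_distance,
#'   peaks_per_exon, exons_per_peak).
#' @export
link_peak_exon_pairs <- function(peak_results, exon_results, features) {
  sid <- function(r) if ("dsnp_id" %in% names(r)) "dsnp_id" else "snp_id"
  pk <- peak_results |> filter(.data$significant) |>
    select(peak_id = "feature_id", snp = dplyr::all_of(sid(peak_results)))
  ex <- exon_results |> filter(.data$significant) |>
    select(exon_id = "feature_id", snp = dplyr::all_of(sid(exon_results)))
  mid <- setNames(features$features$midpoint, features$features$feature_id)
  pairs <- inner_join(pk, ex, by = "snp", relationship = "many-to-many") |>
    group_by(.data$peak_id, .data$exon_id) |>
    summarise(n_shared_dsnps = dplyr::n_distinct(.data$snp), .groups = "drop") |>
    mutate(distance_bp = abs(mid[.data$peak_id] - mid[.data$exon_id]))
  summary <- tibble(
    n_pairs = nrow(pairs),
    median_distance = if (nrow(pairs)) median(pairs$distance_bp) else NA_real_,
    peaks_per_exon = if (nrow(pairs)) {
      nrow(pairs) / dplyr::n_distinct(pairs$exon_id)
    } else NA_real_,
    exons_per_peak = if (nrow(pairs)) {
      nrow(pairs) / dplyr::n_distinct(pairs$peak_id)
    } else NA_real_)
  list(pairs = pairs, summary = summary)
}

#' Combine four p-values on the chi-squared scale
#'
#' Each p is converted to its upper-tail chi-squared(1 df) quantile, the
#' quantiles are summed, and the combined p is the upper tail of
#' chi-squared with 4 df at the sum. Zero inputs are clamped to the smallest
#' representable positive double with a warning.
#'
#' @param p_h,p_ee,p_asb1,p_ase1 Numeric vectors of p-values in (0, 1]
#'   (histone, exon-expression, and first-test allele-specific binding and
#'   expression).
#' @return Numeric vector of combined p-values.
#' @export
#' @examples
#' combine_pvalues(0.05, 0.05, 0.05, 0.05)
combine_pvalues <- function(p_h, p_ee, p_asb1, p_ase1) {
  ps <- cbind(p_h, p_ee, p_asb1, p_ase1)
  if (any(ps == 0, na.rm = TRUE)) {
    warn("p-value of 0 clamped to the smallest representable positive value")
    ps[ps == 0] <- .Machine$double.xmin
  }
  stopifnot(all(ps > 0 & ps <= 1, na.rm = TRUE))
  chi <- qchisq(ps, df = 1, lower.tail = FALSE)
  pchisq(rowSums(chi), df = 4, lower.tail = FALSE)
}

#' Select putative causal variants
#'
#' Applies the three published filter criteria to the four result sets: the
#' variant is significant (p below `significance`) in the histone and
#' exon-expression scans and in the *first* test of both allele-specific
#' scans; it lies inside the peak it is associated with; and its direction
#' of effect agrees across all four analyses. Surviving candidates get a
#' 4-df chi-squared combined p, and only the lowest combined p per
#' (peak, exon) pair is retained (ties broken by lowest genomic position,
#' logged in the `tie_broken` attribute).
#'
#' @param h_results,ee_results Tibbles from [trad_scan()] (peaks, exons).
#' @param asb_results,ase_results Tibbles from [as_scan()] (peaks, exons).
#' @param features An `asqtl_features` (peak intervals).
#' @param significance Threshold for all four p-values (default 1e-4).
#' @return Tibble of class `asqtl_causal`: snp_id, peak_id, exon_id, pos,
#'   p_h, p_ee, p_asb1, p_ase1, combined_p, in_peak, direction_concordant.
#' @export
select_putative_causal <- function(h_results, ee_results, asb_results,
                                   ase_results, features,
                                   significance = 1e-4) {
  feats <- features$features
  h <- h_results |>
    select(peak_id = "feature_id", snp_id = "snp_id", pos = "pos",
           p_h = "p", eff_h = "beta")
  ee <- ee_results |>
    select(exon_id = "feature_id", snp_id = "snp_id", p_ee = "p",
           eff_ee = "beta")
  asb <- asb_results |>
    select(peak_id = "feature_id", snp_id = "dsnp_id", p_asb1 = "p1",
           eff_asb = "b")
  ase <- ase_results |>
    select(exon_id = "feature_id", snp_id = "dsnp_id", p_ase1 = "p1",
           eff_ase = "b")

  cand <- h |>
    inner_join(asb, by = c("peak_id", "snp_id")) |>
    inner_join(ee, by = "snp_id", relationship = "many-to-many") |>
    inner_join(ase, by = c("exon_id", "snp_id"))

  if (nrow(cand) == 0) {
    out <- tibble(snp_id = character(), peak_id = character(),
                  exon_id = character(), pos = integer(), p_h = numeric(),
                  p_ee = numeric(), p_asb1 = numeric(), p_ase1 = numeric(),
                  combined_p = numeric(), in_peak = logical(),
                  direction_concordant = logical())
    class(out) <- c("asqtl_causal", class(out))
    return(out)
  }

  pk <- feats[match(cand$peak_id, feats$feature_id), ]
  cand <- cand |>
    mutate(
      in_peak = .data$pos >= pk$start & .data$pos < pk$end,
      direction_concordant =
        sign(.data$eff_h) == sign(.data$eff_ee) &
        sign(.data$eff_h) == sign(.data$eff_asb) &
        sign(.data$eff_h) == sign(.data$eff_ase) &
        sign(.data$eff_h) != 0,
      pass_p = .data$p_h < significance & .data$p_ee < significance &
        .data$p_asb1 < significance & .data$p_ase1 < significance) |>
    filter(.data$pass_p, .data$in_peak, .data$direction_concordant)

  if (nrow(cand) == 0) {
    out <- cand |>
      mutate(combined_p = numeric(0)) |>
      select("snp_id", "peak_id", "exon_id", "pos", "p_h", "p_ee", "p_asb1",
             "p_ase1", "combined_p", "in_peak", "direction_concordant")
    class(out) <- c("asqtl_causal", class(out))
    return(out)
  }

  cand$combined_p <- combine_pvalues(cand$p_h, cand$p_ee, cand$p_asb1,
                                     cand$p_ase1)
  # deterministic selection: order first so ties resolve to lowest position
  cand <- cand |> arrange(.data$peak_id, .data$exon_id, .data$combined_p,
                          .data$pos)
  ties <- cand |>
    group_by(.data$peak_id, .data$exon_id) |>
    filter(sum(.data$combined_p == min(.data$combined_p)) > 1) |>
    ungroup()
  out <- cand |>
    group_by(.data$peak_id, .data$exon_id) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("snp_id", "peak_id", "exon_id", "pos", "p_h", "p_ee", "p_asb1",
           "p_ase1", "combined_p", "in_peak", "direction_concordant")
  attr(out, "tie_broken") <- unique(ties[, c("peak_id", "exon_id")])
  class(out) <- c("asqtl_causal", class(out))
  out
}
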