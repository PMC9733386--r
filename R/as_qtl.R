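# Two-stage allele-specific QTL scan: binomial first-test gate, then a
# phased log-ratio regression.

#' Allele-specific first test
#'
#' Over animals heterozygous at the candidate driver SNP (dSNP), pools the
#' reads carrying the alternate-haplotype signal:
#' `A = sum(maternal | dSNP 1|0) + sum(paternal | dSNP 0|1)`, `T` the total
#' reads of those animals, and `Z = (A/T - 0.5) * sqrt(4T)`, approximately
#' standard normal under the null of no cis effect. Two-sided p from the
#' normal tail.
#'
#' @param maternal,paternal Per-animal summed feature allele counts.
#' @param x Per-animal dSNP phase coding: +1 for 1|0 (alternate maternal),
#'   -1 for 0|1, 0 for homozygous; NA for unphased (dropped).
#' @param gate First-test gate threshold (default 0.001).
#' @return Tibble: A, T, Z, p1, n_het, gated. `T = 0` gives an NA result.
#' @export
#' @examples
#' as_first_test(c(30, 10), c(10, 30), c(1, -1))
as_first_test <- function(maternal, paternal, x, gate = 1e-3) {
  keep <- !is.na(x)
  maternal <- maternal[keep]; paternal <- paternal[keep]; x <- x[keep]
  het <- x != 0
  T_tot <- sum(maternal[het] + paternal[het])
  if (T_tot == 0) {
    return(tibble(A = NA_real_, T = 0, Z = NA_real_, p1 = NA_real_,
                  n_het = sum(het), gated = FALSE))
  }
  A <- sum(maternal[het & x == 1]) + sum(paternal[het & x == -1])
  Z <- (A / T_tot - 0.5) * sqrt(4 * T_tot)
  p1 <- 2 * pnorm(-abs(Z))
  tibble(A = A, T = T_tot, Z = Z, p1 = p1, n_het = sum(het), gated = p1 < gate)
}

#' Allele-specific second test (phased log-ratio regression)
#'
#' Fits `Y_i = a + b X_i` by ordinary least squares, where
#' `Y_i = ln((maternal_i + 10) / (paternal_i + 10))` over every animal with
#' feature counts and a phased dSNP genotype, and `X_i` is 0 / +1 / -1 for
#' dSNP 0|0 or 1|1 / 1|0 / 0|1. The +10 pseudocount stabilises low counts.
#' Two-sided t-test on the slope.
#'
#' @inheritParams as_first_test
#' @return Tibble: a, b, se, p2, n, slope_sign, degenerate (zero residual
#'   variance or fewer than 2 distinct X values, p undefined).
#' @export
as_second_test <- function(maternal, paternal, x) {
  keep <- !is.na(x)
  maternal <- maternal[keep]; paternal <- paternal[keep]; x <- x[keep]
  y <- log((maternal + 10) / (paternal + 10))
  n <- length(y)
  if (n < 3 || length(unique(x)) < 2) {
    return(tibble(a = NA_real_, b = NA_real_, se = NA_real_, p2 = NA_real_,
                  n = n, slope_sign = NA_real_, degenerate = TRUE))
  }
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  if (rss < 1e-12) {
    return(tibble(a = a, b = b, se = 0, p2 = NA_real_, n = n,
                  slope_sign = sign(b), degenerate = TRUE))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- b / se
  tibble(a = a, b = b, se = se, p2 = 2 * pt(-abs(tstat), n - 2), n = n,
         slope_sign = sign(b), degenerate = FALSE)
}

#' Scan one feature for allele-specific QTL
#'
#' Tests every SNP within `window` bp of the feature midpoint as a candidate
#' dSNP: the first test gates (p < `gate`), gated SNPs get the second test,
#' and a dSNP is significant when both p-values fall below `significance`.
#'
#' @param feature One row of a feature tibble (feature_id, chrom, midpoint).
#' @param feature_counts Tibble of per-animal summed counts for this feature
#'   (animal_id, maternal_count, paternal_count).
#' @param phase An `asqtl_phase` (or simulator truth phase).
#' @param window Bp either side of the midpoint (default 1 Mb).
#' @param gate,significance Thresholds (defaults 1e-3 and 1e-4).
#' @return Tibble of results, one row per tested dSNP.
#' @export
scan_feature <- function(feature, feature_counts, phase,
                         window = 1e6, gate = 1e-3, significance = 1e-4) {
  snps <- phase$snps
  cand <- which(snps$chrom == feature$chrom &
                  abs(snps$pos - feature$midpoint) <= window)
  empty <- tibble(feature_id = character(), dsnp_id = character(),
                  chrom = character(), pos = integer(), distance_bp = integer(),
                  A = numeric(), T = numeric(), Z = numeric(), p1 = numeric(),
                  b = numeric(), se = numeric(), p2 = numeric(),
                  slope_sign = numeric(), n_het = integer(),
                  significant = logical())
  if (length(cand) == 0 || nrow(feature_counts) == 0) return(empty)

  animals <- feature_counts$animal_id
  ai <- match(animals, rownames(phase$maternal))
  mat <- feature_counts$maternal_count
  pat <- feature_counts$paternal_count
  xmat <- (phase$maternal - phase$paternal)[ai, cand, drop = FALSE]
  phased_ok <- matrix(phase$provenance[ai, cand] %in%
                        c("homozygous", "sire-homozygous", "carried-phase"),
                      length(ai), length(cand))
  xmat[!phased_ok] <- NA

  # vectorised first test across candidate dSNPs
  het_m <- !is.na(xmat) & xmat != 0
  Tvec <- as.numeric(crossprod(mat + pat, het_m))
  Avec <- as.numeric(crossprod(mat, het_m & xmat == 1)) +
    as.numeric(crossprod(pat, het_m & xmat == -1))
  Zvec <- ifelse(Tvec > 0, (Avec / Tvec - 0.5) * sqrt(4 * Tvec), NA_real_)
  p1 <- 2 * pnorm(-abs(Zvec))

  res <- tibble(
    feature_id = feature$feature_id,
    dsnp_id = snps$snp_id[cand],
    chrom = snps$chrom[cand],
    pos = snps$pos[cand],
    distance_bp = as.integer(snps$pos[cand] - feature$midpoint),
    A = ifelse(Tvec > 0, Avec, NA_real_),
    T = Tvec, Z = Zvec, p1 = p1,
    b = NA_real_, se = NA_real_, p2 = NA_real_, slope_sign = NA_real_,
    n_het = as.integer(colSums(het_m))
  ) |> filter(.data$T > 0)

  # second test, vectorised over gated dSNPs (same closed form as
  # as_second_test; animals with unphased dSNP genotypes drop per column)
  gated <- which(res$p1 < gate)
  if (length(gated) > 0) {
    k <- match(res$dsnp_id[gated], snps$snp_id[cand])
    y <- log((mat + 10) / (pat + 10))
    X <- xmat[, k, drop = FALSE]
    V <- !is.na(X)
    X0 <- ifelse(V, X, 0)
    nv <- colSums(V)
    sx <- colSums(X0); sy <- as.numeric(crossprod(y, V))
    sxx <- colSums(X0^2) - sx^2 / nv
    sxy <- as.numeric(crossprod(y, X0)) - sx * sy / nv
    syy <- as.numeric(crossprod(y^2, V)) - sy^2 / nv
    b <- ifelse(sxx > 0, sxy / sxx, NA_real_)
    rss <- pmax(syy - b^2 * sxx, 0)
    ok <- !is.na(b) & nv >= 3 & rss > 1e-12
    se <- ifelse(ok, sqrt(rss / (nv - 2) / sxx), NA_real_)
    p2 <- ifelse(ok, 2 * pt(-abs(b / se), nv - 2), NA_real_)
    res$b[gated] <- b
    res$se[gated] <- se
    res$p2[gated] <- p2
    res$slope_sign[gated] <- sign(b)
  }
  res$significant <- !is.na(res$p1) & res$p1 < significance &
    !is.na(res$p2) & res$p2 < significance
  res
}

#' Allele-specific QTL scan over a feature class
#'
#' Runs [scan_feature()] for every feature of the requested type that has an
#' aggregated allele-count table.
#'
#' @param feature_counts An `asqtl_feature_counts` (from
#'   [collect_feature_counts()]).
#' @param features An `asqtl_features`.
#' @param phase An `asqtl_phase`.
#' @param type `"peak"` (allele-specific binding) or `"exon"`
#'   (allele-specific expression).
#' @inheritParams scan_feature
#' @return Tibble of class `asqtl_as_scan` with one row per feature-dSNP
#'   pair tested.
#' @export
as_scan <- function(feature_counts, features, phase, type = c("peak", "exon"),
                    window = 1e6, gate = 1e-3, significance = 1e-4) {
  type <- match.arg(type)
  feats <- features$features |> filter(.data$type == !!type)
  counts <- feature_counts$counts
  out <- purrr::map_dfr(seq_len(nrow(feats)), function(i) {
    f <- feats[i, ]
    fc <- counts |> filter(.data$feature_id == f$feature_id)
    if (nrow(fc) == 0) return(NULL)
    scan_feature(f, fc, phase, window = window, gate = gate,
                 significance = significance)
  })
  class(out) <- c("asqtl_as_scan", class(out))
  attr(out, "type") <- type
  attr(out, "significance") <- significance
  out
}
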