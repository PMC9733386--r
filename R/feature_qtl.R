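# Traditional QTL phenotypes: peak QC and input-residual normalisation,
# expression stabilisation, PCA outlier removal.

#' Quality-control ChIP peaks
#'
#' Removes peaks whose total read count (summed across animals) falls below
#' the 1% empirical quantile of per-peak totals, and peaks whose total input
#' count exceeds five times the mean total input (reference-genome
#' artefacts). Quantiles use the default linear-interpolation convention.
#'
#' @param peak_counts,input_counts Peak x animal count matrices, aligned.
#' @param quantile_cut Lower quantile for the peak-count rule (default 0.01).
#' @param input_fold Fold-over-mean threshold for the input rule (default 5).
#' @return List: `peak_counts`, `input_counts` (retained rows) and `removed`
#'   tibble (feature_id, reason).
#' @export
qc_peaks <- function(peak_counts, input_counts, quantile_cut = 0.01,
                     input_fold = 5) {
  stopifnot(identical(dim(peak_counts), dim(input_counts)))
  peak_tot <- rowSums(peak_counts)
  input_tot <- rowSums(input_counts)
  low <- peak_tot < quantile(peak_tot, quantile_cut)
  artefact <- input_tot > input_fold * mean(input_tot)
  removed <- bind_rows(
    tibble(feature_id = rownames(peak_counts)[low], reason = "below-1pct-quantile"),
    tibble(feature_id = rownames(peak_counts)[artefact & !low],
           reason = "input-artefact"))
  keep <- !(low | artefact)
  if (!any(keep)) abort("all peaks removed by QC", class = "asqtl_error")
  list(peak_counts = peak_counts[keep, , drop = FALSE],
       input_counts = input_counts[keep, , drop = FALSE],
       removed = removed)
}

#' Peak phenotype: input-corrected log normalised counts
#'
#' Counts are normalised by the per-animal mean across peaks
#' (`PN_ij = P_ij / mean_i(P_ij)`, same for input), log-transformed
#' (`y = ln(PN + 1)`, `x = ln(IN + 1)`), and per peak an OLS fit
#' `y = alpha + beta x + eps` removes the input effect; the residual vector
#' is the phenotype. Animals with a zero mean count are dropped with a log
#' entry.
#'
#' @param peak_counts,input_counts QC'd peak x animal matrices.
#' @param normalize Divide by the per-animal mean first (default TRUE; FALSE
#'   applies the log/OLS step to the raw counts, useful for checking the
#'   regression in isolation).
#' @return List of class `asqtl_peak_phenotype`: `phenotype` (peak x animal
#'   residual matrix), `coef` tibble (feature_id, alpha, beta), `dropped`
#'   character vector of animals.
#' @export
normalize_peak_phenotype <- function(peak_counts, input_counts,
                                     normalize = TRUE) {
  peak_mean <- colMeans(peak_counts)
  input_mean <- colMeans(input_counts)
  if (!normalize) {
    peak_mean <- rep(1, ncol(peak_counts))
    input_mean <- rep(1, ncol(input_counts))
  }
  drop <- peak_mean == 0 | input_mean == 0
  if (any(drop)) {
    warn(sprintf("dropping %d animal(s) with zero mean count", sum(drop)))
    peak_counts <- peak_counts[, !drop, drop = FALSE]
    input_counts <- input_counts[, !drop, drop = FALSE]
    peak_mean <- peak_mean[!drop]; input_mean <- input_mean[!drop]
  }
  y <- log(sweep(peak_counts, 2, peak_mean, "/") + 1)
  x <- log(sweep(input_counts, 2, input_mean, "/") + 1)
  # row-wise simple OLS, closed form
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sxx <- rowSums(xc^2)
  beta <- ifelse(sxx > 0, rowSums(xc * yc) / sxx, 0)
  alpha <- rowMeans(y) - beta * rowMeans(x)
  resid <- yc - beta * xc
  structure(list(
    phenotype = resid,
    coef = tibble(feature_id = rownames(peak_counts), alpha = alpha, beta = beta),
    dropped = names(drop)[drop]
  ), class = "asqtl_peak_phenotype")
}

#' Expression phenotype: stabilised, batch-adjusted exon counts
#'
#' Exons with a median read count below `min_median` are excluded. Remaining
#' counts are divided by median-of-ratios size factors (the ratio, per
#' animal, of counts to the exon-wise geometric mean, taking the median over
#' exons) and transformed `log2(count / sf + 1)` — a defined
#' variance-stabilising stand-in. Batch effects are then removed per exon by
#' centring each batch at the grand mean; single-animal batches are left
#' uncentred with a warning.
#'
#' @param exon_counts Exon x animal count matrix.
#' @param batches Tibble (animal_id, batch) or NULL for no adjustment.
#' @param min_median Median-count exclusion threshold (default 5).
#' @return List of class `asqtl_expression_phenotype`: `phenotype` (exon x
#'   animal matrix), `size_factors`, `excluded` (exon ids).
#' @export
transform_expression <- function(exon_counts, batches = NULL, min_median = 5) {
  med <- apply(exon_counts, 1, median)
  excluded <- rownames(exon_counts)[med < min_median]
  counts <- exon_counts[med >= min_median, , drop = FALSE]
  assert_that(nrow(counts) > 0, "all exons removed by the median filter")
  sf <- median_of_ratios(counts)
  v <- log2(sweep(counts, 2, sf, "/") + 1)
  if (!is.null(batches)) {
    b <- batches$batch[match(colnames(v), batches$animal_id)]
    sizes <- table(b)
    small <- names(sizes)[sizes < 2]
    if (length(small) > 0) {
      warn(sprintf("batch(es) with a single animal left uncentred: %s",
                   paste(small, collapse = ", ")))
    }
    grand <- rowMeans(v)
    for (lev in setdiff(names(sizes), small)) {
      idx <- which(b == lev)
      v[, idx] <- v[, idx] - rowMeans(v[, idx, drop = FALSE]) + grand
    }
  }
  structure(list(phenotype = v, size_factors = sf, excluded = excluded),
            class = "asqtl_expression_phenotype")
}

# DESeq-style median-of-ratios size factors
median_of_ratios <- function(counts) {
  logs <- log(counts)
  usable <- apply(is.finite(logs), 1, all)
  if (!any(usable)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
  log_geo <- rowMeans(logs[usable, , drop = FALSE])
  sf <- apply(logs[usable, , drop = FALSE], 2,
              function(col) exp(median(col - log_geo)))
  setNames(sf, colnames(counts))
}

#' PCA-based outlier filtering of animals
#'
#' Single-pass: animals whose score on any of the first `n_components`
#' principal components lies more than `sd_limit` standard deviations from
#' that component's mean are removed. With fewer animals than requested
#' components, all available components are used with a warning.
#'
#' @param phenotype Feature x animal phenotype matrix.
#' @param n_components Number of leading components to screen (default 7).
#' @param sd_limit Standard-deviation limit (default 4).
#' @return List: `retained` (animal ids), `removed`, `scores` (animal x PC).
#' @export
pca_outlier_filter <- function(phenotype, n_components = 7, sd_limit = 4) {
  x <- t(phenotype)  # animals x features
  k_max <- min(nrow(x) - 1L, ncol(x))
  k <- min(n_components, k_max)
  if (k < n_components) {
    warn(sprintf("only %d component(s) available; capping", k))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  z <- sweep(sweep(scores, 2, colMeans(scores)), 2, apply(scores, 2, sd), "/")
  out <- apply(abs(z) > sd_limit, 1, any)
  list(retained = rownames(x)[!out], removed = rownames(x)[out], scores = scores)
}
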