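# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an allele-specific scan
#'
#' One row per feature-dSNP pair with both test p-values, the slope and its
#' sign, matching broom term-level conventions.
#'
#' @param x An `asqtl_as_scan`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.asqtl_as_scan <- function(x, ...) {
  as_tibble(x) |>
    select("feature_id", "dsnp_id", "distance_bp", statistic = "Z",
           p.value.test1 = "p1", estimate = "b", std.error = "se",
           p.value.test2 = "p2", "significant")
}

#' @rdname tidy.asqtl_as_scan
#' @export
glance.asqtl_as_scan <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_features = dplyr::n_distinct(x$feature_id),
    n_gated = sum(!is.na(x$p2)),
    n_significant_pairs = sum(x$significant, na.rm = TRUE),
    n_significant_features = dplyr::n_distinct(x$feature_id[x$significant]),
    significance = attr(x, "significance") %||% NA_real_)
}

#' Tidy a mixed-model scan
#'
#' @param x An `asqtl_mlm_scan` (or single-phenotype `asqtl_mlm`).
#' @param ... Unused.
#' @return A tibble with broom-style `estimate`, `std.error`, `p.value`.
#' @export
tidy.asqtl_mlm_scan <- function(x, ...) {
  out <- as_tibble(x)
  if (!"feature_id" %in% names(out)) out$feature_id <- NA_character_
  out |>
    select("feature_id", term = "snp_id", estimate = "beta",
           std.error = "se", p.value = "p",
           dplyr::any_of(c("distance_bp", "significant")))
}

#' @rdname tidy.asqtl_mlm_scan
#' @export
tidy.asqtl_mlm <- tidy.asqtl_mlm_scan

#' @rdname tidy.asqtl_mlm_scan
#' @export
glance.asqtl_mlm_scan <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_features = if ("feature_id" %in% names(x)) {
      dplyr::n_distinct(x$feature_id)
    } else 1L,
    n_significant = sum(x$significant %||% (x$p < 1e-4), na.rm = TRUE))
}

#' Tidy a motif set
#'
#' @param x An `asqtl_motif_set`.
#' @param ... Unused.
#' @return One row per retained cluster.
#' @export
tidy.asqtl_motif_set <- function(x, ...) as_tibble(x$clusters)

#' @rdname tidy.asqtl_motif_set
#' @export
glance.asqtl_motif_set <- function(x, ...) {
  bind_cols(tibble(n_sequences = nrow(x$sequences),
                   n_skipped = nrow(x$skipped)),
            summarize_skew(x))
}

#' Tidy a causal-candidate table
#' @param x An `asqtl_causal`.
#' @param ... Unused.
#' @return A tibble sorted by combined p.
#' @export
tidy.asqtl_causal <- function(x, ...) {
  as_tibble(x) |> arrange(.data$combined_p)
}

#' @rdname tidy.asqtl_causal
#' @export
glance.asqtl_causal <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_unique_snps = dplyr::n_distinct(x$snp_id),
         n_peaks = dplyr::n_distinct(x$peak_id),
         n_exons = dplyr::n_distinct(x$exon_id))
}
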