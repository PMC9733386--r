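# End-to-end orchestration of the synthetic pipeline.

# one-hot batch covariates with reference level dropped
batch_covariates <- function(batches) {
  lev <- sort(unique(batches$batch))
  if (length(lev) < 2) return(NULL)
  m <- vapply(lev[-1], function(l) as.numeric(batches$batch == l),
              numeric(nrow(batches)))
  rownames(m) <- batches$animal_id
  m
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a dataset, assigns parental origin, aggregates allele counts
#' and tests within-feature heterogeneity, runs the two-stage
#' allele-specific scans (binding on peaks, expression on exons) and the
#' traditional mixed-model scans (peak height, exon expression), intersects
#' the four result sets, and — when any variant clears the motif-selection
#' thresholds — discovers motifs around them.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `asqtl_run`: the simulated `data`, the stage
#'   outputs (`phase`, `feature_counts`, `heterogeneity`, `asb`, `ase`,
#'   `hqtl`, `eeqtl`, `integration`, `motifs`) and a `report` tibble of
#'   per-stage phenotype/significance counts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "asqtl_pipeline_config"))
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "asqtl_stage_error")
    })
  }
  sim <- stage("simulate", simulate_dataset(config$sim))
  phase <- stage("phase", assign_parental_origin(
    sim$panel$hap_a, sim$panel$hap_b, sim$panel$sire_dosage, sim$panel$snps))
  fc <- stage("counts", collect_feature_counts(
    phase, sim$counts$allele_counts, sim$features))
  het <- stage("heterogeneity", {
    tab <- feature_heterogeneity(sim$counts$allele_counts, sim$features)
    summarize_heterogeneity(tab, config$heterogeneity_alpha)
  })

  asb <- stage("as-scan", as_scan(fc, sim$features, phase, type = "peak",
                                  window = config$window, gate = config$as_gate,
                                  significance = config$significance))
  ase <- stage("as-scan", as_scan(fc, sim$features, phase, type = "exon",
                                  window = config$window, gate = config$as_gate,
                                  significance = config$significance))

  trad <- stage("trad-scan", {
    qc <- qc_peaks(sim$counts$peak_counts, sim$counts$input_counts)
    peak_ph <- normalize_peak_phenotype(qc$peak_counts, qc$input_counts)
    keep_pk <- pca_outlier_filter(peak_ph$phenotype)$retained
    expr_ph <- transform_expression(sim$counts$exon_counts, sim$counts$batches)
    keep_ex <- pca_outlier_filter(expr_ph$phenotype)$retained
    grm <- build_grm(panel_dosage(sim$panel), sim$panel$snps)
    cov_b <- batch_covariates(sim$counts$batches)
    hqtl <- trad_scan(peak_ph$phenotype[, keep_pk, drop = FALSE],
                      sim$features, sim$panel, grm, covariates = cov_b,
                      window = config$window,
                      significance = config$significance)
    eeqtl <- trad_scan(expr_ph$phenotype[, keep_ex, drop = FALSE],
                       sim$features, sim$panel, grm, covariates = NULL,
                       window = config$window,
                       significance = config$significance)
    list(hqtl = hqtl, eeqtl = eeqtl, qc = qc$removed,
         peak_phenotype = peak_ph, expr_phenotype = expr_ph)
  })

  integration <- stage("intersect", {
    sig_feats <- function(r) unique(r$feature_id[r$significant])
    peaks_tested <- intersect(unique(asb$feature_id), unique(trad$hqtl$feature_id))
    exons_tested <- intersect(unique(ase$feature_id), unique(trad$eeqtl$feature_id))
    or_peaks <- overlap_odds_ratio(length(peaks_tested),
                                   intersect(sig_feats(asb), peaks_tested),
                                   intersect(sig_feats(trad$hqtl), peaks_tested))
    or_exons <- overlap_odds_ratio(length(exons_tested),
                                   intersect(sig_feats(ase), exons_tested),
                                   intersect(sig_feats(trad$eeqtl), exons_tested))
    conc_peaks <- direction_concordance(asb, trad$hqtl)
    conc_exons <- direction_concordance(ase, trad$eeqtl)
    peaks_tbl <- sim$features$features |> filter(.data$type == "peak")
    all_pos <- sim$panel$snps[, c("chrom", "pos")]
    sig_snps <- unique(c(asb$dsnp_id[asb$significant],
                         trad$hqtl$snp_id[trad$hqtl$significant]))
    enr <- if (length(sig_snps) > 0) {
      enrichment_under_peaks(
        sim$panel$snps[sim$panel$snps$snp_id %in% sig_snps, c("chrom", "pos")],
        peaks_tbl, all_positions = all_pos)
    } else NULL
    pairs <- link_peak_exon_pairs(asb, ase, sim$features)
    causal <- select_putative_causal(trad$hqtl, trad$eeqtl, asb, ase,
                                     sim$features,
                                     significance = config$significance)
    list(or_peaks = or_peaks, or_exons = or_exons,
         concordance_peaks = conc_peaks, concordance_exons = conc_exons,
         enrichment = enr, peak_exon_pairs = pairs, causal = causal)
  })

  motifs <- stage("motifs", {
    assert_that(length(sim$genome$genome) > 0, "no reference FASTA available")
    asb_m <- asb |> mutate(mark = config$mark)
    vars <- select_variants_for_motifs(
      asb_m, ase, sim$features, mark = config$mark,
      thresholds = config$motif_thresholds,
      ase_threshold = config$ase_motif_threshold,
      tss_window = config$ase_tss_window)
    if (nrow(vars) == 0) {
      NULL
    } else {
      snps <- sim$panel$snps
      idx <- match(vars$snp_id, snps$snp_id)
      vars$reference_allele <- snps$ref[idx]
      vars$positive_allele <- ifelse(vars$effect_sign >= 0,
                                     snps$alt[idx], snps$ref[idx])
      discover_motifs(vars, sim$genome$genome,
                      base_freqs = genome_base_freqs(sim$genome$genome),
                      literal_entropy = config$literal_entropy_trim,
                      seed = config$sim$seed)
    }
  })

  n_sig <- function(r) dplyr::n_distinct(r$feature_id[r$significant])
  report <- tibble(
    stage = c("asb", "ase", "hqtl", "eeqtl", "heterogeneity", "causal",
              "motif_clusters"),
    n_phenotypes_tested = c(dplyr::n_distinct(asb$feature_id),
                            dplyr::n_distinct(ase$feature_id),
                            dplyr::n_distinct(trad$hqtl$feature_id),
                            dplyr::n_distinct(trad$eeqtl$feature_id),
                            sum(het$n_multi_site), NA, NA),
    n_significant = c(n_sig(asb), n_sig(ase), n_sig(trad$hqtl),
                      n_sig(trad$eeqtl), sum(het$n_heterogeneous),
                      nrow(integration$causal),
                      if (is.null(motifs)) 0L else nrow(motifs$clusters)))

  structure(list(data = sim, phase = phase, feature_counts = fc,
                 heterogeneity = het, asb = asb, ase = ase,
                 hqtl = trad$hqtl, eeqtl = trad$eeqtl, qc_removed = trad$qc,
                 integration = integration, motifs = motifs,
                 report = report, config = config),
            class = "asqtl_run")
}

#' @export
print.asqtl_run <- function(x, ...) {
  cat("asqtl pipeline run (seed", x$config$sim$seed, ")\n")
  print(x$report)
  invisible(x)
}
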