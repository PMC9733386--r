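#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every synthetic
#' data generator. The defaults describe the study conditions the rest of the
#' package is tested under: a diploid population of phased trios, cis-acting
#' variants that shift both the maternal:paternal allele-count ratio
#' (beta-binomial) and total feature counts (negative-binomial), batch and
#' polygenic structure, and a small genome with motif instances planted at
#' variant sites.
#'
#' @param n_animals Number of genotyped offspring.
#' @param n_chromosomes Number of chromosomes in the toy genome.
#' @param chrom_length Chromosome length in bp.
#' @param n_snps_per_chrom Biallelic SNPs per chromosome.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP alternate allele
#'   frequencies are drawn uniformly from this interval.
#' @param n_peaks,n_exons Number of ChIP peaks and exons to simulate.
#' @param feature_width_range Length-2 integer range of feature widths (bp).
#' @param frac_causal_features Fraction of features assigned a causal driver
#'   SNP (dSNP) within 1 Mb.
#' @param effect_size_range Range of |effect| on the allelic log-odds ratio
#'   for causal features (log-odds units).
#' @param effect_on_level_range Range of |effect| of one alternate allele on
#'   the log feature total (additive per-allele).
#' @param overdispersion Beta-binomial intra-class correlation rho in [0, 1)
#'   for allelic counts; 0 gives binomial sampling.
#' @param mean_depth Mean read depth per informative site (and mean feature
#'   total).
#' @param nb_dispersion Negative-binomial dispersion of totals (variance
#'   mu + dispersion * mu^2); 0 gives Poisson.
#' @param n_batches Number of sequencing batches.
#' @param batch_sd Standard deviation of batch effects on the log total.
#' @param polygenic_var Variance of the additive polygenic term on the log
#'   total (genome-wide small effects, so totals carry kinship structure).
#' @param base_freqs Named length-4 numeric (A, C, G, T) summing to 1; genome
#'   background composition.
#' @param planted_motifs A tibble/data.frame with columns `consensus`
#'   (IUPAC string) and `count`, or NULL for none. Instances are planted
#'   centred on SNP positions.
#' @param frac_causal_in_feature Fraction of causal dSNPs placed inside their
#'   target feature (the rest fall elsewhere in the 1 Mb window).
#' @param shared_regulation Fraction of causal peaks whose driver variant
#'   also regulates one or two nearby exons (same sign) — the regulatory
#'   architecture that makes peak-exon links and four-way causal candidates
#'   recoverable.
#' @param seed Master seed; per-generator streams are derived from it by
#'   fixed offsets.
#'
#' @return A validated list of class `asqtl_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_animals = 50, n_snps_per_chrom = 100, seed = 1)
sim_config <- function(n_animals = 200,
                       n_chromosomes = 2,
                       chrom_length = 3e6,
                       n_snps_per_chrom = 400,
                       maf_range = c(0.1, 0.5),
                       n_peaks = 60,
                       n_exons = 60,
                       feature_width_range = c(300L, 2000L),
                       frac_causal_features = 0.3,
                       effect_size_range = c(1.5, 2.5),
                       effect_on_level_range = c(0.3, 0.6),
                       overdispersion = 0.02,
                       mean_depth = 50,
                       nb_dispersion = 0.2,
                       n_batches = 3,
                       batch_sd = 0.15,
                       polygenic_var = 0.05,
                       base_freqs = c(A = 0.291, C = 0.209, G = 0.209, T = 0.291),
                       planted_motifs = NULL,
                       frac_causal_in_feature = 0.5,
                       shared_regulation = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_animals = as.integer(n_animals),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    maf_range = as.numeric(maf_range),
    n_peaks = as.integer(n_peaks),
    n_exons = as.integer(n_exons),
    feature_width_range = as.integer(feature_width_range),
    frac_causal_features = as.numeric(frac_causal_features),
    effect_size_range = as.numeric(effect_size_range),
    effect_on_level_range = as.numeric(effect_on_level_range),
    overdispersion = as.numeric(overdispersion),
    mean_depth = as.numeric(mean_depth),
    nb_dispersion = as.numeric(nb_dispersion),
    n_batches = as.integer(n_batches),
    batch_sd = as.numeric(batch_sd),
    polygenic_var = as.numeric(polygenic_var),
    base_freqs = base_freqs,
    planted_motifs = if (is.null(planted_motifs)) NULL else as_tibble(planted_motifs),
    frac_causal_in_feature = as.numeric(frac_causal_in_feature),
    shared_regulation = as.numeric(shared_regulation),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "asqtl_sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < min) {
      config_error(field, sprintf("must be a single count >= %d", min))
    }
  }
  for (f in c("n_animals", "n_chromosomes", "chrom_length", "n_snps_per_chrom",
              "n_peaks", "n_exons", "n_batches")) {
    chk_count(f)
  }
  mr <- cfg$maf_range
  if (length(mr) != 2 || any(is.na(mr)) || mr[1] > mr[2] ||
      mr[1] <= 0 || mr[2] > 0.5) {
    config_error("maf_range", "must be a pair of frequencies within (0, 0.5]")
  }
  fw <- cfg$feature_width_range
  if (length(fw) != 2 || any(fw < 1) || fw[1] > fw[2]) {
    config_error("feature_width_range", "must be a pair of widths >= 1 bp")
  }
  if (fw[2] >= cfg$chrom_length) {
    config_error("feature_width_range", "feature wider than chromosome")
  }
  for (f in c("frac_causal_features", "frac_causal_in_feature",
              "shared_regulation")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) config_error(f, "must be in [0, 1]")
  }
  if (cfg$overdispersion < 0 || cfg$overdispersion >= 1) {
    config_error("overdispersion", "beta-binomial rho must be in [0, 1)")
  }
  if (cfg$mean_depth <= 0) config_error("mean_depth", "must be positive")
  if (cfg$nb_dispersion < 0) config_error("nb_dispersion", "must be >= 0")
  bf <- cfg$base_freqs
  if (length(bf) != 4 || abs(sum(bf) - 1) > 1e-9 || any(bf < 0)) {
    config_error("base_freqs", "must be 4 probabilities summing to 1 (tol 1e-9)")
  }
  if (!is.null(cfg$planted_motifs)) {
    pm <- cfg$planted_motifs
    if (!all(c("consensus", "count") %in% names(pm))) {
      config_error("planted_motifs", "needs columns `consensus` and `count`")
    }
    if (any(!grepl("^[ACGTRYSWKMBDHVN]+$", pm$consensus))) {
      config_error("planted_motifs", "consensus strings must be IUPAC nucleotides")
    }
    if (any(nchar(pm$consensus) > 21)) {
      config_error("planted_motifs", "motif longer than 21 bp")
    }
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) config_error("seed", "must be a single integer")
  invisible(cfg)
}

#' Pipeline configuration
#'
#' Thresholds and switches for a full synthetic-run of the pipeline. Defaults
#' are the published analysis settings: the allele-specific first-test gate at
#' p < 0.001, significance in either QTL family at p < 0.0001, a 1 Mb cis
#' window, within-feature heterogeneity flagged at p < 0.05, mark-specific
#' motif-selection thresholds, the 10 kb TSS window and 1e-15 threshold for
#' expression variants entering motif discovery, and PFM matches reported at
#' relScore > 90.
#'
#' @param sim A [sim_config()] object describing the synthetic inputs.
#' @param mark Label for the simulated histone mark (sets the motif-selection
#'   threshold).
#' @param as_gate First-test gate p-value before the regression stage.
#' @param significance Significance threshold applied to every QTL family.
#' @param window Cis window, bp either side of the feature midpoint.
#' @param heterogeneity_alpha Within-feature G-test flag level.
#' @param motif_thresholds Named numeric of first-test p thresholds per mark.
#' @param ase_motif_threshold,ase_tss_window Expression-side motif selection:
#'   p threshold and max distance to the feature start.
#' @param rel_score_min Minimum PFM relScore (percent) to report a match.
#' @param literal_entropy_trim Use the literal low-entropy trimming rule for
#'   consensus construction instead of the information-content reading (see
#'   [build_consensus()]).
#' @return A list of class `asqtl_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            mark = "H3K4Me3",
                            as_gate = 1e-3,
                            significance = 1e-4,
                            window = 1e6,
                            heterogeneity_alpha = 0.05,
                            motif_thresholds = c(H3K4Me1 = 1e-8,
                                                 H3K4Me3 = 1e-7,
                                                 H3K27ac = 1e-6),
                            ase_motif_threshold = 1e-15,
                            ase_tss_window = 1e4,
                            rel_score_min = 90,
                            literal_entropy_trim = FALSE) {
  if (!inherits(sim, "asqtl_sim_config")) {
    config_error("sim", "must be built with sim_config()")
  }
  for (f in c("as_gate", "significance", "heterogeneity_alpha",
              "ase_motif_threshold")) {
    v <- get(f)
    if (length(v) != 1 || v <= 0 || v >= 1) config_error(f, "must be in (0, 1)")
  }
  if (window <= 0) config_error("window", "must be > 0")
  if (!mark %in% names(motif_thresholds)) {
    config_error("mark", sprintf("unknown mark %s: no motif threshold", mark))
  }
  structure(list(sim = sim, mark = mark, as_gate = as_gate,
                 significance = significance, window = window,
                 heterogeneity_alpha = heterogeneity_alpha,
                 motif_thresholds = motif_thresholds,
                 ase_motif_threshold = ase_motif_threshold,
                 ase_tss_window = ase_tss_window,
                 rel_score_min = rel_score_min,
                 literal_entropy_trim = literal_entropy_trim),
            class = "asqtl_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every entry of [pipeline_config()] (and the nested `sim:` block, matching
#' [sim_config()]) may appear in the file; missing entries keep their
#' defaults. Validation runs on load.
#'
#' @param path Path to a YAML file.
#' @return A `asqtl_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$base_freqs)) sim_args$base_freqs <- unlist(sim_args$base_freqs)
  if (!is.null(sim_args$planted_motifs)) {
    sim_args$planted_motifs <- dplyr::bind_rows(sim_args$planted_motifs)
  }
  sim <- do.call(sim_config, sim_args)
  top <- raw[setdiff(names(raw), "sim")]
  if (!is.null(top$motif_thresholds)) top$motif_thresholds <- unlist(top$motif_thresholds)
  do.call(pipeline_config, c(list(sim = sim), top))
}
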