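# Intersection statistics: odds ratios, concordance, enrichment, linking,
# p-value combination and causal selection.

test_that("overlap odds ratios reproduce published-scale marginals", {
  # expression row: 48,456 tested, 15,308 vs 25,163 hits, 10,678 shared
  rna <- overlap_odds_ratio(48456, 15308, 25163, n_both = 10678)
  expect_equal(round(rna$odds_ratio, 2), 2.97)
  # enhancer mark row of the peak-level table
  me1 <- overlap_odds_ratio(220588, 20555, 18840, n_both = 4706)
  expect_equal(round(me1$odds_ratio, 1), 3.9)
})

test_that("odds-ratio boundary behaviour: identical and disjoint sets", {
  same <- overlap_odds_ratio(100, c("a", "b"), c("a", "b"))
  expect_true(same$infinite)
  expect_equal(same$odds_ratio, Inf)
  disj <- overlap_odds_ratio(100, c("a", "b"), c("c", "d"))
  expect_lt(disj$odds_ratio, 1)
  expect_error(overlap_odds_ratio(3, 10, 2, n_both = 1), "inconsistent")
})

test_that("direction concordance: identical, flipped, and zero effects", {
  r <- tibble::tibble(feature_id = c("f1", "f2"), dsnp_id = c("s1", "s2"),
                      b = c(1.2, -0.5), significant = TRUE)
  expect_equal(direction_concordance(r, r)$fraction_same_sign, 1)
  r_flip <- dplyr::mutate(r, b = -b)
  expect_equal(direction_concordance(r, r_flip)$fraction_same_sign, 0)
  r_zero <- dplyr::mutate(r, b = c(0, 1))
  cc <- direction_concordance(r, r_zero)
  expect_equal(cc$n_zero, 1)
  expect_equal(cc$n_shared, 2)
})

test_that("enrichment formula: arithmetic and boundary cases", {
  # direct arithmetic: (10/100)/(50/1000) = 2
  all_pos <- tibble::tibble(chrom = "chr1", pos = 0:999)
  peaks <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  qtl <- tibble::tibble(chrom = "chr1", pos = c(0:9, seq(200, 980, 20)))
  e <- enrichment_under_peaks(qtl, peaks, all_positions = all_pos)
  expect_equal(e$A, 100); expect_equal(e$B, 50); expect_equal(e$C, 10)
  expect_equal(e$enrichment, 2)

  # all QTL inside peaks covering 10% of positions
  qtl_in <- tibble::tibble(chrom = "chr1", pos = 0:49)
  e2 <- enrichment_under_peaks(qtl_in, peaks, all_positions = all_pos)
  expect_equal(e2$enrichment, 10)

  expect_error(enrichment_under_peaks(
    tibble::tibble(chrom = character(), pos = integer()), peaks,
    all_positions = all_pos), "undefined")
})

test_that("enrichment matches a brute-force per-position count", {
  set.seed(21)
  genome_len <- 1e5
  peaks <- tibble::tibble(chrom = "chr1",
                          start = as.integer(sort(sample(genome_len - 500, 30))))
  peaks$end <- peaks$start + sample(50:400, 30, replace = TRUE)
  qtl <- tibble::tibble(chrom = "chr1",
                        pos = sort(sample(genome_len, 400)) - 1L)
  e <- enrichment_under_peaks(qtl, peaks, genome_size = genome_len,
                              mode = "bp")
  # brute force: mark each covered base
  covered <- logical(genome_len)
  for (i in seq_len(nrow(peaks))) {
    covered[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
  }
  A <- sum(covered)
  C <- sum(covered[qtl$pos + 1])
  expect_equal(e$A, A)
  expect_equal(e$C, C)
  expect_equal(e$enrichment, (C / A) / (400 / genome_len))
})

test_that("uniformly scattered QTL show no enrichment", {
  set.seed(22)
  genome_len <- 1e6
  peaks <- tibble::tibble(chrom = "chr1",
                          start = as.integer(seq(0, genome_len - 2000, by = 10000)))
  peaks$end <- peaks$start + 1000L
  qtl <- tibble::tibble(chrom = "chr1",
                        pos = sample.int(genome_len, 1e5) - 1L)
  e <- enrichment_under_peaks(qtl, peaks, genome_size = genome_len, mode = "bp")
  expect_equal(e$enrichment, 1, tolerance = 0.1)
})

test_that("peak-exon linking is the Cartesian product over shared dSNPs", {
  pk <- tibble::tibble(feature_id = c("peak_1", "peak_2"), dsnp_id = "s1",
                       significant = TRUE)
  ex <- tibble::tibble(feature_id = c("exon_1", "exon_2", "exon_3"),
                       dsnp_id = "s1", significant = TRUE)
  feats <- list(features = tibble::tibble(
    feature_id = c("peak_1", "peak_2", "exon_1", "exon_2", "exon_3"),
    midpoint = c(100L, 200L, 300L, 400L, 500L)))
  lk <- link_peak_exon_pairs(pk, ex, feats)
  expect_equal(nrow(lk$pairs), 6)
  expect_equal(lk$summary$peaks_per_exon, 2)
  expect_equal(lk$summary$exons_per_peak, 3)
  # no shared dSNPs: empty
  ex2 <- dplyr::mutate(ex, dsnp_id = "s9")
  expect_equal(nrow(link_peak_exon_pairs(pk, ex2, feats)$pairs), 0)
})

test_that("chi-squared combination matches its 4-df closed form", {
  expect_equal(combine_pvalues(1, 1, 1, 1), 1)
  # all four p = 0.05: quantiles 3.8415 summing to 15.366
  comb <- combine_pvalues(0.05, 0.05, 0.05, 0.05)
  x <- 4 * qchisq(0.05, 1, lower.tail = FALSE)
  expect_equal(comb, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(comb, 0.0040, tolerance = 1e-4)
  # monotone: lowering any input cannot raise the combination
  base <- combine_pvalues(0.2, 0.3, 0.4, 0.5)
  expect_lte(combine_pvalues(0.1, 0.3, 0.4, 0.5), base)
  expect_lte(combine_pvalues(0.2, 0.3, 0.4, 0.05), base)
  expect_warning(combine_pvalues(0, 0.5, 0.5, 0.5), "clamped")
})

test_that("combination agrees with Monte-Carlo over uniform p-values", {
  set.seed(23)
  B <- 1e6
  u <- matrix(runif(4 * B), B, 4)
  stat <- rowSums(qchisq(u, 1, lower.tail = FALSE))
  target <- combine_pvalues(0.05, 0.1, 0.2, 0.1)
  crit <- qchisq(target, 4, lower.tail = FALSE)
  mc <- mean(stat >= crit)
  se <- sqrt(target * (1 - target) / B)
  expect_lt(abs(mc - target), 2 * se + 1e-4)
})

causal_fixture <- function() {
  feats <- list(features = tibble::tibble(
    feature_id = c("peak_1", "exon_1"), type = c("peak", "exon"),
    chrom = "chr1", start = c(1000L, 5000L), end = c(2000L, 5600L),
    midpoint = c(1500L, 5300L), tss = c(1000L, 5000L)))
  snps <- tibble::tibble(snp_id = sprintf("s%d", 1:5),
                         pos = c(1100L, 1200L, 1300L, 2500L, 1400L))
  mk <- function(p_vec, eff_vec, feature, snp_col) {
    tibble::tibble(feature_id = feature, snp_id = snps$snp_id,
                   dsnp_id = snps$snp_id, pos = snps$pos,
                   p = p_vec, p1 = p_vec, beta = eff_vec, b = eff_vec,
                   Z = eff_vec, significant = p_vec < 1e-4)
  }
  list(feats = feats, snps = snps, mk = mk)
}

test_that("causal selection applies all three filters then keeps the best", {
  fx <- causal_fixture()
  # five candidates; s4 is outside the peak; s5 has a discordant sign;
  # s3 fails the p threshold in one analysis; s1 and s2 pass, s2 wins
  p_h <- c(1e-6, 1e-8, 1e-6, 1e-9, 1e-6)
  p_ee <- c(1e-6, 1e-7, 1e-6, 1e-9, 1e-6)
  p_asb <- c(1e-5, 1e-6, 2e-4, 1e-9, 1e-6)
  p_ase <- c(1e-5, 1e-6, 1e-6, 1e-9, 1e-6)
  eff <- c(1, 1, 1, 1, 1)
  h <- fx$mk(p_h, eff, "peak_1")
  ee <- fx$mk(p_ee, eff, "exon_1")
  asb <- fx$mk(p_asb, eff, "peak_1")
  ase <- fx$mk(p_ase, c(1, 1, 1, 1, -1), "exon_1")
  out <- select_putative_causal(h, ee, asb, ase, fx$feats)
  expect_equal(nrow(out), 1)
  expect_equal(out$snp_id, "s2")
  expect_true(out$in_peak)
  expect_true(out$direction_concordant)

  # row order invariance
  shuf <- sample(5)
  out2 <- select_putative_causal(h[shuf, ], ee[shuf, ], asb[shuf, ],
                                 ase[shuf, ], fx$feats)
  expect_equal(out2, out)
})

test_that("simulated shared causal variants drive concordant scans", {
  cfg <- tiny_sim_config(n_animals = 150, n_peaks = 25, n_exons = 25,
                         frac_causal_features = 0.6,
                         effect_size_range = c(2, 2),
                         effect_on_level_range = c(0.5, 0.5), seed = 30)
  sim <- simulate_dataset(cfg)
  ph <- assign_parental_origin(sim$panel$hap_a, sim$panel$hap_b,
                               sim$panel$sire_dosage, sim$panel$snps)
  fc <- collect_feature_counts(ph, sim$counts$allele_counts, sim$features)
  asb <- as_scan(fc, sim$features, ph, "peak")
  grm <- build_grm(panel_dosage(sim$panel), sim$panel$snps)
  qc <- qc_peaks(sim$counts$peak_counts, sim$counts$input_counts)
  pp <- normalize_peak_phenotype(qc$peak_counts, qc$input_counts)
  h <- trad_scan(pp$phenotype, sim$features, sim$panel, grm)
  cc <- direction_concordance(asb, h)
  expect_gt(cc$n_shared, 3)
  expect_gt(cc$fraction_same_sign, 0.9)
})
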