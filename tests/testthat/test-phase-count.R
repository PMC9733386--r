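# Parental-origin assignment, feature-count aggregation and the
# heterogeneity G-test.

make_phase_input <- function(hap_a, hap_b, sire, pos = NULL,
                             chrom = NULL) {
  m <- ncol(hap_a)
  snps <- tibble::tibble(
    snp_id = sprintf("s%d", seq_len(m)),
    chrom = chrom %||% rep("chr1", m),
    pos = pos %||% (seq_len(m) * 100L),
    ref = "A", alt = "G", maf = 0.5)
  dimnames(hap_a) <- dimnames(hap_b) <- dimnames(sire) <-
    list(sprintf("a%d", seq_len(nrow(hap_a))), snps$snp_id)
  list(hap_a = hap_a, hap_b = hap_b, sire = sire, snps = snps)
}

test_that("homozygous-sire rule assigns the sire allele as paternal", {
  # child het (A/G coded 0/1), sire homozygous reference (AA): the
  # reference allele is paternal, the alternate maternal
  inp <- make_phase_input(hap_a = matrix(1, 1, 1), hap_b = matrix(0, 1, 1),
                          sire = matrix(0, 1, 1))
  ph <- assign_parental_origin(inp$hap_a, inp$hap_b, inp$sire, inp$snps)
  expect_equal(ph$maternal[1, 1], 1)
  expect_equal(ph$paternal[1, 1], 0)
  expect_equal(ph$provenance[1, 1], "sire-homozygous")
  # sire homozygous alternate: alternate paternal
  inp <- make_phase_input(matrix(1, 1, 1), matrix(0, 1, 1), matrix(2, 1, 1))
  ph <- assign_parental_origin(inp$hap_a, inp$hap_b, inp$sire, inp$snps)
  expect_equal(ph$paternal[1, 1], 1)
  expect_equal(ph$maternal[1, 1], 0)
})

test_that("homozygous offspring entries pass through unchanged", {
  inp <- make_phase_input(matrix(1, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1))
  ph <- assign_parental_origin(inp$hap_a, inp$hap_b, inp$sire, inp$snps)
  expect_equal(ph$maternal[1, 1], 1)
  expect_equal(ph$paternal[1, 1], 1)
  expect_equal(ph$provenance[1, 1], "homozygous")
})

test_that("heterozygous-sire sites carry the nearest upstream orientation", {
  # SNP1 resolved by a homozygous sire (hap_a maternal); SNP2 has a
  # heterozygous sire and inherits hap_a-maternal orientation
  inp <- make_phase_input(hap_a = cbind(1, 1), hap_b = cbind(0, 0),
                          sire = cbind(0, 1))
  ph <- assign_parental_origin(inp$hap_a, inp$hap_b, inp$sire, inp$snps)
  expect_equal(ph$provenance[1, ], c(s1 = "sire-homozygous", s2 = "carried-phase"))
  expect_equal(unname(ph$maternal[1, 2]), 1)
  # flipped resolution at SNP1 flips the carried orientation at SNP2
  inp2 <- make_phase_input(hap_a = cbind(1, 1), hap_b = cbind(0, 0),
                           sire = cbind(2, 1))
  ph2 <- assign_parental_origin(inp2$hap_a, inp2$hap_b, inp2$sire, inp2$snps)
  expect_equal(unname(ph2$maternal[1, 2]), 0)
})

test_that("sites with no upstream resolution are unphased; chromosome
          boundaries reset the carry", {
  inp <- make_phase_input(hap_a = cbind(1, 0, 1), hap_b = cbind(0, 1, 0),
                          sire = cbind(1, 0, 1),
                          chrom = c("chr1", "chr1", "chr2"))
  ph <- assign_parental_origin(inp$hap_a, inp$hap_b, inp$sire, inp$snps)
  expect_equal(unname(ph$provenance[1, 1]), "unphased")
  expect_equal(unname(ph$provenance[1, 2]), "sire-homozygous")
  # chr2 het site cannot borrow chr1's orientation
  expect_equal(unname(ph$provenance[1, 3]), "unphased")
})

test_that("impossible homozygous genotypes are flagged Mendelian-inconsistent", {
  inp <- make_phase_input(matrix(0, 1, 1), matrix(0, 1, 1), matrix(2, 1, 1))
  ph <- assign_parental_origin(inp$hap_a, inp$hap_b, inp$sire, inp$snps)
  expect_equal(ph$provenance[1, 1], "mendelian-inconsistent")
})

test_that("recovered parental origin matches simulator truth", {
  panel <- simulate_population(tiny_sim_config(seed = 4))
  ph <- assign_parental_origin(panel$hap_a, panel$hap_b, panel$sire_dosage,
                               panel$snps)
  het <- panel$maternal != panel$paternal
  resolved <- ph$provenance %in% c("sire-homozygous", "carried-phase")
  dim(resolved) <- dim(het)
  expect_gt(mean(resolved[het]), 0.9)
  expect_true(all((ph$maternal == panel$maternal)[het & resolved]))
  # unordered pair always equals the input genotype
  expect_true(all(ph$maternal + ph$paternal == panel$hap_a + panel$hap_b))
})

feature_fixture <- function(counts_tbl, snp_ids, phase_het, prov = NULL) {
  n_animal <- nrow(phase_het)
  features <- list(
    features = tibble::tibble(feature_id = "f1", type = "peak", chrom = "chr1",
                              start = 0L, end = 1000L, midpoint = 500L,
                              tss = 0L),
    snp_map = tibble::tibble(feature_id = "f1", snp_id = snp_ids))
  maternal <- matrix(as.integer(phase_het), n_animal, length(snp_ids),
                     dimnames = list(rownames(phase_het), snp_ids))
  paternal <- matrix(0L, n_animal, length(snp_ids),
                     dimnames = dimnames(maternal))
  provenance <- prov %||% matrix("sire-homozygous", n_animal, length(snp_ids),
                                 dimnames = dimnames(maternal))
  phase <- structure(list(maternal = maternal, paternal = paternal,
                          provenance = provenance),
                     class = "asqtl_phase")
  list(phase = phase, features = features, counts = counts_tbl)
}

test_that("feature counts sum retained heterozygous sites exactly", {
  fx <- feature_fixture(
    tibble::tibble(animal_id = c("a1", "a1"), snp_id = c("s1", "s2"),
                   maternal_count = c(10L, 7L), paternal_count = c(5L, 3L)),
    snp_ids = c("s1", "s2"),
    phase_het = matrix(TRUE, 1, 2, dimnames = list("a1", NULL)))
  out <- collect_feature_counts(fx$phase, fx$counts, fx$features)
  expect_equal(out$counts$maternal_count, 17L)
  expect_equal(out$counts$paternal_count, 8L)
  expect_equal(out$counts$n_informative_sites, 2L)
})

test_that("monoallelic heterozygous sites and homozygous animals are excluded", {
  fx <- feature_fixture(
    tibble::tibble(animal_id = c("a1", "a2"), snp_id = c("s1", "s1"),
                   maternal_count = c(12L, 9L), paternal_count = c(0L, 4L)),
    snp_ids = "s1",
    phase_het = matrix(c(TRUE, FALSE), 2, 1,
                       dimnames = list(c("a1", "a2"), NULL)))
  out <- collect_feature_counts(fx$phase, fx$counts, fx$features)
  # a1 monoallelic, a2 homozygous: nothing retained
  expect_equal(nrow(out$counts), 0)
  expect_setequal(out$exclusions$reason, c("monoallelic", "homozygous"))
})

test_that("count aggregation conserves retained per-site counts", {
  cfg <- tiny_sim_config(seed = 8)
  sim <- simulate_dataset(cfg)
  ph <- assign_parental_origin(sim$panel$hap_a, sim$panel$hap_b,
                               sim$panel$sire_dosage, sim$panel$snps)
  fc <- collect_feature_counts(ph, sim$counts$allele_counts, sim$features)
  retained <- dplyr::anti_join(
    dplyr::inner_join(sim$features$snp_map, sim$counts$allele_counts,
                      by = "snp_id", relationship = "many-to-many"),
    fc$exclusions, by = c("feature_id", "animal_id", "snp_id"))
  expect_equal(sum(fc$counts$maternal_count), sum(retained$maternal_count))
  expect_equal(sum(fc$counts$paternal_count), sum(retained$paternal_count))
})

test_that("G-test reproduces hand-computed and degenerate cases", {
  same <- heterogeneity_g_test(rbind(c(10, 10), c(20, 20)))
  expect_equal(same$G, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  flip <- heterogeneity_g_test(rbind(c(30, 10), c(10, 30)))
  expect_equal(flip$G, 20.93, tolerance = 0.005)
  expect_equal(flip$df, 1L)

  single <- heterogeneity_g_test(rbind(c(50, 1)))
  expect_equal(single$G, 0)
  expect_equal(single$df, 0L)
  expect_equal(single$p, 1)
  expect_true(single$degenerate)
})

test_that("G matches an independent contingency-table implementation", {
  set.seed(12)
  for (i in 1:100) {
    s <- sample(2:6, 1)
    tab <- matrix(rpois(2 * s, 30) + 1, s, 2)
    expect_equal(heterogeneity_g_test(tab)$G, g_test_oracle(tab),
                 tolerance = 1e-8)
  }
})

test_that("G is invariant to column swaps and row permutations", {
  set.seed(14)
  tab <- matrix(rpois(8, 25) + 1, 4, 2)
  g0 <- heterogeneity_g_test(tab)$G
  expect_equal(heterogeneity_g_test(tab[, 2:1])$G, g0)
  expect_equal(heterogeneity_g_test(tab[sample(4), ])$G, g0)
  # zero cells contribute nothing
  tab0 <- rbind(c(0, 10), c(5, 5))
  expect_equal(heterogeneity_g_test(tab0)$G, g_test_oracle(tab0),
               tolerance = 1e-8)
})

test_that("G-test type-I error is near nominal on shared-ratio features", {
  set.seed(16)
  p_vals <- vapply(seq_len(2000), function(i) {
    heterogeneity_g_test(random_shared_ratio_table(3, 40))$p
  }, 0)
  rate <- mean(p_vals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("planted heterogeneity is detected at depth 100", {
  set.seed(18)
  hits <- vapply(seq_len(200), function(i) {
    tab <- rbind(random_shared_ratio_table(2, 100, 0.7),
                 random_shared_ratio_table(1, 100, 0.3))
    heterogeneity_g_test(tab)$p < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})

test_that("heterogeneity summary reports fractions by feature class", {
  cfg <- tiny_sim_config(seed = 22, frac_causal_features = 0,
                         mean_depth = 40)
  sim <- simulate_dataset(cfg)
  het <- feature_heterogeneity(sim$counts$allele_counts, sim$features)
  summ <- summarize_heterogeneity(het)
  expect_true(all(summ$fraction >= 0 & summ$fraction <= 1))
  expect_true(all(summ$n_heterogeneous <= summ$n_multi_site))
  # single-site-only input reports 0 of 0
  one_site <- het[het$s == 1, ]
  expect_equal(nrow(summarize_heterogeneity(one_site)), 0)
})
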