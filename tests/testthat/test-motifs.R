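# Motif discovery: selection, extraction, clustering, consensus,
# enrichment, skew tests and PFM similarity.

test_that("variant selection honours mark thresholds and the in-peak rule", {
  feats <- list(features = tibble::tibble(
    feature_id = c("peak_1", "exon_1"), type = c("peak", "exon"),
    chrom = "chr1", start = c(1000L, 50000L), end = c(2000L, 50500L),
    midpoint = c(1500L, 50250L), tss = c(1000L, 50000L)))
  asb <- tibble::tibble(
    feature_id = "peak_1", dsnp_id = c("s1", "s2", "s3"), chrom = "chr1",
    pos = c(1100L, 1200L, 5000L), p1 = c(5e-9, 5e-7, 1e-12), Z = 3)
  # H3K4Me1 threshold 1e-8: s1 passes, s2 fails on p, s3 is outside the peak
  v <- select_variants_for_motifs(asb, NULL, feats, mark = "H3K4Me1")
  expect_equal(v$snp_id, "s1")
  # H3K4Me3 threshold 1e-7 keeps s1 only (s2 at 5e-7 fails, s3 not in peak)
  v3 <- select_variants_for_motifs(asb, NULL, feats, mark = "H3K4Me3")
  expect_equal(v3$snp_id, "s1")
  # H3K27ac is exempt from the in-peak requirement and uses the 1e-6
  # threshold, so all three variants pass
  v27 <- select_variants_for_motifs(asb, NULL, feats, mark = "H3K27ac")
  expect_setequal(v27$snp_id, c("s1", "s2", "s3"))
  expect_error(select_variants_for_motifs(asb, NULL, feats, mark = "H3"),
               "unknown mark")
})

test_that("expression variants require TSS proximity and a 1e-15 threshold", {
  feats <- list(features = tibble::tibble(
    feature_id = "exon_1", type = "exon", chrom = "chr1",
    start = 50000L, end = 50500L, midpoint = 50250L, tss = 50000L))
  ase <- tibble::tibble(
    feature_id = "exon_1", dsnp_id = c("t1", "t2", "t3"), chrom = "chr1",
    pos = c(45000L, 62001L, 48000L), p1 = c(1e-16, 1e-20, 1e-14), Z = -2)
  v <- select_variants_for_motifs(NULL, ase, feats)
  # t2 is 12 kb from the start, t3 misses the threshold
  expect_equal(v$snp_id, "t1")
})

test_that("sequence extraction: bounds, alphabet and revcomp involution", {
  genome <- c(chr1 = paste(rep("ACGT", 20), collapse = ""))
  variants <- tibble::tibble(snp_id = c("edge", "mid", "n"),
                             chrom = "chr1", pos = c(9L, 40L, 20L),
                             positive_allele = "A", reference_allele = "G")
  g2 <- genome
  substr(g2["chr1"], 25, 25) <- "N"
  ext <- extract_sequences(variants, g2)
  expect_setequal(ext$skipped$snp_id, c("edge", "n"))
  seqs <- ext$sequences
  expect_equal(nrow(seqs), 2)
  expect_equal(unique(nchar(seqs$sequence)), 21)
  fwd <- seqs$sequence[seqs$orientation == "forward"]
  rev <- seqs$sequence[seqs$orientation == "revcomp"]
  expect_identical(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev))), fwd)
  # alleles complemented on the reverse strand
  expect_equal(seqs$positive_allele, c("A", "T"))
  expect_equal(seqs$reference_allele, c("G", "C"))
})

test_that("clustering groups identical sequences and separates distant ones", {
  seqs <- rep(strrep("AC", 10) |> paste0("A"), 12)
  cl <- cluster_sequences(seqs)
  expect_equal(length(unique(cl$cluster)), 1)
  expect_true(all(cl$retained))

  # central 9-mers differing at 4 positions never co-cluster
  a <- paste0(strrep("A", 6), "ACGTACGTA", strrep("A", 6))
  b <- paste0(strrep("A", 6), "TGCAACGTA", strrep("A", 6))
  expect_equal(utils::adist(substr(a, 7, 15), substr(b, 7, 15))[1], 4)
  cl2 <- cluster_sequences(c(a, b), min_size = 1)
  expect_equal(length(unique(cl2$cluster)), 2)
})

test_that("clustering matches exhaustive complete linkage for small sets", {
  set.seed(41)
  for (rep in 1:5) {
    n <- sample(8:15, 1)
    seqs <- vapply(seq_len(n), function(i) {
      core <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
      paste0(strrep("A", 6), core, strrep("A", 6))
    }, "")
    ours <- cluster_sequences(seqs, min_size = 1)$cluster
    oracle <- complete_linkage_oracle(substr(seqs, 7, 15), 3)
    # same partition up to label renaming
    expect_equal(length(unique(ours)), length(unique(oracle)))
    cross <- table(ours, oracle)
    expect_true(all(rowSums(cross > 0) == 1))
    expect_true(all(colSums(cross > 0) == 1))
    # every intra-cluster central distance is at most 3
    for (k in unique(ours)) {
      mem <- substr(seqs[ours == k], 7, 15)
      if (length(mem) > 1) expect_lte(max(utils::adist(mem)), 3)
    }
  }
})

test_that("PFM columns sum to the cluster size", {
  seqs <- c("ACGTA", "ACGTT", "ACGGA")
  pfm <- pfm_from_sequences(seqs)
  expect_equal(unname(colSums(pfm)), rep(3, 5))
  expect_equal(unname(pfm["A", 1]), 3L)
})

test_that("consensus construction follows the strict 0.85 accumulation", {
  # single-column matrices isolate the accumulation rule (trimming off)
  col <- function(f) matrix(f * 100, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons1 <- function(f) build_consensus(col(f), entropy_threshold = 0)
  # the worked example: 0.4 + 0.3 + 0.2 > 0.85 gives a three-base class
  expect_equal(cons1(c(0.4, 0.3, 0.2, 0.1))$regex, "[ACG]")
  # a fixed column is a bare base
  expect_equal(cons1(c(1, 0, 0, 0))$regex, "A")
  # boundary: 0.86 exceeds, 0.85 does not
  expect_equal(cons1(c(0.86, 0.14, 0, 0))$regex, "A")
  expect_equal(cons1(c(0.85, 0.15, 0, 0))$regex, "[AC]")
  # IUPAC rendering
  expect_equal(cons1(c(0.5, 0, 0.5, 0))$iupac, "R")
})

test_that("entropy trimming drops near-random flanks, keeps the core", {
  core <- matrix(c(30, 0, 0, 0), 4, 1)
  flank <- matrix(c(8, 8, 7, 7), 4, 1)
  pfm <- cbind(flank, core, core, flank)
  rownames(pfm) <- c("A", "C", "G", "T")
  cons <- build_consensus(pfm)
  expect_equal(unname(cons$span), c(2, 3))
  expect_equal(cons$regex, "AA")
  # the literal low-entropy reading keeps high-entropy flanks and trims
  # the conserved columns; an all-conserved matrix trims away entirely
  lit <- build_consensus(pfm, literal_entropy = TRUE)
  expect_equal(unname(lit$span), c(1, 4))
  expect_error(build_consensus(cbind(core, core), literal_entropy = TRUE),
               "trimmed")
})

test_that("genomic enrichment: worked arithmetic on toy genomes", {
  cons_at <- structure(list(span = c(first = 1, last = 1),
                            bases = list(c("A", "T")),
                            iupac = "W", regex = "[AT]"),
                       class = "asqtl_consensus")
  g <- c(chr1 = strrep("A", 1000))
  uniform <- c(A = .25, C = .25, G = .25, T = .25)
  e <- genomic_enrichment(cons_at, g, uniform)
  expect_equal(e$observed, 1000)
  expect_equal(e$expected, 500)
  expect_equal(e$enrichment, 2)

  cons_acgt <- structure(list(span = c(first = 1, last = 4),
                              bases = list("A", "C", "G", "T"),
                              iupac = "ACGT", regex = "ACGT"),
                         class = "asqtl_consensus")
  g2 <- c(chr1 = strrep("ACGT", 100))
  e2 <- genomic_enrichment(cons_acgt, g2, uniform)
  expect_equal(e2$observed, 100)
  expect_equal(e2$expected, 400 * 0.25^4)
  expect_equal(e2$enrichment, 64)
})

test_that("observed counts match a brute-force non-overlapping scan", {
  set.seed(43)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 1e5, TRUE,
                             prob = c(.3, .2, .2, .3)), collapse = ""))
  cons <- structure(list(span = c(first = 1, last = 5),
                         bases = list("A", c("C", "G"), "G", c("A", "T"), "T"),
                         iupac = "ASGWT", regex = "A[CG]G[AT]T"),
                    class = "asqtl_consensus")
  e <- genomic_enrichment(cons, g, c(A = .3, C = .2, G = .2, T = .3))
  expect_equal(e$observed, motif_count_oracle(cons$regex, g[[1]]))
})

test_that("null genomes show calibrated enrichment near 1", {
  set.seed(44)
  freqs <- c(A = 0.291, C = 0.209, G = 0.209, T = 0.291)
  g <- c(chr1 = paste(sample(names(freqs), 1e6, TRUE, prob = freqs),
                      collapse = ""))
  cons <- structure(list(span = c(first = 1, last = 6),
                         bases = list("T", "G", "A", c("C", "G"), "T", "C"),
                         iupac = "TGASTC", regex = "TGA[CG]TC"),
                    class = "asqtl_consensus")
  e <- genomic_enrichment(cons, g, freqs)
  # 3 SD of the Poisson-scale match count
  expect_lt(abs(e$observed - e$expected), 3 * sqrt(e$expected))
})

test_that("allele skew: uniform, degenerate and enumerated p-values", {
  u <- allele_skew_test(c(A = 5, C = 5, G = 5, T = 5))
  expect_equal(u$llr, 0)
  expect_equal(u$p, 1)
  expect_equal(u$method, "exact")

  one <- allele_skew_test(c(A = 10, C = 0, G = 0, T = 0))
  expect_equal(one$llr, 20 * log(4), tolerance = 1e-10)
  expect_equal(one$p, 4 * 0.25^10, tolerance = 1e-12)

  expect_error(allele_skew_test(character(0)), "no alleles")
})

test_that("exact skew p equals full enumeration for N <= 12", {
  set.seed(45)
  for (i in 1:6) {
    N <- sample(4:12, 1)
    counts <- as.integer(rmultinom(1, N, c(.1, .2, .3, .4)))
    names(counts) <- c("A", "C", "G", "T")
    ours <- allele_skew_test(counts)
    expect_equal(ours$method, "exact")
    expect_equal(ours$p, skew_p_oracle(counts), tolerance = 1e-10)
  }
})

test_that("Monte-Carlo skew p agrees with the exact path at N = 15", {
  counts <- c(A = 7, C = 4, G = 3, T = 1)
  exact <- allele_skew_test(counts)
  mc <- allele_skew_test(counts, exact_max = 0, mc_draws = 1e5, seed = 2)
  expect_equal(mc$method, "monte-carlo")
  se <- sqrt(exact$p * (1 - exact$p) / 1e5)
  expect_lt(abs(mc$p - exact$p), 3 * se + 1e-4)
})

test_that("PFM similarity scoring contract", {
  q <- matrix(c(10, 0, 0, 0,
                0, 10, 0, 0), 4, 2,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  db <- list(list(id = "M1", name = "exact", collection = "CORE", pfm = q),
             list(id = "M2", name = "disjoint", collection = "POLII",
                  pfm = q[c(3, 4, 1, 2), ] |>
                    (\(m) { rownames(m) <- c("A", "C", "G", "T"); m })()))
  res <- pfm_similarity(q, db, rel_score_min = -1)
  expect_equal(res$rel_score[res$database_id == "M1"], 100)
  expect_equal(res$rel_score[res$database_id == "M2"], 0)
  # default threshold reports only matches above 90
  res90 <- pfm_similarity(q, db)
  expect_equal(res90$database_id, "M1")

  half <- matrix(c(0.5, 0.5, 0, 0), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  target <- matrix(c(1, 0, 0, 0), 4, 1,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  r <- pfm_similarity(half, list(list(id = "T", name = "T",
                                      collection = "CORE", pfm = target)),
                      rel_score_min = -1)
  expect_equal(r$rel_score, 50)
})

test_that("JASPAR round-trip preserves matrices and collections", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  pfm <- matrix(sample(0:20, 4 * 6, TRUE), 4, 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  write_jaspar(list(list(id = "MA0001.1", name = "TEST", collection = "POLII",
                         pfm = pfm)), tmp)
  back <- read_jaspar(tmp)
  expect_equal(back[[1]]$id, "MA0001.1")
  expect_equal(back[[1]]$collection, "POLII")
  expect_equal(unname(back[[1]]$pfm), unname(pfm))
})

test_that("planted motif clusters are recovered with a matching consensus", {
  set.seed(46)
  plant <- "TGACGTCAC"
  mutate_one <- function(s) {
    i <- sample(nchar(s), 1)
    substr(s, i, i) <- sample(c("A", "C", "G", "T"), 1)
    s
  }
  rand_flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")
  planted <- vapply(1:30, function(i) {
    paste0(rand_flank(6), mutate_one(plant), rand_flank(6))
  }, "")
  background <- vapply(1:100, function(i) rand_flank(21), "")
  cl <- cluster_sequences(c(planted, background))
  planted_cl <- cl$cluster[1:30]
  main <- as.integer(names(which.max(table(planted_cl))))
  members <- which(cl$cluster == main)
  expect_gte(length(members), 25)
  expect_true(all(cl$retained[members]))
  # consensus of the planted cluster reduces to the planted core: random
  # flanks trim away and each core column keeps its majority base
  pfm <- pfm_from_sequences(cl$sequence[members])
  cons <- build_consensus(pfm)
  expect_gte(cons$span["first"], 5)
  expect_lte(cons$span["last"], 17)
  expect_true(grepl(cons$regex, plant) ||
                mean(grepl(cons$regex, planted)) >= 0.5)
})
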