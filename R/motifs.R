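# Variant-centred motif discovery: flank extraction, Levenshtein
# clustering, PFMs, consensus regexes, genomic enrichment, allele-skew
# tests and PFM database matching.

DNA <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[b]

#' Select variants entering motif discovery
#'
#' Allele-specific binding variants are kept when their first-test p falls
#' below the mark-specific threshold and (except for H3K27ac) they lie
#' inside the peak they are associated with. Allele-specific expression
#' variants are kept when within `tss_window` of the target feature's start
#' and below `ase_threshold`.
#'
#' @param asb_results [as_scan()] results for peaks, with a `mark` column or
#'   a single `mark` label supplied here.
#' @param ase_results [as_scan()] results for exons (or NULL).
#' @param features An `asqtl_features` (peak intervals, exon starts).
#' @param mark Mark label for `asb_results` when they carry none.
#' @param thresholds Named first-test p thresholds per mark.
#' @param ase_threshold,tss_window Expression-side selection parameters.
#' @return Tibble: snp_id, chrom, pos, source (mark or "ase"), effect_sign
#'   (+1 when the alternate allele increases binding/expression).
#' @export
select_variants_for_motifs <- function(asb_results, ase_results, features,
                                       mark = "H3K4Me3",
                                       thresholds = c(H3K4Me1 = 1e-8,
                                                      H3K4Me3 = 1e-7,
                                                      H3K27ac = 1e-6),
                                       ase_threshold = 1e-15,
                                       tss_window = 1e4) {
  feats <- features$features
  out <- list()
  if (!is.null(asb_results) && nrow(asb_results) > 0) {
    mk <- if ("mark" %in% names(asb_results)) asb_results$mark else mark
    if (any(!unique(mk) %in% names(thresholds))) {
      abort(sprintf("unknown mark: %s",
                    paste(setdiff(unique(mk), names(thresholds)), collapse = ", ")),
            class = "asqtl_error")
    }
    thr <- thresholds[mk]
    pk <- feats[match(asb_results$feature_id, feats$feature_id), ]
    in_peak <- asb_results$pos >= pk$start & asb_results$pos < pk$end
    keep <- !is.na(asb_results$p1) & asb_results$p1 < thr &
      (in_peak | mk == "H3K27ac")
    out$asb <- asb_results[keep, ] |>
      mutate(source = if ("mark" %in% names(asb_results)) .data$mark else mark,
             effect_sign = sign(.data$Z)) |>
      select(snp_id = "dsnp_id", "chrom", "pos", "source", "effect_sign")
  }
  if (!is.null(ase_results) && nrow(ase_results) > 0) {
    ex <- feats[match(ase_results$feature_id, feats$feature_id), ]
    near_tss <- abs(ase_results$pos - ex$tss) <= tss_window
    keep <- !is.na(ase_results$p1) & ase_results$p1 < ase_threshold & near_tss
    out$ase <- ase_results[keep, ] |>
      mutate(source = "ase", effect_sign = sign(.data$Z)) |>
      select(snp_id = "dsnp_id", "chrom", "pos", "source", "effect_sign")
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(snp_id = character(), chrom = character(), pos = integer(),
                  source = character(), effect_sign = numeric()))
  }
  res |> distinct(.data$snp_id, .data$source, .keep_all = TRUE)
}

#' Extract 21 bp variant-centred sequences (forward and reverse complement)
#'
#' For each variant, the reference bases at the SNP site plus 10 bp either
#' side are extracted; a second entry carries the reverse complement with
#' complemented alleles. Variants within 10 bp of a contig end, or whose
#' window contains a non-ACGT base, are skipped and logged.
#'
#' @param variants Tibble with `snp_id`, `chrom`, `pos` (0-based), and
#'   optionally `positive_allele`, `reference_allele` (bases).
#' @param genome Named character vector of chromosome sequences.
#' @return List: `sequences` tibble (snp_id, sequence, orientation,
#'   positive_allele, reference_allele, ...) and `skipped` tibble
#'   (snp_id, reason).
#' @export
extract_sequences <- function(variants, genome) {
  skipped <- tibble(snp_id = character(), reason = character())
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    chrom_seq <- genome[[v$chrom]]
    if (is.null(chrom_seq) || is.na(chrom_seq)) {
      skipped <- bind_rows(skipped, tibble(snp_id = v$snp_id, reason = "unknown-contig"))
      next
    }
    L <- nchar(chrom_seq)
    if (v$pos < 10 || v$pos > L - 11) {
      skipped <- bind_rows(skipped, tibble(snp_id = v$snp_id, reason = "contig-edge"))
      next
    }
    s <- substr(chrom_seq, v$pos + 1 - 10, v$pos + 1 + 10)
    if (grepl("[^ACGT]", s)) {
      skipped <- bind_rows(skipped, tibble(snp_id = v$snp_id, reason = "non-acgt"))
      next
    }
    pos_allele <- if ("positive_allele" %in% names(v)) v$positive_allele else NA_character_
    ref_allele <- if ("reference_allele" %in% names(v)) v$reference_allele else substr(s, 11, 11)
    extra <- v[setdiff(names(v), c("snp_id", "chrom", "pos",
                                   "positive_allele", "reference_allele"))]
    rows[[length(rows) + 1]] <- bind_cols(
      tibble(snp_id = rep(v$snp_id, 2),
             sequence = c(s, revcomp(s)),
             orientation = c("forward", "revcomp"),
             positive_allele = c(pos_allele, unname(comp_base(pos_allele))),
             reference_allele = c(ref_allele, unname(comp_base(ref_allele)))),
      extra[rep(1, 2), , drop = FALSE])
  }
  list(sequences = bind_rows(rows), skipped = skipped)
}

central_9mer <- function(sequences) substr(sequences, 7, 15)

#' Cluster variant sequences by central-9-mer edit distance
#'
#' Levenshtein distances between the central nine bases of each 21 bp
#' sequence feed complete-linkage hierarchical clustering; the dendrogram is
#' cut at height 3, so every intra-cluster pair differs by at most three
#' edits. Clusters below `min_size` members are marked discarded.
#'
#' @param sequences Character vector of 21 bp sequences (or a tibble with a
#'   `sequence` column, returned augmented).
#' @param height Cut height (default 3).
#' @param min_size Minimum retained cluster size (default 10).
#' @return Tibble with columns `sequence`, `cluster` (integer id) and
#'   `retained` (cluster size >= `min_size`), plus any input columns.
#' @export
cluster_sequences <- function(sequences, height = 3, min_size = 10) {
  tbl <- if (is.character(sequences)) tibble(sequence = sequences) else as_tibble(sequences)
  assert_that(nrow(tbl) >= 1, "no sequences to cluster")
  if (nrow(tbl) == 1) {
    tbl$cluster <- 1L
    tbl$retained <- min_size <= 1
    return(tbl)
  }
  d <- adist(central_9mer(tbl$sequence))
  hc <- hclust(stats::as.dist(d), method = "complete")
  tbl$cluster <- unname(cutree(hc, h = height))
  sizes <- table(tbl$cluster)
  tbl$retained <- sizes[as.character(tbl$cluster)] >= min_size
  tbl
}

#' Position frequency matrix of a sequence set
#'
#' @param sequences Equal-length character vector.
#' @return 4 x width integer count matrix with rows A, C, G, T; every column
#'   sums to the number of sequences.
#' @export
pfm_from_sequences <- function(sequences) {
  w <- unique(nchar(sequences))
  assert_that(length(w) == 1, "sequences must share one length")
  chars <- do.call(rbind, strsplit(sequences, ""))
  pfm <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = DNA))
    as.integer(tab)
  }, integer(4))
  rownames(pfm) <- DNA
  pfm
}

iupac_from_bases <- function(bases) {
  key <- paste(sort(bases), collapse = "")
  lookup <- c(A = "A", C = "C", G = "G", T = "T",
              AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
              CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  unname(lookup[key])
}

#' Build a consensus motif from a PFM
#'
#' Flanking columns are trimmed while uninformative, then each retained
#' column contributes either a single base or a bracketed character class:
#' base frequencies are sorted descending (ties in fixed A, C, G, T order)
#' and accumulated until the running sum strictly exceeds `cum_freq`.
#'
#' By default a column is trimmed when its information content
#' (2 - entropy, bits) falls below `entropy_threshold` — near-random flanks
#' go, conserved columns stay. `literal_entropy = TRUE` instead trims
#' columns whose raw entropy is below the threshold (the most conserved
#' columns), retained as a switch for strict reproduction of that reading.
#'
#' @param pfm 4 x width count (or frequency) matrix, rows A, C, G, T.
#' @param entropy_threshold Bits (default 0.2).
#' @param cum_freq Cumulative-frequency threshold (default 0.85, strict
#'   "exceeds").
#' @param literal_entropy Use the literal low-entropy trimming direction.
#' @return List of class `asqtl_consensus`: `span` (first, last retained
#'   column), `bases` (list of included base sets), `iupac`, `regex`.
#' @export
#' @examples
#' pfm <- matrix(c(0.4, 0.3, 0.2, 0.1) * 10, 4, 1, dimnames = list(c("A","C","G","T"), NULL))
#' build_consensus(pfm)$regex
build_consensus <- function(pfm, entropy_threshold = 0.2, cum_freq = 0.85,
                            literal_entropy = FALSE) {
  stopifnot(nrow(pfm) == 4)
  freq <- sweep(pfm, 2, colSums(pfm), "/")
  ent <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  keep_score <- if (literal_entropy) ent else 2 - ent
  keep <- keep_score >= entropy_threshold
  if (!any(keep)) {
    abort("all columns trimmed: empty motif", class = "asqtl_error")
  }
  first <- min(which(keep)); last <- max(which(keep))
  cols <- seq(first, last)
  bases <- lapply(cols, function(j) {
    f <- freq[, j]
    ord <- order(-f, match(DNA, DNA))  # ties resolve A, C, G, T
    acc <- cumsum(f[ord])
    k <- which(acc > cum_freq)[1]
    if (is.na(k)) k <- 4L
    sort(DNA[ord][seq_len(k)])
  })
  regex <- paste(vapply(bases, function(b) {
    if (length(b) == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, ""), collapse = "")
  iupac <- paste(vapply(bases, iupac_from_bases, ""), collapse = "")
  structure(list(span = c(first = first, last = last), bases = bases,
                 iupac = iupac, regex = regex),
            class = "asqtl_consensus")
}

#' Genomic enrichment of a consensus motif
#'
#' Observed counts are non-overlapping forward-strand regex matches summed
#' over all sequences; expected counts are the product over consensus
#' positions of the summed background frequencies of the included bases,
#' multiplied by the total sequence length. Enrichment is observed over
#' expected.
#'
#' @param consensus An `asqtl_consensus` (from [build_consensus()]).
#' @param genome Named character vector of sequences.
#' @param base_freqs Named (A, C, G, T) background frequencies; the default
#'   is the autosomal composition used in the published analysis
#'   (A = T = 0.291, C = G = 0.209). Use [genome_base_freqs()] to recompute
#'   from a supplied genome.
#' @return Tibble: observed, expected, enrichment, total_length.
#' @export
genomic_enrichment <- function(consensus, genome,
                               base_freqs = c(A = 0.291, C = 0.209,
                                              G = 0.209, T = 0.291)) {
  assert_that(nchar(consensus$regex) > 0, "empty motif regex")
  observed <- sum(vapply(genome, function(s) {
    m <- gregexpr(consensus$regex, s, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, integer(1)))
  per_pos <- vapply(consensus$bases, function(b) sum(base_freqs[b]), 0)
  total_length <- sum(nchar(genome))
  expected <- prod(per_pos) * total_length
  assert_that(expected > 0, "expected motif count is 0")
  tibble(observed = observed, expected = expected,
         enrichment = observed / expected, total_length = total_length)
}

#' Base composition of a genome
#' @param genome Named character vector of sequences.
#' @return Named (A, C, G, T) frequencies.
#' @export
genome_base_freqs <- function(genome) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(genome))[, DNA, drop = FALSE])
  counts / sum(counts)
}

multinomial_llr <- function(counts) {
  N <- sum(counts)
  2 * sum(xlogx(counts) - counts * log(N / 4))
}

# all compositions of N into 4 non-negative parts
compositions4 <- function(N) {
  out <- list()
  for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
    out[[length(out) + 1]] <- c(a, b, cc, N - a - b - cc)
  }
  do.call(rbind, out)
}

#' Multinomial log-likelihood-ratio test of allele skew
#'
#' Tests the base composition of a cluster's alleles against equal
#' representation (25% each): `LLR = 2 sum n_b ln(n_b / (N/4))` with
#' `0 ln 0 = 0`. The p-value is exact (full enumeration of outcomes with
#' LLR at least as large) for `N <= exact_max`, otherwise Monte-Carlo with
#' `mc_draws` seeded draws; the method used is recorded.
#'
#' @param alleles Character vector of bases, or a named (A, C, G, T) count
#'   vector.
#' @param exact_max Largest N for exact enumeration (default 20).
#' @param mc_draws Monte-Carlo sample size (default 1e5).
#' @param seed Seed for the Monte-Carlo path.
#' @return Tibble: n_A, n_C, n_G, n_T, llr, p, method.
#' @export
#' @examples
#' allele_skew_test(c(A = 10, C = 0, G = 0, T = 0))
allele_skew_test <- function(alleles, exact_max = 20, mc_draws = 1e5,
                             seed = 1L) {
  counts <- if (is.character(alleles)) {
    as.integer(table(factor(alleles, levels = DNA)))
  } else {
    as.integer(alleles[DNA])
  }
  N <- sum(counts)
  assert_that(N > 0, "no alleles supplied")
  llr <- multinomial_llr(counts)
  if (N <= exact_max) {
    comp <- compositions4(N)
    llrs <- apply(comp, 1, multinomial_llr)
    logp <- lfactorial(N) - rowSums(lfactorial(comp)) + N * log(0.25)
    p <- sum(exp(logp)[llrs >= llr - 1e-9])
    method <- "exact"
  } else {
    p <- with_stream(seed, 77L, {
      sim <- rmultinom(mc_draws, N, rep(0.25, 4))
      sim_llr <- 2 * colSums(xlogx(sim) - sim * log(N / 4))
      (sum(sim_llr >= llr - 1e-9) + 1) / (mc_draws + 1)
    })
    method <- "monte-carlo"
  }
  tibble(n_A = counts[1], n_C = counts[2], n_G = counts[3], n_T = counts[4],
         llr = llr, p = min(p, 1), method = method)
}

#' Motif discovery over selected variants
#'
#' Runs the full variant-centred motif chain: sequence extraction,
#' clustering, and per retained cluster a PFM, a consensus motif with
#' genomic enrichment, and allele-skew tests of the positive-effect and
#' reference alleles at the central position.
#'
#' @param variants Output of [select_variants_for_motifs()], augmented with
#'   `positive_allele` and `reference_allele` columns (see
#'   [run_pipeline()] for how those derive from the panel and effect signs).
#' @param genome Named character vector of chromosome sequences.
#' @param base_freqs Background composition for enrichment.
#' @param min_size Minimum cluster size (default 10).
#' @param entropy_threshold,cum_freq,literal_entropy Consensus parameters,
#'   see [build_consensus()].
#' @param seed Seed for Monte-Carlo skew p-values.
#' @return List of class `asqtl_motif_set`: `sequences` (clustered tibble),
#'   `clusters` tibble (cluster, size, iupac, regex, observed, expected,
#'   enrichment, skew p-values), `skipped`.
#' @export
discover_motifs <- function(variants, genome,
                            base_freqs = c(A = 0.291, C = 0.209,
                                           G = 0.209, T = 0.291),
                            min_size = 10, entropy_threshold = 0.2,
                            cum_freq = 0.85, literal_entropy = FALSE,
                            seed = 1L) {
  ext <- extract_sequences(variants, genome)
  if (nrow(ext$sequences) == 0) {
    return(structure(list(
      sequences = ext$sequences,
      clusters = tibble(cluster = integer(), size = integer(),
                        iupac = character(), regex = character(),
                        observed = integer(), expected = numeric(),
                        enrichment = numeric(), skew_positive_p = numeric(),
                        skew_reference_p = numeric()),
      skipped = ext$skipped), class = "asqtl_motif_set"))
  }
  seqs <- cluster_sequences(ext$sequences, min_size = min_size)
  kept <- seqs |> filter(.data$retained)
  clusters <- purrr::map_dfr(unique(kept$cluster), function(cl) {
    mem <- kept |> filter(.data$cluster == cl)
    pfm <- pfm_from_sequences(mem$sequence)
    cons <- tryCatch(
      build_consensus(pfm, entropy_threshold, cum_freq, literal_entropy),
      asqtl_error = function(e) NULL)
    enr <- if (is.null(cons)) {
      tibble(observed = NA_integer_, expected = NA_real_, enrichment = NA_real_)
    } else {
      genomic_enrichment(cons, genome, base_freqs)
    }
    pos_ok <- !is.na(mem$positive_allele)
    skew_pos <- if (any(pos_ok)) {
      allele_skew_test(mem$positive_allele[pos_ok], seed = seed)$p
    } else NA_real_
    skew_ref <- if (any(!is.na(mem$reference_allele))) {
      allele_skew_test(mem$reference_allele[!is.na(mem$reference_allele)],
                       seed = seed)$p
    } else NA_real_
    tibble(cluster = cl, size = nrow(mem),
           iupac = if (is.null(cons)) NA_character_ else cons$iupac,
           regex = if (is.null(cons)) NA_character_ else cons$regex,
           observed = enr$observed[1], expected = enr$expected[1],
           enrichment = enr$enrichment[1],
           skew_positive_p = skew_pos, skew_reference_p = skew_ref)
  })
  structure(list(sequences = seqs, clusters = clusters, skipped = ext$skipped),
            class = "asqtl_motif_set")
}

#' Percentage of motif clusters with skewed allele composition
#'
#' @param motif_set An `asqtl_motif_set`.
#' @param alpha Skew flag level (default 0.05).
#' @return Tibble: n_clusters, pct_positive_skewed, pct_reference_skewed
#'   (0 of 0 reported as zero counts with NA percentages).
#' @export
summarize_skew <- function(motif_set, alpha = 0.05) {
  cl <- motif_set$clusters
  n <- nrow(cl)
  tibble(
    n_clusters = n,
    pct_positive_skewed = if (n > 0) {
      100 * mean(cl$skew_positive_p < alpha, na.rm = TRUE)
    } else NA_real_,
    pct_reference_skewed = if (n > 0) {
      100 * mean(cl$skew_reference_p < alpha, na.rm = TRUE)
    } else NA_real_)
}
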