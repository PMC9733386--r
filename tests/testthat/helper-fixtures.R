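# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_animals = 60, n_chromosomes = 2, chrom_length = 1e6,
                   n_snps_per_chrom = 120, n_peaks = 15, n_exons = 15,
                   seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# independent G-test oracle: observed-vs-expected log-likelihood ratio form
g_test_oracle <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cells <- tab * log(tab / expected)
  2 * sum(cells[tab > 0])
}

# exhaustive complete-linkage clustering at a height cut (oracle for
# cluster_sequences); naive agglomeration recomputing the full max-distance
# matrix at every merge
complete_linkage_oracle <- function(strings, height) {
  n <- length(strings)
  d <- utils::adist(strings)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    if (best_d > height) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[1]]])
    clusters[[best[1]]] <- NULL
  }
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  membership
}

# brute-force per-position motif occurrence count (oracle for
# genomic_enrichment observed counts): non-overlapping scan
motif_count_oracle <- function(regex, s) {
  count <- 0L; from <- 1L
  repeat {
    m <- regexpr(regex, substr(s, from, nchar(s)), perl = TRUE)
    if (m == -1) break
    count <- count + 1L
    from <- from + as.integer(m) - 1L + attr(m, "match.length")
    if (from > nchar(s)) break
  }
  count
}

# full multinomial enumeration oracle for the skew test p-value
skew_p_oracle <- function(counts) {
  N <- sum(counts)
  grid <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
  grid <- grid[grid$a + grid$b + grid$c <= N, ]
  grid$d <- N - grid$a - grid$b - grid$c
  llr_of <- function(n) {
    n <- n[n > 0]
    2 * sum(n * log(n / (N / 4)))
  }
  obs <- llr_of(counts)
  llrs <- apply(grid, 1, llr_of)
  probs <- apply(grid, 1, function(n) stats::dmultinom(n, prob = rep(0.25, 4)))
  sum(probs[llrs >= obs - 1e-9])
}

# random maternal/paternal count table with a shared ratio
random_shared_ratio_table <- function(s, depth, p = 0.5) {
  m <- stats::rbinom(s, depth, p)
  cbind(m, depth - m)
}
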