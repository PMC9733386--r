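# Synthetic-data generators: phased trio genotypes, features with causal
# effects, beta-binomial/negative-binomial counts, and a toy genome.

#' Simulate a phased trio genotype panel
#'
#' Draws biallelic SNPs at uniform random positions (strictly increasing per
#' chromosome), per-SNP alternate-allele frequencies uniform in
#' `maf_range`, and for every offspring a maternal haplotype (drawn from the
#' population frequency) and a paternal haplotype transmitted from a
#' simulated sire, so paternal alleles are Mendelian-consistent with the
#' recorded sire genotype by construction. Offspring genotypes are also
#' carried as "input-phased" haplotypes whose orientation relative to
#' parental origin is randomised per animal and chromosome — the situation a
#' statistical phaser leaves you in, and the input that
#' [assign_parental_origin()] resolves using the sire.
#'
#' @param config A [sim_config()].
#' @return A list of class `asqtl_panel`: `snps` tibble (snp_id, chrom, pos
#'   (0-based), ref, alt, maf), `animals`, truth haplotype matrices
#'   `maternal`/`paternal` (animals x SNPs, 0 = reference, 1 = alternate),
#'   input-phased matrices `hap_a`/`hap_b`, and `sire_dosage` (0/1/2).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  with_stream(config$seed, 101L, {
    n <- config$n_animals
    snps <- purrr::map_dfr(seq_len(config$n_chromosomes), function(chrom) {
      pos <- sort(sample.int(config$chrom_length - 42L, config$n_snps_per_chrom)) + 20L
      tibble(
        chrom = sprintf("chr%d", chrom),
        pos = as.integer(pos),  # 0-based internally
        maf = runif(config$n_snps_per_chrom, config$maf_range[1], config$maf_range[2])
      )
    })
    m <- nrow(snps)
    snps$snp_id <- sprintf("snp_%05d", seq_len(m))
    # reference/alternate bases; reference base is written into the genome
    # by simulate_reference()
    bases <- c("A", "C", "G", "T")
    snps$ref <- sample(bases, m, replace = TRUE, prob = config$base_freqs)
    snps$alt <- vapply(snps$ref, function(r) sample(setdiff(bases, r), 1), "")
    snps <- snps[, c("snp_id", "chrom", "pos", "ref", "alt", "maf")]

    animals <- sprintf("animal_%03d", seq_len(n))
    draw_hap <- function() {
      matrix(rbinom(n * m, 1L, rep(snps$maf, each = n)), n, m,
             dimnames = list(animals, snps$snp_id))
    }
    sire1 <- draw_hap(); sire2 <- draw_hap()
    maternal <- draw_hap()
    transmit <- matrix(runif(n * m) < 0.5, n, m)
    paternal <- ifelse(transmit, sire1, sire2)
    dimnames(paternal) <- dimnames(maternal)

    # input phasing: orientation unknown per animal x chromosome
    flip <- matrix(FALSE, n, m, dimnames = dimnames(maternal))
    for (ch in unique(snps$chrom)) {
      idx <- which(snps$chrom == ch)
      flip[, idx] <- runif(n) < 0.5
    }
    hap_a <- ifelse(flip, paternal, maternal)
    hap_b <- ifelse(flip, maternal, paternal)
    dimnames(hap_a) <- dimnames(hap_b) <- dimnames(maternal)

    structure(list(
      snps = snps,
      animals = animals,
      maternal = maternal,
      paternal = paternal,
      hap_a = hap_a,
      hap_b = hap_b,
      sire_dosage = sire1 + sire2
    ), class = "asqtl_panel")
  })
}

#' Alternate-allele dosage matrix of a panel
#' @param panel An `asqtl_panel`.
#' @return Integer matrix animals x SNPs with entries 0/1/2.
#' @export
panel_dosage <- function(panel) panel$maternal + panel$paternal

# truth phased X coding: +1 alt maternal, -1 alt paternal, 0 homozygous
panel_phase_coding <- function(panel) panel$maternal - panel$paternal

#' Simulate peaks, exons and a causal-effect truth table
#'
#' Features are anchored on randomly chosen SNPs (so every feature contains
#' at least one informative site) with widths drawn from
#' `feature_width_range`. A fraction `frac_causal_features` of features is
#' assigned a causal driver SNP within 1 Mb of the feature midpoint —
#' `frac_causal_in_feature` of those inside the feature itself — with an
#' allelic log-odds effect and an additive log-level effect of common random
#' sign (one cis mechanism drives both).
#'
#' @param panel An `asqtl_panel`.
#' @param config The [sim_config()] used to build it.
#' @return A list of class `asqtl_features`: `features` tibble (feature_id,
#'   type, chrom, start, end, midpoint, tss; 0-based half-open), `snp_map`
#'   tibble (feature_id, snp_id) of contained SNPs, and `truth` tibble
#'   (causal_variant_id, target_feature_id, effect_on_ratio,
#'   effect_on_level, in_peak).
#' @export
simulate_features <- function(panel, config) {
  validate_sim_config(config)
  assert_that(nrow(panel$snps) > 0, "panel is empty")
  with_stream(config$seed, 202L, {
    snps <- panel$snps
    n_feat_all <- config$n_peaks + config$n_exons
    assert_that(n_feat_all <= nrow(snps),
                "more features requested than SNPs available to anchor them")
    # distinct anchor SNPs so features do not share informative sites
    anchor_idx <- sample.int(nrow(snps), n_feat_all)
    make_feats <- function(type, n_feat, anchors) {
      width <- sample(seq(config$feature_width_range[1],
                          config$feature_width_range[2]), n_feat, replace = TRUE)
      left <- floor(runif(n_feat) * width)
      start <- pmax(0L, as.integer(anchors$pos - left))
      end <- pmin(config$chrom_length, as.integer(start + width))
      tibble(
        feature_id = sprintf("%s_%04d", type, seq_len(n_feat)),
        type = type,
        chrom = anchors$chrom,
        start = start,
        end = end,
        midpoint = as.integer(floor((start + end) / 2)),
        tss = start
      )
    }
    features <- bind_rows(
      make_feats("peak", config$n_peaks,
                 snps[anchor_idx[seq_len(config$n_peaks)], ]),
      make_feats("exon", config$n_exons,
                 snps[anchor_idx[config$n_peaks + seq_len(config$n_exons)], ]))

    snp_map <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
      f <- features[i, ]
      hit <- snps$chrom == f$chrom & snps$pos >= f$start & snps$pos < f$end
      tibble(feature_id = f$feature_id, snp_id = snps$snp_id[hit])
    })

    n_causal <- rbinom(1L, nrow(features), config$frac_causal_features)
    causal_feats <- features[sample.int(nrow(features), n_causal), ]
    truth <- purrr::map_dfr(seq_len(nrow(causal_feats)), function(i) {
      f <- causal_feats[i, ]
      inside <- snp_map$snp_id[snp_map$feature_id == f$feature_id]
      in_window <- snps$snp_id[snps$chrom == f$chrom &
                                 abs(snps$pos - f$midpoint) <= 1e6]
      use_inside <- length(inside) > 0 &&
        runif(1) < config$frac_causal_in_feature
      pool <- if (use_inside) inside else setdiff(in_window, inside)
      if (length(pool) == 0) pool <- in_window
      snp <- sample(pool, 1)
      sgn <- sample(c(-1, 1), 1)
      tibble(
        causal_variant_id = snp,
        target_feature_id = f$feature_id,
        effect_on_ratio = sgn * runif(1, config$effect_size_range[1],
                                      config$effect_size_range[2]),
        effect_on_level = sgn * runif(1, config$effect_on_level_range[1],
                                      config$effect_on_level_range[2]),
        in_peak = snp %in% inside
      )
    })
    if (n_causal == 0) {
      truth <- tibble(causal_variant_id = character(), target_feature_id = character(),
                      effect_on_ratio = numeric(), effect_on_level = numeric(),
                      in_peak = logical())
    }
    # shared regulatory architecture: some causal peak variants also drive
    # nearby exons (same sign), so peak-exon links exist by construction
    if (nrow(truth) > 0 && config$shared_regulation > 0) {
      type_of <- setNames(features$type, features$feature_id)
      peak_rows <- which(type_of[truth$target_feature_id] == "peak" &
                           runif(nrow(truth)) < config$shared_regulation)
      extra <- purrr::map_dfr(peak_rows, function(r) {
        snp <- snps[snps$snp_id == truth$causal_variant_id[r], ]
        taken <- truth$target_feature_id
        near <- features$feature_id[features$type == "exon" &
                                      features$chrom == snp$chrom &
                                      abs(features$midpoint - snp$pos) <= 1e6 &
                                      !features$feature_id %in% taken]
        if (length(near) == 0) return(NULL)
        pick <- sample(near, min(length(near), sample(1:2, 1)))
        sgn <- sign(truth$effect_on_ratio[r])
        tibble(
          causal_variant_id = truth$causal_variant_id[r],
          target_feature_id = pick,
          effect_on_ratio = sgn * runif(length(pick),
                                        config$effect_size_range[1],
                                        config$effect_size_range[2]),
          effect_on_level = sgn * runif(length(pick),
                                        config$effect_on_level_range[1],
                                        config$effect_on_level_range[2]),
          in_peak = truth$in_peak[r])
      })
      # an exon picked twice keeps its first assignment
      truth <- bind_rows(truth, extra) |>
        distinct(.data$target_feature_id, .keep_all = TRUE)
    }
    structure(list(features = features, snp_map = snp_map, truth = truth),
              class = "asqtl_features")
  })
}

# beta-binomial sampler: size n trials, mean prob p, intra-class rho
rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate allele counts and feature count matrices
#'
#' Per informative (heterozygous) site of each animal in each feature, a read
#' depth is drawn negative-binomial at `mean_depth` and split
#' maternal/paternal by a beta-binomial whose mean is
#' `plogis(X * effect_on_ratio)`, where X is +1/-1 by which haplotype of the
#' causal dSNP carries the alternate allele (0, i.e. a balanced 0.5, for
#' animals homozygous at the dSNP or for non-causal features). Feature totals
#' (peak, exon) are negative-binomial with log-mean
#' `log(mean_depth) + dosage * effect_on_level + batch + polygenic`; input
#' totals are independent of genotype.
#'
#' @param panel An `asqtl_panel`.
#' @param features An `asqtl_features`.
#' @param config The shared [sim_config()].
#' @return A list of class `asqtl_counts`: `allele_counts` tibble (animal_id,
#'   snp_id, maternal_count, paternal_count), matrices `peak_counts`,
#'   `input_counts`, `exon_counts` (features x animals), and `batches` tibble
#'   (animal_id, batch).
#' @export
simulate_counts <- function(panel, features, config) {
  validate_sim_config(config)
  truth <- features$truth
  assert_that(all(truth$causal_variant_id %in% panel$snps$snp_id),
              "truth references SNPs absent from the panel")
  assert_that(all(truth$target_feature_id %in% features$features$feature_id),
              "truth references unknown features")
  with_stream(config$seed, 303L, {
    n <- length(panel$animals)
    phase <- panel_phase_coding(panel)    # +1 alt-maternal, -1 alt-paternal
    dosage <- panel_dosage(panel)
    feats <- features$features

    batches <- tibble(
      animal_id = panel$animals,
      batch = sprintf("batch_%d", sample.int(config$n_batches, n, replace = TRUE))
    )
    batch_eff <- setNames(rnorm(config$n_batches, 0, config$batch_sd),
                          sprintf("batch_%d", seq_len(config$n_batches)))
    # polygenic term: many small SNP effects -> kinship-structured totals
    m <- ncol(dosage)
    poly <- as.numeric(scale(dosage) %*% rnorm(m, 0, sqrt(config$polygenic_var / m)))
    poly[is.na(poly)] <- 0

    # per-feature per-animal maternal fraction, from the causal dSNP phase
    frac <- matrix(0.5, nrow(feats), n,
                   dimnames = list(feats$feature_id, panel$animals))
    level_shift <- matrix(0, nrow(feats), n,
                          dimnames = list(feats$feature_id, panel$animals))
    for (i in seq_len(nrow(truth))) {
      fid <- truth$target_feature_id[i]
      x <- phase[, truth$causal_variant_id[i]]
      frac[fid, ] <- plogis(x * truth$effect_on_ratio[i])
      level_shift[fid, ] <- dosage[, truth$causal_variant_id[i]] *
        truth$effect_on_level[i]
    }

    # allele counts at informative sites
    # a site inside several overlapping features yields one set of reads;
    # causal features take precedence in setting its allelic fraction
    sm <- features$snp_map |>
      left_join(feats[, c("feature_id", "type")], by = "feature_id") |>
      mutate(causal = .data$feature_id %in% truth$target_feature_id) |>
      arrange(dplyr::desc(.data$causal))
    site_tab <- sm |> distinct(.data$snp_id, .keep_all = TRUE)
    allele_counts <- purrr::map_dfr(seq_len(nrow(site_tab)), function(i) {
      sid <- site_tab$snp_id[i]
      fid <- site_tab$feature_id[i]
      het <- which(phase[, sid] != 0)
      if (length(het) == 0) return(NULL)
      depth <- rnb(length(het), config$mean_depth, config$nb_dispersion)
      p <- frac[fid, het]
      mat <- rbetabinom(length(het), depth, p, config$overdispersion)
      tibble(animal_id = panel$animals[het], snp_id = sid,
             maternal_count = as.integer(mat),
             paternal_count = as.integer(depth - mat))
    })
    if (nrow(allele_counts) == 0) {
      allele_counts <- tibble(animal_id = character(), snp_id = character(),
                              maternal_count = integer(), paternal_count = integer())
    }

    log_mu <- log(config$mean_depth) + level_shift +
      matrix(rep(batch_eff[batches$batch] + poly, each = nrow(feats)),
             nrow(feats), n)
    totals <- matrix(rnb(length(log_mu), exp(log_mu), config$nb_dispersion),
                     nrow(feats), n, dimnames = dimnames(frac))
    inputs <- matrix(rnb(length(log_mu), config$mean_depth, config$nb_dispersion),
                     nrow(feats), n, dimnames = dimnames(frac))

    is_peak <- feats$type == "peak"
    structure(list(
      allele_counts = allele_counts,
      peak_counts = totals[is_peak, , drop = FALSE],
      input_counts = inputs[is_peak, , drop = FALSE],
      exon_counts = totals[!is_peak, , drop = FALSE],
      batches = batches
    ), class = "asqtl_counts")
  })
}

iupac_table <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# one concrete realisation of an IUPAC consensus
realise_iupac <- function(consensus) {
  letters <- strsplit(consensus, "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(iupac_table[[l]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, ""), collapse = "")
}

#' Simulate a reference genome with motifs planted at variant sites
#'
#' Background bases are i.i.d. from `base_freqs`. The reference allele of
#' every SNP in `panel` is written at its position so genome and panel are
#' consistent. Each requested motif is planted `count` times, each instance a
#' concrete realisation of the IUPAC consensus centred on a distinct randomly
#' chosen SNP (the central base both realises the consensus and becomes that
#' SNP's reference allele).
#'
#' @param config A [sim_config()] (fields `planted_motifs`, `base_freqs`).
#' @param panel Optional `asqtl_panel`; required when motifs are planted, and
#'   recommended always so SNP reference alleles appear in the genome.
#' @return A list of class `asqtl_genome`: `genome` (named character vector
#'   of chromosome sequences) and `manifest` tibble (consensus, instance,
#'   chrom, start (0-based), snp_id).
#' @export
simulate_reference <- function(config, panel = NULL) {
  validate_sim_config(config)
  with_stream(config$seed, 404L, {
    bases <- c("A", "C", "G", "T")
    genome <- lapply(seq_len(config$n_chromosomes), function(i) {
      sample(bases, config$chrom_length, replace = TRUE, prob = config$base_freqs)
    })
    names(genome) <- sprintf("chr%d", seq_len(config$n_chromosomes))

    if (!is.null(panel)) {
      for (i in seq_len(nrow(panel$snps))) {
        s <- panel$snps[i, ]
        genome[[s$chrom]][s$pos + 1L] <- s$ref
      }
    }

    manifest <- tibble(consensus = character(), instance = character(),
                       chrom = character(), start = integer(),
                       snp_id = character())
    pm <- config$planted_motifs
    if (!is.null(pm) && nrow(pm) > 0) {
      assert_that(!is.null(panel),
                  "planting motifs at variant sites requires a genotype panel")
      avail <- panel$snps
      # keep away from chromosome ends so the 21 bp window always fits
      avail <- avail[avail$pos >= 30 & avail$pos <= config$chrom_length - 30, ]
      for (k in seq_len(nrow(pm))) {
        cons <- toupper(pm$consensus[k])
        cnt <- pm$count[k]
        assert_that(nrow(avail) >= cnt, "not enough SNPs left to plant motifs")
        pick <- sample.int(nrow(avail), cnt)
        sites <- avail[pick, ]
        avail <- avail[-pick, ]
        w <- nchar(cons)
        centre <- ceiling(w / 2)
        for (j in seq_len(cnt)) {
          inst <- realise_iupac(cons)
          start0 <- sites$pos[j] - (centre - 1L)  # motif centre at the SNP
          idx <- seq(start0 + 1L, start0 + w)
          genome[[sites$chrom[j]]][idx] <- strsplit(inst, "")[[1]]
          # keep panel consistency: planted centre base is the ref allele
          if (!is.null(panel)) {
            ri <- match(sites$snp_id[j], panel$snps$snp_id)
            panel$snps$ref[ri] <- substr(inst, centre, centre)
            if (panel$snps$alt[ri] == panel$snps$ref[ri]) {
              panel$snps$alt[ri] <- setdiff(bases, panel$snps$ref[ri])[1]
            }
          }
          manifest <- bind_rows(manifest, tibble(
            consensus = cons, instance = inst, chrom = sites$chrom[j],
            start = as.integer(start0), snp_id = sites$snp_id[j]))
        }
      }
    }
    structure(list(
      genome = vapply(genome, paste, "", collapse = ""),
      manifest = manifest,
      panel_snps = if (is.null(panel)) NULL else panel$snps
    ), class = "asqtl_genome")
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running all four generators off one config/master
#' seed. The returned panel carries any reference-allele adjustments made by
#' motif planting.
#'
#' @param config A [sim_config()].
#' @return List of class `asqtl_sim`: `panel`, `features`, `counts`,
#'   `genome`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  panel <- simulate_population(config)
  genome <- simulate_reference(config, panel)
  if (!is.null(genome$panel_snps)) panel$snps <- genome$panel_snps
  features <- simulate_features(panel, config)
  counts <- simulate_counts(panel, features, config)
  structure(list(panel = panel, features = features, counts = counts,
                 genome = genome, config = config),
            class = "asqtl_sim")
}
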