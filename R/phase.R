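# Parental-origin assignment and per-feature allele-count aggregation.

#' Assign parental origin to phased offspring genotypes
#'
#' Homozygous entries are unchanged. For heterozygous entries, if the sire is
#' homozygous for an allele that allele is designated paternal. If the sire
#' is heterozygous, the orientation (which input haplotype is maternal) is
#' carried from the nearest upstream SNP on the same chromosome whose
#' orientation was resolved from a homozygous sire (`carried-phase`
#' provenance, relying on the internal consistency of the input phasing); if
#' no such SNP exists the entry is marked `unphased` and excluded downstream.
#' Homozygous offspring entries incompatible with a homozygous sire (neither
#' offspring allele present in the sire) are flagged `mendelian-inconsistent`
#' and excluded.
#'
#' @param hap_a,hap_b Animal x SNP 0/1 matrices: the offspring's input-phased
#'   haplotypes (orientation relative to parental origin unknown, but
#'   consistent along a chromosome).
#' @param sire_dosage Animal x SNP matrix of sire alternate-allele dosages
#'   (0/1/2).
#' @param snps Tibble with `snp_id`, `chrom`, `pos` matching the matrix
#'   columns, in column order.
#' @return A list of class `asqtl_phase`: `maternal`, `paternal` 0/1
#'   matrices and a `provenance` character matrix with values
#'   `homozygous`, `sire-homozygous`, `carried-phase`, `unphased`,
#'   `mendelian-inconsistent`.
#' @export
assign_parental_origin <- function(hap_a, hap_b, sire_dosage, snps) {
  stopifnot(identical(dim(hap_a), dim(hap_b)),
            identical(dim(hap_a), dim(sire_dosage)),
            ncol(hap_a) == nrow(snps))
  n <- nrow(hap_a); m <- ncol(hap_a)
  maternal <- hap_a
  paternal <- hap_b
  provenance <- matrix("homozygous", n, m, dimnames = dimnames(hap_a))

  het <- hap_a != hap_b
  hom <- !het
  # Mendelian check at homozygous offspring sites: offspring allele must be
  # transmissible by the sire
  bad_hom <- hom & ((hap_a == 1 & sire_dosage == 0) |
                      (hap_a == 0 & sire_dosage == 2))
  provenance[bad_hom] <- "mendelian-inconsistent"

  sire_hom <- sire_dosage != 1
  resolved <- het & sire_hom
  # sire homozygous: its allele (0 if dosage 0, 1 if dosage 2) is paternal
  sire_allele <- (sire_dosage == 2) * 1L
  # orientation: TRUE means hap_a is maternal
  a_maternal <- matrix(NA, n, m)
  a_maternal[resolved] <- hap_b[resolved] == sire_allele[resolved]
  provenance[resolved] <- "sire-homozygous"

  # carry orientation to sire-het heterozygous sites, per chromosome
  chrom_idx <- split(seq_len(m), snps$chrom)
  carry_fill <- function(x) {
    # last-observation-carried-forward for logical with NAs
    idx <- cumsum(!is.na(x))
    filled <- x[!is.na(x)][pmax(idx, 1)]
    filled[idx == 0] <- NA
    filled
  }
  for (cols in chrom_idx) {
    ord <- cols[order(snps$pos[cols])]
    for (a in seq_len(n)) {
      known <- a_maternal[a, ord]
      carried <- carry_fill(known)
      need <- het[a, ord] & !sire_hom[a, ord]
      fill <- need & is.na(known)
      a_maternal[a, ord][fill] <- carried[fill]
      provenance[a, ord][fill & !is.na(carried)] <- "carried-phase"
      provenance[a, ord][fill & is.na(carried)] <- "unphased"
    }
  }

  swap <- het & !is.na(a_maternal) & !a_maternal
  maternal[swap] <- hap_b[swap]
  paternal[swap] <- hap_a[swap]
  keep_a <- het & !is.na(a_maternal) & a_maternal
  maternal[keep_a] <- hap_a[keep_a]
  paternal[keep_a] <- hap_b[keep_a]
  unres <- het & is.na(a_maternal)
  provenance[unres] <- "unphased"

  structure(list(maternal = maternal, paternal = paternal,
                 provenance = provenance, snps = snps),
            class = "asqtl_phase")
}

# phase built directly from simulator truth (no ambiguity)
truth_phase <- function(panel) {
  structure(list(maternal = panel$maternal, paternal = panel$paternal,
                 provenance = matrix(
                   ifelse(panel$maternal == panel$paternal,
                          "homozygous", "sire-homozygous"),
                   nrow(panel$maternal), ncol(panel$maternal),
                   dimnames = dimnames(panel$maternal)),
                 snps = panel$snps),
            class = "asqtl_phase")
}

#' Aggregate per-SNP allele counts into per-feature phenotypes
#'
#' For every animal x feature, maternal and paternal read counts are summed
#' over the animal's heterozygous, phased sites inside the feature. Animals
#' homozygous at every site in a feature are excluded (uninformative), as
#' are heterozygous sites that are monoallelic in the read data (one
#' parental count zero while the other is positive — potential imputation
#' errors) and sites whose phase provenance is `unphased` or
#' `mendelian-inconsistent`. Features containing no SNPs are skipped with a
#' log entry.
#'
#' @param phase An `asqtl_phase`.
#' @param allele_counts Tibble with `animal_id`, `snp_id`, `maternal_count`,
#'   `paternal_count` (heterozygous sites only).
#' @param features An `asqtl_features` (uses `features` and `snp_map`).
#' @return List of class `asqtl_feature_counts`: `counts` tibble
#'   (feature_id, animal_id, maternal_count, paternal_count,
#'   n_informative_sites) and `exclusions` tibble (feature_id, animal_id,
#'   snp_id, reason).
#' @export
collect_feature_counts <- function(phase, allele_counts, features) {
  feats <- features$features
  sm <- features$snp_map

  no_snp <- feats$feature_id[!feats$feature_id %in% sm$feature_id]
  exclusions <- tibble(feature_id = no_snp, animal_id = NA_character_,
                       snp_id = NA_character_, reason = "no-snps-in-feature")

  het <- phase$maternal != phase$paternal
  prov_ok <- phase$provenance %in% c("sire-homozygous", "carried-phase")
  dim(prov_ok) <- dim(het); dimnames(prov_ok) <- dimnames(het)

  joined <- sm |>
    inner_join(allele_counts, by = "snp_id", relationship = "many-to-many")
  if (nrow(joined) == 0) {
    return(structure(list(
      counts = tibble(feature_id = character(), animal_id = character(),
                      maternal_count = integer(), paternal_count = integer(),
                      n_informative_sites = integer()),
      exclusions = exclusions), class = "asqtl_feature_counts"))
  }
  ai <- match(joined$animal_id, rownames(het))
  si <- match(joined$snp_id, colnames(het))
  joined$is_het <- het[cbind(ai, si)]
  joined$phase_ok <- prov_ok[cbind(ai, si)]
  joined$monoallelic <- (joined$maternal_count == 0) != (joined$paternal_count == 0)

  excl <- joined |>
    filter(!.data$is_het | !.data$phase_ok | .data$monoallelic) |>
    mutate(reason = dplyr::case_when(
      !.data$is_het ~ "homozygous",
      !.data$phase_ok ~ "unphased",
      TRUE ~ "monoallelic")) |>
    select("feature_id", "animal_id", "snp_id", "reason")
  exclusions <- bind_rows(exclusions, excl)

  counts <- joined |>
    filter(.data$is_het, .data$phase_ok, !.data$monoallelic) |>
    group_by(.data$feature_id, .data$animal_id) |>
    summarise(maternal_count = sum(.data$maternal_count),
              paternal_count = sum(.data$paternal_count),
              n_informative_sites = n(), .groups = "drop")

  structure(list(counts = counts, exclusions = exclusions),
            class = "asqtl_feature_counts")
}
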