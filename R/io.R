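# Plain-text interchange: VCF (phased GT), BED6, TSV tables, FASTA.

#' Write a phased genotype panel as VCF (offspring) plus a sire VCF
#'
#' Offspring genotypes are written phased maternal|paternal in the GT field
#' of a minimal VCFv4.2 file; sire genotypes go to a paired file with
#' unphased GT. Internal 0-based positions convert to VCF 1-based.
#'
#' @param panel An `asqtl_panel`.
#' @param path Offspring VCF path; the sire file gets a `.sires.vcf`
#'   suffix next to it.
#' @return Invisibly, c(offspring = path, sires = sire_path).
#' @export
write_panel_vcf <- function(panel, path) {
  snps <- panel$snps
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$animals), collapse = "\t"))
  gt <- matrix(paste0(t(panel$maternal), "|", t(panel$paternal)),
               nrow(snps), length(panel$animals))
  body <- paste(snps$chrom, snps$pos + 1, snps$snp_id, snps$ref, snps$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)

  sire_path <- sub("\\.vcf$", ".sires.vcf", path)
  if (identical(sire_path, path)) sire_path <- paste0(path, ".sires.vcf")
  sgt <- t(apply(panel$sire_dosage, 1, function(d) {
    c("0/0", "0/1", "1/1")[d + 1]
  }))
  header_s <- sub(paste(panel$animals, collapse = "\t"),
                  paste(paste0("sire_of_", panel$animals), collapse = "\t"),
                  header, fixed = TRUE)
  body_s <- paste(snps$chrom, snps$pos + 1, snps$snp_id, snps$ref, snps$alt,
                  ".", "PASS", ".", "GT",
                  apply(t(sgt), 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header_s, body_s), sire_path)
  invisible(c(offspring = path, sires = sire_path))
}

#' Read a phased VCF written by [write_panel_vcf()]
#'
#' @param path VCF path.
#' @return List: `snps` tibble (snp_id, chrom, pos 0-based, ref, alt) and
#'   haplotype matrices `hap1`, `hap2` (animals x SNPs; NA when unphased).
#' @export
read_panel_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  animals <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  snps <- tibble(
    snp_id = vapply(rows, `[[`, "", 3),
    chrom = vapply(rows, `[[`, "", 1),
    pos = as.integer(vapply(rows, `[[`, "", 2)) - 1L,
    ref = vapply(rows, `[[`, "", 4),
    alt = vapply(rows, `[[`, "", 5))
  gts <- t(vapply(rows, function(r) r[-(1:9)], character(length(animals))))
  a1 <- suppressWarnings(matrix(as.integer(substr(t(gts), 1, 1)),
                                length(animals), nrow(snps)))
  a2 <- suppressWarnings(matrix(as.integer(substr(t(gts), 3, 3)),
                                length(animals), nrow(snps)))
  dimnames(a1) <- dimnames(a2) <- list(animals, snps$snp_id)
  list(snps = snps, hap1 = a1, hap2 = a2)
}

#' Write features as BED6
#' @param features An `asqtl_features` (or its `features` tibble).
#' @param path Output path.
#' @export
write_features_bed <- function(features, path) {
  f <- if (inherits(features, "asqtl_features")) features$features else features
  readr::write_tsv(tibble(chrom = f$chrom, start = f$start, end = f$end,
                          name = f$feature_id, score = 0, strand = "+"),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 feature file
#' @param path BED path.
#' @return Tibble: feature_id, chrom, start, end, midpoint, tss.
#' @export
read_features_bed <- function(path) {
  b <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                           "score", "strand"),
                       col_types = "ciicdc", progress = FALSE)
  tibble(feature_id = b$name, chrom = b$chrom, start = b$start, end = b$end,
         midpoint = as.integer(floor((b$start + b$end) / 2)), tss = b$start)
}

#' Write a genome as FASTA
#' @param genome Named character vector of sequences, or an `asqtl_genome`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  g <- if (inherits(genome, "asqtl_genome")) genome$genome else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write all synthetic-dataset files
#'
#' Emits the full plain-text bundle for a simulated dataset: offspring and
#' sire VCFs, BED6 features, the per-SNP allele-count TSV (animal_id,
#' snp_id, maternal_count, paternal_count), peak/input/exon count matrices
#' (feature x animal TSV), batches, the truth table and the genome FASTA
#' with its planted-motif manifest.
#'
#' @param sim An `asqtl_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_panel_vcf(sim$panel, p("genotypes.vcf"))
  write_features_bed(sim$features, p("features.bed"))
  readr::write_tsv(sim$counts$allele_counts, p("allele_counts.tsv"))
  write_matrix <- function(m, file) {
    readr::write_tsv(as_tibble(m, rownames = "feature_id"), p(file))
  }
  write_matrix(sim$counts$peak_counts, "peak_counts.tsv")
  write_matrix(sim$counts$input_counts, "input_counts.tsv")
  write_matrix(sim$counts$exon_counts, "exon_counts.tsv")
  readr::write_tsv(sim$counts$batches, p("batches.tsv"))
  readr::write_tsv(sim$features$truth, p("truth.tsv"))
  write_genome_fasta(sim$genome, p("genome.fa"))
  readr::write_tsv(sim$genome$manifest, p("motif_manifest.tsv"))
  invisible(dir)
}

#' Read a feature-by-animal count matrix TSV
#' @param path TSV with a `feature_id` column then one column per animal.
#' @return Numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  m
}
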