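# Genomic relationship matrices and EMMA-style mixed-model association.

#' Build a genomic relationship matrix (and leave-one-chromosome-out set)
#'
#' First VanRaden method: with dosage matrix M (animals x SNPs) and observed
#' alternate-allele frequencies p, columns are standardised
#' `W = (M - 2p) / sqrt(2 p (1 - p))` and `G = W W' / m`. Monomorphic SNPs
#' are skipped. `loco = TRUE` additionally returns, per chromosome, the GRM
#' built from all other chromosomes.
#'
#' @param dosage Animal x SNP matrix of alternate-allele counts (0/1/2).
#' @param snps Tibble with `snp_id`, `chrom` matching the columns.
#' @param loco Build leave-one-chromosome-out variants too?
#' @return List of class `asqtl_grm`: `grm`, `loco` (named list by excluded
#'   chromosome), `n_snps_used`.
#' @export
build_grm <- function(dosage, snps, loco = TRUE) {
  stopifnot(ncol(dosage) == nrow(snps))
  assert_that(nrow(dosage) >= 2, "need at least 2 animals")
  p <- colMeans(dosage) / 2
  poly <- p > 0 & p < 1
  assert_that(sum(poly) >= 10, "need at least 10 polymorphic SNPs")
  W <- sweep(dosage[, poly, drop = FALSE], 2, 2 * p[poly])
  W <- sweep(W, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  chrom <- snps$chrom[poly]
  cross <- tcrossprod(W)
  grm <- cross / ncol(W)
  loco_list <- NULL
  if (loco) {
    loco_list <- lapply(unique(chrom), function(ch) {
      keep <- chrom != ch
      Wc <- W[, keep, drop = FALSE]
      tcrossprod(Wc) / ncol(Wc)
    })
    names(loco_list) <- unique(chrom)
  }
  structure(list(grm = grm, loco = loco_list, n_snps_used = ncol(W)),
            class = "asqtl_grm")
}

# REML profile for y = X b + u + e, cov(u) = sg2 K, via the spectral
# decomposition of K. Returns variance component ratio and rotated pieces.
emma_reml <- function(y, X, eig) {
  n <- length(y)
  ystar <- crossprod(eig$vectors, y)
  Xstar <- crossprod(eig$vectors, X)
  d <- pmax(eig$values, 0)
  q <- ncol(X)
  neg_ll <- function(log_lambda) {
    lambda <- exp(log_lambda)
    w <- 1 / (lambda * d + 1)
    XtWX <- crossprod(Xstar, Xstar * w)
    bh <- solve(XtWX, crossprod(Xstar, ystar * w))
    r <- ystar - Xstar %*% bh
    rss <- sum(w * r^2)
    s2 <- rss / (n - q)
    0.5 * ((n - q) * log(s2) + sum(log(lambda * d + 1)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(neg_ll, c(log(1e-6), log(1e6)))
  lambda <- exp(opt$minimum)
  # boundary: effectively no genetic variance
  if (opt$minimum <= log(1e-6) + 1e-8) lambda <- 0
  w <- 1 / (lambda * d + 1)
  XtWX <- crossprod(Xstar, Xstar * w)
  bh <- solve(XtWX, crossprod(Xstar, ystar * w))
  rss <- sum(w * (ystar - Xstar %*% bh)^2)
  s2e <- rss / (n - q)
  list(lambda = lambda, sigma2_e = s2e, sigma2_g = lambda * s2e,
       ystar = as.numeric(ystar), Xstar = Xstar, w = w, eig = eig)
}

#' Mixed-linear-model cis association for one phenotype
#'
#' Fits `y = covariates c + dosage beta + u + e` with `cov(u) =
#' sigma_g^2 K`, K the leave-one-chromosome-out GRM for the phenotype's
#' chromosome. Variance components are estimated once per phenotype by REML
#' through a single spectral decomposition of K (EMMA-style), then each
#' candidate SNP gets a generalised-least-squares effect estimate, standard
#' error and two-sided t-test p. Non-positive-definite K gets a 1e-6 ridge.
#'
#' @param y Named numeric phenotype vector (animals).
#' @param dosage Animal x SNP dosage matrix (0/1/2), animals as in `y`.
#' @param snp_ids Columns of `dosage` to test.
#' @param grm_loco The K matrix to use (already leave-one-chromosome-out).
#' @param covariates Animal x q numeric matrix (without intercept), or NULL.
#' @return Tibble of class `asqtl_mlm`: snp_id, beta, se, p, n_used, plus
#'   attributes `sigma2_g`, `sigma2_e`.
#' @export
mlm_association <- function(y, dosage, snp_ids, grm_loco, covariates = NULL) {
  animals <- names(y)
  stopifnot(!is.null(animals), all(animals %in% rownames(dosage)))
  K <- grm_loco[animals, animals]
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    K <- K + diag(1e-6, nrow(K))
    eig <- eigen(K, symmetric = TRUE)
  }
  X <- cbind(intercept = rep(1, length(y)))
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(covariates)[animals, , drop = FALSE])
  }
  fit <- emma_reml(y, X, eig)
  mlm_scan_snps(fit, dosage[animals, , drop = FALSE], snp_ids)
}

# GLS per SNP under fixed variance components, vectorised across SNPs via
# partitioned regression: each dosage column is residualised against the
# covariates in the rotated/weighted metric, then the effect is a ratio of
# weighted inner products
mlm_scan_snps <- function(fit, dosage, snp_ids) {
  w <- fit$w
  n <- length(fit$ystar)
  q <- ncol(fit$Xstar)
  G <- dosage[, snp_ids, drop = FALSE]
  mono <- apply(G, 2, function(g) length(unique(g)) < 2)
  Gstar <- crossprod(fit$eig$vectors, G)
  XtWX <- crossprod(fit$Xstar, fit$Xstar * w)
  XtWy <- crossprod(fit$Xstar, fit$ystar * w)
  XtWG <- crossprod(fit$Xstar, Gstar * w)
  bh0 <- solve(XtWX, XtWy)
  yres <- fit$ystar - as.numeric(fit$Xstar %*% bh0)
  Gres <- Gstar - fit$Xstar %*% solve(XtWX, XtWG)
  gg <- colSums(Gres^2 * w)
  gy <- as.numeric(crossprod(Gres, yres * w))
  rss0 <- sum(w * yres^2)
  beta <- gy / gg
  rss <- pmax(rss0 - beta^2 * gg, 0)
  s2 <- rss / (n - q - 1)
  se <- sqrt(s2 / gg)
  p <- 2 * pt(-abs(beta / se), n - q - 1)
  beta[mono] <- se[mono] <- p[mono] <- NA_real_
  res <- tibble(snp_id = snp_ids, beta = beta, se = se, p = p, n_used = n)
  attr(res, "sigma2_g") <- fit$sigma2_g
  attr(res, "sigma2_e") <- fit$sigma2_e
  class(res) <- c("asqtl_mlm", class(res))
  res
}

#' Traditional cis-QTL scan over a feature class
#'
#' Builds per-feature phenotypes (peak residuals or stabilised expression,
#' already prepared), then for every feature tests all SNPs within `window`
#' of its midpoint with [mlm_association()] using the leave-one-chromosome-
#' out GRM of the feature's chromosome. One spectral decomposition per
#' chromosome is shared by its features.
#'
#' @param phenotype Feature x animal phenotype matrix.
#' @param features An `asqtl_features` (positions/midpoints).
#' @param panel An `asqtl_panel` (dosages, SNP positions).
#' @param grm An `asqtl_grm` with LOCO components.
#' @param covariates Animal x q matrix or NULL (e.g. batch indicators).
#' @param window Cis window in bp (default 1 Mb).
#' @param significance Threshold recorded in the `significant` column.
#' @return Tibble of class `asqtl_mlm_scan`: feature_id, snp_id, chrom, pos,
#'   distance_bp, beta, se, p, n_used, significant.
#' @export
trad_scan <- function(phenotype, features, panel, grm, covariates = NULL,
                      window = 1e6, significance = 1e-4) {
  feats <- features$features |>
    filter(.data$feature_id %in% rownames(phenotype))
  dosage <- panel_dosage(panel)
  snps <- panel$snps
  animals <- colnames(phenotype)

  out <- vector("list", nrow(feats))
  eig_cache <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    cand <- snps$snp_id[snps$chrom == f$chrom &
                          abs(snps$pos - f$midpoint) <= window]
    if (length(cand) == 0) next
    ch <- f$chrom
    if (is.null(eig_cache[[ch]])) {
      K <- grm$loco[[ch]][animals, animals]
      eig <- eigen(K, symmetric = TRUE)
      if (min(eig$values) < -1e-8) {
        eig <- eigen(K + diag(1e-6, nrow(K)), symmetric = TRUE)
      }
      eig_cache[[ch]] <- eig
    }
    y <- phenotype[f$feature_id, animals]
    X <- cbind(intercept = rep(1, length(y)))
    if (!is.null(covariates)) {
      X <- cbind(X, as.matrix(covariates)[animals, , drop = FALSE])
    }
    fit <- emma_reml(y, X, eig_cache[[ch]])
    res <- mlm_scan_snps(fit, dosage[animals, , drop = FALSE], cand)
    res$feature_id <- f$feature_id
    res$chrom <- f$chrom
    res$pos <- snps$pos[match(res$snp_id, snps$snp_id)]
    res$distance_bp <- as.integer(res$pos - f$midpoint)
    out[[i]] <- res
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(feature_id = character(), snp_id = character(),
                  chrom = character(), pos = integer(),
                  distance_bp = integer(), beta = numeric(), se = numeric(),
                  p = numeric(), n_used = integer())
  }
  res <- res |>
    mutate(significant = !is.na(.data$p) & .data$p < significance) |>
    select("feature_id", "snp_id", "chrom", "pos", "distance_bp",
           "beta", "se", "p", "n_used", "significant")
  class(res) <- c("asqtl_mlm_scan", class(res))
  attr(res, "significance") <- significance
  res
}
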