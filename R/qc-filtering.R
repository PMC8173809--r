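#' @name qc_filtering
#' @title SNP quality-control filters
#' @description
#' The QC pipeline mirrors standard SNP-chip practice: minor allele
#' frequency filtering, per-SNP call-rate filtering, then LD pruning,
#' applied in that order. Each filter returns the filtered dataset together
#' with a `filter_report` recording what was removed.
NULL

filter_report <- function(n_input, n_removed_maf = 0L, n_removed_geno = 0L,
                          n_removed_ld = 0L, kept_snp_ids) {
  r <- list(n_input = n_input,
            n_removed_maf = n_removed_maf,
            n_removed_geno = n_removed_geno,
            n_removed_ld = n_removed_ld,
            n_kept = length(kept_snp_ids),
            kept_snp_ids = kept_snp_ids)
  stopifnot(r$n_input == r$n_kept + n_removed_maf + n_removed_geno + n_removed_ld)
  class(r) <- "filter_report"
  r
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d in -> %d kept (MAF -%d, call rate -%d, LD -%d)\n",
    x$n_input, x$n_kept, x$n_removed_maf, x$n_removed_geno, x$n_removed_ld))
  invisible(x)
}

#' Minor-allele-frequency filter
#'
#' Removes SNPs whose pooled minor allele frequency, computed on non-missing
#' genotypes, is below `min_maf`. The boundary is kept (`MAF >= min_maf`
#' passes), matching PLINK's `--maf` semantics.
#'
#' @param ds a `genotype_dataset`.
#' @param min_maf frequency threshold (default 0.05).
#' @return `list(dataset =, report =)`.
#' @export
filter_maf <- function(ds, min_maf = 0.05) {
  p <- allele_freq(ds)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0                        # all-missing SNP: treated as monomorphic
  keep <- maf >= min_maf - 1e-12
  if (!any(keep)) stop("MAF filter removed every SNP (min_maf = ", min_maf, ")")
  out <- subset(ds, snps = ds$snp_ids[keep])
  list(dataset = out,
       report = filter_report(length(keep), n_removed_maf = sum(!keep),
                              kept_snp_ids = out$snp_ids))
}

#' Call-rate filter
#'
#' Removes SNPs whose missing-genotype fraction exceeds `max_missing`
#' (strictly greater, PLINK `--geno` semantics).
#'
#' @param ds a `genotype_dataset`.
#' @param max_missing maximum tolerated missing fraction (default 0.01).
#' @return `list(dataset =, report =)`.
#' @export
filter_call_rate <- function(ds, max_missing = 0.01) {
  miss <- colMeans(is.na(ds$genotypes))
  keep <- miss <= max_missing + 1e-12
  if (!any(keep)) stop("call-rate filter removed every SNP")
  out <- subset(ds, snps = ds$snp_ids[keep])
  list(dataset = out,
       report = filter_report(length(keep), n_removed_geno = sum(!keep),
                              kept_snp_ids = out$snp_ids))
}

# squared Pearson correlation of two genotype columns over shared
# non-missing samples; 0 when undefined
geno_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(0)
  sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x[ok], y[ok])^2
}

#' Pairwise-r2 LD pruning
#'
#' Greedy windowed pruning in PLINK `--indep-pairwise` style: within each
#' window of `window` SNPs, while some retained pair has genotype
#' correlation r2 above `r2_max`, one member of the offending pair is
#' removed (the one with the lower MAF; map-order-later on ties). The
#' window then slides forward by `step` SNPs. Windows never span
#' chromosomes. After the scan, no retained within-window pair exceeds the
#' threshold.
#'
#' @param ds a `genotype_dataset` with SNPs sorted by (chrom, pos).
#' @param window window size in SNPs (default 50).
#' @param step slide in SNPs (default 10).
#' @param r2_max retention threshold (default 0.1).
#' @return `list(dataset =, report =)`.
#' @export
ld_prune_pairwise <- function(ds, window = 50, step = 10, r2_max = 0.1) {
  if (window < 2) stop("window must span at least 2 SNPs")
  m <- length(ds$snp_ids)
  p <- allele_freq(ds)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)

  for (ch in unique(ds$chrom)) {
    idx <- which(ds$chrom == ch)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win <- win[keep[win]]
      if (length(win) >= 2L) {
        repeat {
          R2 <- suppressWarnings(
            stats::cor(ds$genotypes[, win, drop = FALSE],
                       use = "pairwise.complete.obs")^2)
          R2[is.na(R2)] <- 0
          diag(R2) <- 0
          mx <- max(R2)
          if (mx <= r2_max) break
          hit <- which(R2 == mx, arr.ind = TRUE)[1, ]
          a <- win[hit[1]]; b <- win[hit[2]]
          drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
          keep[drop] <- FALSE
          win <- win[win != drop]
          if (length(win) < 2L) break
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  out <- subset(ds, snps = ds$snp_ids[keep])
  list(dataset = out,
       report = filter_report(m, n_removed_ld = sum(!keep),
                              kept_snp_ids = out$snp_ids))
}

#' VIF-based LD pruning
#'
#' PLINK `--indep` style pruning: within each window, each SNP is regressed
#' on the other retained SNPs of the window and its variance inflation
#' factor VIF = 1 / (1 - R2) computed; while the largest VIF exceeds
#' `vif_max`, that SNP is removed (worst first). Windows slide by `step`
#' SNPs and never span chromosomes.
#'
#' @param ds a `genotype_dataset` with SNPs sorted by (chrom, pos).
#' @param window window size in SNPs (default 50).
#' @param step slide in SNPs (default 5).
#' @param vif_max VIF threshold (default 1.2).
#' @return `list(dataset =, report =)`.
#' @export
ld_prune_vif <- function(ds, window = 50, step = 5, vif_max = 1.2) {
  if (window < 2) stop("window must span at least 2 SNPs")
  m <- length(ds$snp_ids)
  keep <- rep(TRUE, m)

  for (ch in unique(ds$chrom)) {
    idx <- which(ds$chrom == ch)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window - 1L, length(idx))]
      win <- win[keep[win]]
      while (length(win) >= 2L) {
        v <- window_vif(ds$genotypes[, win, drop = FALSE])
        worst <- which.max(v)
        if (v[worst] <= vif_max + 1e-12) break
        keep[win[worst]] <- FALSE
        win <- win[-worst]
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  out <- subset(ds, snps = ds$snp_ids[keep])
  list(dataset = out,
       report = filter_report(m, n_removed_ld = sum(!keep),
                              kept_snp_ids = out$snp_ids))
}

# VIFs of the columns of a genotype sub-matrix (mean-imputed missing)
window_vif <- function(G) {
  G <- apply(G, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  k <- ncol(G)
  v <- numeric(k)
  for (j in seq_len(k)) {
    y <- G[, j]
    if (stats::sd(y) == 0) { v[j] <- 1; next }
    X <- G[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    r2 <- min(r2, 1 - 1e-12)
    v[j] <- 1 / (1 - r2)
  }
  v
}
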