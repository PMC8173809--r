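#' Observed and expected heterozygosity of a breed
#'
#' Per SNP, observed heterozygosity is the fraction of heterozygous
#' genotypes among non-missing ones, and expected heterozygosity is
#' `2 p (1 - p)` with `p` the within-breed A1 frequency. Means and standard
#' deviations are taken across SNPs. The optional `unbiased` flag applies
#' the `2n/(2n - 1)` small-sample correction to He.
#'
#' @param ds a `genotype_dataset`.
#' @param breed breed code (or `NULL` with `group` set).
#' @param group optional group label instead of a breed.
#' @param unbiased apply the `2n/(2n-1)` correction to He (default FALSE,
#'   matching the usual chip-report convention).
#' @return Named list: `Ho_mean`, `Ho_sd`, `He_mean`, `He_sd`.
#' @export
heterozygosity <- function(ds, breed = NULL, group = NULL, unbiased = FALSE) {
  g <- genotypes_of(ds, breed = breed, group = group)
  ho <- colMeans(g == 1L, na.rm = TRUE)
  p <- colMeans(g, na.rm = TRUE) / 2
  he <- 2 * p * (1 - p)
  if (unbiased) {
    n2 <- 2 * colSums(!is.na(g))
    he <- he * n2 / pmax(n2 - 1, 1)
  }
  list(Ho_mean = mean(ho, na.rm = TRUE), Ho_sd = stats::sd(ho[!is.nan(ho)]),
       He_mean = mean(he, na.rm = TRUE), He_sd = stats::sd(he[!is.nan(he)]))
}

#' Mean minor allele frequency of a breed
#'
#' @inheritParams heterozygosity
#' @return Named list: `MAF_mean`, `MAF_sd` (across SNPs).
#' @export
mean_maf <- function(ds, breed = NULL, group = NULL) {
  g <- genotypes_of(ds, breed = breed, group = group)
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  list(MAF_mean = mean(maf, na.rm = TRUE), MAF_sd = stats::sd(maf[!is.nan(maf)]))
}

#' Per-breed diversity summary
#'
#' Ho, He and MAF means and standard deviations across SNPs plus the
#' most-recent defined effective population size estimate from the LD-based
#' trajectory, tabulated per breed in the style of a chip diversity report.
#'
#' @param ds a `genotype_dataset`.
#' @param ne_bins optional recombination-distance bin edges (Morgans) passed
#'   to [ne_trajectory()]; `NULL` skips the Ne column.
#' @return Data frame, one row per breed.
#' @export
diversity_summary <- function(ds, ne_bins = NULL) {
  breeds <- sort(unique(ds$pop_map$breed))
  rows <- lapply(breeds, function(b) {
    h <- heterozygosity(ds, breed = b)
    m <- mean_maf(ds, breed = b)
    ne <- NA_real_
    if (!is.null(ne_bins)) {
      tr <- ne_trajectory(ds, breed = b, bins = ne_bins)
      ok <- which(!is.na(tr$Ne_hat))
      if (length(ok)) ne <- tr$Ne_hat[ok[1]]     # most recent defined bin
    }
    data.frame(breed = b, n = n_samples_of(ds, breed = b),
               Ho_mean = h$Ho_mean, Ho_sd = h$Ho_sd,
               He_mean = h$He_mean, He_sd = h$He_sd,
               MAF_mean = m$MAF_mean, MAF_sd = m$MAF_sd, Ne = ne)
  })
  do.call(rbind, rows)
}

#' LD-based effective population size trajectory
#'
#' Sved's relation between linkage disequilibrium and effective size. For
#' every intra-chromosomal SNP pair within the bin range, the recombination
#' fraction is approximated from physical distance (`c = bp * cm_per_mb *
#' 1e-8` Morgans), the genotype-correlation r2 is corrected for finite
#' sample size by subtracting `1/(2n)` (phase-unknown data), and pairs are
#' binned by `c`. Each bin yields `Ne = (1/(4c)) * (1/mean(r2_adj) - alpha)`
#' at `generations_ago = 1/(2c_mid)`. With `mutation_adjust = TRUE` the
#' constant `alpha` becomes 2.2.
#'
#' @param ds a `genotype_dataset` with physical positions.
#' @param breed breed code (or `group`).
#' @param group optional group label.
#' @param bins increasing vector of bin edges for `c`, in Morgans.
#' @param cm_per_mb recombination map density (default 1 cM/Mb).
#' @param alpha Sved constant (default 1; ignored if `mutation_adjust`).
#' @param mutation_adjust use alpha = 2.2 (default FALSE).
#' @return Data frame of class `ne_trajectory`: one row per bin with
#'   `generations_ago`, `Ne_hat` (NA where undefined), `n_snp_pairs`,
#'   `mean_r2_adj`, ordered by increasing `generations_ago`.
#' @export
ne_trajectory <- function(ds, breed = NULL, group = NULL,
                          bins = seq(0.005, 0.05, by = 0.005),
                          cm_per_mb = 1.0, alpha = 1.0,
                          mutation_adjust = FALSE) {
  if (length(bins) < 2L || any(diff(bins) <= 0))
    stop("bins must be an increasing vector of at least two edges")
  if (mutation_adjust) alpha <- 2.2
  g <- genotypes_of(ds, breed = breed, group = group)
  n <- nrow(g)

  cs <- numeric(0); r2 <- numeric(0)
  for (ch in unique(ds$chrom)) {
    idx <- which(ds$chrom == ch)
    if (length(idx) < 2L) next
    pos <- ds$pos_bp[idx]
    R <- suppressWarnings(
      stats::cor(g[, idx, drop = FALSE], use = "pairwise.complete.obs"))
    pr <- which(upper.tri(R), arr.ind = TRUE)
    cc <- abs(pos[pr[, 2]] - pos[pr[, 1]]) * cm_per_mb * 1e-8
    ok <- cc >= bins[1] & cc <= bins[length(bins)] & !is.na(R[pr])
    cs <- c(cs, cc[ok])
    r2 <- c(r2, R[pr][ok]^2)
  }
  r2_adj <- r2 - 1 / (2 * n)

  bin <- cut(cs, bins, include.lowest = TRUE)
  mid <- (bins[-length(bins)] + bins[-1]) / 2
  mean_r2 <- tapply(r2_adj, bin, mean)
  npairs <- tapply(r2_adj, bin, length)
  npairs[is.na(npairs)] <- 0L

  ne <- (1 / (4 * mid)) * (1 / mean_r2 - alpha)
  ne[!is.finite(ne) | ne <= 0] <- NA_real_     # degenerate bins flagged, not fabricated
  out <- data.frame(generations_ago = 1 / (2 * mid),
                    Ne_hat = as.numeric(ne),
                    n_snp_pairs = as.integer(npairs),
                    mean_r2_adj = as.numeric(mean_r2))
  out <- out[order(out$generations_ago), ]
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Identity-by-state distance matrix
#'
#' `D[i, j] = 1 - mean(shared alleles / 2)` over SNPs non-missing in both
#' samples; identical genotypes give 0, opposite homozygotes at every SNP
#' give 1.
#'
#' @param ds a `genotype_dataset`.
#' @return Square symmetric matrix with zero diagonal, labelled by sample
#'   id.
#' @export
ibs_distance <- function(ds) {
  g <- ds$genotypes
  n <- nrow(g)
  D <- matrix(0, n, n, dimnames = list(ds$sample_ids, ds$sample_ids))
  for (i in seq_len(n - 1L)) {
    gi <- g[i, ]
    for (j in (i + 1L):n) {
      d <- abs(gi - g[j, ])
      D[i, j] <- D[j, i] <- mean(d, na.rm = TRUE) / 2
    }
  }
  D[is.nan(D)] <- 0
  D
}

# within-breed A1 frequency + diploid sample count per SNP (internal)
freq_and_n <- function(ds, breed = NULL, group = NULL) {
  g <- genotypes_of(ds, breed = breed, group = group)
  list(p = colMeans(g, na.rm = TRUE) / 2, n = colSums(!is.na(g)))
}

#' Reynolds coancestry distance between two breeds
#'
#' Pure-drift coancestry estimator from the two breeds' per-SNP allele
#' frequencies, accumulated as a ratio of sums over loci:
#' `theta = sum((p1 - p2)^2 - corr) / sum(p1 (1 - p2) + p2 (1 - p1))`,
#' where `corr = p1 q1 / (2 n1 - 1) + p2 q2 / (2 n2 - 1)` removes the
#' sampling variance of the frequency difference (`n` diploid counts).
#' With `correction = FALSE` the raw frequency form is used, which is
#' exactly 0 for identical frequency vectors and 1 for a fixed difference
#' at every SNP.
#'
#' @param ds a `genotype_dataset`.
#' @param breedA,breedB breed codes (or group labels if `by_group`).
#' @param by_group interpret `breedA`/`breedB` as group labels.
#' @param correction apply the finite-sample correction (default TRUE).
#' @param linearized return `-ln(1 - theta)` instead of `theta`.
#' @return The scalar distance.
#' @export
reynolds_distance <- function(ds, breedA, breedB, by_group = FALSE,
                              correction = TRUE, linearized = FALSE) {
  fa <- if (by_group) freq_and_n(ds, group = breedA) else freq_and_n(ds, breed = breedA)
  fb <- if (by_group) freq_and_n(ds, group = breedB) else freq_and_n(ds, breed = breedB)
  p1 <- fa$p; p2 <- fb$p
  ok <- !is.nan(p1) & !is.nan(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  num <- (p1 - p2)^2
  if (correction) {
    n1h <- 2 * fa$n[ok]; n2h <- 2 * fb$n[ok]
    num <- num - p1 * (1 - p1) / pmax(n1h - 1, 1) -
                 p2 * (1 - p2) / pmax(n2h - 1, 1)
  }
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  th <- sum(num) / sum(den)
  if (linearized) -log(1 - th) else th
}

#' Hudson's FST between two breeds
#'
#' Ratio-of-sums Hudson estimator:
#' `sum((p1 - p2)^2 - p1 q1/(n1 - 1) - p2 q2/(n2 - 1)) /
#'  sum(p1 (1 - p2) + p2 (1 - p1))` with `n` haploid allele counts.
#'
#' @inheritParams reynolds_distance
#' @return The scalar FST estimate.
#' @export
hudson_fst <- function(ds, breedA, breedB, by_group = FALSE) {
  fa <- if (by_group) freq_and_n(ds, group = breedA) else freq_and_n(ds, breed = breedA)
  fb <- if (by_group) freq_and_n(ds, group = breedB) else freq_and_n(ds, breed = breedB)
  p1 <- fa$p; p2 <- fb$p
  ok <- !is.nan(p1) & !is.nan(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  n1h <- 2 * fa$n[ok]; n2h <- 2 * fb$n[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1h - 1, 1) -
                       p2 * (1 - p2) / pmax(n2h - 1, 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Nei's standard genetic distance between two breeds
#'
#' `D = -ln(Jxy / sqrt(Jx Jy))` with `Jxy = sum_l sum_u p1u p2u` and
#' `Jx`, `Jy` the corresponding within-population identities, summed over
#' loci.
#'
#' @inheritParams reynolds_distance
#' @return The scalar distance (0 for identical frequency vectors).
#' @export
nei_distance <- function(ds, breedA, breedB, by_group = FALSE) {
  fa <- if (by_group) freq_and_n(ds, group = breedA) else freq_and_n(ds, breed = breedA)
  fb <- if (by_group) freq_and_n(ds, group = breedB) else freq_and_n(ds, breed = breedB)
  p1 <- fa$p; p2 <- fb$p
  ok <- !is.nan(p1) & !is.nan(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  jxy <- sum(p1 * p2 + (1 - p1) * (1 - p2))
  jx <- sum(p1^2 + (1 - p1)^2)
  jy <- sum(p2^2 + (1 - p2)^2)
  -log(jxy / sqrt(jx * jy))
}

#' f3 admixture statistic
#'
#' `f3(T; A, B) = mean over SNPs of (pT - pA)(pT - pB)`, optionally with
#' the small-sample bias correction `- pT qT / (nT - 1)` (haploid count) on
#' the target frequency. Significantly negative values indicate that the
#' target is a mixture of populations related to the two sources.
#'
#' @param ds a `genotype_dataset`.
#' @param target,source1,source2 breed codes (or group labels).
#' @param by_group interpret labels as groups.
#' @param bias_correction subtract the target sampling-variance term
#'   (default TRUE).
#' @return The scalar f3 value (raw covariance form, no heterozygosity
#'   normalization).
#' @export
f3_statistic <- function(ds, target, source1, source2, by_group = FALSE,
                         bias_correction = TRUE) {
  ft <- if (by_group) freq_and_n(ds, group = target) else freq_and_n(ds, breed = target)
  fa <- if (by_group) freq_and_n(ds, group = source1) else freq_and_n(ds, breed = source1)
  fb <- if (by_group) freq_and_n(ds, group = source2) else freq_and_n(ds, breed = source2)
  pt <- ft$p; pa <- fa$p; pb <- fb$p
  ok <- !is.nan(pt) & !is.nan(pa) & !is.nan(pb)
  v <- (pt[ok] - pa[ok]) * (pt[ok] - pb[ok])
  if (bias_correction) {
    nth <- 2 * ft$n[ok]
    v <- v - pt[ok] * (1 - pt[ok]) / pmax(nth - 1, 1)
  }
  mean(v)
}

#' Pairwise distance matrix across breeds or groups
#'
#' Applies [reynolds_distance()], [hudson_fst()] or [nei_distance()] to all
#' pairs of breeds (or groups).
#'
#' @param ds a `genotype_dataset`.
#' @param method one of `"reynolds"`, `"fst"`, `"nei"`.
#' @param by_group compute between groups instead of breeds.
#' @param ... passed to the pairwise statistic.
#' @return Square symmetric labelled matrix with zero diagonal.
#' @export
population_distance <- function(ds, method = c("reynolds", "fst", "nei"),
                                by_group = FALSE, ...) {
  method <- match.arg(method)
  labs <- sort(unique(if (by_group) ds$pop_map$group else ds$pop_map$breed))
  k <- length(labs)
  D <- matrix(0, k, k, dimnames = list(labs, labs))
  f <- switch(method, reynolds = reynolds_distance, fst = hudson_fst,
              nei = nei_distance)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    D[i, j] <- D[j, i] <- f(ds, labs[i], labs[j], by_group = by_group, ...)
  D
}
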