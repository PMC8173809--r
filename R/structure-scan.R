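#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and returns the top-k
#' eigenvectors scaled by the square root of their eigenvalues. Negative
#' eigenvalues (non-Euclidean input) are truncated with a warning.
#'
#' @param dist square symmetric distance matrix (or `dist` object).
#' @param k number of output dimensions (default 2).
#' @return `n x k` coordinate matrix; attribute `"eigenvalues"` carries the
#'   full eigenvalue vector.
#' @export
classical_mds <- function(dist, k = 2) {
  D <- as.matrix(dist)
  fit <- suppressWarnings(
    stats::cmdscale(D, k = min(k, nrow(D) - 1L), eig = TRUE))
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("distance matrix is not Euclidean; negative eigenvalues truncated")
  pts <- fit$points
  if (ncol(pts) < k) {  # pad with zero coordinates for degenerate inputs
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  structure(pts, eigenvalues = fit$eig)
}

#' Genotype principal component analysis
#'
#' Columns are centered at `2p` and scaled by `sqrt(p (1 - p))` with `p`
#' the pooled A1 frequency; missing genotypes are imputed at the column
#' mean (zero after centering). The truncated eigendecomposition is
#' obtained by SVD.
#'
#' @param ds a `genotype_dataset`.
#' @param K number of components to retain.
#' @return List with `scores` (`n x K`, unit-norm columns times singular
#'   value), `loadings` (`m x K`), `eigenvalues` (length `min(n, m)` vector
#'   of covariance eigenvalues, non-increasing), and `scaled` (the scaled
#'   genotype matrix, used by the outlier scan).
#' @export
pca_genotypes <- function(ds, K) {
  n <- nrow(ds$genotypes)
  if (K >= n) stop("K must be smaller than the number of samples")
  Z <- scale_genotypes(ds$genotypes)
  sv <- svd(Z, nu = K, nv = K)
  list(scores = sv$u %*% diag(sv$d[seq_len(K)], K, K),
       loadings = sv$v,
       eigenvalues = sv$d^2 / (n - 1),
       scaled = Z)
}

# center at 2p, scale by sqrt(p(1-p)), mean-impute missing (internal)
scale_genotypes <- function(G) {
  p <- colMeans(G, na.rm = TRUE) / 2
  s <- sqrt(p * (1 - p))
  s[s == 0 | is.na(s)] <- 1
  Z <- sweep(G, 2, 2 * p, "-")
  Z <- sweep(Z, 2, s, "/")
  Z[is.na(Z)] <- 0
  Z
}

#' Selection-outlier scan (PCA + robust Mahalanobis distances)
#'
#' Each scaled SNP column is regressed on the first `K` principal-component
#' score vectors, giving `K` z-scores per SNP. A robust Mahalanobis
#' distance of the z-score vectors across SNPs (orthogonalized
#' Gnanadesikan-Kettenring location/scatter by default) is divided by the
#' genomic inflation factor (median distance over the chi-squared-K median)
#' and referred to the chi-squared upper tail with `K` degrees of freedom.
#' Storey q-values are computed and SNPs with `q < fdr` are flagged for
#' removal.
#'
#' @param ds a `genotype_dataset`.
#' @param K number of principal components (default 5).
#' @param fdr q-value cut-off for removal (default 0.001, i.e. 0.1%).
#' @param robust use the OGK robust covariance (default TRUE; FALSE uses the
#'   plain sample covariance, mainly for testing).
#' @return An `outlier_report`: data frame `snps` (snp_id, the K z-scores,
#'   `stat`, `p`, `q`, `removed`), `gif`, `removed_snp_ids`, and the
#'   filtered `dataset`.
#' @export
pcadapt_scan <- function(ds, K = 5, fdr = 0.001, robust = TRUE) {
  n <- nrow(ds$genotypes)
  if (K >= n) stop("K must be smaller than the number of samples")
  pc <- pca_genotypes(ds, K)
  U <- svd(pc$scaled, nu = K, nv = 0)$u        # orthonormal basis of the K PCs
  Z <- pc$scaled
  m <- ncol(Z)

  B <- crossprod(U, Z)                         # K x m regression coefficients
  rss <- colSums(Z^2) - colSums(B^2)
  sigma <- sqrt(pmax(rss, 0) / (n - K))
  sigma[sigma == 0] <- 1
  zmat <- t(B) / sigma                         # m x K z-scores

  est <- if (robust) ogk_estimate(zmat) else
    list(center = colMeans(zmat), cov = stats::cov(zmat))
  d2 <- stats::mahalanobis(zmat, est$center, est$cov)
  gif <- stats::median(d2) / stats::qchisq(0.5, df = K)
  pval <- stats::pchisq(d2 / gif, df = K, lower.tail = FALSE)
  qval <- storey_qvalues(pval)
  removed <- qval < fdr

  snps <- data.frame(snp_id = ds$snp_ids, zmat, stat = d2, p = pval,
                     q = qval, removed = removed)
  names(snps)[1 + seq_len(K)] <- paste0("z", seq_len(K))
  out <- list(snps = snps, gif = gif, K = K, fdr = fdr,
              removed_snp_ids = ds$snp_ids[removed],
              dataset = if (any(!removed))
                subset(ds, snps = ds$snp_ids[!removed]) else NULL)
  class(out) <- "outlier_report"
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier scan: K = %d, FDR = %g, GIF = %.3f\n", x$K, x$fdr, x$gif))
  cat(sprintf("  %d of %d SNPs removed\n", length(x$removed_snp_ids),
              nrow(x$snps)))
  invisible(x)
}

# Orthogonalized Gnanadesikan-Kettenring robust location and scatter
# (Maronna & Zamar 2002), one orthogonalization step plus a hard-rejection
# reweighting at the chi-squared 0.975 quantile.
ogk_estimate <- function(X) {
  mad0 <- function(v) stats::mad(v)
  k <- ncol(X)
  s <- apply(X, 2, mad0)
  s[s == 0] <- 1e-12
  Y <- sweep(X, 2, s, "/")
  U <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sp <- mad0(Y[, i] + Y[, j]); sm <- mad0(Y[, i] - Y[, j])
    U[i, j] <- U[j, i] <- (sp^2 - sm^2) / 4
  }
  E <- eigen(U, symmetric = TRUE)$vectors
  Zp <- Y %*% E
  sz <- apply(Zp, 2, mad0)
  sz[sz == 0] <- 1e-12
  A <- diag(s, k) %*% E
  center <- as.numeric(A %*% apply(Zp, 2, stats::median))
  cov0 <- A %*% diag(sz^2, k) %*% t(A)

  # reweighting step: refit plainly on the non-extreme points
  d2 <- stats::mahalanobis(X, center, cov0)
  keep <- d2 <= stats::qchisq(0.975, df = k) * stats::median(d2) /
    stats::qchisq(0.5, df = k)
  if (sum(keep) > k + 1) {
    center <- colMeans(X[keep, , drop = FALSE])
    cov0 <- stats::cov(X[keep, , drop = FALSE])
  }
  list(center = center, cov = cov0)
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0 = min(1, mean(p > lambda) /
#' (1 - lambda))` at a fixed `lambda` (default 0.5, robust at small SNP
#' counts) and returns monotone q-values `q_i = min_{p_j >= p_i} pi0 * m *
#' p_j / rank(p_j)`. With `pi0 = 1` this reduces to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param lambda tuning point for the pi0 estimate (default 0.5).
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return Vector of q-values, same length and order as `pvalues`.
#' @export
storey_qvalues <- function(pvalues, lambda = 0.5, pi0 = NULL) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  m <- length(pvalues)
  if (is.null(pi0))
    pi0 <- min(1, mean(pvalues > lambda, na.rm = TRUE) / (1 - lambda))
  if (pi0 <= 0) pi0 <- 1 / m                    # degenerate: all p small
  o <- order(pvalues, decreasing = TRUE)
  q <- pi0 * m * pvalues[o] / seq(m, 1)
  q <- cummin(q)
  q[q > 1] <- 1
  out <- numeric(m)
  out[o] <- q
  out
}
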