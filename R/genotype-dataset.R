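#' SNP genotype dataset
#'
#' Container for diploid biallelic SNP genotypes together with SNP metadata
#' and a population map. Genotypes are stored as counts of the A1 allele
#' (0, 1 or 2); missing genotypes are `NA`, never 0.
#'
#' @param genotypes integer matrix, samples in rows and SNPs in columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param chrom per-SNP chromosome labels.
#' @param pos_bp per-SNP physical positions (base pairs, 1-based).
#' @param alleles character matrix with two columns (A1, A2), one row per
#'   SNP. `"0"` marks an unobserved allele at (partially) monomorphic sites.
#' @param pop_map data frame with columns `sample_id`, `breed` and `group`
#'   assigning every sample to a breed and a geographic group.
#'
#' @return An object of class `genotype_dataset`.
#' @seealso [read_plink_text()], [subset.genotype_dataset()],
#'   [merge_datasets()]
#' @export
genotype_dataset <- function(genotypes, sample_ids, snp_ids, chrom, pos_bp,
                             alleles, pop_map) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  ds <- structure(
    list(
      sample_ids = as.character(sample_ids),
      snp_ids    = as.character(snp_ids),
      chrom      = as.character(chrom),
      pos_bp     = as.integer(pos_bp),
      alleles    = alleles,
      genotypes  = genotypes,
      pop_map    = pop_map
    ),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(ds)
  ds
}

#' @rdname genotype_dataset
#' @param ds a `genotype_dataset`.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(is.matrix(ds$genotypes))
  n <- nrow(ds$genotypes); m <- ncol(ds$genotypes)
  if (length(ds$sample_ids) != n)
    stop("sample_ids length does not match genotype rows")
  if (anyDuplicated(ds$sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(ds$sample_ids[duplicated(ds$sample_ids)]), collapse = ", "))
  if (length(ds$snp_ids) != m) stop("snp_ids length does not match genotype columns")
  if (anyDuplicated(ds$snp_ids))
    stop("duplicate SNP ids: ",
         paste(unique(ds$snp_ids[duplicated(ds$snp_ids)]), collapse = ", "))
  if (length(ds$chrom) != m || length(ds$pos_bp) != m)
    stop("chrom/pos_bp length does not match SNP count")
  bad <- ds$genotypes[!is.na(ds$genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(ds$alleles) && (nrow(ds$alleles) != m || ncol(ds$alleles) != 2L))
    stop("alleles must be an m x 2 matrix")
  # positions strictly increasing within a chromosome (in map order)
  for (ch in unique(ds$chrom)) {
    p <- ds$pos_bp[ds$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  pm <- ds$pop_map
  if (!all(c("sample_id", "breed", "group") %in% names(pm)))
    stop("pop_map needs columns sample_id, breed, group")
  if (!all(ds$sample_ids %in% pm$sample_id))
    stop("every sample needs a breed assignment in pop_map")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  grp <- table(x$pop_map$group[match(x$sample_ids, x$pop_map$sample_id)])
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.genotype_dataset <- function(object, ...) {
  p <- allele_freq(object)
  out <- list(
    n_samples = nrow(object$genotypes),
    n_snps = ncol(object$genotypes),
    missingness = mean(is.na(object$genotypes)),
    mean_maf = mean(pmin(p, 1 - p), na.rm = TRUE),
    breeds = sort(unique(object$pop_map$breed))
  )
  class(out) <- "summary.genotype_dataset"
  out
}

#' @export
print.summary.genotype_dataset <- function(x, ...) {
  cat(sprintf("%d samples, %d SNPs, %.2f%% missing, mean MAF %.3f\n",
              x$n_samples, x$n_snps, 100 * x$missingness, x$mean_maf))
  cat("breeds:", paste(x$breeds, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype dataset
#'
#' Selects samples (by id or by group) and/or SNPs, preserving order and all
#' dataset invariants.
#'
#' @param x a `genotype_dataset`.
#' @param samples character vector of sample ids to keep (default: all).
#' @param snps character vector of SNP ids to keep (default: all).
#' @param groups character vector of group labels to keep (default: all).
#' @param ... unused.
#' @return A `genotype_dataset` restricted to the selection.
#' @export
subset.genotype_dataset <- function(x, samples = NULL, snps = NULL,
                                    groups = NULL, ...) {
  keep_s <- x$sample_ids
  if (!is.null(groups)) {
    known <- unique(x$pop_map$group)
    bad <- setdiff(groups, known)
    if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
    gs <- x$pop_map$sample_id[x$pop_map$group %in% groups]
    keep_s <- keep_s[keep_s %in% gs]
  }
  if (!is.null(samples)) {
    bad <- setdiff(samples, x$sample_ids)
    if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
    keep_s <- keep_s[keep_s %in% samples]
  }
  si <- match(keep_s, x$sample_ids)

  if (is.null(snps)) {
    mi <- seq_along(x$snp_ids)
  } else {
    bad <- setdiff(snps, x$snp_ids)
    if (length(bad)) stop("unknown SNP id(s): ", paste(bad, collapse = ", "))
    mi <- which(x$snp_ids %in% snps)
  }

  genotype_dataset(
    genotypes  = x$genotypes[si, mi, drop = FALSE],
    sample_ids = x$sample_ids[si],
    snp_ids    = x$snp_ids[mi],
    chrom      = x$chrom[mi],
    pos_bp     = x$pos_bp[mi],
    alleles    = x$alleles[mi, , drop = FALSE],
    pop_map    = x$pop_map[x$pop_map$sample_id %in% keep_s, , drop = FALSE]
  )
}

#' Merge two genotype datasets on their shared SNPs
#'
#' Keeps the intersection of SNP ids and concatenates samples. When the two
#' datasets carry the same alleles with A1 and A2 swapped, the second
#' dataset's codes are flipped (0 <-> 2). SNPs whose allele pairs cannot be
#' reconciled by a swap are dropped with a message; strand flips are not
#' resolved.
#'
#' @param a,b `genotype_dataset` objects with disjoint sample ids.
#' @return The merged `genotype_dataset` (SNPs in `a`'s order).
#' @export
merge_datasets <- function(a, b) {
  if (length(intersect(a$sample_ids, b$sample_ids)))
    stop("duplicate sample ids across inputs: ",
         paste(intersect(a$sample_ids, b$sample_ids), collapse = ", "))
  shared <- intersect(a$snp_ids, b$snp_ids)
  if (!length(shared)) {
    warning("no shared SNPs between the two datasets")
  }
  ia <- match(shared, a$snp_ids)
  ib <- match(shared, b$snp_ids)

  ga <- a$genotypes[, ia, drop = FALSE]
  gb <- b$genotypes[, ib, drop = FALSE]
  al_a <- a$alleles[ia, , drop = FALSE]
  al_b <- b$alleles[ib, , drop = FALSE]

  # an unobserved allele ("0") on one side matches anything on that side
  same <- (al_a[, 1] == al_b[, 1] | al_a[, 1] == "0" | al_b[, 1] == "0") &
          (al_a[, 2] == al_b[, 2] | al_a[, 2] == "0" | al_b[, 2] == "0")
  swap <- !same &
          (al_a[, 1] == al_b[, 2] | al_a[, 1] == "0" | al_b[, 2] == "0") &
          (al_a[, 2] == al_b[, 1] | al_a[, 2] == "0" | al_b[, 1] == "0")
  drop <- !(same | swap)
  if (any(swap)) gb[, swap] <- 2L - gb[, swap]
  if (any(drop))
    message(sum(drop), " SNP(s) dropped at merge: allele pairs not ",
            "reconcilable by an A1/A2 swap")

  keep <- which(!drop)
  pm <- rbind(a$pop_map, b$pop_map)
  genotype_dataset(
    genotypes  = rbind(ga[, keep, drop = FALSE], gb[, keep, drop = FALSE]),
    sample_ids = c(a$sample_ids, b$sample_ids),
    snp_ids    = shared[keep],
    chrom      = a$chrom[ia][keep],
    pos_bp     = a$pos_bp[ia][keep],
    alleles    = al_a[keep, , drop = FALSE],
    pop_map    = pm[!duplicated(pm$sample_id), , drop = FALSE]
  )
}

#' A1 allele frequencies
#'
#' Per-SNP frequency of the A1 allele from non-missing genotypes, optionally
#' restricted to one breed or group.
#'
#' @param ds a `genotype_dataset`.
#' @param breed optional breed code; `group` optional group label.
#' @param group optional group label (ignored when `breed` is given).
#' @return Numeric vector of length `n_snps`; `NaN` where all genotypes are
#'   missing.
#' @export
allele_freq <- function(ds, breed = NULL, group = NULL) {
  g <- genotypes_of(ds, breed = breed, group = group)
  colMeans(g, na.rm = TRUE) / 2
}

# rows of the genotype matrix for a breed/group (internal)
genotypes_of <- function(ds, breed = NULL, group = NULL) {
  if (!is.null(breed)) {
    ids <- ds$pop_map$sample_id[ds$pop_map$breed == breed]
    if (!length(ids)) stop("unknown breed: ", breed)
  } else if (!is.null(group)) {
    ids <- ds$pop_map$sample_id[ds$pop_map$group == group]
    if (!length(ids)) stop("unknown group: ", group)
  } else {
    ids <- ds$sample_ids
  }
  ds$genotypes[ds$sample_ids %in% ids, , drop = FALSE]
}

# sample count for a breed/group (internal)
n_samples_of <- function(ds, breed = NULL, group = NULL) {
  nrow(genotypes_of(ds, breed = breed, group = group))
}
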