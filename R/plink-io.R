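#' Read PLINK-dialect text genotypes (PED/MAP)
#'
#' Parses space-delimited PED/MAP files into a [genotype_dataset()]. Allele
#' pairs are recoded to counts of the A1 allele; `0 0` becomes missing. By
#' default A1 is the minor allele (ties broken by character order), matching
#' the usual PLINK convention; pass `a1` to force a reference allele per SNP.
#'
#' @param ped_path path to the PED file (6 leading columns: family id,
#'   sample id, father, mother, sex, phenotype; then two allele columns per
#'   SNP).
#' @param map_path path to the MAP file (chromosome, SNP id, genetic
#'   position, physical position).
#' @param a1 optional character vector (length = number of SNPs) fixing the
#'   counted allele.
#' @param pop_map optional population map data frame (columns `sample_id`,
#'   `breed`, `group`); defaults to one breed/group `"unknown"`.
#' @return A `genotype_dataset`.
#' @export
read_plink_text <- function(ped_path, map_path, a1 = NULL, pop_map = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  names(map) <- c("chrom", "snp_id", "cm", "pos_bp")
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  for (i in seq_len(n)) {
    if (length(toks[[i]]) != want)
      stop(sprintf(
        "PED parse error at line %d: %d fields, expected %d (6 + 2 x %d SNPs)",
        i, length(toks[[i]]), want, m))
  }
  ped <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  sample_ids <- ped[, 2]

  A <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  B <- ped[, 6L + 2L * seq_len(m), drop = FALSE]

  geno <- matrix(NA_integer_, n, m)
  alleles <- matrix("0", m, 2L)
  for (j in seq_len(m)) {
    aj <- A[, j]; bj <- B[, j]
    obs <- c(aj, bj)
    obs <- obs[obs != "0"]
    u <- sort(unique(obs))
    if (length(u) > 2L)
      stop("non-biallelic SNP: ", map$snp_id[j],
           " (alleles ", paste(u, collapse = "/"), ")")
    if (length(u) == 0L) next
    if (is.null(a1)) {
      if (length(u) == 1L) {
        a1j <- "0"; a2j <- u                       # monomorphic: A1 unobserved
      } else {
        cnt <- table(factor(obs, levels = u))
        a1j <- if (cnt[[1]] < cnt[[2]]) u[1] else if (cnt[[2]] < cnt[[1]]) u[2] else u[1]
        a2j <- setdiff(u, a1j)
      }
    } else {
      a1j <- a1[j]
      a2j <- setdiff(u, a1j)
      if (!length(a2j)) a2j <- "0"
      a2j <- a2j[1]
    }
    alleles[j, ] <- c(a1j, a2j)
    ok <- aj != "0" & bj != "0"
    geno[ok, j] <- (aj[ok] == a1j) + (bj[ok] == a1j)
  }

  if (is.null(pop_map))
    pop_map <- data.frame(sample_id = sample_ids, breed = "unknown",
                          group = "unknown", stringsAsFactors = FALSE)

  genotype_dataset(geno, sample_ids, map$snp_id, map$chrom, map$pos_bp,
                   alleles, pop_map)
}

#' Write PLINK-dialect text genotypes (PED/MAP)
#'
#' Inverse of [read_plink_text()]: when the dataset's A1 alleles follow the
#' minor-allele convention (see [canonicalize_alleles()]) the write/read
#' round trip reproduces genotype codes exactly; missing genotypes are
#' written as `0 0`.
#'
#' @param ds a `genotype_dataset`.
#' @param ped_path,map_path output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_plink_text <- function(ds, ped_path, map_path) {
  m <- length(ds$snp_ids)
  map <- data.frame(ds$chrom, ds$snp_ids, 0, ds$pos_bp)
  utils::write.table(map, map_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)

  a1 <- ds$alleles[, 1]; a2 <- ds$alleles[, 2]
  n <- nrow(ds$genotypes)
  out <- character(n)
  for (i in seq_len(n)) {
    g <- ds$genotypes[i, ]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1L, a1, a2))
    second <- ifelse(is.na(g), "0", ifelse(g == 2L, a1, a2))
    out[i] <- paste(c(ds$sample_ids[i], ds$sample_ids[i], "0", "0", "0", "-9",
                      as.vector(rbind(first, second))), collapse = " ")
  }
  writeLines(out, ped_path)
  invisible(c(ped_path, map_path))
}

#' Recode genotypes so that A1 is the minor allele
#'
#' Flips codes (0 <-> 2) and swaps the allele pair at SNPs where the counted
#' allele has frequency above one half (frequency-0.5 ties keep the
#' character-first allele as A1). All summary statistics in this package are
#' invariant to this recoding; it exists so that PLINK text round trips are
#' exact.
#'
#' @param ds a `genotype_dataset`.
#' @return The recoded `genotype_dataset`.
#' @export
canonicalize_alleles <- function(ds) {
  p <- allele_freq(ds)
  flip <- !is.na(p) &
    (p > 0.5 | (p == 0.5 & ds$alleles[, 2] < ds$alleles[, 1] &
                  ds$alleles[, 2] != "0"))
  if (any(flip)) {
    ds$genotypes[, flip] <- 2L - ds$genotypes[, flip]
    ds$alleles[flip, ] <- ds$alleles[flip, 2:1, drop = FALSE]
  }
  ds
}

#' Read a population map
#'
#' Two plain TSV files: `sample_path` maps sample id to breed code;
#' `group_path` maps breed code to one of the fixed group labels.
#'
#' @param sample_path TSV with columns sample_id, breed (no header).
#' @param group_path TSV with columns breed, group (no header).
#' @return Data frame with columns `sample_id`, `breed`, `group`.
#' @export
read_population_map <- function(sample_path, group_path) {
  sm <- utils::read.table(sample_path, header = FALSE, sep = "\t",
                          col.names = c("sample_id", "breed"),
                          colClasses = "character")
  gm <- utils::read.table(group_path, header = FALSE, sep = "\t",
                          col.names = c("breed", "group"),
                          colClasses = "character")
  bad <- setdiff(gm$group, podabc_groups())
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(sm$breed, gm$breed)
  if (length(miss))
    stop("breed(s) without a group: ", paste(miss, collapse = ", "))
  sm$group <- gm$group[match(sm$breed, gm$breed)]
  sm
}

#' Fixed vocabulary of geographic group labels
#' @return Character vector of the recognised group labels.
#' @export
podabc_groups <- function() {
  c("indicine", "african_taurine", "nonpodolian_taurine",
    "italian_podolian", "balkan_podolian", "se_podolian", "other", "unknown")
}
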