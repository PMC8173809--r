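# shared fixture builders; everything is generated in code at test time

# quick genotype_dataset from a plain matrix (one breed unless given)
make_ds <- function(G, breed = NULL, group = NULL, chrom = NULL,
                    pos = NULL, alleles = NULL) {
  G <- as.matrix(G)
  n <- nrow(G); m <- ncol(G)
  if (is.null(breed)) breed <- rep("B1", n)
  if (is.null(group)) group <- rep("other", n)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(alleles)) alleles <- cbind(rep("A", m), rep("G", m))
  ids <- paste0("s", seq_len(n))
  genotype_dataset(G, ids, paste0("snp", seq_len(m)), chrom, pos, alleles,
                   data.frame(sample_id = ids, breed = breed, group = group,
                              stringsAsFactors = FALSE))
}

# hand-written 3-sample x 2-SNP PED/MAP pair; returns the paths and the
# genotype matrix coded by hand from the PED text (counts of the minor
# allele, ties broken by character order)
write_ped_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- c(
    "f1 s1 0 0 1 -9 A A C T",
    "f2 s2 0 0 2 -9 A G 0 0",
    "f3 s3 0 0 1 -9 G G T T"
  )
  map <- c("1 rs1 0 1000", "1 rs2 0 2000")
  ped_path <- file.path(dir, "fix.ped")
  map_path <- file.path(dir, "fix.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  # rs1 alleles A (3 copies) vs G (3 copies): tie -> A1 = "A"
  # rs2 alleles C (1) vs T (3): A1 = "C"
  hand <- matrix(c(2L, 1L, 0L,
                   1L, NA, 0L), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("rs1", "rs2")))
  list(ped = ped_path, map = map_path, hand = hand)
}

# two-population dataset with a fixed between-group frequency contrast,
# drawn under Hardy-Weinberg within each group
two_pop_ds <- function(n_per = 30, m = 200, delta = 0.3) {
  p1 <- runif(m, 0.2, 0.8)
  p2 <- pmin(pmax(p1 + sample(c(-1, 1), m, TRUE) * delta, 0.02), 0.98)
  g1 <- vapply(p1, function(p) rbinom(n_per, 2, p), integer(n_per))
  g2 <- vapply(p2, function(p) rbinom(n_per, 2, p), integer(n_per))
  make_ds(rbind(g1, g2),
          breed = rep(c("P1", "P2"), each = n_per),
          group = rep(c("other", "unknown"), each = n_per))
}

# forward Wright-Fisher simulator with recombination: the independent
# oracle for the LD-based Ne trajectory. Returns a genotype_dataset of a
# sample of n_sample diploids after `gens` generations at constant diploid
# size N. Loci sit on one chromosome with adjacent-locus recombination
# fraction rec_adj, mapped to base pairs at 1 cM/Mb.
wf_forward_sim <- function(N, L, gens, rec_adj, n_sample, p0 = NULL) {
  if (is.null(p0)) p0 <- runif(L, 0.2, 0.8)
  H <- matrix(rbinom(2 * N * L, 1, rep(p0, each = 2 * N)), nrow = 2 * N)
  for (g in seq_len(gens)) {
    Hn <- H
    parents <- sample.int(N, 2 * N, replace = TRUE)
    # crossover masks: recombination between adjacent loci with prob rec_adj
    for (k in seq_len(2 * N)) {
      a <- H[2 * parents[k] - 1L, ]
      b <- H[2 * parents[k], ]
      swap <- cumsum(c(rbinom(1, 1, 0.5), rbinom(L - 1, 1, rec_adj))) %% 2L
      Hn[k, ] <- ifelse(swap == 1L, a, b)
    }
    H <- Hn
    # guard against total fixation wrecking correlations silently
  }
  idx <- sample.int(N, n_sample)
  G <- H[2 * idx - 1L, ] + H[2 * idx, ]
  pos <- as.integer(seq_len(L) * rec_adj * 1e8)   # 1 cM/Mb map
  make_ds(G, pos = pos)
}

# brute-force IBS distance by per-SNP allele-sharing counts
brute_ibs <- function(G) {
  n <- nrow(G)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    share <- ok <- 0
    for (s in seq_len(ncol(G))) {
      gi <- G[i, s]; gj <- G[j, s]
      if (is.na(gi) || is.na(gj)) next
      ok <- ok + 1
      share <- share + (2 - abs(gi - gj))
    }
    D[i, j] <- 1 - (share / ok) / 2
  }
  D
}
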