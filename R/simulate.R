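#' Simulation configuration
#'
#' Locus count, chip-like ascertainment floor and per-population diploid
#' sample sizes. The default sample sizes (IND 30, NPT 40, ITP 49, BKP 48,
#' SEP 43) are the pooled two-breeds-per-group counts used for the
#' demographic analysis.
#'
#' @param n_loci number of unlinked biallelic loci (default 1000).
#' @param min_maf pooled minor-allele-frequency floor for locus retention
#'   (default 0.05, matching the QC filter).
#' @param sample_sizes named integer vector of diploid sample sizes for
#'   IND, NPT, ITP, BKP, SEP.
#' @param max_retries redraw cap per locus at the MAF floor (default 1000).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 1000, min_maf = 0.05,
                       sample_sizes = c(IND = 30, NPT = 40, ITP = 49,
                                        BKP = 48, SEP = 43),
                       max_retries = 1000) {
  stopifnot(n_loci >= 1, all(sample_sizes >= 1),
            setequal(names(sample_sizes), c("IND", "NPT", "ITP", "BKP", "SEP")))
  structure(list(n_loci = as.integer(n_loci), min_maf = min_maf,
                 sample_sizes = sample_sizes[c("IND", "NPT", "ITP", "BKP", "SEP")],
                 max_retries = as.integer(max_retries)),
            class = "sim_config")
}

# group label for each simulated population code
group_of_pop <- c(IND = "indicine", NPT = "nonpodolian_taurine",
                  ITP = "italian_podolian", BKP = "balkan_podolian",
                  SEP = "se_podolian")

#' Simulate a chip-like genotype dataset under a demographic scenario
#'
#' Runs an independent backward-in-time coalescent per locus over the
#' scenario's populations (piecewise-constant sizes; split, bottleneck and
#' admixture-pulse events), drops exactly one mutation uniformly on the
#' genealogy's total branch length, and pairs the sampled haploid lineages
#' into diploid genotypes. A locus is retained only if its pooled minor
#' allele frequency reaches the configured floor, emulating SNP-chip
#' ascertainment; rejected genealogies are redrawn up to the retry cap.
#' Genotype codes count the pooled minor allele (ties kept as drawn).
#'
#' Loci are unlinked; for bookkeeping they are placed round-robin on 29
#' autosomes at 5 Mb spacing.
#'
#' @param scenario a `scenario_spec` from [build_builtin_scenarios()].
#' @param params a `param_vector` from [draw_params()].
#' @param simcfg a [sim_config()].
#' @return A [genotype_dataset()] with the five groups in its `pop_map`.
#' @export
simulate_dataset <- function(scenario, params, simcfg = sim_config()) {
  validate_scenario(scenario, params)
  se <- scenario_events(scenario, params)
  nsam_dip <- simcfg$sample_sizes
  nsam_hap <- integer(length(se$populations))
  nsam_hap[match(names(nsam_dip), se$populations)] <- 2L * as.integer(nsam_dip)

  res <- .simulate_genotypes_cpp(se$events, se$sizes0, nsam_hap,
                                 simcfg$n_loci, simcfg$min_maf,
                                 simcfg$max_retries)
  G <- res$genotypes

  # recode to minor-allele counts so the dataset is in canonical A1 form
  p <- colMeans(G) / 2
  flip <- p > 0.5
  G[, flip] <- 2L - G[, flip]

  m <- ncol(G)
  chrom <- as.character(rep_len(1:29, m))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- seq_len(k) * 5000000L
  }
  alleles <- cbind(rep("A", m), rep("G", m))

  breed <- rep(names(nsam_dip), times = nsam_dip)
  sample_ids <- paste0(breed, "_", unlist(lapply(nsam_dip, seq_len)))
  pop_map <- data.frame(sample_id = sample_ids, breed = breed,
                        group = unname(group_of_pop[breed]),
                        stringsAsFactors = FALSE)

  genotype_dataset(G, sample_ids, sprintf("snp%05d", seq_len(m)),
                   chrom, pos, alleles, pop_map)
}

#' Simulate pseudo-observed datasets (PODs)
#'
#' Replicate datasets at fixed parameters, differing only through the
#' random-number stream; used for scenario-recovery and coverage
#' validation in place of real genotypes.
#'
#' @param scenario a `scenario_spec`.
#' @param fixed_params a `param_vector` shared by all replicates.
#' @param n_replicates number of datasets.
#' @param simcfg a [sim_config()].
#' @return List of `genotype_dataset` objects.
#' @export
simulate_pods <- function(scenario, fixed_params, n_replicates,
                          simcfg = sim_config()) {
  lapply(seq_len(n_replicates), function(i)
    simulate_dataset(scenario, fixed_params, simcfg))
}

#' Midpoint-of-prior parameter vector
#'
#' Deterministic parameter draw at the midpoint of every prior interval,
#' with the ordered times spread evenly below the `tdt` midpoint so both
#' scenario sets' ordering constraints hold. Used for pseudo-observed
#' datasets at "typical" parameter values.
#'
#' @param priors a `prior_spec`.
#' @param scenario a `scenario_spec` (for the time ordering).
#' @return A `param_vector`.
#' @export
midprior_params <- function(priors, scenario) {
  mid <- function(nm) mean(priors[[nm]])
  tdt <- mid("tdt")
  lo <- priors[["ta1"]][1]
  qs <- lo + (tdt - lo) * c(0.8, 0.6, 0.4, 0.2)  # descending, below tdt
  tt <- if (scenario$set == 1L)
    c(tD = qs[1], ta = qs[2], t1 = qs[3], ta1 = qs[4])
  else
    c(ta = qs[1], tD = qs[2], t1 = qs[3], ta1 = qs[4])
  p <- c(N1 = mid("N1"), N2 = mid("N2"), N3 = mid("N3"), N4 = mid("N4"),
         N4b = mid("N4b"), N5 = mid("N5"), N5b = mid("N5b"),
         t3 = mid("t3"), tdt = tdt, tdi = mid("tdi"),
         tt[c("tD", "ta", "t1", "ta1")],
         r = mid("r"), ra = mid("ra"),
         bn_size_t = mid("bn_size_t"), bn_dur_t = mid("bn_dur_t"),
         bn_size_i = mid("bn_size_i"), bn_dur_i = mid("bn_dur_i"),
         bn_size_f = mid("bn_size_f"), bn_dur_f = mid("bn_dur_f"))
  class(p) <- "param_vector"
  p
}

#' Pairwise coalescence times under a scenario
#'
#' Draws one lineage from each of two populations (or two lineages from
#' one) and returns the simulated times to their most recent common
#' ancestor; an oracle hook for checking the engine against coalescent
#' theory (a single population of constant diploid size N has expected
#' pairwise coalescence time 2N generations).
#'
#' @param scenario a `scenario_spec`.
#' @param params a `param_vector`.
#' @param pop_a,pop_b population labels among IND, NPT, ITP, BKP, SEP.
#' @param n_reps number of independent genealogies.
#' @return Numeric vector of TMRCAs in generations.
#' @export
pair_tmrca <- function(scenario, params, pop_a, pop_b, n_reps = 1000) {
  se <- scenario_events(scenario, params)
  ia <- match(pop_a, se$populations) - 1L
  ib <- match(pop_b, se$populations) - 1L
  if (is.na(ia) || is.na(ib)) stop("unknown population label")
  .pair_tmrca_cpp(se$events, se$sizes0, ia, ib, as.integer(n_reps))
}

#' @rdname pair_tmrca
#' @param N constant diploid population size.
#' @export
single_pop_tmrca <- function(N, n_reps = 1000) {
  ev <- matrix(numeric(0), nrow = 0, ncol = 6)
  .pair_tmrca_cpp(ev, as.numeric(N), 0L, 0L, as.integer(n_reps))
}

#' Hardy-Weinberg fixture dataset
#'
#' Genotypes drawn Binomial(2, p) per SNP for a single population; a
#' convenience generator for unit-test fixtures.
#'
#' @param freqs per-SNP A1 allele frequencies.
#' @param n_diploids number of samples.
#' @param breed breed code recorded in the population map.
#' @param group group label recorded in the population map.
#' @return A `genotype_dataset`.
#' @export
hw_fixture <- function(freqs, n_diploids, breed = "HW", group = "other") {
  m <- length(freqs)
  G <- vapply(freqs, function(p) stats::rbinom(n_diploids, 2, p),
              integer(n_diploids))
  G <- matrix(G, nrow = n_diploids)
  ids <- paste0(breed, "_", seq_len(n_diploids))
  genotype_dataset(G, ids, sprintf("snp%05d", seq_len(m)),
                   rep("1", m), seq_len(m) * 1000L,
                   cbind(rep("A", m), rep("G", m)),
                   data.frame(sample_id = ids, breed = breed, group = group,
                              stringsAsFactors = FALSE))
}
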