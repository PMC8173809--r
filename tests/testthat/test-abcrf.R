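# synthetic reference table on the canonical 37-statistic layout; class k
# has its first `n_inform` statistics shifted by k * delta
toy_table <- function(n_per, classes = 1:2, delta = 2, n_inform = 4,
                      params = NULL) {
  nm <- names(podabc:::summary_stat_names())
  rows <- lapply(classes, function(k) {
    X <- matrix(rnorm(n_per * length(nm)), n_per)
    X[, seq_len(n_inform)] <- X[, seq_len(n_inform)] + k * delta
    X
  })
  st <- do.call(rbind, rows)
  colnames(st) <- nm
  tab <- list(scenario = rep(classes, each = n_per),
              params = if (is.null(params))
                matrix(runif(nrow(st)), ncol = 1,
                       dimnames = list(NULL, "p1")) else params,
              stats = st, meta = list())
  class(tab) <- "reference_table"
  tab
}

test_that("summary vector has the canonical 37-statistic layout", {
  set.seed(91)
  sc <- build_builtin_scenarios()[[4]]
  p <- draw_params(default_priors(), sc)
  ds <- simulate_dataset(sc, p, sim_config(
    n_loci = 80, sample_sizes = c(IND = 8, NPT = 8, ITP = 8, BKP = 8,
                                  SEP = 8)))
  s <- summarize_dataset(ds)
  expect_length(s, 37L)
  expect_identical(names(s), names(podabc:::summary_stat_names()))
  expect_true(all(is.finite(s)))
  expect_identical(attr(s, "n_imputed"), 0L)
  # invariant to sample order
  perm <- sample(ds$sample_ids)
  expect_equal(as.numeric(summarize_dataset(subset(ds, samples = perm))),
               as.numeric(s))
  # group labels resolve to the same five populations here
  expect_equal(as.numeric(summarize_dataset(ds, use_groups = TRUE)),
               as.numeric(s))
  # heterozygosities and polymorphism proportions live in [0, 1]
  expect_true(all(s[grep("_He$|_polym$", names(s))] >= 0 &
                    s[grep("_He$|_polym$", names(s))] <= 1))
})

test_that("undefined summary statistics are imputed as zero and counted", {
  G <- matrix(0L, 10, 5)   # every group monomorphic
  ds <- make_ds(G, breed = rep(c("IND", "NPT", "ITP", "BKP", "SEP"),
                               each = 2))
  s <- summarize_dataset(ds)
  expect_true(all(is.finite(s)))
  expect_gt(attr(s, "n_imputed"), 0L)
})

test_that("reference tables have coherent shapes and reproducible content", {
  sc <- build_builtin_scenarios()[c(1, 4)]
  cfg <- sim_config(n_loci = 50, sample_sizes = c(IND = 6, NPT = 6, ITP = 6,
                                                  BKP = 6, SEP = 6))
  set.seed(92)
  tab <- build_reference_table(sc, default_priors(), n_per_scenario = 4,
                               simcfg = cfg)
  expect_s3_class(tab, "reference_table")
  expect_identical(tab$scenario, rep(c(1L, 4L), each = 4))
  expect_identical(dim(tab$stats), c(8L, 37L))
  expect_identical(colnames(tab$stats),
                   names(podabc:::summary_stat_names()))
  expect_identical(nrow(tab$params), 8L)
  expect_true(all(c("tdt", "tD", "r", "N4b") %in% colnames(tab$params)))
  expect_identical(tab$meta$failures, c(0L, 0L))
  set.seed(92)
  tab2 <- build_reference_table(sc, default_priors(), n_per_scenario = 4,
                                simcfg = cfg)
  expect_identical(tab$stats, tab2$stats)
  expect_output(print(tab), "8 rows")
})

test_that("LDA augmentation appends k - 1 discriminant axes", {
  set.seed(93)
  tab2 <- toy_table(60, classes = 1:2)
  obs <- tab2$stats[1, ]
  aug2 <- add_lda_axes(tab2, obs)
  expect_identical(ncol(aug2$table$stats), 38L)
  expect_identical(colnames(aug2$table$stats)[38], "LD1")
  expect_length(aug2$observed, 38L)
  # the discriminant axis separates the two classes
  ld <- aug2$table$stats[, "LD1"]
  expect_gt(abs(mean(ld[tab2$scenario == 1]) - mean(ld[tab2$scenario == 2])) /
              sd(ld), 1.5)

  tab3 <- toy_table(40, classes = 1:3)
  aug3 <- add_lda_axes(tab3, tab3$stats[1, ])
  expect_identical(ncol(aug3$table$stats), 39L)
  # constant columns are tolerated (dropped before the LDA fit)
  tabc <- tab2
  tabc$stats[, 37] <- 5
  expect_silent(add_lda_axes(tabc, tabc$stats[1, ]))
})

test_that("prior compatibility separates in-cloud from far-out observations", {
  set.seed(94)
  tab <- toy_table(150, classes = 1:2)
  inside <- prior_compatibility_check(tab, tab$stats[8, ])
  expect_true(inside$compatible)
  expect_true(all(inside$axes$inside))
  far <- tab$stats[8, ] + 50
  outside <- prior_compatibility_check(tab, far)
  expect_false(outside$compatible)
})

test_that("the forest classifier recovers a separable toy with high confidence", {
  set.seed(95)
  tab <- toy_table(100, classes = 1:2, delta = 3)
  obs <- c(3, 3, 3, 3, rep(0, 33))          # clean class-1 center
  names(obs) <- colnames(tab$stats)
  fit <- abc_rf(tab, obs, n_trees = 200, seed = 5)
  expect_s3_class(fit, "abc_rf")
  expect_lt(fit$oob_misclassification, 0.05)
  mc <- predict(fit, obs)
  expect_identical(mc$selected, "1")
  expect_identical(sum(mc$votes), 200L)
  expect_gte(mc$votes[["1"]] / 200, 0.95)
  expect_gte(mc$posterior_prob, 0.9)
  expect_lte(mc$posterior_prob, 1)
  # one-call wrapper agrees
  mc2 <- rf_model_choice(tab, obs, n_trees = 200, seed = 5)
  expect_identical(mc2$votes, mc$votes)
  # a training row predicts its own class
  row <- tab$stats[150, ]                    # class-2 row
  expect_identical(rf_model_choice(tab, row, n_trees = 200)$selected, "2")
  expect_error(abc_rf(tab, obs, n_trees = 10), "n_trees")
  expect_output(print(mc), "selected: 1")
})

test_that("irrelevant noise statistics do not break scenario choice", {
  set.seed(96)
  tab <- toy_table(100, classes = 1:2, delta = 3, n_inform = 2)
  # the other 35 statistics are pure noise by construction
  obs <- c(3, 3, rep(0, 35)); names(obs) <- colnames(tab$stats)
  expect_identical(rf_model_choice(tab, obs, n_trees = 200)$selected, "1")
})

test_that("grouped model choice validates the partition and pools votes", {
  set.seed(97)
  tab <- toy_table(60, classes = 1:4, delta = 2)
  obs <- c(2, 2, 2, 2, rep(0, 33)); names(obs) <- colnames(tab$stats)
  expect_error(grouped_model_choice(tab, list(a = 1:2, b = 2:4), obs),
               "partition")
  expect_error(grouped_model_choice(tab, list(a = 1:2, b = 3), obs),
               "partition")
  g <- grouped_model_choice(tab, list(low = 1:2, high = 3:4), obs,
                            n_trees = 200)
  expect_identical(sort(names(g$votes)), c("high", "low"))
  expect_identical(sum(g$votes), 200L)
  expect_identical(g$selected, "low")
})

test_that("quantile-forest parameter posteriors track a planted signal", {
  set.seed(98)
  n <- 500
  nm <- names(podabc:::summary_stat_names())
  st <- matrix(0, n, 37, dimnames = list(NULL, nm))
  st[, 1] <- runif(n)
  y <- 1000 + 5000 * st[, 1]
  tab <- list(scenario = rep(3L, n),
              params = cbind(tD = y, fixed = rep(42, n)),
              stats = st, meta = list())
  class(tab) <- "reference_table"
  obs <- st[1, ]; obs[1] <- 0.5
  est <- rf_parameter_estimate(tab, obs, "tD", scenario_id = 3,
                               n_trees = 300)
  expect_s3_class(est, "param_posterior")
  expect_lt(abs(est$median - 3500) / 3500, 0.05)
  expect_lte(est$q05, est$median); expect_lte(est$median, est$q95)
  expect_identical(est$median_ybp, generations_to_years(est$median))
  # constant parameter collapses to a point mass
  cst <- rf_parameter_estimate(tab, obs, "fixed", scenario_id = 3)
  expect_identical(c(cst$median, cst$q05, cst$q95), c(42, 42, 42))
  expect_error(rf_parameter_estimate(tab, obs, "nope"), "unknown parameter")
  expect_output(print(est), "tD: median")
})

test_that("reference tables round trip through their TSV/JSON text form", {
  sc <- build_builtin_scenarios()[1]
  cfg <- sim_config(n_loci = 40, sample_sizes = c(IND = 5, NPT = 5, ITP = 5,
                                                  BKP = 5, SEP = 5))
  set.seed(99)
  tab <- build_reference_table(sc, default_priors(), n_per_scenario = 3,
                               simcfg = cfg)
  d <- withr::local_tempdir()
  stem <- file.path(d, "ref")
  write_reference_table(tab, stem)
  expect_true(file.exists(paste0(stem, ".tsv")))
  expect_true(file.exists(paste0(stem, ".json")))
  rt <- read_reference_table(stem)
  expect_identical(rt$scenario, tab$scenario)
  expect_equal(rt$params, tab$params, ignore_attr = TRUE)
  expect_equal(colnames(rt$stats), colnames(tab$stats))
  expect_equal(unname(rt$stats), unname(tab$stats))
})

test_that("generation-to-year conversion floors at 2.5 years per generation", {
  expect_identical(generations_to_years(2593), 6482L)
  expect_identical(generations_to_years(5439), 13597L)
  expect_identical(generations_to_years(913.86), 2284L)
  expect_identical(generations_to_years(790), 1975L)
  expect_identical(generations_to_years(161), 402L)
  expect_identical(generations_to_years(0), 0L)
  expect_identical(generations_to_years(c(2053.10, 1874.90, 657.30)),
                   c(5132L, 4687L, 1643L))
  expect_identical(generations_to_years(4320.35), 10800L)
  expect_identical(generations_to_years(100, gen_time = 3), 300L)
})
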