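test_that("heterozygosity and MAF match direct counting on a printed fixture", {
  # 5 samples x 3 SNPs, written out by hand
  G <- matrix(c(0L, 1L, 1L, 2L, 1L,    # Ho 3/5, p 5/10, He 0.5
                1L, 1L, 1L, 1L, 1L,    # Ho 1,   p 0.5,  He 0.5
                0L, 0L, NA, 2L, 0L),   # Ho 0,   p 2/8,  He 2*.25*.75
              nrow = 5)
  ds <- make_ds(G)
  h <- heterozygosity(ds, breed = "B1")
  ho <- c(3 / 5, 1, 0)
  he <- c(0.5, 0.5, 2 * 0.25 * 0.75)
  expect_equal(h$Ho_mean, mean(ho))
  expect_equal(h$Ho_sd, sd(ho))
  expect_equal(h$He_mean, mean(he))
  expect_equal(h$He_sd, sd(he))

  m <- mean_maf(ds, breed = "B1")
  maf <- c(0.5, 0.5, 0.25)
  expect_equal(m$MAF_mean, mean(maf))
  expect_equal(m$MAF_sd, sd(maf))

  # all-heterozygote column and p = 0.5 edge values
  ds2 <- make_ds(matrix(1L, 4, 1))
  h2 <- heterozygosity(ds2, breed = "B1")
  expect_equal(h2$Ho_mean, 1)
  expect_equal(h2$He_mean, 0.5)
  # monomorphic SNP has MAF 0
  expect_equal(mean_maf(make_ds(matrix(2L, 4, 1)), breed = "B1")$MAF_mean, 0)

  # unbiased He correction: 2n/(2n-1) with n = 5
  hu <- heterozygosity(ds, breed = "B1", unbiased = TRUE)
  expect_equal(hu$He_mean, mean(c(0.5 * 10 / 9, 0.5 * 10 / 9,
                                  2 * 0.25 * 0.75 * 8 / 7)))
})

test_that("IBS distances equal brute-force allele-sharing counts", {
  set.seed(31)
  G <- matrix(sample(c(0:2, NA), 5 * 12, TRUE, prob = c(.3, .3, .3, .1)), 5)
  D <- ibs_distance(make_ds(G))
  expect_equal(unname(D), brute_ibs(G))
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 5))

  # identical rows -> 0; opposite homozygotes everywhere -> 1
  H <- rbind(rep(0L, 6), rep(0L, 6), rep(2L, 6))
  D2 <- ibs_distance(make_ds(H))
  expect_equal(D2[1, 2], 0)
  expect_equal(D2[1, 3], 1)
})

test_that("Reynolds distance evaluates its formula on a printed two-SNP toy", {
  # breed A: 4 diploids, breed B: 2 diploids
  GA <- matrix(c(2L, 2L, 1L, 1L,   # p1 = 6/8 = 0.75
                 0L, 1L, 0L, 1L),  # p1 = 2/8 = 0.25
               nrow = 4)
  GB <- matrix(c(0L, 1L,           # p2 = 1/4 = 0.25
                 2L, 2L),          # p2 = 4/4 = 1.00
               nrow = 2)
  ds <- make_ds(rbind(GA, GB), breed = rep(c("A", "B"), c(4, 2)))

  p1 <- c(0.75, 0.25); p2 <- c(0.25, 1.00)
  den <- sum(p1 * (1 - p2) + p2 * (1 - p1))
  # uncorrected form: ratio of sums of squared frequency differences
  expect_equal(reynolds_distance(ds, "A", "B", correction = FALSE),
               sum((p1 - p2)^2) / den)
  # corrected form subtracts the sampling variances (2n - 1 denominators)
  num <- sum((p1 - p2)^2 - p1 * (1 - p1) / 7 - p2 * (1 - p2) / 3)
  expect_equal(reynolds_distance(ds, "A", "B"), num / den)
  # linearized variant
  expect_equal(reynolds_distance(ds, "A", "B", linearized = TRUE),
               -log(1 - num / den))

  # identical frequency vectors -> exactly 0 without correction
  dsx <- make_ds(rbind(GA, GA), breed = rep(c("A", "B"), each = 4))
  expect_equal(reynolds_distance(dsx, "A", "B", correction = FALSE), 0)
  # fixed difference at every SNP -> 1
  dsf <- make_ds(rbind(matrix(0L, 3, 4), matrix(2L, 3, 4)),
                 breed = rep(c("A", "B"), each = 3))
  expect_equal(reynolds_distance(dsf, "A", "B"), 1)
})

test_that("Hudson FST evaluates its formula and hits both extremes", {
  GA <- matrix(c(2L, 1L, 1L, 0L,
                 2L, 2L, 1L, 1L), nrow = 4)   # p1 = 0.5, 0.75
  GB <- matrix(c(0L, 0L, 1L,
                 1L, 0L, 0L), nrow = 3)        # p2 = 1/6, 1/6
  ds <- make_ds(rbind(GA, GB), breed = rep(c("A", "B"), c(4, 3)))
  p1 <- c(0.5, 0.75); p2 <- c(1 / 6, 1 / 6)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / 7 - p2 * (1 - p2) / 5
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(hudson_fst(ds, "A", "B"), sum(num) / sum(den))

  dsf <- make_ds(rbind(matrix(0L, 3, 4), matrix(2L, 3, 4)),
                 breed = rep(c("A", "B"), each = 3))
  expect_equal(hudson_fst(dsf, "A", "B"), 1)
  # identical populations: near zero (noise only)
  set.seed(32)
  big <- hw_fixture(runif(300, 0.2, 0.8), 100)
  big$pop_map$breed <- rep(c("A", "B"), each = 50)
  expect_lt(abs(hudson_fst(big, "A", "B")), 0.01)
})

test_that("Nei distance is zero for identical frequencies and grows with divergence", {
  GA <- matrix(c(2L, 1L, 1L, 0L, 2L, 2L, 1L, 1L), nrow = 4)
  ds0 <- make_ds(rbind(GA, GA), breed = rep(c("A", "B"), each = 4))
  expect_equal(nei_distance(ds0, "A", "B"), 0)
  p1 <- c(0.5, 0.75); p2 <- c(0.2, 0.9)
  jxy <- sum(p1 * p2 + (1 - p1) * (1 - p2))
  jx <- sum(p1^2 + (1 - p1)^2); jy <- sum(p2^2 + (1 - p2)^2)
  GB <- rbind(c(0L, 2L), c(0L, 2L), c(1L, 2L), c(1L, 1L), c(0L, 2L))
  # p(GB) = (2/10, 9/10)
  dsd <- make_ds(rbind(GA, GB), breed = rep(c("A", "B"), c(4, 5)))
  expect_equal(nei_distance(dsd, "A", "B"), -log(jxy / sqrt(jx * jy)))
})

test_that("f3 sign behaviour: zero at T = A, negative for a mixture, positive after drift", {
  # T identical to A: exactly zero without the bias correction
  set.seed(33)
  GA <- matrix(rbinom(40 * 6, 2, 0.5), 40)
  GB <- matrix(rbinom(40 * 6, 2, 0.2), 40)
  ds <- make_ds(rbind(GA, GA, GB),
                breed = rep(c("T", "A", "B"), each = 40))
  expect_equal(f3_statistic(ds, "T", "A", "B", bias_correction = FALSE), 0)

  # frequencies constructed directly: T is the 50:50 mixture of diverged A, B
  m <- 400
  pa <- runif(m, 0.05, 0.45); pb <- pa + 0.5   # strongly diverged sources
  pt <- (pa + pb) / 2
  n <- 150
  mk <- function(p) vapply(p, function(x) rbinom(n, 2, x), integer(n))
  dsmix <- make_ds(rbind(mk(pt), mk(pa), mk(pb)),
                   breed = rep(c("T", "A", "B"), each = n))
  expect_lt(f3_statistic(dsmix, "T", "A", "B"), 0)

  # T drifted far from both sources: positive
  ptd <- pmin(pmax(pa + sample(c(-0.4, 0.4), m, TRUE), 0.02), 0.98)
  dsdrift <- make_ds(rbind(mk(ptd), mk(pa), mk(pa)),
                     breed = rep(c("T", "A", "B"), each = n))
  expect_gt(f3_statistic(dsdrift, "T", "A", "B"), 0)
})

test_that("diversity and distance statistics are invariant to allele relabelling", {
  set.seed(34)
  ds <- two_pop_ds(n_per = 25, m = 120, delta = 0.25)
  flip <- ds
  flip$genotypes <- 2L - flip$genotypes
  for (f in list(function(d) heterozygosity(d, breed = "P1")$He_mean,
                 function(d) mean_maf(d, breed = "P2")$MAF_mean,
                 function(d) hudson_fst(d, "P1", "P2"),
                 function(d) reynolds_distance(d, "P1", "P2"),
                 function(d) nei_distance(d, "P1", "P2")))
    expect_equal(f(flip), f(ds))
})

test_that("Reynolds and Hudson FST converge to zero as frequencies converge", {
  set.seed(35)
  n <- 200; m <- 300
  p <- runif(m, 0.2, 0.8)
  prev_r <- prev_f <- Inf
  for (delta in c(0.3, 0.1, 0.03)) {
    p2 <- pmin(pmax(p + delta, 0.01), 0.99)
    g1 <- vapply(p, function(q) rbinom(n, 2, q), integer(n))
    g2 <- vapply(p2, function(q) rbinom(n, 2, q), integer(n))
    ds <- make_ds(rbind(g1, g2), breed = rep(c("A", "B"), each = n))
    r <- reynolds_distance(ds, "A", "B")
    f <- hudson_fst(ds, "A", "B")
    expect_lt(r, prev_r); expect_lt(f, prev_f)
    prev_r <- r; prev_f <- f
  }
  expect_lt(prev_r, 0.02)
  expect_lt(prev_f, 0.02)
})

test_that("population_distance assembles symmetric zero-diagonal matrices", {
  set.seed(36)
  ds <- two_pop_ds(n_per = 20, m = 80)
  for (meth in c("reynolds", "fst", "nei")) {
    D <- population_distance(ds, method = meth)
    expect_true(isSymmetric(D))
    expect_equal(unname(diag(D)), rep(0, 2))
  }
})

test_that("diversity_summary tabulates one row per breed", {
  set.seed(37)
  ds <- two_pop_ds(n_per = 15, m = 60)
  tab <- diversity_summary(ds)
  expect_identical(tab$breed, c("P1", "P2"))
  expect_identical(tab$n, c(15L, 15L))
  expect_true(all(tab$Ho_mean >= 0 & tab$Ho_mean <= 1))
  expect_true(all(tab$He_mean >= 0 & tab$He_mean <= 1))
})
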