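# Allele frequencies, exact HWE, F-statistics and the cline trend test.

test_that("estimateFreq computes p and MAF from genotype counts", {
  expect_equal(estimateFreq(25, 50, 25)[, c("p", "maf")],
               data.frame(p = 0.5, maf = 0.5))
  expect_equal(estimateFreq(100, 0, 0)$p, 1)
  expect_equal(estimateFreq(100, 0, 0)$maf, 0)
  fr <- estimateFreq(44, 6, 0)  # 88% HbAA / 12% HbAS composition
  expect_equal(fr$p, 0.94)
  expect_equal(fr$maf, 0.06)
  expect_equal(fr$nChrom, 100L)
  expect_error(estimateFreq(0, 0, 0), "at least one")
})

test_that("hweExact matches hand enumeration and handles degenerate input", {
  # (1,0,1): 2 rare alleles in 2 individuals; het counts {0, 2} have
  # conditional probabilities 1/3 and 2/3, so the p-value is 1/3
  expect_equal(hweExact(1, 0, 1), 1 / 3)
  # perfectly conformant data sit at the modal configuration: p = 1
  expect_equal(hweExact(25, 50, 25), 1)
  expect_equal(hweExact(50, 0, 0), 1)  # monomorphic
  # symmetric in allele orientation
  expect_equal(hweExact(3, 5, 12), hweExact(12, 5, 3))
  # chi-square option agrees with stats::chisq on expected counts
  p <- hweExact(30, 40, 30, method = "chisq")
  expect_true(p > 0 && p <= 1)
})

test_that("hweExact equals the recurrence oracle on random tables", {
  withr::with_seed(55, {
    for (rep in 1:200) {
      n <- sample(1:80, 1)
      nAa <- sample(0:n, 1)
      nAA <- if (n - nAa > 0) sample(0:(n - nAa), 1) else 0
      naa <- n - nAa - nAA
      expect_equal(hweExact(nAA, nAa, naa),
                   oracle_hwe_exact(nAA, nAa, naa), tolerance = 1e-10)
    }
  })
})

test_that("pairwiseFst has the closed-form Wright values and properties", {
  expect_equal(pairwiseFst(0.3, 0.3), 0)
  expect_equal(pairwiseFst(0, 1), 1)
  expect_equal(pairwiseFst(0.2, 0.8), 0.36)
  expect_equal(pairwiseFst(0, 0), 0)   # both fixed: defined as 0
  expect_error(pairwiseFst(-0.1, 0.5), "\\[0, 1\\]")
  withr::with_seed(13, {
    for (rep in 1:50) {
      p1 <- runif(1); p2 <- runif(1)
      f <- pairwiseFst(p1, p2)
      expect_equal(f, pairwiseFst(p2, p1))
      expect_true(f >= 0 && f <= 1)
      if (p1 != p2) expect_gt(f, 0)
    }
  })
})

test_that("weirCockerhamFst is near zero for samples from one population", {
  withr::with_seed(29, {
    vals <- replicate(20, {
      g1 <- table(factor(rbinom(200, 2, 0.3), levels = 0:2))
      g2 <- table(factor(rbinom(200, 2, 0.3), levels = 0:2))
      weirCockerhamFst(as.integer(g1), as.integer(g2))
    })
  })
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("fstMatrix aggregates per-SNP pairwise values", {
  m <- rbind(a = c(s1 = 0.2, s2 = 0.1, s3 = 0.4),
             b = c(s1 = 0.8, s2 = 0.1, s3 = 0.3),
             c = c(s1 = 0.5, s2 = 0.2, s3 = 0.4))
  fm <- fstMatrix(m)
  expect_equal(unname(diag(fm$mean)), rep(0, 3))
  expect_equal(fm$mean, t(fm$mean))
  expect_equal(fm$perSnp$s1["a", "b"], pairwiseFst(0.2, 0.8))
  expected_ab <- mean(c(pairwiseFst(0.2, 0.8), pairwiseFst(0.1, 0.1),
                        pairwiseFst(0.4, 0.3)))
  expect_equal(fm$mean["a", "b"], expected_ab)
  # identical frequency vectors: all-zero matrix
  fm0 <- fstMatrix(rbind(a = c(s = 0.3), b = c(s = 0.3)))
  expect_true(all(fm0$mean == 0))
  # 2 populations, 1 SNP reduces to pairwiseFst
  fm1 <- fstMatrix(rbind(a = c(s = 0.1), b = c(s = 0.4)))
  expect_equal(fm1$mean["a", "b"], pairwiseFst(0.1, 0.4))
  # missing cell drops from the aggregate
  m2 <- rbind(a = c(s1 = 0.2, s2 = NA), b = c(s1 = 0.6, s2 = 0.2))
  fm2 <- fstMatrix(m2)
  expect_true(is.na(fm2$perSnp$s2["a", "b"]))
  expect_equal(fm2$mean["a", "b"], pairwiseFst(0.2, 0.6))
})

test_that("clineTrend statistic and exact p match the enumeration oracle", {
  dec <- c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05)
  tr <- clineTrend(dec)
  expect_equal(tr$statistic, -1)
  expect_true(tr$exact)
  expect_equal(tr$nPermutations, factorial(6))
  expect_equal(tr$pValue, oracle_cline_p(dec))
  # one inversion from strictly decreasing
  inv <- c(0.30, 0.20, 0.25, 0.15, 0.10, 0.05)
  tr2 <- clineTrend(inv)
  expect_equal(tr2$pValue, oracle_cline_p(inv))
  expect_equal(tr2$statistic,
               suppressWarnings(cor(1:6, inv, method = "spearman")))
  # constant MAFs: degenerate
  tr3 <- clineTrend(rep(0.2, 6))
  expect_equal(tr3$statistic, 0)
  expect_equal(tr3$pValue, 1)
  expect_true(tr3$degenerate)
  expect_error(clineTrend(c(0.1, 0.2)), "three")
})

test_that("clineTrend handles ties by midranks and large k by Monte-Carlo", {
  tied <- c(0.3, 0.2, 0.2, 0.1, 0.05, 0.05)
  tr <- clineTrend(tied)
  expect_equal(tr$statistic,
               suppressWarnings(cor(1:6, tied, method = "spearman")))
  expect_equal(tr$pValue, oracle_cline_p(tied))
  big <- seq(0.5, 0.05, length.out = 10)
  trMC <- clineTrend(big, nPerm = 500, seed = 3)
  expect_false(trMC$exact)
  expect_lt(trMC$pValue, 0.05)
  expect_equal(trMC$statistic, -1)
})
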