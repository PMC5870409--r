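# Two-locus counting, EM haplotype frequencies, D'/r2, likelihood CIs
# and Gabriel block detection.

test_that("twoLocusCounts tallies phased haplotypes and excludes missing", {
  mk <- data.frame(label = c("a", "b"), chrom = "11", pos = c(10L, 20L),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  g <- rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
  p <- HaplotypePanel(mk, g, phased = TRUE)
  tc <- twoLocusCounts(p, "a", "b")
  expect_equal(unname(tc$hapCounts), c(2, 0, 0, 2))
  g2 <- rbind(g, c(NA, 1L))
  p2 <- HaplotypePanel(mk, g2, phased = TRUE,
                       populations = rep("x", 5),
                       individuals = paste0("i", 1:5))
  tc2 <- twoLocusCounts(p2, 1, 2)
  expect_equal(tc2$n, 4)
  expect_equal(tc2$nExcluded, 1)
  expect_error(twoLocusCounts(p, "a", "zz"), "unknown marker")
  # random panels equal a brute-force tally
  withr::with_seed(31, {
    for (rep in 1:20) {
      pp <- random_phased_panel(4, 30, missingRate = 0.1)
      tc <- twoLocusCounts(pp, 2, 4)
      g <- genotypes(pp)
      keep <- !is.na(g[, 2]) & !is.na(g[, 4])
      manual <- table(factor(g[keep, 2], 0:1), factor(g[keep, 4], 0:1))
      expect_equal(unname(tc$hapCounts), as.vector(t(manual)))
    }
  })
})

test_that("EM equals counting with no double heterozygotes", {
  tab <- matrix(0, 3, 3)
  tab[1, 1] <- 3; tab[3, 3] <- 2; tab[1, 3] <- 1; tab[2, 1] <- 2
  r <- emHaplotypeFreq(tab)
  n <- sum(tab)
  expected <- c(p00 = (2 * 3 + 2) / (2 * n), p01 = 2 / (2 * n),
                p10 = 2 / (2 * n), p11 = (2 * 2) / (2 * n))
  expect_equal(r$freqs, expected, tolerance = 1e-7)
  expect_false(r$unidentifiable)
})

test_that("EM resolves double heterozygotes towards the ML solution", {
  # two cis-supporting homozygote pairs plus one double het: the double
  # het goes overwhelmingly to cis
  tab <- matrix(0, 3, 3)
  tab[1, 1] <- 2; tab[3, 3] <- 2; tab[2, 2] <- 1
  r <- emHaplotypeFreq(tab)
  expect_gt(r$freqs[["p00"]] + r$freqs[["p11"]], 0.95)
  expect_lt(abs(r$freqs[["p11"]] - oracle_ml_p11(tab)), 2e-4)
  # a lone double heterozygote is unidentifiable
  only <- matrix(0, 3, 3); only[2, 2] <- 1
  r2 <- emHaplotypeFreq(only)
  expect_true(r2$unidentifiable)
  expect_equal(unname(r2$freqs), rep(0.25, 4))
  expect_error(emHaplotypeFreq(matrix(0, 3, 3)), "empty")
})

test_that("EM preserves margins, sums to 1 and never decreases loglik", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      tab <- random_geno_table(50)
      if (sum(tab) == tab[2, 2]) next
      r <- emHaplotypeFreq(tab)
      f <- r$freqs
      expect_equal(sum(f), 1, tolerance = 1e-9)
      n <- sum(tab)
      pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
      expect_equal(unname(f[["p10"]] + f[["p11"]]), pA, tolerance = 1e-6)
    }
  })
})

test_that("ldPair computes D, D' and r2 with the standard normalizations", {
  r <- ldPair(c(0.25, 0.25, 0.25, 0.25))
  expect_equal(r$D, 0)
  expect_equal(r$r2, 0)
  r2 <- ldPair(c(0.5, 0, 0, 0.5))
  expect_equal(r2$Dprime, 1)
  expect_equal(r2$r2, 1)
  # pA=0.2, pB=0.4, p11=0.1
  r3 <- ldPair(c(0.5, 0.3, 0.1, 0.1))
  expect_equal(r3$D, 0.02)
  expect_equal(r3$Dprime, 0.02 / 0.12, tolerance = 1e-12)
  expect_equal(r3$r2, 0.0004 / 0.0384, tolerance = 1e-12)
  mono <- ldPair(c(0.5, 0.5, 0, 0))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$r2))
  expect_error(ldPair(c(0.5, 0.4, 0.2, 0.2)), "sum to 1")
  # properties on random frequency vectors
  withr::with_seed(17, {
    for (rep in 1:100) {
      f <- rgamma(4, 1); f <- f / sum(f)
      r <- ldPair(f)
      if (r$monomorphic) next
      expect_true(r$r2 <= 1 + 1e-12)
      expect_true(r$Dprime >= 0 && r$Dprime <= 1 + 1e-12)
      if (r$r2 > 1 - 1e-9) expect_equal(r$Dprime, 1)
    }
  })
})

test_that("dprimeCI concentrates with information and widens without", {
  mk <- data.frame(label = c("a", "b"), chrom = "11", pos = c(1L, 2L),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  # complete LD, large n: lower bound >= 0.98
  g <- rbind(matrix(rep(c(0L, 0L), 500), ncol = 2, byrow = TRUE),
             matrix(rep(c(1L, 1L), 500), ncol = 2, byrow = TRUE))
  ci <- dprimeCI(twoLocusCounts(HaplotypePanel(mk, g, TRUE), 1, 2))
  expect_gte(ci$lower, 0.98)
  # tiny sample: wide interval
  g4 <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 0L), c(1L, 1L))
  ci4 <- dprimeCI(twoLocusCounts(HaplotypePanel(mk, g4, TRUE), 1, 2))
  expect_lt(ci4$lower, 0.7)
  # independence at large n: upper bound < 0.9
  withr::with_seed(23, {
    gi <- cbind(rbinom(2000, 1, 0.5), rbinom(2000, 1, 0.5))
  })
  cii <- dprimeCI(twoLocusCounts(HaplotypePanel(mk, gi, TRUE), 1, 2))
  expect_lt(cii$upper, 0.9)
  # monomorphic marker: uninformative
  gm <- cbind(rep(0L, 10), rep(c(0L, 1L), 5))
  cim <- dprimeCI(twoLocusCounts(HaplotypePanel(mk, gm, TRUE), 1, 2))
  expect_false(cim$informative)
})

test_that("gabrielBlocks matches an exhaustive span check and is order-invariant", {
  spec <- RegionSpec(nMarkers = 10, nChromosomes = 500,
                     breakpoints = c(3L, 7L), seed = 61)
  panel <- simulateRegionPanel(spec)
  pairs <- ldPairs(panel)
  blocks <- gabrielBlocks(panel, pairs = pairs)
  # oracle: recompute the rule over all spans from the pair table, then
  # greedy longest-first, leftmost ties
  M <- 10
  strong <- matrix(NA, M, M)
  for (r in seq_len(nrow(pairs)))
    strong[pairs$i[r], pairs$j[r]] <-
      if (pairs$category[r] == "uninformative") NA
      else pairs$category[r] == "strong"
  ok <- function(a, b) {
    v <- strong[a:b, a:b][upper.tri(strong[a:b, a:b])]
    v <- v[!is.na(v)]
    length(v) > 0 && mean(v) >= 0.95
  }
  cand <- do.call(rbind, lapply(1:(M - 1), function(a)
    do.call(rbind, lapply((a + 1):M, function(b)
      if (ok(a, b)) c(a, b) else NULL))))
  taken <- rep(FALSE, M)
  expected <- list()
  for (k in order(-(cand[, 2] - cand[, 1]), cand[, 1])) {
    if (any(taken[cand[k, 1]:cand[k, 2]])) next
    taken[cand[k, 1]:cand[k, 2]] <- TRUE
    expected[[length(expected) + 1]] <- cand[k, ]
  }
  expected <- expected[order(vapply(expected, `[`, numeric(1), 1))]
  got <- lapply(blocks, function(b) c(b$start, b$end))
  expect_equal(lapply(got, as.numeric), lapply(expected, as.numeric))
  # chromosome order invariance
  withr::with_seed(5, perm <- sample.int(500))
  shuffled <- HaplotypePanel(markers(panel), genotypes(panel)[perm, ],
                             phased = TRUE,
                             populations = populations(panel)[perm],
                             individuals = individuals(panel)[perm])
  blocks2 <- gabrielBlocks(shuffled)
  expect_equal(lapply(blocks2, function(b) c(b$start, b$end)), got)
  # independent markers: no blocks
  withr::with_seed(19, gi <- matrix(rbinom(500 * 4, 1, 0.5), 500, 4))
  mki <- data.frame(label = paste0("m", 1:4), chrom = "11",
                    pos = c(10L, 20L, 30L, 40L), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  expect_length(gabrielBlocks(HaplotypePanel(mki, gi, TRUE)), 0)
})

test_that("block haplotype frequencies count distinct strings over chromosomes", {
  spec <- RegionSpec(nMarkers = 4, nChromosomes = 300, seed = 71)
  panel <- simulateRegionPanel(spec)
  bf <- blockHaplotypeFreqs(panel, c(1L, 4L))
  expect_equal(sum(bf$proportion), 1, tolerance = 1e-12)
  expect_lte(nrow(bf), 2)  # two founders
  expect_lt(abs(bf$proportion[1] - 0.5), 3 * sqrt(0.25 / 300))
  # identical chromosomes: one haplotype at 100%
  mk <- markers(panel)
  gOne <- matrix(1L, 10, 4)
  bf1 <- blockHaplotypeFreqs(HaplotypePanel(mk, gOne, TRUE), c(1L, 4L))
  expect_equal(bf1$proportion, 1)
  # unphased input is refused
  up <- HaplotypePanel(mk, matrix(0L, 10, 4), phased = FALSE)
  expect_error(blockHaplotypeFreqs(up, c(1L, 4L)), "phased")
})
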