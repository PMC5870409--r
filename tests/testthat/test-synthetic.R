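# Synthetic-data generator: cohorts, sequence emission round trip,
# region panels, determinism and frequency recovery.

tab <- defaultHaplotypeTable()

test_that("degenerate cohort draws are exact", {
  spec0 <- CohortSpec("z", 10, 0, c(Benin = 1), seed = 1)
  co <- simulateCohort(spec0, tab)
  expect_equal(nrow(chromosomes(co)), 20)
  expect_true(all(chromosomes(co)$hbs == "A"))
  spec1 <- CohortSpec("b", 5, 0.2, c(Benin = 1), seed = 2)
  co1 <- simulateCohort(spec1, tab)
  benin <- paste(patternFor(tab, "Benin"), collapse = "")
  pats <- apply(chromosomes(co1)[RFLP_LOCI], 1, paste, collapse = "")
  expect_true(all(pats == benin))
})

test_that("spec validation rejects bad mixtures and unknown labels", {
  expect_error(CohortSpec("x", 5, 0.1, c(Benin = 0.5, Bantu = 0.4)),
               "sum to 1")
  expect_error(simulateCohort(CohortSpec("x", 5, 0.1, c(Atlantis = 1)), tab),
               "Atlantis")
  expect_error(CohortSpec("x", 0, 0.1, c(Benin = 1)), "nIndividuals")
  expect_error(CohortSpec("x", 5, 0.1, c(Benin = 1),
                          snpMafs = c(s = 0.7)), "0.5")
})

test_that("identical spec and seed give byte-identical cohorts", {
  spec <- CohortSpec("d", 50, 0.1, c(Benin = 0.5, "atypical-I" = 0.5),
                     snpMafs = c(ABO_proxy = 0.2), seed = 99)
  expect_identical(simulateCohort(spec, tab), simulateCohort(spec, tab))
  spec2 <- CohortSpec("d", 50, 0.1, c(Benin = 0.5, "atypical-I" = 0.5),
                      snpMafs = c(ABO_proxy = 0.2), seed = 100)
  expect_false(identical(chromosomes(simulateCohort(spec, tab)),
                         chromosomes(simulateCohort(spec2, tab))))
})

test_that("digest after emit reproduces profiles and HbS alleles exactly", {
  # 100 random profiles via random label/allele assignments
  withr::with_seed(7, {
    labs <- sample(haplotypeLabels(tab), 100, replace = TRUE)
    hbs <- sample(c("A", "T"), 100, replace = TRUE)
  })
  co <- makeCohort("rt", labs, hbs, table = tab)
  seqs <- emitSequences(co)
  expect_equal(length(seqs), 100)
  dg <- digestCohort(seqs)
  df <- chromosomes(co)
  for (locus in RFLP_LOCI)
    expect_identical(dg[[locus]], df[[locus]])
  expect_identical(dg$hbs, df$hbs)
  # all-"+" profile: every enzyme finds its site
  coPlus <- makeCohort("p", rep("atypical-V", 2), "A", table = tab)
  dgPlus <- digestCohort(emitSequences(coPlus))
  expect_true(all(as.matrix(dgPlus[RFLP_LOCI]) == "+"))
  # HbS chromosome: codon-6 window has no DdeI match
  coS <- makeCohort("s", rep("Benin", 2), "T", table = tab)
  expect_true(all(digestCohort(emitSequences(coS))$DdeI_codon6 == "-"))
})

test_that("emitSequences validates its template", {
  co <- makeCohort("t", rep("Benin", 2), "A", table = tab)
  tmpl <- rflpTemplate()
  tmpl$windows <- tmpl$windows[tmpl$windows$locus != "HinfI_5b", ]
  expect_error(emitSequences(co, tmpl), "HinfI_5b")
})

test_that("frequency recovery within 3 binomial SEs at n = 2000", {
  mix <- c(Benin = 0.25, "atypical-I" = 0.55, Cameroon = 0.20)
  spec <- CohortSpec("big", 2000, 0.06, mix,
                     snpMafs = c(ABO_proxy = 0.30, HBB_proxy = 0.10),
                     seed = 321)
  co <- simulateCohort(spec, tab)
  df <- chromosomes(co)
  nChrom <- nrow(df)
  se <- function(p) sqrt(p * (1 - p) / nChrom)
  expect_lt(abs(mean(df$hbs == "T") - 0.06), 3 * se(0.06))
  for (lab in names(mix))
    expect_lt(abs(mean(df$haplotype == lab) - mix[[lab]]),
              3 * se(mix[[lab]]))
  for (sn in names(spec@snpMafs))
    expect_lt(abs(mean(df[[sn]]) - spec@snpMafs[[sn]]),
              3 * se(spec@snpMafs[[sn]]))
  # marker genotypes conform to HWE (exact allele-level draws)
  cc <- cohortGenotypeCounts(co, "ABO_proxy")
  expect_gt(hweExact(cc[1], cc[2], cc[3]), 0.001)
})

test_that("region panels realize the block-copy structure", {
  # one block, one founder pair, complete LD: every within-block pair
  # has |D'| = 1; chromosomes are copies of the two founders
  spec <- RegionSpec(nMarkers = 5, nChromosomes = 400, seed = 8)
  p <- simulateRegionPanel(spec)
  expect_true(isPhased(p))
  expect_equal(dim(genotypes(p)), c(400L, 5L))
  haps <- apply(genotypes(p), 1, paste, collapse = "")
  expect_lte(length(unique(haps)), 2L)
  for (j in 2:5) {
    counts <- twoLocusCounts(p, 1, j)
    expect_equal(ldPair(counts$hapCounts / counts$n)$Dprime, 1)
  }
  # two blocks: between-block r^2 is sampling noise around 0
  spec2 <- RegionSpec(nMarkers = 6, nChromosomes = 2000,
                      breakpoints = 3L, seed = 9)
  p2 <- simulateRegionPanel(spec2)
  counts <- twoLocusCounts(p2, 1, 6)
  r2 <- ldPair(counts$hapCounts / counts$n)$r2
  expect_lt(r2, 0.01)
  expect_error(RegionSpec(nMarkers = 1, nChromosomes = 10), "nMarkers")
})

test_that("panels are reproducible from their spec seed", {
  spec <- RegionSpec(nMarkers = 8, nChromosomes = 50, breakpoints = 4L,
                     seed = 12)
  expect_identical(genotypes(simulateRegionPanel(spec)),
                   genotypes(simulateRegionPanel(spec)))
})
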