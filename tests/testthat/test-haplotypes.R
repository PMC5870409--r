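# Haplotype classification and tabulation.

tab <- defaultHaplotypeTable()

test_that("classify matches exact patterns and routes the rest to atypical", {
  expect_equal(classifyProfile(patternFor(tab, "Benin"), tab)$label, "Benin")
  expect_equal(classifyProfile(patternFor(tab, "atypical-II"), tab)$label,
               "atypical-II")
  # every table pattern classifies back to its own label
  for (lab in haplotypeLabels(tab))
    expect_equal(classifyProfile(patternFor(tab, lab), tab)$label, lab)
  # a pattern absent from the table
  all_pats <- apply(expand.grid(rep(list(c("+", "-")), 5)), 1, paste,
                    collapse = "")
  absent <- setdiff(all_pats, c(tab@classical, tab@atypical))[1]
  expect_equal(classifyProfile(strsplit(absent, "")[[1]], tab)$label,
               "atypical-other")
  # one missing state -> unresolved even if the rest matches Benin
  p <- patternFor(tab, "Benin")
  p[3] <- NA
  expect_equal(classifyProfile(p, tab)$label, "unresolved")
  expect_error(classifyProfile(c("+", "-"), tab), "five")
})

test_that("classification is a pure function of profile and table", {
  p <- patternFor(tab, "Cameroon")
  expect_identical(classifyProfile(p, tab), classifyProfile(p, tab))
})

test_that("haplotype frequencies conserve counts and collapse consistently", {
  calls <- c(rep("Benin", 10), rep("atypical-I", 5), rep("atypical-other", 3),
             rep("Cameroon", 2), "unresolved")
  fine <- haplotypeFrequencies(calls, "fine")
  coarse <- haplotypeFrequencies(calls, "classical-vs-atypical")
  expect_equal(fine$denominator, 20)
  expect_equal(coarse$denominator, 20)
  expect_equal(fine$nUnresolved, 1)
  expect_equal(sum(fine$table$count), fine$denominator)
  expect_equal(sum(fine$table$proportion), 1, tolerance = 1e-12)
  # coarse atypical equals the sum of its fine constituents
  atyFine <- sum(fine$table$count[grepl("^atypical", fine$table$category)])
  expect_equal(coarse$table$count[coarse$table$category == "atypical"],
               atyFine)
  expect_equal(haplotypeFrequencies(rep("Benin", 10))$table$percent, 100)
  expect_error(haplotypeFrequencies(rep("unresolved", 3)), "resolved")
})

test_that("pair combinations are order-insensitive and collapse atypicals", {
  ids <- rep(c("i1", "i2", "i3"), each = 2)
  calls <- c("Benin", "atypical-I", "atypical-IV", "Benin", "Benin", "Benin")
  pc <- pairCombinations(ids, calls)
  # {Benin, atypical-I} and {atypical-IV, Benin} collapse to the same
  # unordered combination
  expect_equal(pc$records$combination[pc$records$individual == "i1"],
               pc$records$combination[pc$records$individual == "i2"])
  expect_equal(pc$table$count[pc$table$combination ==
                                pc$records$combination[1]], 2)
  expect_equal(sum(pc$table$count), 3)
  expect_error(pairCombinations(c("i1", "i1", "i2"), rep("Benin", 3)),
               "i2")
  # unresolved chromosome excludes the individual from the denominator
  pc2 <- pairCombinations(rep(c("a", "b"), each = 2),
                          c("Benin", "unresolved", "Benin", "Benin"))
  expect_equal(pc2$denominator, 1)
  expect_equal(pc2$nUnresolved, 1)
})

test_that("generated cohorts classify back to their generating labels", {
  mix <- c(Benin = 0.3, Cameroon = 0.2, "atypical-I" = 0.3,
           "atypical-V" = 0.2)
  spec <- CohortSpec("rt", 40, 0.1, mix, seed = 11)
  co <- simulateCohort(spec, tab)
  calls <- classifyProfiles(chromosomes(co), tab)
  expect_identical(calls, chromosomes(co)$haplotype)
})

test_that("haplotype table validity enforces distinct patterns", {
  expect_error(new("HaplotypeTable", loci = RFLP_LOCI,
                   classical = c(A = "++++-", B = "++++-"),
                   atypical = c(x = "+----")[0], version = "v"),
               "distinct")
})
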