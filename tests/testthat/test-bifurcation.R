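# Bifurcation trees, EHH and serialization.

make_panel <- function(g, pos = NULL) {
  M <- ncol(g)
  if (is.null(pos)) pos <- seq.int(10L, by = 10L, length.out = M)
  mk <- data.frame(label = paste0("m", seq_len(M)), chrom = "11",
                   pos = pos, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  HaplotypePanel(mk, g, phased = TRUE,
                 populations = rep("t", nrow(g)))
}

test_that("identical haplotypes form a single non-branching path", {
  g <- matrix(1L, 4, 4)
  tr <- buildBifurcation(make_panel(g), 1, 1L, "distal")
  nd <- treeNodes(tr)
  expect_equal(rootCount(tr), 4)
  expect_true(all(nd$count == 4))
  expect_equal(max(nd$depth), 3)
  expect_equal(nrow(nd), 4)  # root + one node per flanking marker
})

test_that("haplotypes differing at the first flanking marker split at once", {
  g <- rbind(c(1L, 0L), c(1L, 1L))
  tr <- buildBifurcation(make_panel(g), 1, 1L, "distal")
  nd <- treeNodes(tr)
  kids <- nd[nd$depth == 1, ]
  expect_equal(nrow(kids), 2)
  expect_equal(kids$count, c(1, 1))
})

test_that("trees match the prefix-grouping oracle and conserve counts", {
  withr::with_seed(83, {
    for (rep in 1:100) {
      M <- sample(4:8, 1)
      N <- sample(6:30, 1)
      miss <- sample(c(0, 0.1), 1)
      panel <- random_phased_panel(M, N, missingRate = miss)
      core <- sample(seq_len(M), 1)
      allele <- sample(0:1, 1)
      dir <- sample(c("distal", "proximal"), 1)
      g <- genotypes(panel)
      carriers <- which(!is.na(g[, core]) & g[, core] == allele)
      if (!length(carriers)) {
        expect_warning(tr <- buildBifurcation(panel, core, allele, dir),
                       "empty tree")
        expect_equal(rootCount(tr), 0)
        next
      }
      tr <- buildBifurcation(panel, core, allele, dir)
      nd <- treeNodes(tr)
      pos <- markers(panel)$pos
      flank <- if (dir == "distal") {
        idx <- which(pos > pos[core]); idx[order(pos[idx])]
      } else {
        idx <- which(pos < pos[core]); idx[order(-pos[idx])]
      }
      for (d in seq_along(flank)) {
        want <- oracle_prefix_counts(g, carriers, flank, d)
        got <- sort(nd$count[nd$depth == d])
        expect_equal(got, want)
        # depth-wise conservation: counts at depth d plus cumulative
        # missing-data drops equal the root count
        dropped <- tr@dropped
        cumDrop <- sum(dropped$count[dropped$depth <= d])
        expect_equal(sum(nd$count[nd$depth == d]) + cumDrop,
                     rootCount(tr))
      }
    }
  })
})

test_that("EHH has the combinatorial form and decays monotonically", {
  # 4 carriers split 2/2 at depth 1: EHH(1) = (1 + 1) / 6
  g <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L))
  p <- make_panel(g)
  expect_equal(ehh(p, 1, 1L, 0, "distal"), 1)
  expect_equal(ehh(p, 1, 1L, 1, "distal"), 2 / 6)
  # all carriers identical to depth d: EHH = 1
  gid <- matrix(1L, 5, 3)
  expect_equal(ehh(make_panel(gid), 1, 1L, 2, "distal"), 1)
  # non-increasing on random panels; tree-based EHH agrees
  withr::with_seed(91, {
    for (rep in 1:20) {
      panel <- random_phased_panel(6, 20)
      curve <- ehhCurve(panel, 2, 1L, "distal")
      expect_true(all(diff(curve$ehh) <= 1e-12))
      tr <- buildBifurcation(panel, 2, 1L, "distal")
      for (d in curve$depth)
        expect_equal(ehhFromTree(tr, d), curve$ehh[curve$depth == d])
    }
  })
  # fewer than two carriers: undefined
  g1 <- rbind(c(1L, 0L), c(0L, 0L))
  expect_warning(v <- ehh(make_panel(g1), 1, 1L, 1, "distal"), "undefined")
  expect_true(is.na(v))
})

test_that("tree JSON serialization round-trips losslessly", {
  withr::with_seed(97, {
    for (rep in 1:10) {
      panel <- random_phased_panel(6, 15, missingRate = 0.05)
      tr <- buildBifurcation(panel, 3, 1L,
                             sample(c("distal", "proximal"), 1))
      tr2 <- treeFromJSON(treeToJSON(tr))
      expect_identical(treeNodes(tr2), treeNodes(tr))
      expect_identical(tr2@dropped, tr@dropped)
      expect_identical(tr2@coreMarker, tr@coreMarker)
      expect_identical(tr2@rootCount, tr@rootCount)
    }
  })
  # empty tree keeps core metadata
  g <- matrix(0L, 4, 3)
  expect_warning(tr0 <- buildBifurcation(make_panel(g), 1, 1L, "distal"))
  tr0b <- treeFromJSON(treeToJSON(tr0))
  expect_equal(rootCount(tr0b), 0)
  expect_equal(nrow(treeNodes(tr0b)), 0)
})

test_that("equal marker positions are rejected and subsampling is seeded", {
  g <- matrix(1L, 4, 3)
  expect_error(make_panel(g, pos = c(10L, 10L, 30L)),
               "strictly increasing")
  panel <- random_phased_panel(5, 40)
  s1 <- subsampleChromosomes(panel, 20, seed = 4)
  s2 <- subsampleChromosomes(panel, 20, seed = 4)
  expect_identical(genotypes(s1), genotypes(s2))
  expect_equal(nrow(genotypes(s1)), 20)
})
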