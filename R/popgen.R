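# Population-genetic statistics: allele frequencies, exact
# Hardy-Weinberg testing, pairwise F-statistics between population
# allele frequencies, and the geographic cline trend test.

.check_counts <- function(nAA, nAa, naa) {
  counts <- c(nAA, nAa, naa)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0) ||
      any(counts != as.integer(counts)))
    stop("genotype counts must be three non-negative integers")
  if (sum(counts) < 1L) stop("at least one individual required")
  as.integer(counts)
}

#' Allele frequency and MAF from genotype counts
#'
#' Estimates the frequency of the reference-designated allele as
#' `p = (2 nAA + nAa) / (2n)`, the minor allele frequency as
#' `min(p, 1 - p)`, and attaches the exact Hardy-Weinberg p-value.
#'
#' @param nAA,nAa,naa Genotype counts of one biallelic SNP in one
#'   population (AA = homozygote for the reference-designated allele).
#' @return A one-row `data.frame` with columns `p`, `maf`, `hweP`,
#'   `nChrom`.
#' @export
#' @examples
#' estimateFreq(44, 6, 0)  # p = 0.94, MAF = 0.06
estimateFreq <- function(nAA, nAa, naa) {
  counts <- .check_counts(nAA, nAa, naa)
  n <- sum(counts)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  data.frame(p = p, maf = min(p, 1 - p),
             hweP = hweExact(counts[1], counts[2], counts[3]),
             nChrom = 2L * n)
}

# Log conditional probability of nAa = h heterozygotes given n
# individuals and nr copies of the rarer allele (Levene/Haldane):
# P(h) = n! 2^h / (nAA! h! naa!) * nr! nR! / (2n)!
.log_hwe_prob <- function(h, n, nr) {
  naa <- (nr - h) / 2
  nAA <- n - h - naa
  lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
    h * log(2) + lfactorial(nr) + lfactorial(2 * n - nr) -
    lfactorial(2 * n)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: conditions on the observed allele counts and
#' sums the probabilities of all heterozygote counts (same parity as
#' the rare-allele total) whose conditional probability does not exceed
#' that of the observed count. Valid at small cohort sizes where the
#' chi-square approximation is not.
#'
#' @inheritParams estimateFreq
#' @param method `"exact"` (default) or `"chisq"` (1-df chi-square
#'   without continuity correction, offered for comparison).
#' @return Two-sided p-value in `(0, 1]`; a monomorphic SNP returns 1
#'   (degenerate case).
#' @export
#' @examples
#' hweExact(25, 50, 25)
#' hweExact(50, 0, 0)  # monomorphic
hweExact <- function(nAA, nAa, naa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- .check_counts(nAA, nAa, naa)
  n <- sum(counts)
  # rare allele copies: orient so "a" is the rarer allele
  na_ <- 2L * counts[3] + counts[2]
  nr <- min(na_, 2L * n - na_)
  if (nr == 0L) return(1.0)
  if (method == "chisq") {
    p <- (2 * counts[1] + counts[2]) / (2 * n)
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - expd)^2 / expd)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  hs <- seq.int(nr %% 2L, nr, by = 2L)
  hs <- hs[(nr - hs) / 2 <= n - hs]          # naa, nAA non-negative
  lp <- .log_hwe_prob(hs, n, nr)
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  obs <- probs[match(counts[2], hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Pairwise F-statistic between two allele frequencies
#'
#' Wright's two-population variance ratio computed from frequencies
#' alone: with `pbar = (p1 + p2) / 2`,
#' `Fst = Var(p) / (pbar (1 - pbar))` where
#' `Var(p) = ((p1 - pbar)^2 + (p2 - pbar)^2) / 2`. No sample-size
#' correction is applied, matching the frequency-only setting in which
#' per-population genotype tables are unavailable. Returns 0 when both
#' populations are fixed (`pbar (1 - pbar) = 0`).
#'
#' @param p1,p2 Allele frequencies in `[0, 1]`.
#' @return F-statistic in `[0, 1]`; 0 iff `p1 == p2`.
#' @export
#' @examples
#' pairwiseFst(0.2, 0.8)  # 0.36
pairwiseFst <- function(p1, p2) {
  if (anyNA(c(p1, p2)) || p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("allele frequencies must lie in [0, 1]")
  pbar <- (p1 + p2) / 2
  denom <- pbar * (1 - pbar)
  if (denom == 0) return(0)
  varp <- ((p1 - pbar)^2 + (p2 - pbar)^2) / 2
  varp / denom
}

#' Weir-Cockerham two-population Fst from genotype counts
#'
#' Sample-size-corrected variant for users with full genotype tables;
#' provided alongside the frequency-only [pairwiseFst()], which remains
#' the default aggregation used by [fstMatrix()].
#'
#' @param counts1,counts2 Integer vectors `c(nAA, nAa, naa)` for the
#'   two populations.
#' @return Weir-Cockerham theta estimate (may be slightly negative for
#'   undifferentiated samples; NA if undefined).
#' @export
weirCockerhamFst <- function(counts1, counts2) {
  c1 <- .check_counts(counts1[1], counts1[2], counts1[3])
  c2 <- .check_counts(counts2[1], counts2[2], counts2[3])
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- (2 * c1[1] + c1[2]) / (2 * n1)
  p2 <- (2 * c2[1] + c2[2]) / (2 * n2)
  h1 <- c1[2] / n1; h2 <- c2[2] / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

#' Population differentiation matrices from a MAF table
#'
#' Computes the per-SNP symmetric matrix of pairwise F-statistics
#' between every population pair, plus the unweighted mean across SNPs.
#' Missing MAF cells flag the affected pair as missing for that SNP and
#' drop it from the aggregate mean.
#'
#' @param mafTable Numeric matrix or `data.frame`, rows = populations
#'   (rownames = labels, order preserved), columns = SNPs.
#' @return A list with `perSnp` (named list of matrices), `mean`
#'   (aggregate matrix) and `populations`.
#' @export
#' @examples
#' m <- rbind(popA = c(s1 = 0.3, s2 = 0.2), popB = c(0.1, 0.2))
#' fstMatrix(m)$mean
fstMatrix <- function(mafTable) {
  m <- as.matrix(mafTable)
  if (nrow(m) < 2L) stop("at least two populations required")
  if (ncol(m) < 1L) stop("at least one SNP required")
  pops <- rownames(m)
  if (is.null(pops)) pops <- paste0("pop", seq_len(nrow(m)))
  perSnp <- lapply(seq_len(ncol(m)), function(j) {
    fm <- matrix(NA_real_, nrow(m), nrow(m), dimnames = list(pops, pops))
    for (a in seq_len(nrow(m)))
      for (b in seq_len(nrow(m)))
        if (!is.na(m[a, j]) && !is.na(m[b, j]))
          fm[a, b] <- pairwiseFst(m[a, j], m[b, j])
    fm
  })
  names(perSnp) <- colnames(m)
  stack <- simplify2array(perSnp)
  agg <- apply(stack, c(1, 2), function(x)
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  list(perSnp = perSnp, mean = agg, populations = pops)
}

.spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(0)
  stats::cor(rx, ry)
}

#' Geographic cline trend test
#'
#' Rank correlation (Spearman, midranks for ties) between the fixed
#' geographic position index (1 = most equatorial) and per-population
#' MAFs, with a two-sided permutation p-value: full enumeration of all
#' orderings for up to 8 populations, seeded Monte-Carlo beyond.
#'
#' @param mafs Numeric MAFs, one per population, in geographic order.
#' @param nPerm Monte-Carlo permutations when populations > 8.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return A list with `statistic` (in `[-1, 1]`), `pValue`,
#'   `nPermutations`, `exact` and `degenerate` (TRUE when all MAFs are
#'   equal: statistic 0, p-value 1).
#' @export
#' @examples
#' clineTrend(c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05))$statistic  # -1
clineTrend <- function(mafs, nPerm = 10000L, seed = 1L) {
  k <- length(mafs)
  if (k < 3L) stop("at least three populations required")
  if (anyNA(mafs)) stop("missing MAFs are not supported")
  if (length(unique(mafs)) == 1L)
    return(list(statistic = 0, pValue = 1.0, nPermutations = 0L,
                exact = TRUE, degenerate = TRUE))
  idx <- seq_len(k)
  obs <- .spearman(idx, mafs)
  if (k <= 8L) {
    perms <- .permutations(k)
    stats_ <- apply(perms, 1, function(pp) .spearman(idx, mafs[pp]))
    p <- mean(abs(stats_) >= abs(obs) - 1e-12)
    list(statistic = obs, pValue = p, nPermutations = nrow(perms),
         exact = TRUE, degenerate = FALSE)
  } else {
    stats_ <- withr::with_seed(seed, vapply(seq_len(nPerm), function(i)
      .spearman(idx, sample(mafs)), numeric(1)))
    p <- (1 + sum(abs(stats_) >= abs(obs) - 1e-12)) / (nPerm + 1)
    list(statistic = obs, pValue = p, nPermutations = as.integer(nPerm),
         exact = FALSE, degenerate = FALSE)
  }
}
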