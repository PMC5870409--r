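# Linkage disequilibrium: two-locus haplotype frequencies (direct
# counting when phased, EM when unphased), D / D' / r-squared,
# likelihood-grid confidence intervals on |D'|, and Gabriel-style
# haplotype blocks with per-block haplotype frequencies.

.marker_index <- function(panel, marker) {
  mk <- markers(panel)
  if (is.character(marker)) {
    i <- match(marker, mk$label)
    if (is.na(i)) stop("unknown marker: ", marker)
    return(i)
  }
  if (marker < 1L || marker > nrow(mk)) stop("unknown marker: ", marker)
  as.integer(marker)
}

#' Two-locus counts for a marker pair
#'
#' For a phased panel, counts the four haplotypes (00, 01, 10, 11) over
#' chromosomes complete at both markers; for an unphased panel, the
#' 3x3 genotype dosage table. Rows with missing data at either marker
#' are excluded.
#'
#' @param panel A [HaplotypePanel].
#' @param markerI,markerJ Marker labels or indices.
#' @return A list with `type` (`"phased"`/`"unphased"`), `hapCounts`
#'   (named numeric, phased only), `genoTable` (3x3 matrix, unphased
#'   only), `n` (chromosomes or individuals used) and `nExcluded`.
#' @export
twoLocusCounts <- function(panel, markerI, markerJ) {
  i <- .marker_index(panel, markerI)
  j <- .marker_index(panel, markerJ)
  g <- genotypes(panel)
  a <- g[, i]; b <- g[, j]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (isPhased(panel)) {
    counts <- c(`00` = sum(a == 0 & b == 0), `01` = sum(a == 0 & b == 1),
                `10` = sum(a == 1 & b == 0), `11` = sum(a == 1 & b == 1))
    list(type = "phased", hapCounts = counts, genoTable = NULL,
         n = length(a), nExcluded = sum(!keep))
  } else {
    tab <- matrix(0L, 3, 3, dimnames = list(0:2, 0:2))
    for (x in 0:2) for (y in 0:2)
      tab[x + 1L, y + 1L] <- sum(a == x & b == y)
    list(type = "unphased", hapCounts = NULL, genoTable = tab,
         n = length(a), nExcluded = sum(!keep))
  }
}

# Genotype-cell probabilities implied by haplotype frequencies
# f = c(p00, p01, p10, p11); cell [x+1, y+1] = P(dosage x at A, y at B).
.geno_probs <- function(f) {
  p00 <- f[1]; p01 <- f[2]; p10 <- f[3]; p11 <- f[4]
  m <- matrix(0, 3, 3)
  m[1, 1] <- p00^2
  m[1, 2] <- 2 * p00 * p01
  m[1, 3] <- p01^2
  m[2, 1] <- 2 * p00 * p10
  m[2, 2] <- 2 * (p00 * p11 + p01 * p10)
  m[2, 3] <- 2 * p01 * p11
  m[3, 1] <- p10^2
  m[3, 2] <- 2 * p10 * p11
  m[3, 3] <- p11^2
  m
}

.geno_loglik <- function(f, tab) {
  pr <- .geno_probs(f)
  sum(tab[tab > 0] * log(pmax(pr[tab > 0], 1e-300)))
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from an unphased 3x3
#' genotype dosage table. Only double heterozygotes are ambiguous
#' (cis 00/11 vs trans 01/10); the EM splits them by their expected
#' posterior fractions each iteration until the largest frequency
#' change falls below `tol` (the log-likelihood is non-decreasing
#' throughout). With no double heterozygotes the result is the exact
#' counting estimate at the first iteration. A table containing only
#' double heterozygotes has a flat ridge; the EM then stays at its
#' uninformative initialization and is flagged.
#'
#' @param genoTable 3x3 matrix of genotype counts (rows = dosage at
#'   locus A, columns = dosage at locus B).
#' @param tol Convergence tolerance on haplotype frequencies.
#' @param maxIter Iteration cap.
#' @return A list with `freqs` (named `p00, p01, p10, p11`), `logLik`,
#'   `iterations`, `converged` and `unidentifiable`.
#' @export
#' @examples
#' tab <- matrix(0, 3, 3); tab[1, 1] <- 2; tab[3, 3] <- 2
#' emHaplotypeFreq(tab)$freqs
emHaplotypeFreq <- function(genoTable, tol = 1e-8, maxIter = 1000L) {
  tab <- as.matrix(genoTable)
  if (!all(dim(tab) == c(3, 3)) || any(tab < 0) || anyNA(tab))
    stop("genoTable must be a non-negative 3x3 count matrix")
  n <- sum(tab)
  if (n < 1) stop("empty genotype table")
  nDH <- tab[2, 2]
  if (nDH == n)
    return(list(freqs = c(p00 = 0.25, p01 = 0.25, p10 = 0.25, p11 = 0.25),
                logLik = .geno_loglik(rep(0.25, 4), tab),
                iterations = 0L, converged = TRUE, unidentifiable = TRUE))
  # unambiguous haplotype contributions (counts of each haplotype
  # excluding the double-het cell)
  base <- c(
    `00` = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
    `01` = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    `10` = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
    `11` = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3])
  f <- rep(0.25, 4)
  ll <- -Inf
  iters <- 0L
  converged <- FALSE
  repeat {
    iters <- iters + 1L
    cis <- f[1] * f[4]
    trans <- f[2] * f[3]
    wc <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    hap <- base + nDH * c(wc, 1 - wc, 1 - wc, wc)
    fNew <- hap / (2 * n)
    delta <- max(abs(fNew - f))
    f <- fNew
    ll <- .geno_loglik(f, tab)
    if (delta < tol) { converged <- TRUE; break }
    if (iters >= maxIter) break
  }
  names(f) <- c("p00", "p01", "p10", "p11")
  list(freqs = f, logLik = ll, iterations = iters,
       converged = converged, unidentifiable = FALSE)
}

#' Two-locus LD statistics from haplotype frequencies
#'
#' With `pA = p10 + p11` and `pB = p01 + p11`:
#' `D = p11 - pA pB`; `Dmax = min(pA (1 - pB), (1 - pA) pB)` if `D > 0`
#' else `min(pA pB, (1 - pA)(1 - pB))`; `D' = |D| / Dmax`;
#' `r^2 = D^2 / (pA (1 - pA) pB (1 - pB))`. A monomorphic marker makes
#' D' and r-squared undefined (NA, flagged).
#'
#' @param freqs Numeric vector `c(p00, p01, p10, p11)` summing to 1.
#' @return A list with `D`, `Dprime`, `r2`, `pA`, `pB` and
#'   `monomorphic`.
#' @export
#' @examples
#' ldPair(c(0.42, 0.38, 0.1, 0.1))
ldPair <- function(freqs) {
  freqs <- unname(as.numeric(freqs))
  if (length(freqs) != 4L || anyNA(freqs) || any(freqs < -1e-12))
    stop("freqs must be four non-negative frequencies")
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("haplotype frequencies must sum to 1")
  pA <- freqs[3] + freqs[4]
  pB <- freqs[2] + freqs[4]
  D <- freqs[4] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  if (denom <= 0)
    return(list(D = D, Dprime = NA_real_, r2 = NA_real_,
                pA = pA, pB = pB, monomorphic = TRUE))
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (D == 0) 0 else abs(D) / dmax
  list(D = D, Dprime = dp, r2 = D^2 / denom, pA = pA, pB = pB,
       monomorphic = FALSE)
}

# Log-likelihood of two-locus data at given haplotype freqs.
.counts_loglik <- function(f, counts) {
  if (counts$type == "phased") {
    hc <- counts$hapCounts
    sum(hc[hc > 0] * log(pmax(f[hc > 0], 1e-300)))
  } else .geno_loglik(f, counts$genoTable)
}

#' Likelihood-grid confidence bounds on |D'|
#'
#' The conventional Gabriel/Haploview construction: with allele
#' frequencies fixed at their sample estimates, the likelihood of the
#' data is evaluated on a uniform grid of |D'| values in `[0, 1]`
#' (oriented by the sign of the observed D) and normalized; the lower
#' bound is the smallest grid value whose cumulative likelihood reaches
#' 5%, the upper bound the largest with at least 5% in the upper tail.
#'
#' @param counts Output of [twoLocusCounts()].
#' @param gridSize Number of grid points (default 101).
#' @return A list with `lower`, `upper`, `dprime` (point estimate) and
#'   `informative` (FALSE when either marker is monomorphic).
#' @export
dprimeCI <- function(counts, gridSize = 101L) {
  if (counts$n < 1) stop("no complete observations")
  if (counts$type == "phased") {
    f0 <- counts$hapCounts / counts$n
  } else {
    f0 <- emHaplotypeFreq(counts$genoTable)$freqs
  }
  est <- ldPair(f0)
  if (est$monomorphic)
    return(list(lower = NA_real_, upper = NA_real_, dprime = NA_real_,
                informative = FALSE))
  pA <- est$pA; pB <- est$pB
  sgn <- if (est$D >= 0) 1 else -1
  dmaxPos <- min(pA * (1 - pB), (1 - pA) * pB)
  dmaxNeg <- min(pA * pB, (1 - pA) * (1 - pB))
  dmax <- if (sgn > 0) dmaxPos else dmaxNeg
  grid <- seq(0, 1, length.out = gridSize)
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * dmax
    f <- c(p00 = (1 - pA) * (1 - pB) + D, p01 = (1 - pA) * pB - D,
           p10 = pA * (1 - pB) - D, p11 = pA * pB + D)
    f <- pmax(f, 0)
    .counts_loglik(f / sum(f), counts)
  }, numeric(1))
  lik <- exp(ll - max(ll))
  lik <- lik / sum(lik)
  cum <- cumsum(lik)
  lower <- grid[which(cum >= 0.05)[1]]
  upperTail <- rev(cumsum(rev(lik)))
  upper <- grid[max(which(upperTail >= 0.05))]
  list(lower = lower, upper = upper, dprime = est$Dprime,
       informative = TRUE)
}

#' Pairwise LD over all marker pairs of a panel
#'
#' @param panel A [HaplotypePanel].
#' @return `data.frame` with one row per marker pair: labels, indices,
#'   `D`, `Dprime`, `r2`, CI bounds and the Gabriel pair category
#'   (`"strong"`, `"recomb"`, `"other"`, `"uninformative"`).
#' @param ciLow,ciHigh,recombHigh Gabriel thresholds: a pair is in
#'   strong LD iff CI lower `>= ciLow` and CI upper `>= ciHigh`; it
#'   shows strong evidence of recombination iff CI upper `< recombHigh`.
#' @export
ldPairs <- function(panel, ciLow = 0.70, ciHigh = 0.98, recombHigh = 0.90) {
  M <- nrow(markers(panel))
  if (M < 2L) stop("at least two markers required")
  rows <- list()
  k <- 1L
  for (i in seq_len(M - 1L)) {
    for (j in seq.int(i + 1L, M)) {
      counts <- twoLocusCounts(panel, i, j)
      freqs <- if (counts$type == "phased") counts$hapCounts / counts$n
               else emHaplotypeFreq(counts$genoTable)$freqs
      est <- ldPair(freqs)
      ci <- dprimeCI(counts)
      cat_ <- if (!ci$informative) "uninformative"
        else if (ci$lower >= ciLow && ci$upper >= ciHigh) "strong"
        else if (ci$upper < recombHigh) "recomb"
        else "other"
      rows[[k]] <- data.frame(
        markerI = markers(panel)$label[i], markerJ = markers(panel)$label[j],
        i = i, j = j, D = est$D, Dprime = est$Dprime, r2 = est$r2,
        ciLower = ci$lower, ciUpper = ci$upper, category = cat_,
        stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gabriel-style haplotype block detection
#'
#' A candidate span of two or more markers is a block iff at least
#' `minStrongFrac` of its informative pairs (both markers polymorphic)
#' are in strong LD by the D' confidence-interval rule. Maximal
#' non-overlapping spans are selected greedily, longest first, ties by
#' leftmost start. Thresholds default to the Haploview values.
#'
#' @inheritParams ldPairs
#' @param minStrongFrac Minimum strong-LD fraction among informative
#'   pairs in a span (default 0.95).
#' @param pairs Optional precomputed [ldPairs()] table (with matching
#'   thresholds) to avoid recomputation.
#' @return A list of blocks, each a list with `start`, `end` (marker
#'   indices, inclusive), `markers` (labels) and, for phased panels,
#'   `haplotypes` (the per-block frequency table from
#'   [blockHaplotypeFreqs()]).
#' @export
gabrielBlocks <- function(panel, ciLow = 0.70, ciHigh = 0.98,
                          recombHigh = 0.90, minStrongFrac = 0.95,
                          pairs = NULL) {
  M <- nrow(markers(panel))
  if (M < 2L) return(list())
  if (is.null(pairs))
    pairs <- ldPairs(panel, ciLow = ciLow, ciHigh = ciHigh,
                     recombHigh = recombHigh)
  strong <- matrix(NA, M, M)  # NA = uninformative
  for (r in seq_len(nrow(pairs)))
    strong[pairs$i[r], pairs$j[r]] <-
      if (pairs$category[r] == "uninformative") NA
      else pairs$category[r] == "strong"
  spanOk <- function(a, b) {
    sub <- strong[a:b, a:b]
    vals <- sub[upper.tri(sub)]
    vals <- vals[!is.na(vals)]
    length(vals) > 0 && mean(vals) >= minStrongFrac
  }
  cand <- list()
  for (a in seq_len(M - 1L))
    for (b in seq.int(a + 1L, M))
      if (spanOk(a, b)) cand[[length(cand) + 1L]] <- c(a, b)
  if (!length(cand)) return(list())
  lens <- vapply(cand, function(s) s[2] - s[1], integer(1))
  starts <- vapply(cand, `[`, integer(1), 1L)
  ord <- order(-lens, starts)
  taken <- rep(FALSE, M)
  blocks <- list()
  for (k in ord) {
    s <- cand[[k]]
    if (any(taken[s[1]:s[2]])) next
    taken[s[1]:s[2]] <- TRUE
    blk <- list(start = s[1], end = s[2],
                markers = markers(panel)$label[s[1]:s[2]])
    if (isPhased(panel))
      blk$haplotypes <- blockHaplotypeFreqs(panel, s)
    blocks[[length(blocks) + 1L]] <- blk
  }
  ord2 <- order(vapply(blocks, `[[`, integer(1), "start"))
  blocks[ord2]
}

#' Haplotype frequencies within a block
#'
#' Counts the distinct allele strings over the block's markers among
#' chromosomes with no missing data in the block.
#'
#' @param panel A phased [HaplotypePanel].
#' @param block Either a block list from [gabrielBlocks()] or a
#'   length-2 vector `c(start, end)` of marker indices.
#' @return `data.frame` with columns `haplotype`, `count`,
#'   `proportion` (proportions sum to 1).
#' @export
blockHaplotypeFreqs <- function(panel, block) {
  if (!isPhased(panel))
    stop("block haplotype frequencies require phased data; ",
         "the two-locus EM does not generalize to blocks of >2 markers")
  idx <- if (is.list(block)) c(block$start, block$end) else block
  g <- genotypes(panel)[, idx[1]:idx[2], drop = FALSE]
  keep <- stats::complete.cases(g)
  if (!any(keep)) stop("no chromosomes complete within the block")
  haps <- apply(g[keep, , drop = FALSE], 1, paste, collapse = "")
  counts <- sort(table(haps), decreasing = TRUE)
  out <- data.frame(haplotype = names(counts), count = as.integer(counts),
                    proportion = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
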