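# Independent oracles. Each reimplements the quantity under test by a
# different route (brute force, recurrence, grid search, direct string
# grouping) and shares no code with the package internals.

# --- brute-force IUPAC scan ------------------------------------------------

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_find_sites <- function(sequence, pattern) {
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  m <- length(p)
  L <- length(s)
  if (L < m) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(L - m + 1)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      ch <- s[i + k - 1]
      code <- p[k]
      match1 <- if (code == "N") TRUE
        else if (ch == "N") FALSE
        else ch %in% .oracle_iupac[[code]]
      if (!match1) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

random_sequence <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- HWE exact test via the Wigginton-style recurrence ---------------------

# P(h + 2) = P(h) * 4 nAA(h) naa(h) / ((h + 2)(h + 1)); start at the
# smallest feasible het count, fill upward, normalize.
oracle_hwe_exact <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na_ <- 2 * naa + nAa
  nr <- min(na_, 2 * n - na_)
  if (nr == 0) return(1)
  hs <- seq(nr %% 2, nr, by = 2)
  hs <- hs[(nr - hs) / 2 <= n - hs]
  probs <- numeric(length(hs))
  probs[1] <- 1
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    naa_h <- (nr - h) / 2
    nAA_h <- n - h - naa_h
    probs[k] <- probs[k - 1] * 4 * nAA_h * naa_h / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[hs == nAa]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# --- two-locus ML by 1-D grid search ---------------------------------------

# The ML haplotype frequencies preserve the observed allele-count
# margins, so the likelihood is one-dimensional in p11; grid-search it.
oracle_geno_loglik <- function(p00, p01, p10, p11, tab) {
  pr <- matrix(c(p00^2, 2 * p00 * p01, p01^2,
                 2 * p00 * p10, 2 * (p00 * p11 + p01 * p10), 2 * p01 * p11,
                 p10^2, 2 * p10 * p11, p11^2),
               3, 3, byrow = TRUE)
  sum(tab[tab > 0] * log(pmax(pr[tab > 0], 1e-300)))
}

oracle_ml_p11 <- function(tab, step = 1e-4) {
  n <- sum(tab)
  pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)        # dosage at locus A
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- unique(c(seq(lo, hi, by = step), hi))
  ll <- vapply(grid, function(p11)
    oracle_geno_loglik(1 - pA - pB + p11, pB - p11, pA - p11, p11, tab),
    numeric(1))
  grid[which.max(ll)]
}

random_geno_table <- function(n = 60) {
  f <- as.numeric(stats::rgamma(4, 1))
  f <- f / sum(f)
  pr <- matrix(c(f[1]^2, 2 * f[1] * f[2], f[2]^2,
                 2 * f[1] * f[3], 2 * (f[1] * f[4] + f[2] * f[3]),
                 2 * f[2] * f[4],
                 f[3]^2, 2 * f[3] * f[4], f[4]^2),
               3, 3, byrow = TRUE)
  matrix(stats::rmultinom(1, n, as.vector(t(pr))), 3, 3, byrow = TRUE)
}

# --- prefix grouping for bifurcation trees ---------------------------------

# Counts of distinct allele-string prefixes of length d among carriers;
# haplotypes with a missing allele inside the prefix are excluded.
oracle_prefix_counts <- function(geno, carriers, flankCols, d) {
  if (d == 0) return(length(carriers))
  sub <- geno[carriers, flankCols[seq_len(d)], drop = FALSE]
  keep <- !apply(sub, 1, anyNA)
  sub <- sub[keep, , drop = FALSE]
  if (!nrow(sub)) return(integer(0))
  unname(sort(as.integer(table(apply(sub, 1, paste, collapse = "")))))
}

# --- Spearman permutation p-value by direct enumeration --------------------

oracle_cline_p <- function(mafs) {
  k <- length(mafs)
  idx <- seq_len(k)
  obs <- suppressWarnings(stats::cor(idx, mafs, method = "spearman"))
  perms <- combinat_perms(k)
  stats_ <- apply(perms, 1, function(pp)
    suppressWarnings(stats::cor(idx, mafs[pp], method = "spearman")))
  mean(abs(stats_) >= abs(obs) - 1e-12)
}

# all permutations of 1..n, own construction (lexicographic insertion)
combinat_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (k in 2:n) {
    rows <- list()
    for (i in seq_len(nrow(out))) {
      for (pos in seq_len(k)) {
        rows[[length(rows) + 1L]] <- append(out[i, ], k, after = pos - 1L)
      }
    }
    out <- do.call(rbind, rows)
  }
  out
}

# --- misc fixtures ----------------------------------------------------------

random_phased_panel <- function(nMarkers, nChrom, missingRate = 0) {
  g <- matrix(stats::rbinom(nMarkers * nChrom, 1, 0.5), nChrom, nMarkers)
  if (missingRate > 0)
    g[stats::runif(length(g)) < missingRate] <- NA_integer_
  mk <- data.frame(label = sprintf("m%02d", seq_len(nMarkers)),
                   chrom = "11",
                   pos = sort(sample.int(100000L, nMarkers)),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  HaplotypePanel(mk, g, phased = TRUE,
                 populations = rep("t", nChrom))
}
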