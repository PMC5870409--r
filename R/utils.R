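# Internal helpers shared across modules.

# IUPAC nucleotide codes expanded to the unambiguous bases they stand for.
# A pattern "N" is a wildcard (matches any base, including an N in the
# subject); any other code never matches a subject "N".
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' The five diagnostic restriction loci, in fixed 5'-to-3' order
#'
#' XmnI (5'G-gamma), HindIII (G-gamma), HindIII (A-gamma), HincII
#' (3'psi-beta) and HinfI (5'beta). All RFLP profiles, haplotype table
#' patterns and cohort columns follow this order.
#'
#' @format Character vector of five locus names.
#' @export
RFLP_LOCI <- c("XmnI_5Gg", "HindIII_Gg", "HindIII_Ag", "HincII_3psb", "HinfI_5b")

# Enzyme assayed at each locus (the two HindIII loci share an enzyme).
.LOCUS_ENZYME <- c(
  XmnI_5Gg = "XmnI", HindIII_Gg = "HindIII", HindIII_Ag = "HindIII",
  HincII_3psb = "HincII", HinfI_5b = "HinfI", DdeI_codon6 = "DdeI"
)

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

.is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)

#' Derive a stage-specific seed from a master seed
#'
#' Stable integer hash of a stage name folded into a master seed, so a
#' single pipeline seed yields distinct, reproducible per-stage seeds.
#' The result is always in `[0, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
#' @examples
#' deriveSeed(1L, "simulate")
deriveSeed <- function(master, stage) {
  stopifnot(.is_count(master), is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 7919 + h) %% 2147483647)
}

#' Parse and format samtools-style region strings
#'
#' Regions are written `chrom:start-end` with 1-based inclusive
#' coordinates (the samtools/VCF convention). `parseRegion` and
#' `formatRegion` are mutual inverses.
#'
#' @param region Character region string, e.g. `"11:5200000-5300000"`.
#' @return `parseRegion`: a list with elements `chrom`, `start`, `end`.
#' @export
#' @examples
#' parseRegion("11:100-200")
#' formatRegion(parseRegion("11:100-200"))
parseRegion <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region string (expected chrom:start-end): ", region)
  out <- list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
  if (out$start < 1L || out$end < out$start)
    stop("region coordinates must satisfy 1 <= start <= end: ", region)
  out
}

#' @rdname parseRegion
#' @param parsed A list as returned by `parseRegion`.
#' @return `formatRegion`: the region string.
#' @export
formatRegion <- function(parsed) {
  sprintf("%s:%d-%d", parsed$chrom, parsed$start, parsed$end)
}

# All permutations of 1..n as an n! x n matrix (n small, <= 8 in practice).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Write a data.frame as TSV with fixed formatting (deterministic bytes).
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
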