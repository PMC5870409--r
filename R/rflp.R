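# In-silico RFLP: restriction-site scanning, fragment prediction,
# per-locus cut/uncut calls, and HbS genotyping by DdeI-site loss.
#
# The sickle mutation (rs334, HBB codon 6, A->T) destroys a DdeI
# recognition site (CTNAG): the HbA context CCTGAGGAG is cut, the HbS
# context CCTGTGGAG is not, which is how the wet-lab assay and its
# in-silico equivalent here distinguish the alleles.

#' Built-in enzyme set for beta-globin cluster haplotyping
#'
#' Reads the packaged enzyme definitions (DdeI, XmnI, HindIII, HincII,
#' HinfI) from the JSON config shipped with the package.
#'
#' @param path Optional path to an alternative enzyme JSON config (a
#'   list of objects with fields `name`, `recognition`, `cut_offset`).
#' @return A named list of [RestrictionEnzyme] objects.
#' @export
#' @examples
#' names(defaultEnzymes())
defaultEnzymes <- function(path = system.file("extdata", "enzymes.json",
                                              package = "sickleHaps")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  enz <- lapply(raw, function(e)
    RestrictionEnzyme(e$name, e$recognition, e$cut_offset))
  names(enz) <- vapply(enz, function(e) e@name, character(1))
  enz
}

.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string")
  s <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(s), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid sequence characters: ", paste(bad, collapse = ", "))
  s
}

#' Find restriction-site matches in a sequence
#'
#' Scans a single strand for matches to the enzyme's IUPAC recognition
#' pattern. Ambiguity codes in the pattern are expanded (`N` matches any
#' base); an `N` in the sequence matches only a pattern `N`. All
#' (possibly overlapping) matches are reported.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N`.
#' @param enzyme A [RestrictionEnzyme].
#' @return Sorted integer vector of 1-based match start positions
#'   (empty for an empty sequence).
#' @export
#' @examples
#' ddei <- RestrictionEnzyme("DdeI", "CTNAG", 1L)
#' findSites("CCTGAGGAG", ddei)  # HbA codon-6 context: one site
#' findSites("CCTGTGGAG", ddei)  # HbS context: none
findSites <- function(sequence, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  if (!nzchar(sequence)) return(integer(0))
  s <- .check_sequence(sequence)
  pat <- strsplit(enzyme@recognition, "")[[1]]
  m <- length(pat)
  L <- length(s)
  if (L < m) return(integer(0))
  ok <- rep(TRUE, L - m + 1L)
  for (k in seq_len(m)) {
    code <- pat[k]
    sub <- s[k:(L - m + k)]
    hit <- sub %in% .IUPAC[[code]]
    if (code == "N") hit <- hit | sub == "N"
    ok <- ok & hit
  }
  which(ok)
}

#' Predict restriction fragment lengths
#'
#' Cuts the sequence at every recognition-site match (cut placed
#' `cutOffset` bases into the site) and returns the ordered fragment
#' lengths. Fragments always partition the sequence: their lengths sum
#' to the sequence length and there is one more fragment than distinct
#' cut positions.
#'
#' @inheritParams findSites
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @export
#' @examples
#' ddei <- RestrictionEnzyme("DdeI", "CTNAG", 1L)
#' digestSequence("CCTGAGGAG", ddei)
digestSequence <- function(sequence, enzyme) {
  L <- nchar(sequence)
  sites <- findSites(sequence, enzyme)
  cuts <- sort(unique(sites - 1L + enzyme@cutOffset))
  cuts <- cuts[cuts > 0L & cuts < L]
  diff(c(0L, cuts, L))
}

#' Call cut/uncut state of one restriction locus
#'
#' A locus is called `"+"` (site present) iff at least one recognition
#' match starts within the locus window; matches may extend past the
#' window end. Windows are 1-based inclusive.
#'
#' @inheritParams findSites
#' @param window Length-2 integer vector `c(start, end)`, 1-based
#'   inclusive, within the sequence bounds.
#' @param locus Optional locus label carried into the result.
#' @return A list with elements `locus`, `state` (`"+"` or `"-"`) and
#'   `evidence` (match start positions inside the window).
#' @export
#' @examples
#' ddei <- RestrictionEnzyme("DdeI", "CTNAG", 1L)
#' callSiteState("CCCCTGAGCCC", c(3, 9), ddei)$state
callSiteState <- function(sequence, window, enzyme, locus = NA_character_) {
  stopifnot(length(window) == 2L)
  L <- nchar(sequence)
  if (window[1] < 1L || window[2] > L || window[1] > window[2])
    stop("locus window out of sequence bounds")
  sites <- findSites(sequence, enzyme)
  ev <- sites[sites >= window[1] & sites <= window[2]]
  list(locus = locus, state = if (length(ev)) "+" else "-", evidence = ev)
}

#' Genotype HbS from two codon-6 DdeI calls
#'
#' The rs334 A allele (HbA) retains the DdeI site at HBB codon 6
#' (`"+"`); the T allele (HbS) destroys it (`"-"`). The call is
#' symmetric in its two arguments; any missing state yields
#' `"unknown"`.
#'
#' @param state1,state2 Per-chromosome codon-6 DdeI states, `"+"`,
#'   `"-"` or `NA`.
#' @return `"HbAA"`, `"HbAS"`, `"HbSS"` or `"unknown"`.
#' @export
#' @examples
#' genotypeHbs("+", "+")
#' genotypeHbs("+", "-")
genotypeHbs <- function(state1, state2) {
  states <- c(state1, state2)
  if (anyNA(states) || !all(states %in% c("+", "-"))) return("unknown")
  n_s <- sum(states == "-")
  c("HbAA", "HbAS", "HbSS")[n_s + 1L]
}
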