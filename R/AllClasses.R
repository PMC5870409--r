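#' @import methods
NULL

#' RestrictionEnzyme: a recognition pattern and cut offset
#'
#' Models one restriction endonuclease by its IUPAC recognition pattern
#' and the offset (in bases from the start of the recognition site) at
#' which the enzyme cuts the top strand. Scanning is single-strand, with
#' patterns supplied in the orientation of the reference strand, so
#' palindromic sites (HindIII AAGCTT) are counted once.
#'
#' @slot name Enzyme name, e.g. `"DdeI"`.
#' @slot recognition IUPAC pattern, e.g. `"CTNAG"`.
#' @slot cutOffset Integer offset of the cut within the site,
#'   `0 <= cutOffset <= nchar(recognition)`.
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  rec <- object@recognition
  if (length(rec) != 1L || !nzchar(rec))
    msg <- c(msg, "recognition must be a single non-empty string")
  else if (!all(strsplit(rec, "")[[1]] %in% names(.IUPAC)))
    msg <- c(msg, "recognition contains non-IUPAC characters")
  if (length(object@cutOffset) != 1L || is.na(object@cutOffset) ||
      object@cutOffset < 0L || object@cutOffset > nchar(rec))
    msg <- c(msg, "cutOffset must lie within [0, pattern length]")
  if (length(msg)) msg else TRUE
})

#' @rdname RestrictionEnzyme-class
#' @param name,recognition,cutOffset See slots.
#' @return A `RestrictionEnzyme` object.
#' @export
#' @examples
#' RestrictionEnzyme("DdeI", "CTNAG", 1L)
RestrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = name, recognition = toupper(recognition),
      cutOffset = as.integer(cutOffset))
}

#' HaplotypeTable: five-site patterns defining beta-globin haplotypes
#'
#' Maps classical haplotype labels (Benin, Bantu/CAR, Senegal, Cameroon,
#' Arab-Indian) and optionally named atypical subtypes to five-site
#' cut/uncut patterns over the loci in [RFLP_LOCI]. Patterns are strings
#' over `+` (site present, cut) and `-` (site absent). The table is
#' versioned configuration, not a constant: the generator and the
#' classifier must always be bound to the same table.
#'
#' @slot loci The five locus names, in fixed order.
#' @slot classical Named character vector of classical patterns.
#' @slot atypical Named character vector of atypical subtype patterns
#'   (possibly empty).
#' @slot version Version tag of the table.
#' @export
setClass("HaplotypeTable",
  representation(loci = "character", classical = "character",
                 atypical = "character", version = "character"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  if (length(object@loci) != 5L)
    msg <- c(msg, "exactly five loci required")
  pats <- c(object@classical, object@atypical)
  if (!length(object@classical))
    msg <- c(msg, "at least one classical haplotype required")
  if (is.null(names(pats)) || any(!nzchar(names(pats))))
    msg <- c(msg, "all patterns must be named")
  if (any(nchar(pats) != 5L))
    msg <- c(msg, "all patterns must have five states")
  if (any(!grepl("^[+-]+$", pats)))
    msg <- c(msg, "patterns may contain only '+' and '-'")
  if (anyDuplicated(pats))
    msg <- c(msg, "patterns must be pairwise distinct")
  if (anyDuplicated(names(pats)))
    msg <- c(msg, "haplotype labels must be distinct")
  if (length(msg)) msg else TRUE
})

#' CohortSpec: parameters of one simulated population cohort
#'
#' Describes a diploid cohort: its size, HbS (rs334) allele frequency,
#' the mixture of beta-globin haplotype backgrounds, and the minor
#' allele frequencies of unlinked marker SNPs (by role label, e.g.
#' `"ABO_proxy"`). Marker genotypes are drawn under exact Hardy-Weinberg
#' equilibrium; haplotype backgrounds and the HbS allele are drawn
#' independently.
#'
#' @slot populationName Cohort label.
#' @slot nIndividuals Number of diploid individuals (>= 1).
#' @slot hbsAlleleFreq HbS allele frequency in `[0, 1]`.
#' @slot haplotypeMixture Named proportions over haplotype labels,
#'   summing to 1.
#' @slot snpMafs Named MAFs in `[0, 0.5]` for the marker SNPs.
#' @slot seed Integer seed making the draw reproducible.
#' @export
setClass("CohortSpec",
  representation(populationName = "character", nIndividuals = "integer",
                 hbsAlleleFreq = "numeric", haplotypeMixture = "numeric",
                 snpMafs = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@populationName) != 1L || !nzchar(object@populationName))
    msg <- c(msg, "populationName must be a single non-empty string")
  if (length(object@nIndividuals) != 1L || is.na(object@nIndividuals) ||
      object@nIndividuals < 1L)
    msg <- c(msg, "nIndividuals must be >= 1")
  if (!.is_prob(object@hbsAlleleFreq) || length(object@hbsAlleleFreq) != 1L)
    msg <- c(msg, "hbsAlleleFreq must be a single value in [0, 1]")
  mix <- object@haplotypeMixture
  if (!length(mix) || is.null(names(mix)) || any(!nzchar(names(mix))))
    msg <- c(msg, "haplotypeMixture must be a non-empty named vector")
  else {
    if (!.is_prob(mix)) msg <- c(msg, "mixture proportions must lie in [0, 1]")
    if (abs(sum(mix) - 1) > 1e-9)
      msg <- c(msg, "mixture proportions must sum to 1")
  }
  mafs <- object@snpMafs
  if (length(mafs)) {
    if (is.null(names(mafs)) || any(!nzchar(names(mafs))))
      msg <- c(msg, "snpMafs must be named")
    if (!.is_prob(mafs) || any(mafs > 0.5))
      msg <- c(msg, "snpMafs must lie in [0, 0.5]")
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortSpec-class
#' @param populationName,nIndividuals,hbsAlleleFreq,haplotypeMixture,snpMafs,seed
#'   See slots.
#' @return A `CohortSpec`.
#' @export
CohortSpec <- function(populationName, nIndividuals, hbsAlleleFreq,
                       haplotypeMixture, snpMafs = numeric(), seed = 1L) {
  new("CohortSpec", populationName = populationName,
      nIndividuals = as.integer(nIndividuals),
      hbsAlleleFreq = hbsAlleleFreq, haplotypeMixture = haplotypeMixture,
      snpMafs = snpMafs, seed = as.integer(seed))
}

#' ClineSpec: cohorts ordered along a geographic axis
#'
#' An ordered series of [CohortSpec] objects, equatorial to southern,
#' whose per-SNP MAF sequences form the allele-frequency gradient the
#' cline trend test probes. All cohorts must carry the same marker SNP
#' roles.
#'
#' @slot specs List of `CohortSpec`, in fixed geographic order.
#' @export
setClass("ClineSpec", representation(specs = "list"))

setValidity("ClineSpec", function(object) {
  msg <- character()
  if (length(object@specs) < 2L)
    msg <- c(msg, "at least two populations required")
  if (!all(vapply(object@specs, is, logical(1), "CohortSpec")))
    msg <- c(msg, "all elements must be CohortSpec objects")
  else {
    snps <- lapply(object@specs, function(s) names(s@snpMafs))
    if (length(unique(vapply(snps, paste, character(1), collapse = ","))) != 1L)
      msg <- c(msg, "all cohorts must share the same marker SNP roles")
    labs <- vapply(object@specs, function(s) s@populationName, character(1))
    if (anyDuplicated(labs)) msg <- c(msg, "population names must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ClineSpec-class
#' @param specs Ordered list of `CohortSpec`.
#' @return A `ClineSpec`.
#' @export
ClineSpec <- function(specs) new("ClineSpec", specs = specs)

#' RegionSpec: geometry of a simulated phased haplotype panel
#'
#' Parameters of the block-copy panel simulator: a window (default
#' 100 kb, mimicking a region around HBB), marker count, a core marker
#' index, recombination breakpoints splitting markers into blocks, the
#' number of founder haplotypes copied within each block, and the panel
#' size in chromosomes.
#'
#' @slot windowLength Window length in bases.
#' @slot nMarkers Number of biallelic markers (>= 2).
#' @slot coreIndex 1-based index of the core marker.
#' @slot breakpoints Strictly increasing marker indices `b`; a block
#'   boundary falls between markers `b` and `b + 1`.
#' @slot foundersPerBlock Founder haplotypes per block (>= 2).
#' @slot nChromosomes Number of chromosomes in the panel (even).
#' @slot seed Integer seed.
#' @export
setClass("RegionSpec",
  representation(windowLength = "integer", nMarkers = "integer",
                 coreIndex = "integer", breakpoints = "integer",
                 foundersPerBlock = "integer", nChromosomes = "integer",
                 seed = "integer"))

setValidity("RegionSpec", function(object) {
  msg <- character()
  if (object@nMarkers < 2L) msg <- c(msg, "nMarkers must be >= 2")
  if (object@windowLength < object@nMarkers)
    msg <- c(msg, "windowLength must be >= nMarkers")
  if (object@coreIndex < 1L || object@coreIndex > object@nMarkers)
    msg <- c(msg, "coreIndex must lie in [1, nMarkers]")
  bp <- object@breakpoints
  if (length(bp)) {
    if (any(diff(bp) <= 0L)) msg <- c(msg, "breakpoints must be strictly increasing")
    if (any(bp < 1L) || any(bp >= object@nMarkers))
      msg <- c(msg, "breakpoints must lie in [1, nMarkers - 1]")
  }
  if (object@foundersPerBlock < 2L)
    msg <- c(msg, "foundersPerBlock must be >= 2")
  if (object@nChromosomes < 2L || object@nChromosomes %% 2L != 0L)
    msg <- c(msg, "nChromosomes must be an even number >= 2")
  if (length(msg)) msg else TRUE
})

#' @rdname RegionSpec-class
#' @param windowLength,nMarkers,coreIndex,breakpoints,foundersPerBlock,nChromosomes,seed
#'   See slots.
#' @return A `RegionSpec`.
#' @export
RegionSpec <- function(nMarkers, nChromosomes, windowLength = 100000L,
                       coreIndex = max(1L, nMarkers %/% 2L),
                       breakpoints = integer(), foundersPerBlock = 2L,
                       seed = 1L) {
  new("RegionSpec", windowLength = as.integer(windowLength),
      nMarkers = as.integer(nMarkers), coreIndex = as.integer(coreIndex),
      breakpoints = as.integer(breakpoints),
      foundersPerBlock = as.integer(foundersPerBlock),
      nChromosomes = as.integer(nChromosomes), seed = as.integer(seed))
}

#' Cohort: realized chromosomes of one simulated population
#'
#' One row per chromosome (two per individual), carrying the assigned
#' haplotype label, the five realized RFLP site states, the rs334 allele
#' (`"A"` = HbA, site present; `"T"` = HbS, DdeI site lost) and one
#' allele (0 = major, 1 = minor) per marker SNP.
#'
#' @slot population Population label.
#' @slot chromosomes `data.frame` with columns `individual`,
#'   `chromosome`, `haplotype`, the five [RFLP_LOCI] state columns,
#'   `hbs`, and one column per marker SNP.
#' @slot markers Character vector of marker SNP role labels.
#' @export
setClass("Cohort",
  representation(population = "character", chromosomes = "data.frame",
                 markers = "character"))

setValidity("Cohort", function(object) {
  msg <- character()
  df <- object@chromosomes
  need <- c("individual", "chromosome", "haplotype", RFLP_LOCI, "hbs",
            object@markers)
  miss <- setdiff(need, names(df))
  if (length(miss))
    msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
  else {
    if (nrow(df) == 0L || nrow(df) %% 2L != 0L)
      msg <- c(msg, "chromosome rows must come in pairs")
    if (!all(table(df$individual) == 2L))
      msg <- c(msg, "each individual must contribute exactly two chromosomes")
    states <- unlist(df[RFLP_LOCI], use.names = FALSE)
    if (!all(states %in% c("+", "-") | is.na(states)))
      msg <- c(msg, "site states must be '+', '-' or NA")
    if (!all(df$hbs %in% c("A", "T") | is.na(df$hbs)))
      msg <- c(msg, "hbs alleles must be 'A' or 'T'")
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypePanel: genotypes at ordered biallelic markers
#'
#' Phased panels hold one row per chromosome with alleles coded 0/1
#' (NA = missing); unphased panels hold one row per individual with
#' minor-allele dosages 0/1/2. Marker positions are 1-based and strictly
#' increasing within the chromosome.
#'
#' @slot markers `data.frame` with columns `label`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @slot genotypes Integer matrix, rows = chromosomes (phased) or
#'   individuals (unphased), columns = markers.
#' @slot phased Logical scalar.
#' @slot populations Population label per row.
#' @slot individuals Individual id per row (each id on two rows when
#'   phased).
#' @export
setClass("HaplotypePanel",
  representation(markers = "data.frame", genotypes = "matrix",
                 phased = "logical", populations = "character",
                 individuals = "character"))

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  mk <- object@markers
  need <- c("label", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mk)))
    msg <- c(msg, "markers needs columns label, chrom, pos, ref, alt")
  else {
    for (ch in unique(mk$chrom)) {
      pos <- mk$pos[mk$chrom == ch]
      if (any(diff(pos) <= 0))
        msg <- c(msg, "positions must be strictly increasing within a chromosome")
    }
    if (anyDuplicated(mk$label)) msg <- c(msg, "marker labels must be distinct")
  }
  g <- object@genotypes
  if (ncol(g) != nrow(mk))
    msg <- c(msg, "genotype columns must match marker rows")
  top <- if (isTRUE(object@phased)) 1L else 2L
  vals <- g[!is.na(g)]
  if (length(vals) && (any(vals < 0L) || any(vals > top)))
    msg <- c(msg, sprintf("genotype codes must lie in 0..%d or NA", top))
  if (length(object@populations) != nrow(g))
    msg <- c(msg, "one population label per row required")
  if (length(object@individuals) != nrow(g))
    msg <- c(msg, "one individual id per row required")
  if (length(msg)) msg else TRUE
})

#' @rdname HaplotypePanel-class
#' @param markers,genotypes,phased,populations,individuals See slots.
#' @return A `HaplotypePanel`.
#' @export
HaplotypePanel <- function(markers, genotypes, phased,
                           populations = rep("pop", nrow(genotypes)),
                           individuals = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(individuals)) {
    n <- nrow(genotypes)
    individuals <- if (phased)
      paste0("ind", rep(seq_len(ceiling(n / 2)), each = 2))[seq_len(n)]
    else paste0("ind", seq_len(n))
  }
  new("HaplotypePanel", markers = markers, genotypes = genotypes,
      phased = phased, populations = populations, individuals = individuals)
}

#' BifurcationTree: haplotype bifurcation rooted at a core allele
#'
#' A tree whose root is the set of chromosomes carrying a chosen allele
#' at a core marker; each level moves one marker further from the core
#' (proximal or distal) and a node splits when both alleles occur among
#' its haplotypes. Node counts drive line thickness in bifurcation
#' diagrams; chromosomes with missing alleles are dropped at the depth
#' where the gap occurs and logged.
#'
#' @slot coreMarker Core marker label.
#' @slot coreAllele Core allele (0 or 1).
#' @slot direction `"distal"` (increasing position) or `"proximal"`.
#' @slot rootCount Number of chromosomes carrying the core allele.
#' @slot nodes `data.frame` with columns `id`, `parent` (0 = root),
#'   `depth`, `allele`, `count`.
#' @slot dropped `data.frame` with columns `depth`, `count` of
#'   haplotypes excluded for missing data.
#' @export
setClass("BifurcationTree",
  representation(coreMarker = "character", coreAllele = "integer",
                 direction = "character", rootCount = "integer",
                 nodes = "data.frame", dropped = "data.frame"))

setValidity("BifurcationTree", function(object) {
  msg <- character()
  if (!object@direction %in% c("proximal", "distal"))
    msg <- c(msg, "direction must be 'proximal' or 'distal'")
  nd <- object@nodes
  if (nrow(nd)) {
    if (!all(c("id", "parent", "depth", "allele", "count") %in% names(nd)))
      msg <- c(msg, "nodes needs columns id, parent, depth, allele, count")
    else if (anyDuplicated(nd$id))
      msg <- c(msg, "node ids must be distinct")
  }
  if (length(msg)) msg else TRUE
})
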