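# Synthetic data: cohorts with haplotype backgrounds, HbS alleles and
# marker SNPs; amplicon-style sequences realizing RFLP states; and
# phased panels with block-structured LD. The generator defines the
# conditions every downstream stage is tested under; its defaults are
# documented in the methods vignette and are not tuned per analysis.

# Window sequences realizing cut/uncut states for each locus. Single
# base substitutions keep cut and uncut variants the same length, so
# window coordinates are identical across chromosomes. The codon-6
# windows are the true HBB codon 5-7 contexts (CCTGAGGAG / CCTGTGGAG).
.TEMPLATE_VARIANTS <- list(
  XmnI_5Gg    = list(cut = "GAACCCCTTC", uncut = "GAACCCCTTG"),
  HindIII_Gg  = list(cut = "AAGCTT",     uncut = "AAGCTG"),
  HindIII_Ag  = list(cut = "AAGCTT",     uncut = "AAGCTG"),
  HincII_3psb = list(cut = "GTCAAC",     uncut = "GTCAAG"),
  HinfI_5b    = list(cut = "GACTC",      uncut = "GACTG"),
  DdeI_codon6 = list(cut = "CCTGAGGAG",  uncut = "CCTGTGGAG")
)

#' Amplicon template for emitting per-chromosome sequences
#'
#' Builds the template used by [emitSequences()]: an ordered set of
#' locus windows (the five RFLP loci plus the codon-6 DdeI locus), each
#' holding a cut or uncut local sequence variant, separated by inert
#' C-run spacers that cannot complete a recognition site. Windows are
#' 1-based inclusive and identical for every chromosome.
#'
#' @param spacer Spacer sequence placed between (and around) windows.
#' @return A list with `windows` (`data.frame` of `locus`, `enzyme`,
#'   `start`, `end`), `variants` (per-locus cut/uncut sequences) and
#'   `length` (total sequence length).
#' @export
#' @examples
#' rflpTemplate()$windows
rflpTemplate <- function(spacer = strrep("C", 10)) {
  loci <- names(.TEMPLATE_VARIANTS)
  pos <- nchar(spacer)
  rows <- lapply(loci, function(locus) {
    w <- nchar(.TEMPLATE_VARIANTS[[locus]]$cut)
    r <- data.frame(locus = locus, enzyme = .LOCUS_ENZYME[[locus]],
                    start = pos + 1L, end = pos + w,
                    stringsAsFactors = FALSE)
    pos <<- pos + w + nchar(spacer)
    r
  })
  list(windows = do.call(rbind, rows), variants = .TEMPLATE_VARIANTS,
       spacer = spacer, length = pos)
}

#' Construct a cohort from explicit per-chromosome assignments
#'
#' Deterministic low-level constructor behind [simulateCohort()], also
#' useful to build cohorts with exact haplotype and HbS counts. RFLP
#' states are realized from the haplotype table: every chromosome's
#' profile equals the pattern of its assigned label.
#'
#' @param populationName Cohort label.
#' @param haplotypeLabels Haplotype label per chromosome (length
#'   `2 * n`); all labels must exist in `table`.
#' @param hbsAlleles rs334 allele per chromosome, `"A"` (HbA) or `"T"`
#'   (HbS); recycled if length 1.
#' @param markerAlleles Optional integer matrix (chromosomes x marker
#'   SNPs, values 0/1) with column names naming the SNP roles.
#' @param table A [HaplotypeTable].
#' @return A [Cohort].
#' @export
#' @examples
#' co <- makeCohort("toy", rep("Benin", 4), "A")
#' chromosomes(co)
makeCohort <- function(populationName, haplotypeLabels, hbsAlleles = "A",
                       markerAlleles = NULL,
                       table = defaultHaplotypeTable()) {
  nChrom <- length(haplotypeLabels)
  if (nChrom < 2L || nChrom %% 2L != 0L)
    stop("haplotypeLabels must have an even, positive length")
  if (length(hbsAlleles) == 1L) hbsAlleles <- rep(hbsAlleles, nChrom)
  known <- haplotypeLabels %in% haplotypeLabels(table)
  if (!all(known))
    stop("unknown haplotype label: '",
         haplotypeLabels[which(!known)[1]], "'")
  pats <- t(vapply(haplotypeLabels, function(l) patternFor(table, l),
                   character(5)))
  colnames(pats) <- RFLP_LOCI
  df <- data.frame(
    individual = sprintf("%s_ind%04d", populationName,
                         rep(seq_len(nChrom / 2L), each = 2L)),
    chromosome = rep(1:2, nChrom / 2L),
    haplotype = haplotypeLabels,
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(pats, stringsAsFactors = FALSE))
  df$hbs <- hbsAlleles
  markerNames <- character()
  if (!is.null(markerAlleles)) {
    markerAlleles <- as.matrix(markerAlleles)
    if (nrow(markerAlleles) != nChrom)
      stop("markerAlleles must have one row per chromosome")
    markerNames <- colnames(markerAlleles)
    df <- cbind(df, as.data.frame(markerAlleles))
  }
  rownames(df) <- NULL
  new("Cohort", population = populationName, chromosomes = df,
      markers = markerNames)
}

#' Simulate a diploid cohort
#'
#' Draws `2 * nIndividuals` chromosomes: haplotype labels from the
#' mixture, HbS alleles binomially at the HbS allele frequency, and one
#' allele per marker SNP binomially at its MAF (allele-level draws, so
#' marker genotypes are in exact Hardy-Weinberg proportions). The draw
#' is byte-reproducible given the spec's seed.
#'
#' @param spec A [CohortSpec].
#' @param table A [HaplotypeTable]; every mixture label must exist in
#'   it.
#' @return A [Cohort].
#' @export
#' @examples
#' spec <- CohortSpec("demo", 5, 0.1, c(Benin = 1), seed = 7)
#' simulateCohort(spec)
simulateCohort <- function(spec, table = defaultHaplotypeTable()) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  mix <- spec@haplotypeMixture
  unknown <- setdiff(names(mix), haplotypeLabels(table))
  if (length(unknown))
    stop("unknown haplotype label: '", unknown[1], "'")
  nChrom <- 2L * spec@nIndividuals
  withr::with_seed(spec@seed, {
    labs <- sample(names(mix), nChrom, replace = TRUE, prob = mix)
    hbs <- c("A", "T")[stats::rbinom(nChrom, 1L, spec@hbsAlleleFreq) + 1L]
    mk <- NULL
    if (length(spec@snpMafs)) {
      mk <- vapply(spec@snpMafs, function(m)
        stats::rbinom(nChrom, 1L, m), integer(nChrom))
      colnames(mk) <- names(spec@snpMafs)
    }
  })
  makeCohort(spec@populationName, labs, hbs, mk, table)
}

#' Emit per-chromosome sequences realizing RFLP states
#'
#' For each chromosome, assembles a sequence in which every RFLP locus
#' window carries the cut variant iff the chromosome's state is `"+"`,
#' and the codon-6 window carries the HbA context iff the rs334 allele
#' is `"A"`. Digesting emitted sequences with [digestCohort()]
#' reproduces the cohort's profiles and HbS alleles exactly.
#'
#' @param cohort A [Cohort] (no missing states).
#' @param template A template from [rflpTemplate()].
#' @return A [Biostrings::DNAStringSet], one sequence per chromosome,
#'   named `<individual>_h<chromosome>`.
#' @export
#' @examples
#' co <- makeCohort("toy", c("Benin", "Benin"), "A")
#' emitSequences(co)
emitSequences <- function(cohort, template = rflpTemplate()) {
  stopifnot(is(cohort, "Cohort"))
  df <- chromosomes(cohort)
  loci <- template$windows$locus
  need <- c(RFLP_LOCI, "DdeI_codon6")
  miss <- setdiff(need, loci)
  if (length(miss))
    stop("template lacks a window for locus: ", miss[1])
  states <- as.matrix(df[RFLP_LOCI])
  if (anyNA(states) || anyNA(df$hbs))
    stop("cannot emit sequences for chromosomes with missing states")
  seqs <- vapply(seq_len(nrow(df)), function(i) {
    parts <- vapply(loci, function(locus) {
      v <- template$variants[[locus]]
      if (locus == "DdeI_codon6") {
        if (df$hbs[i] == "A") v$cut else v$uncut
      } else if (states[i, locus] == "+") v$cut else v$uncut
    }, character(1))
    paste0(template$spacer,
           paste(parts, collapse = template$spacer), template$spacer)
  }, character(1))
  names(seqs) <- paste0(df$individual, "_h", df$chromosome)
  Biostrings::DNAStringSet(seqs)
}

#' Digest emitted sequences back into RFLP profiles and HbS calls
#'
#' Scans each sequence's locus windows with the corresponding enzymes
#' and returns per-chromosome site states plus the rs334 allele implied
#' by the codon-6 DdeI call (`"+"` = A/HbA, `"-"` = T/HbS).
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character
#'   vector, as produced by [emitSequences()].
#' @param template The template the sequences were emitted from.
#' @param enzymes Named list of [RestrictionEnzyme] objects covering
#'   the template's enzymes.
#' @return `data.frame` with columns `sequence`, `individual`,
#'   `chromosome`, the five [RFLP_LOCI] states, `DdeI_codon6` and
#'   `hbs`.
#' @export
#' @examples
#' co <- makeCohort("toy", c("Benin", "Benin"), c("A", "T"))
#' digestCohort(emitSequences(co))
digestCohort <- function(sequences, template = rflpTemplate(),
                         enzymes = defaultEnzymes()) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  w <- template$windows
  miss <- setdiff(unique(w$enzyme), names(enzymes))
  if (length(miss))
    stop("no enzyme definition for: ", paste(miss, collapse = ", "))
  states <- t(vapply(seqs, function(s) {
    vapply(seq_len(nrow(w)), function(k)
      callSiteState(s, c(w$start[k], w$end[k]), enzymes[[w$enzyme[k]]],
                    locus = w$locus[k])$state,
      character(1))
  }, character(nrow(w))))
  colnames(states) <- w$locus
  m <- regmatches(names(seqs), regexec("^(.*)_h([12])$", names(seqs)))
  ind <- vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                character(1))
  chr <- vapply(m, function(x) if (length(x)) as.integer(x[3]) else NA_integer_,
                integer(1))
  out <- data.frame(sequence = names(seqs), individual = ind,
                    chromosome = chr, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(states, stringsAsFactors = FALSE))
  out$hbs <- ifelse(out$DdeI_codon6 == "+", "A", "T")
  rownames(out) <- NULL
  out
}

#' Simulate a phased panel with block-structured LD
#'
#' Block-copy model: markers are split into blocks at the spec's
#' recombination breakpoints; each block holds a small set of founder
#' haplotypes (pairwise distinct, every marker polymorphic across
#' founders); each chromosome picks one founder per block independently
#' and uniformly. Within a block only founder patterns occur; across
#' breakpoints combinations are randomized, so between-block LD decays
#' to sampling noise while within-block LD is complete for two
#' founders.
#'
#' @param spec A [RegionSpec].
#' @return A phased [HaplotypePanel].
#' @export
#' @examples
#' simulateRegionPanel(RegionSpec(nMarkers = 6, nChromosomes = 20,
#'                                breakpoints = 3L, seed = 1))
simulateRegionPanel <- function(spec) {
  stopifnot(is(spec, "RegionSpec"))
  validObject(spec)
  M <- spec@nMarkers
  N <- spec@nChromosomes
  blockOf <- findInterval(seq_len(M) - 1L, c(0L, spec@breakpoints)) # 1..B
  nBlocks <- max(blockOf)
  withr::with_seed(spec@seed, {
    pos <- sort(sample.int(spec@windowLength, M))
    geno <- matrix(0L, N, M)
    for (b in seq_len(nBlocks)) {
      cols <- which(blockOf == b)
      F <- spec@foundersPerBlock
      founders <- matrix(stats::rbinom(F * length(cols), 1L, 0.5),
                         F, length(cols))
      # every marker polymorphic across founders; founders distinct
      for (j in seq_along(cols))
        if (length(unique(founders[, j])) == 1L)
          founders[1L + (j %% F), j] <- 1L - founders[1L + (j %% F), j]
      while (anyDuplicated(keys <- apply(founders, 1, paste, collapse = ""))) {
        dup <- which(duplicated(keys))[1]
        j <- sample.int(length(cols), 1L)
        founders[dup, j] <- 1L - founders[dup, j]
        if (length(unique(founders[, j])) == 1L)
          founders[1L + (dup %% F), j] <- 1L - founders[1L + (dup %% F), j]
      }
      pick <- sample.int(F, N, replace = TRUE)
      geno[, cols] <- founders[pick, , drop = FALSE]
    }
  })
  mk <- data.frame(label = sprintf("snp%03d", seq_len(M)), chrom = "11",
                   pos = pos, ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  HaplotypePanel(mk, geno, phased = TRUE,
                 populations = rep("synthetic", N))
}

#' Default six-population cline specification
#'
#' An ordered series of cohorts, equatorial to southern, in which the
#' ABO- and HBB-proxy marker SNPs decrease in steps of 0.05 (0.30 down
#' to 0.05) while the MARVELD3-proxy MAF stays flat at 0.25 — the
#' gradient / no-gradient contrast the cline trend test is designed to
#' detect. HbS allele frequencies also decrease southwards.
#'
#' @param nIndividuals Individuals per cohort.
#' @param seed Master seed; per-cohort seeds are derived from it.
#' @return A [ClineSpec].
#' @export
#' @examples
#' defaultClineSpec(nIndividuals = 50)
defaultClineSpec <- function(nIndividuals = 500L, seed = 1L) {
  popNames <- c("equatorial-1", "equatorial-2", "equatorial-3",
                "southern-1", "southern-2", "southern-3")
  abo <- seq(0.30, 0.05, by = -0.05)
  hbb <- seq(0.30, 0.05, by = -0.05)
  marveld3 <- rep(0.25, 6)
  hbsf <- seq(0.10, 0.00, by = -0.02)
  mixture <- c(Benin = 0.20, Cameroon = 0.10, Bantu = 0.02,
               Senegal = 0.03, "atypical-I" = 0.35,
               "atypical-II" = 0.15, "atypical-IV" = 0.15)
  specs <- lapply(seq_along(popNames), function(i)
    CohortSpec(popNames[i], nIndividuals, hbsf[i], mixture,
               snpMafs = c(ABO_proxy = abo[i], HBB_proxy = hbb[i],
                           MARVELD3_proxy = marveld3[i]),
               seed = deriveSeed(seed, popNames[i])))
  ClineSpec(specs)
}

#' Simulate all cohorts of a cline
#'
#' @param cline A [ClineSpec].
#' @param table A [HaplotypeTable].
#' @return Named list of [Cohort] objects, in geographic order.
#' @export
simulateCline <- function(cline, table = defaultHaplotypeTable()) {
  stopifnot(is(cline, "ClineSpec"))
  cohorts <- lapply(cline@specs, simulateCohort, table = table)
  names(cohorts) <- vapply(cline@specs, function(s) s@populationName,
                           character(1))
  cohorts
}

#' Genotype counts of a cohort marker SNP
#'
#' Collapses the two chromosome rows of each individual into a
#' biallelic genotype and counts major homozygotes, heterozygotes and
#' minor homozygotes.
#'
#' @param cohort A [Cohort].
#' @param marker Marker SNP role label present in the cohort.
#' @return Integer vector `c(nAA, nAa, naa)` (AA = major homozygote).
#' @export
cohortGenotypeCounts <- function(cohort, marker) {
  df <- chromosomes(cohort)
  if (!marker %in% markers(cohort))
    stop("unknown marker: ", marker)
  dose <- tapply(df[[marker]], df$individual, sum)
  c(nAA = sum(dose == 0L), nAa = sum(dose == 1L), naa = sum(dose == 2L))
}

#' HbS genotype frequencies of a digested cohort
#'
#' Applies [genotypeHbs()] to the two codon-6 DdeI states of each
#' individual and tabulates genotype counts and percentages.
#'
#' @param digested Output of [digestCohort()] (or any `data.frame` with
#'   `individual` and `DdeI_codon6` columns).
#' @return A list with `counts` (named HbAA/HbAS/HbSS/unknown),
#'   `percent`, `n` and the estimated HbS allele frequency
#'   `hbsAlleleFreq` (over classified individuals).
#' @export
hbsGenotypeTable <- function(digested) {
  ids <- unique(digested$individual)
  geno <- vapply(ids, function(id) {
    st <- digested$DdeI_codon6[digested$individual == id]
    if (length(st) != 2L) "unknown" else genotypeHbs(st[1], st[2])
  }, character(1))
  lv <- c("HbAA", "HbAS", "HbSS", "unknown")
  counts <- table(factor(geno, levels = lv))
  known <- sum(counts[c("HbAA", "HbAS", "HbSS")])
  freqS <- if (known > 0)
    (counts[["HbAS"]] + 2 * counts[["HbSS"]]) / (2 * known) else NA_real_
  list(counts = counts,
       percent = round(100 * as.numeric(counts) / length(ids), 1),
       n = length(ids), hbsAlleleFreq = freqS)
}
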