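# End-to-end orchestration: simulate -> emit -> digest -> classify ->
# frequencies -> Fst -> cline trend -> LD -> blocks -> bifurcation,
# each stage writing plain-text artifacts under an output directory.
# All numeric outputs are reproduced byte-identically by a rerun with
# the same configuration.

#' Default pipeline configuration
#'
#' @param outDir Output directory.
#' @param seed Master seed; per-stage seeds are derived by stable
#'   hashing of stage names ([deriveSeed()]).
#' @param nIndividuals Individuals per cline cohort.
#' @param region Parameters of the simulated phased panel, as a
#'   [RegionSpec].
#' @param stages Character vector of stages to run (subset of
#'   `"simulate"`, `"digest"`, `"haplotype"`, `"popgen"`, `"ld"`,
#'   `"bifurcation"`).
#' @return A named list usable as `config` in [runPipeline()].
#' @export
defaultRunConfig <- function(outDir = tempfile("sickleHaps_run_"),
                             seed = 1L, nIndividuals = 100L,
                             region = NULL,
                             stages = c("simulate", "digest", "haplotype",
                                        "popgen", "ld", "bifurcation")) {
  if (is.null(region))
    region <- RegionSpec(nMarkers = 12L, nChromosomes = 200L,
                         coreIndex = 6L, breakpoints = c(4L, 8L),
                         seed = deriveSeed(seed, "region"))
  list(outDir = outDir, seed = as.integer(seed),
       nIndividuals = as.integer(nIndividuals), region = region,
       stages = stages,
       gabriel = list(ciLow = 0.70, ciHigh = 0.98, recombHigh = 0.90,
                      minStrongFrac = 0.95))
}

#' Run the full analysis pipeline
#'
#' Simulates the default six-population cline, emits and digests
#' sequences for the first cohort, classifies haplotypes and tabulates
#' frequencies and combinations for every cohort, computes per-SNP MAFs
#' with exact HWE p-values, the pairwise Fst matrices, the cline trend
#' per SNP, and, on a simulated phased panel, pairwise LD, Gabriel
#' blocks and bidirectional bifurcation trees with EHH curves. Every
#' stage writes TSV/JSON artifacts under `config$outDir`; a manifest
#' records the configuration and seeds. A rerun with the same config
#' reproduces all numeric outputs exactly.
#'
#' @param config A configuration list from [defaultRunConfig()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name) name %in% config$stages
  table <- defaultHaplotypeTable()

  if (stage("simulate")) {
    cline <- defaultClineSpec(nIndividuals = config$nIndividuals,
                              seed = deriveSeed(config$seed, "simulate"))
    res$cohorts <- simulateCline(cline, table)
    for (nm in names(res$cohorts))
      writeCohortTsv(res$cohorts[[nm]],
                     file.path(config$outDir, paste0("cohort_", nm, ".tsv")))
    res$cline <- cline
  }

  if (stage("digest")) {
    if (is.null(res$cohorts)) stop("stage 'digest' requires 'simulate'")
    co <- res$cohorts[[1]]
    seqs <- emitSequences(co)
    Biostrings::writeXStringSet(
      seqs, file.path(config$outDir, "sequences_pop1.fasta"))
    res$digested <- digestCohort(seqs)
    .write_tsv(res$digested, file.path(config$outDir, "profiles_pop1.tsv"))
    res$hbs <- hbsGenotypeTable(res$digested)
  }

  if (stage("haplotype")) {
    if (is.null(res$cohorts)) stop("stage 'haplotype' requires 'simulate'")
    freqRows <- list(); comboRows <- list()
    for (nm in names(res$cohorts)) {
      df <- chromosomes(res$cohorts[[nm]])
      calls <- classifyProfiles(df, table)
      hf <- haplotypeFrequencies(calls, "classical-vs-atypical",
                                 population = nm)
      hf$table$population <- nm
      freqRows[[nm]] <- hf$table
      pc <- pairCombinations(df$individual, calls)
      pc$table$population <- nm
      comboRows[[nm]] <- pc$table
    }
    res$haplotypeFreqs <- do.call(rbind, freqRows)
    res$combinations <- do.call(rbind, comboRows)
    rownames(res$haplotypeFreqs) <- rownames(res$combinations) <- NULL
    .write_tsv(res$haplotypeFreqs,
               file.path(config$outDir, "haplotype_frequencies.tsv"))
    .write_tsv(res$combinations,
               file.path(config$outDir, "haplotype_combinations.tsv"))
  }

  if (stage("popgen")) {
    if (is.null(res$cohorts)) stop("stage 'popgen' requires 'simulate'")
    snps <- markers(res$cohorts[[1]])
    rows <- list()
    mafm <- matrix(NA_real_, length(res$cohorts), length(snps),
                   dimnames = list(names(res$cohorts), snps))
    for (nm in names(res$cohorts)) {
      for (sn in snps) {
        cc <- cohortGenotypeCounts(res$cohorts[[nm]], sn)
        fr <- estimateFreq(cc[1], cc[2], cc[3])
        mafm[nm, sn] <- fr$maf
        rows[[paste(nm, sn)]] <- cbind(
          data.frame(population = nm, snp = sn, nAA = cc[1], nAa = cc[2],
                     naa = cc[3]), fr)
      }
    }
    res$freqTable <- do.call(rbind, rows)
    rownames(res$freqTable) <- NULL
    .write_tsv(res$freqTable, file.path(config$outDir, "freq_results.tsv"))
    res$fst <- fstMatrix(mafm)
    .write_tsv(cbind(population = rownames(res$fst$mean),
                     as.data.frame(res$fst$mean)),
               file.path(config$outDir, "fst_mean.tsv"))
    jsonlite::write_json(res$fst$perSnp,
                         file.path(config$outDir, "fst_per_snp.json"),
                         matrix = "rowmajor", digits = NA)
    res$trend <- lapply(snps, function(sn) clineTrend(mafm[, sn]))
    names(res$trend) <- snps
    jsonlite::write_json(res$trend, file.path(config$outDir, "trend.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (stage("ld") || stage("bifurcation")) {
    res$panel <- simulateRegionPanel(config$region)
    writeVcfPanel(res$panel, file.path(config$outDir, "panel.vcf"))
  }

  if (stage("ld")) {
    gb <- config$gabriel
    res$ldPairs <- ldPairs(res$panel, ciLow = gb$ciLow, ciHigh = gb$ciHigh,
                           recombHigh = gb$recombHigh)
    .write_tsv(res$ldPairs, file.path(config$outDir, "ld_pairs.tsv"))
    res$blocks <- gabrielBlocks(res$panel, ciLow = gb$ciLow,
                                ciHigh = gb$ciHigh,
                                recombHigh = gb$recombHigh,
                                minStrongFrac = gb$minStrongFrac,
                                pairs = res$ldPairs)
    jsonlite::write_json(res$blocks, file.path(config$outDir, "blocks.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (stage("bifurcation")) {
    core <- config$region@coreIndex
    res$trees <- list()
    for (al in c(0L, 1L)) for (dir in c("proximal", "distal")) {
      tr <- buildBifurcation(res$panel, core, al, dir)
      res$trees[[paste0("allele", al, "_", dir)]] <- tr
      treeToJSON(tr, file.path(config$outDir,
                               sprintf("bifurcation_allele%d_%s.json",
                                       al, dir)))
    }
    grids <- expand.grid(allele = 0:1, direction = c("proximal", "distal"),
                         stringsAsFactors = FALSE)
    res$ehh <- do.call(rbind, lapply(seq_len(nrow(grids)), function(k) {
      cv <- ehhCurve(res$panel, core, grids$allele[k], grids$direction[k])
      cv$allele <- grids$allele[k]
      cv$direction <- grids$direction[k]
      cv
    }))
    .write_tsv(res$ehh, file.path(config$outDir, "ehh.tsv"))
  }

  manifest <- list(
    package = "sickleHaps",
    version = as.character(utils::packageVersion("sickleHaps")),
    seed = config$seed, stages = config$stages,
    nIndividuals = config$nIndividuals,
    region = list(nMarkers = config$region@nMarkers,
                  nChromosomes = config$region@nChromosomes,
                  coreIndex = config$region@coreIndex,
                  breakpoints = config$region@breakpoints,
                  seed = config$region@seed),
    gabriel = config$gabriel)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
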