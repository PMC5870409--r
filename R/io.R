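# Formats: cohort TSV, minimal VCF writing for simulated panels, and a
# region-restricted VCF reader (vcfR behind the scenes). All on-disk
# coordinates are 1-based (VCF convention); regions are samtools-style
# chrom:start-end, 1-based inclusive.

#' Write a cohort as TSV
#'
#' One row per chromosome: individual id, chromosome index, haplotype
#' label, five site states, rs334 allele and marker alleles.
#'
#' @param cohort A [Cohort].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeCohortTsv <- function(cohort, path) {
  .write_tsv(chromosomes(cohort), path)
  invisible(path)
}

#' Write a haplotype panel as minimal VCF
#'
#' VCFv4.2 with GT-only FORMAT; phased panels write `a|b` genotypes,
#' unphased panels `a/b` dosage-compatible genotypes. Positions are the
#' panel's 1-based marker positions.
#'
#' @param panel A [HaplotypePanel].
#' @param path Output file (plain text).
#' @return The path, invisibly.
#' @export
writeVcfPanel <- function(panel, path) {
  mk <- markers(panel)
  g <- genotypes(panel)
  if (isPhased(panel)) {
    ids <- individuals(panel)[seq(1, nrow(g), by = 2)]
    gt <- vapply(seq_len(nrow(mk)), function(j) {
      a <- g[seq(1, nrow(g), by = 2), j]
      b <- g[seq(2, nrow(g), by = 2), j]
      paste0(ifelse(is.na(a), ".", a), "|", ifelse(is.na(b), ".", b))
    }, character(length(ids)))
  } else {
    ids <- individuals(panel)
    gt <- vapply(seq_len(nrow(mk)), function(j) {
      d <- g[, j]
      out <- rep("./.", length(d))
      out[!is.na(d) & d == 0L] <- "0/0"
      out[!is.na(d) & d == 1L] <- "0/1"
      out[!is.na(d) & d == 2L] <- "1/1"
      out
    }, character(length(ids)))
  }
  gt <- matrix(gt, ncol = nrow(mk))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=sickleHaps",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(mk)), function(j)
    paste(c(mk$chrom[j], mk$pos[j], mk$label[j], mk$ref[j], mk$alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t"),
    character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read biallelic SNPs of a VCF region into a panel
#'
#' Reads a (plain-text or bgzipped) VCF with `vcfR`, restricts it to a
#' samtools-style region (`chrom:start-end`, 1-based inclusive), drops
#' non-biallelic or non-SNP records (count reported to stderr) and
#' returns the genotypes as a [HaplotypePanel]. Phase is preserved: the
#' panel is phased iff every genotype uses the `|` separator.
#'
#' @param path VCF file.
#' @param region Region string; `NULL` keeps all records.
#' @param population Population label to attach to all rows.
#' @return A [HaplotypePanel] (zero-marker panel, with a message, when
#'   the region is empty).
#' @export
readVcfRegion <- function(path, region = NULL, population = "pop") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gtm <- vcfR::extract.gt(v, element = "GT")
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    rg <- parseRegion(region)
    pos <- as.integer(fix$POS)
    keep <- fix$CHROM == rg$chrom & pos >= rg$start & pos <= rg$end
  }
  snp <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L &
    nchar(fix$ALT) == 1L & fix$ALT %in% c("A", "C", "G", "T")
  nDropped <- sum(keep & !snp)
  if (nDropped > 0)
    message("readVcfRegion: dropped ", nDropped,
            " non-biallelic-SNP record(s)")
  keep <- keep & snp
  if (!any(keep)) {
    message("readVcfRegion: empty region")
    mk <- data.frame(label = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     stringsAsFactors = FALSE)
    return(HaplotypePanel(mk, matrix(integer(), 0, 0), phased = TRUE,
                          populations = character(),
                          individuals = character()))
  }
  fix <- fix[keep, , drop = FALSE]
  gtm <- gtm[keep, , drop = FALSE]
  ord <- order(fix$CHROM, as.integer(fix$POS))
  fix <- fix[ord, , drop = FALSE]
  gtm <- gtm[ord, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(
    fix$CHROM[is.na(ids) | ids == "."], ":", fix$POS[is.na(ids) | ids == "."])
  mk <- data.frame(label = ids, chrom = fix$CHROM,
                   pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                   stringsAsFactors = FALSE)
  phased <- all(grepl("\\|", gtm[!is.na(gtm)]))
  samples <- colnames(gtm)
  if (phased) {
    n <- 2L * length(samples)
    geno <- matrix(NA_integer_, n, nrow(mk))
    for (j in seq_len(nrow(mk))) {
      parts <- strsplit(gtm[j, ], "|", fixed = TRUE)
      a <- vapply(parts, function(p)
        if (length(p) == 2L && p[1] %in% c("0", "1"))
          as.integer(p[1]) else NA_integer_, integer(1))
      b <- vapply(parts, function(p)
        if (length(p) == 2L && p[2] %in% c("0", "1"))
          as.integer(p[2]) else NA_integer_, integer(1))
      geno[seq(1, n, by = 2), j] <- a
      geno[seq(2, n, by = 2), j] <- b
    }
    HaplotypePanel(mk, geno, phased = TRUE,
                   populations = rep(population, n),
                   individuals = rep(samples, each = 2))
  } else {
    geno <- matrix(NA_integer_, length(samples), nrow(mk))
    for (j in seq_len(nrow(mk))) {
      parts <- strsplit(gtm[j, ], "[/|]")
      geno[, j] <- vapply(parts, function(p) {
        if (length(p) != 2L || !all(p %in% c("0", "1")))
          return(NA_integer_)
        sum(as.integer(p))
      }, integer(1))
    }
    HaplotypePanel(mk, geno, phased = FALSE,
                   populations = rep(population, length(samples)),
                   individuals = samples)
  }
}

#' Write / read locus windows as TSV
#'
#' Locus windows (locus, enzyme, start, end; 1-based inclusive) as a
#' plain TSV, so digestion can run against user-configured amplicon
#' layouts: `readLocusWindows` returns a template-compatible list that
#' [digestCohort()] accepts directly (sequence emission additionally
#' needs per-locus variants, which only [rflpTemplate()] provides).
#'
#' @param windows A `data.frame` with columns `locus`, `enzyme`,
#'   `start`, `end` (e.g. `rflpTemplate()$windows`).
#' @param path TSV file.
#' @return `writeLocusWindows`: the path, invisibly;
#'   `readLocusWindows`: a list with element `windows`.
#' @export
writeLocusWindows <- function(windows, path) {
  stopifnot(all(c("locus", "enzyme", "start", "end") %in% names(windows)))
  .write_tsv(windows[c("locus", "enzyme", "start", "end")], path)
  invisible(path)
}

#' @rdname writeLocusWindows
#' @export
readLocusWindows <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "enzyme", "start", "end")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("locus window TSV lacks columns: ", paste(miss, collapse = ", "))
  if (any(w$start < 1L) || any(w$end < w$start))
    stop("locus windows must satisfy 1 <= start <= end")
  list(windows = w[need], variants = NULL)
}
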