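# Generics and accessors. Slots are never reached into directly by
# user code; these accessors are the supported surface.

#' @rdname Cohort-class
#' @param object A `Cohort`, `HaplotypePanel` or other package object.
#' @export
setGeneric("population", function(object) standardGeneric("population"))

#' @rdname Cohort-class
#' @export
setGeneric("chromosomes", function(object) standardGeneric("chromosomes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("isPhased", function(object) standardGeneric("isPhased"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("individuals", function(object) standardGeneric("individuals"))

#' @rdname BifurcationTree-class
#' @export
setGeneric("treeNodes", function(object) standardGeneric("treeNodes"))

#' @rdname BifurcationTree-class
#' @export
setGeneric("rootCount", function(object) standardGeneric("rootCount"))

#' @rdname HaplotypeTable-class
#' @export
setGeneric("haplotypeLabels", function(object) standardGeneric("haplotypeLabels"))

#' @rdname HaplotypeTable-class
#' @param label A haplotype label present in the table.
#' @export
setGeneric("patternFor", function(object, label) standardGeneric("patternFor"))

setMethod("population", "Cohort", function(object) object@population)
setMethod("chromosomes", "Cohort", function(object) object@chromosomes)
setMethod("markers", "Cohort", function(object) object@markers)
setMethod("markers", "HaplotypePanel", function(object) object@markers)
setMethod("genotypes", "HaplotypePanel", function(object) object@genotypes)
setMethod("isPhased", "HaplotypePanel", function(object) object@phased)
setMethod("populations", "HaplotypePanel", function(object) object@populations)
setMethod("individuals", "HaplotypePanel", function(object) object@individuals)
setMethod("treeNodes", "BifurcationTree", function(object) object@nodes)
setMethod("rootCount", "BifurcationTree", function(object) object@rootCount)

setMethod("haplotypeLabels", "HaplotypeTable", function(object)
  c(names(object@classical), names(object@atypical)))

setMethod("patternFor", "HaplotypeTable", function(object, label) {
  pats <- c(object@classical, object@atypical)
  if (!label %in% names(pats))
    stop("unknown haplotype label: '", label, "'")
  strsplit(pats[[label]], "")[[1]]
})

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: %s (cut offset %d)\n",
              object@name, object@recognition, object@cutOffset))
})

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable '%s': %d classical, %d atypical patterns\n",
              object@version, length(object@classical),
              length(object@atypical)))
  cat("  loci:", paste(object@loci, collapse = ", "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec '%s': %d individuals, HbS freq %.3f, %d marker SNPs\n",
              object@populationName, object@nIndividuals,
              object@hbsAlleleFreq, length(object@snpMafs)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort '%s': %d individuals (%d chromosomes), markers: %s\n",
              object@population, nrow(object@chromosomes) / 2,
              nrow(object@chromosomes),
              paste(object@markers, collapse = ", ")))
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d markers x %d %s\n",
              nrow(object@markers), nrow(object@genotypes),
              if (object@phased) "phased chromosomes" else "unphased individuals"))
})

setMethod("show", "BifurcationTree", function(object) {
  cat(sprintf(
    "BifurcationTree at %s (allele %d, %s): root count %d, %d nodes, max depth %d\n",
    object@coreMarker, object@coreAllele, object@direction,
    object@rootCount, nrow(object@nodes),
    if (nrow(object@nodes)) max(object@nodes$depth) else 0L))
})
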