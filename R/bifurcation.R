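# Haplotype bifurcation trees and EHH around a core variant (the rs334
# role): chromosomes carrying a core allele are grouped by successive
# alleles at markers of increasing distance from the core; branch
# counts drive line thickness in bifurcation diagrams, and extended
# haplotype homozygosity (EHH) summarizes the decay of haplotype
# identity with distance.

# Ordered marker indices moving away from the core in one direction.
.flank_order <- function(panel, coreIdx, direction) {
  mk <- markers(panel)
  if (anyDuplicated(mk$pos))
    stop("markers with equal positions are not supported")
  if (direction == "distal") {
    idx <- which(mk$pos > mk$pos[coreIdx])
    idx[order(mk$pos[idx])]
  } else {
    idx <- which(mk$pos < mk$pos[coreIdx])
    idx[order(-mk$pos[idx])]
  }
}

#' Build a haplotype bifurcation tree
#'
#' Roots the tree at the chromosomes carrying `coreAllele` at
#' `coreMarker` and extends marker by marker in the chosen direction
#' (ordered by physical distance from the core). A node splits into two
#' children when both alleles occur among its haplotypes; chromosomes
#' with a missing allele at the next marker are dropped from deeper
#' levels and logged per depth.
#'
#' @param panel A phased [HaplotypePanel].
#' @param coreMarker Core marker label or index.
#' @param coreAllele Core allele, 0 or 1 (rs334 convention: the HbA
#'   allele is ancestral, the HbS allele derived).
#' @param direction `"distal"` (increasing position) or `"proximal"`.
#' @param maxDepth Levels to extend (defaults to all flanking markers).
#' @return A [BifurcationTree].
#' @export
#' @examples
#' panel <- simulateRegionPanel(RegionSpec(nMarkers = 5, nChromosomes = 10,
#'                                         coreIndex = 3, seed = 2))
#' buildBifurcation(panel, 3, coreAllele = 1L, direction = "distal")
buildBifurcation <- function(panel, coreMarker, coreAllele,
                             direction = c("distal", "proximal"),
                             maxDepth = NULL) {
  direction <- match.arg(direction)
  if (!isPhased(panel)) stop("bifurcation trees require a phased panel")
  coreIdx <- .marker_index(panel, coreMarker)
  stopifnot(coreAllele %in% c(0L, 1L))
  flank <- .flank_order(panel, coreIdx, direction)
  if (is.null(maxDepth)) maxDepth <- length(flank)
  if (maxDepth > length(flank))
    stop("maxDepth exceeds available flanking markers")
  flank <- flank[seq_len(maxDepth)]
  g <- genotypes(panel)
  carriers <- which(!is.na(g[, coreIdx]) & g[, coreIdx] == coreAllele)
  label <- markers(panel)$label[coreIdx]
  if (!length(carriers)) {
    warning("no chromosome carries the core allele; empty tree")
    return(new("BifurcationTree", coreMarker = label,
               coreAllele = as.integer(coreAllele), direction = direction,
               rootCount = 0L,
               nodes = data.frame(id = integer(), parent = integer(),
                                  depth = integer(), allele = integer(),
                                  count = integer()),
               dropped = data.frame(depth = integer(), count = integer())))
  }
  nodes <- data.frame(id = 1L, parent = 0L, depth = 0L,
                      allele = NA_integer_, count = length(carriers))
  membership <- list(`1` = carriers)   # node id -> chromosome rows
  frontier <- 1L
  dropped <- data.frame(depth = integer(), count = integer())
  nextId <- 2L
  for (d in seq_along(flank)) {
    mcol <- flank[d]
    newFrontier <- integer()
    nDrop <- 0L
    for (nid in frontier) {
      rows <- membership[[as.character(nid)]]
      alleles <- g[rows, mcol]
      miss <- is.na(alleles)
      nDrop <- nDrop + sum(miss)
      rows <- rows[!miss]
      alleles <- alleles[!miss]
      for (al in c(0L, 1L)) {
        sub <- rows[alleles == al]
        if (!length(sub)) next
        nodes <- rbind(nodes, data.frame(
          id = nextId, parent = nid, depth = d, allele = al,
          count = length(sub)))
        membership[[as.character(nextId)]] <- sub
        newFrontier <- c(newFrontier, nextId)
        nextId <- nextId + 1L
      }
    }
    if (nDrop > 0L)
      dropped <- rbind(dropped, data.frame(depth = d, count = nDrop))
    frontier <- newFrontier
    if (!length(frontier)) break
  }
  rownames(nodes) <- NULL
  new("BifurcationTree", coreMarker = label,
      coreAllele = as.integer(coreAllele), direction = direction,
      rootCount = length(carriers), nodes = nodes, dropped = dropped)
}

#' Extended haplotype homozygosity at a given depth
#'
#' `EHH(d) = sum_h C(n_h, 2) / C(n_core, 2)` over the distinct
#' extended haplotypes `h` of length `d` among core-allele carriers;
#' `EHH(0) = 1` and the curve is non-increasing in depth. Carriers with
#' missing alleles within the first `d` flanking markers are excluded
#' from the numerator; the denominator stays at the root count.
#'
#' @inheritParams buildBifurcation
#' @param depth Number of flanking markers to extend over.
#' @return EHH value in `[0, 1]` (NA with a warning when fewer than two
#'   carriers exist).
#' @export
ehh <- function(panel, coreMarker, coreAllele, depth,
                direction = c("distal", "proximal")) {
  direction <- match.arg(direction)
  if (!isPhased(panel)) stop("EHH requires a phased panel")
  coreIdx <- .marker_index(panel, coreMarker)
  flank <- .flank_order(panel, coreIdx, direction)
  if (depth > length(flank)) stop("depth exceeds available flanking markers")
  g <- genotypes(panel)
  carriers <- which(!is.na(g[, coreIdx]) & g[, coreIdx] == coreAllele)
  nCore <- length(carriers)
  if (nCore < 2L) {
    warning("fewer than two core-allele carriers; EHH undefined")
    return(NA_real_)
  }
  if (depth == 0L) return(1)
  ext <- g[carriers, flank[seq_len(depth)], drop = FALSE]
  keep <- stats::complete.cases(ext)
  ext <- ext[keep, , drop = FALSE]
  if (!nrow(ext)) return(0)
  haps <- apply(ext, 1, paste, collapse = "")
  counts <- as.numeric(table(haps))
  sum(choose(counts, 2)) / choose(nCore, 2)
}

#' EHH decay curve
#'
#' @inheritParams ehh
#' @param maxDepth Deepest level (defaults to all flanking markers).
#' @return `data.frame` with columns `depth`, `ehh`.
#' @export
ehhCurve <- function(panel, coreMarker, coreAllele,
                     direction = c("distal", "proximal"),
                     maxDepth = NULL) {
  direction <- match.arg(direction)
  coreIdx <- .marker_index(panel, coreMarker)
  flank <- .flank_order(panel, coreIdx, direction)
  if (is.null(maxDepth)) maxDepth <- length(flank)
  data.frame(depth = 0:maxDepth,
             ehh = vapply(0:maxDepth, function(d)
               ehh(panel, coreMarker, coreAllele, d, direction),
               numeric(1)))
}

#' EHH recomputed from a bifurcation tree
#'
#' Uses the node counts at a depth instead of haplotype strings;
#' identical to [ehh()] when no haplotypes were dropped for missing
#' data.
#'
#' @param tree A [BifurcationTree].
#' @param depth Depth at which to evaluate.
#' @return EHH value (NA when the root has fewer than two carriers).
#' @export
ehhFromTree <- function(tree, depth) {
  n <- rootCount(tree)
  if (n < 2L) return(NA_real_)
  if (depth == 0L) return(1)
  nd <- treeNodes(tree)
  counts <- nd$count[nd$depth == depth]
  sum(choose(counts, 2)) / choose(n, 2)
}

#' Subsample chromosomes from a phased panel
#'
#' Explicit, seeded subsampling (e.g. to the 20 haplotypes per
#' population conventionally drawn for bifurcation diagrams).
#'
#' @param panel A phased [HaplotypePanel].
#' @param n Number of chromosomes to keep.
#' @param seed Integer seed.
#' @return A [HaplotypePanel] with `n` rows.
#' @export
subsampleChromosomes <- function(panel, n, seed = 1L) {
  if (!isPhased(panel)) stop("subsampling operates on phased panels")
  g <- genotypes(panel)
  if (n > nrow(g)) stop("cannot subsample more chromosomes than present")
  keep <- withr::with_seed(seed, sort(sample.int(nrow(g), n)))
  new("HaplotypePanel", markers = markers(panel),
      genotypes = g[keep, , drop = FALSE], phased = TRUE,
      populations = populations(panel)[keep],
      individuals = individuals(panel)[keep])
}

#' Serialize / parse a bifurcation tree
#'
#' Lossless JSON round-trip of the tree (core metadata plus the node
#' and dropped tables), for plotting or archival:
#' `treeFromJSON(treeToJSON(x))` reproduces `x` exactly.
#'
#' @param tree A [BifurcationTree].
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return `treeToJSON`: JSON string (invisibly, if written to a
#'   file); `treeFromJSON`: a [BifurcationTree].
#' @export
treeToJSON <- function(tree, path = NULL) {
  obj <- list(coreMarker = tree@coreMarker, coreAllele = tree@coreAllele,
              direction = tree@direction, rootCount = tree@rootCount,
              nodes = tree@nodes, dropped = tree@dropped)
  json <- jsonlite::toJSON(obj, dataframe = "columns", na = "null",
                           auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname treeToJSON
#' @param json JSON string or path to a JSON file written by
#'   `treeToJSON`.
#' @export
treeFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json)
  asdf <- function(x, cols) {
    df <- as.data.frame(lapply(x, unlist), stringsAsFactors = FALSE)
    if (!nrow(df)) df <- as.data.frame(
      stats::setNames(rep(list(integer()), length(cols)), cols))
    for (cc in setdiff(cols, "allele")) df[[cc]] <- as.integer(df[[cc]])
    if ("allele" %in% names(df)) df$allele <- as.integer(df$allele)
    df[cols]
  }
  new("BifurcationTree", coreMarker = obj$coreMarker,
      coreAllele = as.integer(obj$coreAllele), direction = obj$direction,
      rootCount = as.integer(obj$rootCount),
      nodes = asdf(obj$nodes, c("id", "parent", "depth", "allele", "count")),
      dropped = asdf(obj$dropped, c("depth", "count")))
}
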