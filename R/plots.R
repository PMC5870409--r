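# Figure helpers (base graphics): Fst heatmap, LD triangle, haplotype
# bifurcation diagram, EHH decay.

#' Heatmap of a pairwise Fst matrix
#'
#' Grey (genetically proximal) to red (distal) rendering of an
#' aggregate Fst matrix.
#'
#' @param fst Output of [fstMatrix()] (or a symmetric numeric matrix).
#' @param main Plot title.
#' @return Invisibly, the matrix drawn.
#' @export
plotFstHeatmap <- function(fst, main = "Pairwise Fst") {
  m <- if (is.list(fst)) fst$mean else fst
  n <- nrow(m)
  pal <- grDevices::colorRampPalette(c("grey85", "grey60", "indianred2",
                                       "red3"))(100)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = main, zlim = c(0, max(m, 1e-6, na.rm = TRUE)))
  graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.8)
  invisible(m)
}

#' Triangle plot of pairwise LD
#'
#' Haploview-style lower triangle of pairwise r-squared (or D')
#' values, with detected blocks outlined.
#'
#' @param pairs Output of [ldPairs()].
#' @param blocks Optional output of [gabrielBlocks()].
#' @param measure `"r2"` or `"Dprime"`.
#' @return Invisibly `NULL`.
#' @export
plotLDTriangle <- function(pairs, blocks = NULL, measure = c("r2", "Dprime")) {
  measure <- match.arg(measure)
  M <- max(pairs$j)
  pal <- grDevices::colorRampPalette(c("white", "red3"))(100)
  graphics::plot(NULL, xlim = c(0, M), ylim = c(0, M), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Pairwise LD (%s)", measure))
  for (r in seq_len(nrow(pairs))) {
    v <- pairs[[measure]][r]
    col <- if (is.na(v)) "grey90" else pal[pmax(1, ceiling(v * 100))]
    graphics::rect(pairs$j[r] - 1, M - pairs$i[r], pairs$j[r],
                   M - pairs$i[r] + 1, col = col, border = "grey70")
  }
  if (!is.null(blocks))
    for (b in blocks)
      graphics::rect(b$start - 1, M - b$end, b$end, M - b$start + 1,
                     border = "black", lwd = 2)
  invisible(NULL)
}

#' Draw a bifurcation diagram
#'
#' Line thickness is proportional to the number of haplotypes sharing
#' each extension; the root (core allele) is marked with a white
#' circle. Proximal trees extend leftwards, distal trees rightwards.
#'
#' @param tree A [BifurcationTree].
#' @param maxLwd Line width of the root branch.
#' @param main Plot title.
#' @return Invisibly `NULL`.
#' @export
plotBifurcation <- function(tree, maxLwd = 10,
                            main = sprintf("%s allele %d (%s)",
                                           tree@coreMarker,
                                           tree@coreAllele,
                                           tree@direction)) {
  nd <- treeNodes(tree)
  if (!nrow(nd)) {
    graphics::plot.new()
    graphics::title(main = paste(main, "(empty)"))
    return(invisible(NULL))
  }
  sgn <- if (tree@direction == "proximal") -1 else 1
  # assign y positions: leaves evenly spaced, internal nodes at the
  # count-weighted mean of their children
  y <- stats::setNames(rep(NA_real_, nrow(nd)), nd$id)
  maxDepth <- max(nd$depth)
  leaves <- nd$id[!(nd$id %in% nd$parent)]
  y[as.character(leaves)] <- seq_along(leaves)
  for (d in rev(seq_len(maxDepth) - 1L)) {
    for (nid in nd$id[nd$depth == d]) {
      kids <- nd[nd$parent == nid, ]
      if (nrow(kids))
        y[as.character(nid)] <-
          sum(y[as.character(kids$id)] * kids$count) / sum(kids$count)
    }
  }
  graphics::plot(NULL, xlim = sort(sgn * c(0, maxDepth + 0.5)),
                 ylim = c(0, length(leaves) + 1), axes = FALSE,
                 xlab = "markers from core", ylab = "", main = main)
  root <- nd[nd$depth == 0L, ]
  for (r in seq_len(nrow(nd))) {
    if (nd$depth[r] == 0L) next
    par_ <- nd[nd$id == nd$parent[r], ]
    graphics::segments(sgn * par_$depth, y[as.character(par_$id)],
                       sgn * nd$depth[r], y[as.character(nd$id[r])],
                       lwd = maxLwd * nd$count[r] / root$count,
                       col = "steelblue4")
  }
  graphics::points(0, y[as.character(root$id)], pch = 21, bg = "white",
                   cex = 1.6)
  graphics::axis(1, at = sgn * 0:maxDepth, labels = 0:maxDepth)
  invisible(NULL)
}

#' Plot an EHH decay curve
#'
#' @param curve Output of [ehhCurve()].
#' @param add Add to an existing plot.
#' @param col Line colour.
#' @return Invisibly `NULL`.
#' @export
plotEhhCurve <- function(curve, add = FALSE, col = "steelblue4") {
  if (!add)
    graphics::plot(curve$depth, curve$ehh, type = "n", ylim = c(0, 1),
                   xlab = "markers from core", ylab = "EHH")
  graphics::lines(curve$depth, curve$ehh, col = col, lwd = 2)
  graphics::points(curve$depth, curve$ehh, col = col, pch = 16)
  invisible(NULL)
}
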