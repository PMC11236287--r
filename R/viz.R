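#' @import ggplot2
#' @importFrom grDevices png svg dev.off colorRampPalette
#' @importFrom graphics axis image mtext par rect text box
NULL

# colour-blind-safe qualitative palette (Okabe-Ito), recycled as needed
.scaffoldPalette <- function(n) {
  pal <- c("#0072B2", "#E69F00", "#009E73", "#CC79A7", "#56B4E9",
           "#D55E00", "#F0E442", "#999999")
  rep_len(pal, n)
}

#' Bar plot of the gene cluster size frequency spectrum
#'
#' Cluster size (singletons = size 1) on the x axis, frequency on the y
#' axis; one colour per scaffold, with a pooled genome-wide panel alongside.
#'
#' @param spectrum the data.frame from [clusterSizeSpectrum()] (scope
#'   `"both"` gives the per-scaffold and pooled panels).
#' @return A ggplot object; with an empty spectrum, a placeholder plot
#'   carrying an explanatory message.
#' @export
plotSpectrum <- function(spectrum) {
  if (nrow(spectrum) == 0L)
    return(.placeholderPlot("empty spectrum: no genes to display"))
  spectrum$panel <- ifelse(spectrum$scaffold == "genome",
                           "genome-wide", "per scaffold")
  spectrum$panel <- factor(spectrum$panel, c("per scaffold", "genome-wide"))
  scafs <- sort(unique(spectrum$scaffold[spectrum$scaffold != "genome"]))
  cols <- c(stats::setNames(.scaffoldPalette(length(scafs)), scafs),
            genome = "#444444")
  ggplot(spectrum, aes(x = factor(.data$size), y = .data$count,
                       fill = .data$scaffold)) +
    geom_col(position = position_dodge2(preserve = "single")) +
    facet_wrap(~panel, nrow = 1L, scales = "free_x") +
    scale_fill_manual(values = cols, name = "scaffold") +
    labs(x = "cluster size (genes)", y = "frequency",
         title = "Gene cluster size frequency spectrum") +
    theme_bw(base_size = 11)
}

.placeholderPlot <- function(msg) {
  ggplot() +
    annotate("text", x = 0, y = 0, label = msg, size = 4.5) +
    theme_void()
}

# map values in [0, max] through a ramp; NA -> grey
.rampColors <- function(vals, ramp, maxVal) {
  cols <- rep("#BBBBBB", length(vals))
  ok <- !is.na(vals)
  if (maxVal <= 0) maxVal <- 1
  idx <- pmin(99L, pmax(0L, as.integer(floor(vals[ok] / maxVal * 99))))
  cols[ok] <- ramp[idx + 1L]
  cols
}

#' Triangular heatmap of physical and evolutionary distances
#'
#' Genes are ordered along both axes by genomic position. The lower triangle
#' shows physical distances in Mb (blue ramp); the upper triangle shows
#' patristic distances in replacements per site (orange ramp) when a matrix
#' is supplied, else it mirrors the physical distances. Cluster extents are
#' outlined as squares on the diagonal; in joint (two-family) mode pass the
#' second family's cluster set via `clusters2` to draw its squares in a
#' second colour. Cross-scaffold physical entries render grey.
#'
#' Drawn with base graphics onto the active device; use [saveFigure()] to
#' write PNG/SVG files.
#'
#' @param phys physical distance matrix from [physicalDistances()] (bp).
#' @param clusterSet a [GeneClusterSet-class] for the cluster outlines.
#' @param evol optional patristic matrix sharing `phys`'s gene universe.
#' @param scaffold optional scaffold name: restrict the plot to that
#'   scaffold's genes (at least 2 required).
#' @param clusters2 optional second [GeneClusterSet-class] (joint mode).
#' @param outlineColors outline colours for `clusterSet` and `clusters2`.
#' @return Invisibly, the gene order used.
#' @export
plotDistanceHeatmap <- function(phys, clusterSet, evol = NULL,
                                scaffold = NULL, clusters2 = NULL,
                                outlineColors = c("#E69F00", "#D53E00")) {
  stopifnot(is(clusterSet, "GeneClusterSet"))
  ids <- rownames(phys)
  if (!is.null(evol)) {
    if (!all(ids %in% rownames(evol)))
      stop("gene order mismatch: evolutionary matrix lacks ",
           paste(utils::head(setdiff(ids, rownames(evol)), 5L),
                 collapse = ", "))
    evol <- evol[ids, ids, drop = FALSE]
  }
  if (!is.null(scaffold)) {
    scafMap <- clusterSet@geneScaffolds
    if (!is.null(clusters2)) scafMap <- c(scafMap, clusters2@geneScaffolds)
    keep <- ids[!is.na(scafMap[ids]) & scafMap[ids] == scaffold]
    if (length(keep) < 2L)
      stop("scaffold ", scaffold, " has fewer than 2 family members")
    phys <- phys[keep, keep, drop = FALSE]
    if (!is.null(evol)) evol <- evol[keep, keep, drop = FALSE]
    ids <- keep
  }
  n <- length(ids)
  lower <- phys / 1e6                         # render in Mb
  upper <- if (is.null(evol)) lower else evol
  blues <- colorRampPalette(c("#F7FBFF", "#08306B"))(100)
  oranges <- colorRampPalette(c("#FFF5EB", "#7F2704"))(100)
  maxLow <- suppressWarnings(max(lower, na.rm = TRUE))
  maxUp <- suppressWarnings(max(upper, na.rm = TRUE))
  colMat <- matrix("#FFFFFF", n, n)
  li <- which(row(colMat) > col(colMat))      # lower triangle
  ui <- which(row(colMat) < col(colMat))
  colMat[li] <- .rampColors(lower[li], blues, maxLow)
  colMat[ui] <- .rampColors(upper[ui], oranges, maxUp)
  op <- par(mar = c(6, 6, 3, 1))
  on.exit(par(op), add = TRUE)
  plot(NA, xlim = c(0.5, n + 0.5), ylim = c(n + 0.5, 0.5), asp = 1,
       axes = FALSE, xlab = "", ylab = "",
       main = sprintf("Distances: physical (lower, Mb) / %s (upper)%s",
                      if (is.null(evol)) "physical (mirrored)"
                      else "evolutionary (subst./site)",
                      if (is.null(scaffold)) "" else paste0(" - ", scaffold)))
  for (i in seq_len(n))                       # row = y, col = x
    rect(seq_len(n) - 0.5, i - 0.5, seq_len(n) + 0.5, i + 0.5,
         col = colMat[i, ], border = NA)
  axis(1, at = seq_len(n), labels = ids, las = 2, cex.axis = 0.6)
  axis(2, at = seq_len(n), labels = ids, las = 2, cex.axis = 0.6)
  .outlineClusters(clusterSet, ids, outlineColors[1L])
  if (!is.null(clusters2)) .outlineClusters(clusters2, ids, outlineColors[2L])
  box()
  invisible(ids)
}

# draw one square per cluster over the diagonal block of its members
.outlineClusters <- function(cs, ids, color) {
  cl <- clusters(cs)
  for (k in seq_len(nrow(cl))) {
    pos <- match(cl$members[[k]], ids)
    pos <- pos[!is.na(pos)]
    if (length(pos) < 2L) next
    rect(min(pos) - 0.5, min(pos) - 0.5, max(pos) + 0.5, max(pos) + 0.5,
         border = color, lwd = 2.5)
  }
}

#' Scatter plot of physical versus evolutionary distances
#'
#' One point per same-scaffold gene pair: physical distance (Mb) on the x
#' axis, patristic distance (replacements per site) on the y axis.
#' Within-cluster pairs are coloured; all other pairs are grey.
#'
#' @param phys physical distance matrix (bp; `NA` cross-scaffold).
#' @param evol patristic distance matrix over the same genes.
#' @param clusterSet a [GeneClusterSet-class].
#' @return A ggplot object, or a placeholder when no same-scaffold pair
#'   exists.
#' @export
plotPhysVsEvol <- function(phys, evol, clusterSet) {
  stopifnot(is(clusterSet, "GeneClusterSet"))
  ids <- rownames(phys)
  if (!all(ids %in% rownames(evol)))
    stop("gene order mismatch between matrices")
  evol <- evol[ids, ids, drop = FALSE]
  pr <- .pairIndices(length(ids))
  pd <- phys[cbind(pr[, 1L], pr[, 2L])]
  ok <- !is.na(pd)                            # same-scaffold pairs only
  if (!any(ok))
    return(.placeholderPlot("no same-scaffold gene pairs to display"))
  byGene <- clusterOf(clusterSet)
  c1 <- byGene[ids[pr[ok, 1L]]]; c2 <- byGene[ids[pr[ok, 2L]]]
  df <- data.frame(
    phys_mb = pd[ok] / 1e6,
    evol = evol[cbind(pr[ok, 1L], pr[ok, 2L])],
    pair = ifelse(!is.na(c1) & !is.na(c2) & c1 == c2,
                  "within cluster", "other"))
  ggplot(df, aes(x = .data$phys_mb, y = .data$evol, colour = .data$pair)) +
    geom_point(alpha = 0.7, size = 1.6) +
    scale_colour_manual(values = c("within cluster" = "#E69F00",
                                   "other" = "#8C8C8C"), name = NULL) +
    labs(x = "physical distance (Mb)",
         y = "evolutionary distance (replacements/site)",
         title = "Physical vs evolutionary distance") +
    theme_bw(base_size = 11)
}

#' Save a figure as PNG and (when cairo is available) SVG
#'
#' @param plotFun a ggplot object, or a function drawing on the active
#'   device (used for the base-graphics heatmap).
#' @param pathBase output path without extension.
#' @param width,height device size in inches.
#' @param dpi PNG resolution.
#' @return Character vector of the files written.
#' @export
saveFigure <- function(plotFun, pathBase, width = 8, height = 5, dpi = 110) {
  draw <- if (inherits(plotFun, "ggplot")) function() print(plotFun)
          else plotFun
  written <- character(0)
  pngPath <- paste0(pathBase, ".png")
  grDevices::png(pngPath, width = width, height = height, units = "in",
                 res = dpi, type = "cairo")
  tryCatch(draw(), finally = grDevices::dev.off())
  written <- c(written, pngPath)
  if (isTRUE(capabilities("cairo"))) {
    svgPath <- paste0(pathBase, ".svg")
    grDevices::svg(svgPath, width = width, height = height)
    tryCatch(draw(), finally = grDevices::dev.off())
    written <- c(written, svgPath)
  }
  written
}
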