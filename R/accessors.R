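#' @importFrom GenomicRanges granges
NULL

#' Accessors for GeneFamily, GeneClusterSet and JointFamilyResult
#'
#' `familyName` returns the family label; `geneIDs` the gene identifiers in
#' canonical order; `familyRanges` the underlying GRanges; `clusters` the
#' per-cluster DataFrame; `singletons` the unclustered gene ids; `clusterOf`
#' a named vector mapping every gene id to its cluster id (NA for
#' singletons); `gapThreshold` and `gapNullPValue` the g / p pair of a
#' parameter set or cluster set; `overlaps` the cluster-overlap records of a
#' joint analysis.
#'
#' @param x a GeneFamily, GeneClusterSet, ClusterParams or JointFamilyResult.
#' @return See the individual descriptions.
#' @name accessors
#' @examples
#' fam <- geneFamily(GenomicRanges::GRanges("s1",
#'   IRanges::IRanges(c(1, 5001), c(1000, 6000)), names = c("a", "b")), "fam")
#' geneIDs(fam)
NULL

#' @rdname accessors
#' @export
setGeneric("familyName", function(x) standardGeneric("familyName"))
#' @rdname accessors
#' @export
setMethod("familyName", "GeneFamily", function(x) x@family)
#' @rdname accessors
#' @export
setMethod("familyName", "GeneClusterSet", function(x) x@family)

#' @rdname accessors
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))
#' @rdname accessors
#' @export
setMethod("geneIDs", "GeneFamily", function(x) names(x@ranges))
#' @rdname accessors
#' @export
setMethod("geneIDs", "GeneClusterSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("familyRanges", function(x) standardGeneric("familyRanges"))
#' @rdname accessors
#' @export
setMethod("familyRanges", "GeneFamily", function(x) x@ranges)

setMethod("length", "GeneFamily", function(x) length(x@ranges))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setMethod("clusters", "GeneClusterSet", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
#' @rdname accessors
#' @export
setMethod("singletons", "GeneClusterSet", function(x) x@singletons)

#' @rdname accessors
#' @export
setGeneric("clusterParamsOf", function(x) standardGeneric("clusterParamsOf"))
#' @rdname accessors
#' @export
setMethod("clusterParamsOf", "GeneClusterSet", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("gapThreshold", function(x) standardGeneric("gapThreshold"))
#' @rdname accessors
#' @export
setMethod("gapThreshold", "ClusterParams", function(x) x@g)
#' @rdname accessors
#' @export
setMethod("gapThreshold", "GeneClusterSet", function(x) x@params@g)

#' @rdname accessors
#' @export
setGeneric("gapNullPValue", function(x) standardGeneric("gapNullPValue"))
#' @rdname accessors
#' @export
setMethod("gapNullPValue", "ClusterParams", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("gapNullPValue", "GeneClusterSet", function(x) x@params@pValue)

#' @rdname accessors
#' @export
setGeneric("clusterOf", function(x) standardGeneric("clusterOf"))
#' @rdname accessors
#' @export
setMethod("clusterOf", "GeneClusterSet", function(x) {
  out <- setNames(rep(NA_character_, length(x@genes)), x@genes)
  if (nrow(x@clusters) > 0L) {
    memb <- unlist(x@clusters$members, use.names = FALSE)
    out[memb] <- rep(x@clusters$cluster_id,
                     lengths(x@clusters$members))
  }
  out
})

#' @rdname accessors
#' @export
setGeneric("overlaps", function(x) standardGeneric("overlaps"))
#' @rdname accessors
#' @export
setMethod("overlaps", "JointFamilyResult", function(x) x@overlaps)

#' @rdname accessors
#' @export
setGeneric("familyA", function(x) standardGeneric("familyA"))
#' @rdname accessors
#' @export
setMethod("familyA", "JointFamilyResult", function(x) x@familyA)

#' @rdname accessors
#' @export
setGeneric("familyB", function(x) standardGeneric("familyB"))
#' @rdname accessors
#' @export
setMethod("familyB", "JointFamilyResult", function(x) x@familyB)

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %.3f Mb (%s bp), %d scaffold name(s) recorded\n",
              object@sizeMb, format(object@sizeBp, big.mark = ","),
              length(object@scaffolds)))
})

setMethod("show", "GeneFamily", function(object) {
  gr <- object@ranges
  cat(sprintf("GeneFamily '%s': %d gene(s) on %d scaffold(s)\n",
              object@family, length(gr),
              length(unique(as.character(seqnames(gr))))))
  if (length(gr) > 0L) {
    n <- min(length(gr), 5L)
    df <- data.frame(gene_id = names(gr)[seq_len(n)],
                     scaffold = as.character(seqnames(gr))[seq_len(n)],
                     start = start(gr)[seq_len(n)], end = end(gr)[seq_len(n)],
                     strand = as.character(strand(gr))[seq_len(n)])
    print(df, row.names = FALSE)
    if (length(gr) > n) cat(sprintf("... and %d more\n", length(gr) - n))
  }
})

setMethod("show", "ClusterParams", function(object) {
  cat(sprintf(
    "ClusterParams: g = %s bp, null p = %.4g (N = %d, genome = %.1f Mb)\n",
    format(object@g, big.mark = ","), object@pValue, object@familySize,
    object@genome@sizeMb))
})

setMethod("show", "GeneClusterSet", function(object) {
  cat(sprintf(
    "GeneClusterSet '%s': %d cluster(s), %d clustered + %d singleton gene(s), g = %s bp\n",
    object@family, nrow(object@clusters),
    length(object@genes) - length(object@singletons),
    length(object@singletons),
    format(object@params@g, big.mark = ",")))
  if (nrow(object@clusters) > 0L) {
    df <- as.data.frame(object@clusters[,
      c("cluster_id", "scaffold", "n", "first_start", "last_end", "span_bp")])
    print(utils::head(df, 5L), row.names = FALSE)
    if (nrow(df) > 5L) cat(sprintf("... and %d more cluster(s)\n", nrow(df) - 5L))
  }
})

setMethod("show", "JointFamilyResult", function(object) {
  cat(sprintf(
    "JointFamilyResult: '%s' (%d clusters) vs '%s' (%d clusters), %d overlap(s)\n",
    object@familyA@family, nrow(object@familyA@clusters),
    object@familyB@family, nrow(object@familyB@clusters),
    nrow(object@overlaps)))
})
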