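#' Joint analysis of two gene families
#'
#' Both families are clustered independently, each with its own parameters
#' (joint mode never changes clustering), and their clusters are compared
#' spatially: every same-scaffold pair of clusters whose genomic spans
#' intersect yields an overlap record. `interleaved_gene_count` counts the
#' members of each cluster lying strictly inside the other cluster's span.
#' No cross-family chaining and no co-clustering statistic is computed.
#'
#' @param famA,famB [GeneFamily-class] objects with distinct labels; gene ids
#'   are prefixed with the family label to keep the id sets disjoint.
#' @param paramsA [ClusterParams-class] for the first family.
#' @param paramsB parameters for the second family; defaults to `paramsA`'s
#'   g applied to family B.
#' @return A [JointFamilyResult-class].
#' @export
jointAnalysis <- function(famA, famB, paramsA, paramsB = NULL) {
  stopifnot(is(famA, "GeneFamily"), is(famB, "GeneFamily"),
            is(paramsA, "ClusterParams"))
  if (familyName(famA) == familyName(famB))
    stop("the two families must have distinct labels")
  if (is.null(paramsB))
    paramsB <- clusterParams(paramsA@genome, length(famB), g = paramsA@g)
  prefix <- function(fam) {
    gr <- familyRanges(fam)
    names(gr) <- paste(familyName(fam), names(gr), sep = ":")
    geneFamily(gr, familyName(fam))
  }
  pA <- prefix(famA); pB <- prefix(famB)
  shared <- intersect(geneIDs(pA), geneIDs(pB))
  if (length(shared) > 0L)
    stop("gene ids shared across families after prefixing: ",
         paste(shared, collapse = ", "))
  csA <- findClusters(pA, paramsA)
  csB <- findClusters(pB, paramsB)
  ovl <- .clusterOverlaps(csA, csB, pA, pB)
  new("JointFamilyResult", familyA = csA, familyB = csB, overlaps = ovl)
}

# spans intersect on the same scaffold; interleaved = genes of either
# cluster strictly inside the other cluster's span
.clusterOverlaps <- function(csA, csB, famA, famB) {
  empty <- DataFrame(cluster_id_a = character(0), cluster_id_b = character(0),
                     scaffold = character(0), overlap_bp = numeric(0),
                     interleaved_gene_count = integer(0))
  clA <- clusters(csA); clB <- clusters(csB)
  if (nrow(clA) == 0L || nrow(clB) == 0L) return(empty)
  grA <- familyRanges(famA); grB <- familyRanges(famB)
  rows <- list()
  for (i in seq_len(nrow(clA))) for (j in seq_len(nrow(clB))) {
    if (clA$scaffold[i] != clB$scaffold[j]) next
    lo <- max(clA$first_start[i], clB$first_start[j])
    hi <- min(clA$last_end[i], clB$last_end[j])
    if (hi < lo) next                       # closed-interval intersection
    inside <- function(gr, members, lo, hi) {
      idx <- match(members, names(gr))
      sum(start(gr)[idx] > lo & end(gr)[idx] < hi)
    }
    inter <- inside(grB, clB$members[[j]], clA$first_start[i], clA$last_end[i]) +
             inside(grA, clA$members[[i]], clB$first_start[j], clB$last_end[j])
    rows[[length(rows) + 1L]] <- DataFrame(
      cluster_id_a = clA$cluster_id[i], cluster_id_b = clB$cluster_id[j],
      scaffold = clA$scaffold[i], overlap_bp = hi - lo + 1,
      interleaved_gene_count = inter)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Write the cluster-overlap table of a joint analysis
#'
#' @param joint a [JointFamilyResult-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeOverlapTable <- function(joint, path) {
  stopifnot(is(joint, "JointFamilyResult"))
  utils::write.table(as.data.frame(overlaps(joint)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
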