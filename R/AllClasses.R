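#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end strand width
NULL

#' GenomeSpec: total genome size and the scaffolds observed in the input
#'
#' The clustering null model needs only the total assembly size; per-scaffold
#' lengths are not required. `sizeBp` is derived as `round(sizeMb * 1e6)`.
#'
#' @slot sizeMb positive numeric, genome size in megabases.
#' @slot sizeBp derived integer-valued numeric, genome size in base pairs.
#' @slot scaffolds character vector of scaffold names seen in the coordinates.
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(sizeMb = "numeric", sizeBp = "numeric",
                 scaffolds = "character"))

setValidity("GenomeSpec", function(object) {
  if (length(object@sizeMb) != 1L || is.na(object@sizeMb) ||
      object@sizeMb <= 0)
    return("sizeMb must be a single positive number")
  if (object@sizeBp != round(object@sizeMb * 1e6))
    return("sizeBp must equal round(sizeMb * 1e6)")
  TRUE
})

#' Construct a GenomeSpec
#'
#' @param sizeMb genome size in Mb (a single positive number).
#' @param scaffolds optional character vector of scaffold names.
#' @return A [GenomeSpec-class] object.
#' @examples
#' genomeSpec(1000)
#' @export
genomeSpec <- function(sizeMb, scaffolds = character()) {
  new("GenomeSpec", sizeMb = as.numeric(sizeMb),
      sizeBp = round(as.numeric(sizeMb) * 1e6),
      scaffolds = as.character(scaffolds))
}

#' GeneFamily: the members of one gene family with genomic coordinates
#'
#' Wraps a [GenomicRanges::GRanges] (1-based closed coordinates, the
#' Bioconductor convention) whose names are the gene identifiers. BED input
#' (0-based half-open) and GFF3 input (1-based closed) are both converted
#' exactly at parse time, so the two encodings of one locus are
#' indistinguishable internally. Records are kept in the canonical order
#' (scaffold, start, end, gene_id); constructors re-sort.
#'
#' @slot ranges GRanges of gene loci, names = gene ids, strand retained but
#'   ignored by all clustering and distance computations.
#' @slot family single character label for the family.
#' @exportClass GeneFamily
setClass("GeneFamily",
  representation(ranges = "GRanges", family = "character"))

setValidity("GeneFamily", function(object) {
  gr <- object@ranges
  if (length(object@family) != 1L || is.na(object@family) ||
      !nzchar(object@family))
    return("family must be a single non-empty label")
  if (length(gr) > 0L) {
    ids <- names(gr)
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      return("every gene must carry an identifier")
    if (anyDuplicated(ids))
      return(sprintf("duplicate gene ids within family '%s': %s",
                     object@family,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    o <- order(as.character(seqnames(gr)), start(gr), end(gr), ids)
    if (!identical(o, seq_along(gr)))
      return("records must be sorted by (scaffold, start, end, gene_id)")
  }
  TRUE
})

# canonical sort used everywhere a GeneFamily is built
.sortFamilyRanges <- function(gr) {
  if (length(gr) == 0L) {
    names(gr) <- character(0)
    return(gr)
  }
  gr[order(as.character(seqnames(gr)), start(gr), end(gr), names(gr))]
}

#' Construct a GeneFamily from a GRanges
#'
#' @param ranges a GRanges with unique names (gene ids). Unstranded ranges
#'   are kept as strand "*".
#' @param family family label.
#' @return A [GeneFamily-class] object in canonical sort order.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 501), c(200, 600)))
#' names(gr) <- c("g1", "g2")
#' geneFamily(gr, "GR")
#' @export
geneFamily <- function(ranges, family) {
  new("GeneFamily", ranges = .sortFamilyRanges(ranges),
      family = as.character(family))
}

#' ClusterParams: the gap threshold g and its Poisson-null p-value
#'
#' Exactly one of `g` (maximum intergenic gap in bp between two members to be
#' chained) and `p` (the null probability that an adjacent pair of uniformly
#' placed members lies within g) is supplied; the other is derived under the
#' homogeneous Poisson placement model with rate lambda = N / genome size.
#' With neither supplied, g defaults to 100 kb, a conventional scale for
#' arthropod chemoreceptor cluster studies.
#'
#' @slot g positive numeric, gap threshold in bp.
#' @slot pValue numeric in (0,1), null probability associated with g.
#' @slot genome [GenomeSpec-class] used for the null model.
#' @slot familySize integer, number of family members N.
#' @exportClass ClusterParams
setClass("ClusterParams",
  representation(g = "numeric", pValue = "numeric",
                 genome = "GenomeSpec", familySize = "integer"))

setValidity("ClusterParams", function(object) {
  if (length(object@g) != 1L || object@g <= 0)
    return("g must be a single positive number of base pairs")
  if (length(object@pValue) != 1L ||
      (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1)))
    return("pValue must lie in [0, 1] (NA allowed for N < 2)")
  if (object@familySize < 1L)
    return("familySize must be positive")
  TRUE
})

#' Construct ClusterParams, deriving g from p or p from g
#'
#' @param genome a [GenomeSpec-class].
#' @param familySize number of family members N (>= 2 for the null model).
#' @param g gap threshold in bp; mutually exclusive with `p`.
#' @param p null probability in (0,1); mutually exclusive with `g`.
#' @return A [ClusterParams-class] object with both g and pValue filled in.
#' @seealso [gapPValue()], [gFromPValue()]
#' @examples
#' clusterParams(genomeSpec(1000), familySize = 100, g = 1e5)
#' @export
clusterParams <- function(genome, familySize, g = NULL, p = NULL) {
  stopifnot(is(genome, "GenomeSpec"))
  familySize <- as.integer(familySize)
  if (!is.null(g) && !is.null(p))
    stop("supply exactly one of 'g' and 'p', not both")
  if (is.null(g) && is.null(p))
    g <- 1e5
  if (is.null(g)) {
    g <- gFromPValue(p, familySize, genome)
  } else {
    g <- as.numeric(g)
    p <- if (familySize >= 2L) gapPValue(g, familySize, genome) else NA_real_
  }
  new("ClusterParams", g = g, pValue = as.numeric(p),
      genome = genome, familySize = familySize)
}

#' GeneClusterSet: partition of a family into clusters and singletons
#'
#' Produced by [findClusters()]. `clusters` is a DataFrame with one row per
#' cluster (id, scaffold, n, first_start, last_end, span_bp, gap_span_bp,
#' max_len_CL and a CharacterList of member ids ordered by start);
#' `singletons` holds ids of unclustered members. Together they partition the
#' family.
#'
#' @slot family family label.
#' @slot genes ids of all family members (the partition universe).
#' @slot geneScaffolds named character vector mapping each gene id to its
#'   scaffold (used by the size spectrum and plots).
#' @slot params the [ClusterParams-class] used.
#' @slot clusters S4Vectors DataFrame, one row per cluster.
#' @slot singletons character vector of unclustered gene ids.
#' @exportClass GeneClusterSet
setClass("GeneClusterSet",
  representation(family = "character", genes = "character",
                 geneScaffolds = "character",
                 params = "ClusterParams", clusters = "DataFrame",
                 singletons = "character"))

setValidity("GeneClusterSet", function(object) {
  memb <- unlist(object@clusters$members, use.names = FALSE)
  all_assigned <- c(memb, object@singletons)
  if (anyDuplicated(all_assigned))
    return("a gene appears in more than one cluster / singleton slot")
  if (!setequal(all_assigned, object@genes) ||
      length(all_assigned) != length(object@genes))
    return("clusters and singletons must partition the family's genes")
  if (nrow(object@clusters) > 0L && any(object@clusters$n < 2L))
    return("clusters must contain at least two members")
  if (!setequal(names(object@geneScaffolds), object@genes))
    return("geneScaffolds must be named by exactly the family's genes")
  TRUE
})

#' JointFamilyResult: two families clustered independently, plus overlaps
#'
#' @slot familyA,familyB per-family [GeneClusterSet-class] objects, identical
#'   to single-family runs (joint mode never alters clustering).
#' @slot overlaps DataFrame of same-scaffold cluster pairs with positive
#'   span intersection: cluster_id_a, cluster_id_b, scaffold, overlap_bp,
#'   interleaved_gene_count.
#' @exportClass JointFamilyResult
setClass("JointFamilyResult",
  representation(familyA = "GeneClusterSet", familyB = "GeneClusterSet",
                 overlaps = "DataFrame"))
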