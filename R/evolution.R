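#' @importFrom ape read.tree write.tree cophenetic.phylo
#' @importFrom stats wilcox.test aggregate
NULL

#' Read a gene-family phylogeny in Newick format
#'
#' Wraps [ape::read.tree()] with the checks the downstream statistics need:
#' unique leaf labels and a branch length on every edge (lengths are
#' amino-acid replacements per site). Multifurcations are legal; quoted
#' labels and scientific-notation lengths are accepted.
#'
#' @param file path to a Newick file, or `NULL` if `text` is given.
#' @param text a Newick string (alternative to `file`).
#' @return An [ape::phylo] tree.
#' @examples
#' readGeneTree(text = "((A:1,B:2):1,C:4);")
#' @export
readGeneTree <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' and 'text'")
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("Newick parse error: no tree could be read")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("every branch must carry a length (replacements per site)")
  if (any(tr$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tr
}

#' Patristic distance matrix of a gene-family tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j — a quantity independent of root placement.
#'
#' @param tree an [ape::phylo] tree with branch lengths (>= 2 leaves).
#' @return A symmetric numeric matrix (replacements per site), zero diagonal,
#'   dimnames = leaf labels.
#' @examples
#' patristicMatrix(readGeneTree(text = "((A:1,B:2):1,C:4);"))
#' @export
patristicMatrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("need at least 2 leaves")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::cophenetic.phylo(tree)
}

# unordered pair indices of x below/above the diagonal, as a 2-column matrix
.pairIndices <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Mann-Whitney U test of within-cluster versus remaining distances
#'
#' Rank-sum comparison of the within-cluster pairwise distances against all
#' remaining pairs. The exact null distribution is used when the smaller
#' sample has at most 8 observations and there are no ties; otherwise the
#' normal approximation with tie correction (and continuity correction) is
#' used. U counts pairs where a `within` value is below a `between` value.
#'
#' @param within numeric vector of within-cluster pairwise distances.
#' @param between numeric vector of the remaining pairwise distances.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with elements `U`, `p` and `exact`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(within, between,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(within) == 0L || length(between) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(within, between)) > 0L
  exact <- min(length(within), length(between)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    within, between, alternative = alternative,
    exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' C_ST: proportion of genetic distance attributable to unclustered genes
#'
#' For each scope (one scaffold, or the whole genome), D_T is the mean
#' patristic distance over all unordered pairs of family members in scope
#' and D_C the mean over pairs whose two genes share one cluster (pooled
#' across clusters). C_ST = (D_T - D_C) / D_T is 0 when clustered copies are
#' no more similar than average and approaches 1 when clustered copies are
#' identical. A Mann-Whitney U test compares the within-cluster pair
#' distances against all remaining pairs in scope (singleton-singleton,
#' singleton-clustered and cross-cluster).
#'
#' C_ST is reported missing with a reason code when D_T = 0 or when the
#' scope contains no within-cluster pair.
#'
#' @param evolDist symmetric patristic distance matrix (as from
#'   [patristicMatrix()]) covering every family member in scope.
#' @param clusterSet a [GeneClusterSet-class].
#' @param scope `"all"` (default: every scaffold with >= 2 members, plus the
#'   pooled `"genome"` scope), `"genome"`, or a scaffold name.
#' @param alternative passed to [mannWhitneyU()].
#' @return A data.frame with one row per scope: scope, n_genes, n_clusters,
#'   D_T, D_C, C_ST, U, p, n_within, n_other, reason.
#' @export
computeCst <- function(evolDist, clusterSet, scope = "all",
                       alternative = "two.sided") {
  stopifnot(is(clusterSet, "GeneClusterSet"))
  ids <- geneIDs(clusterSet)
  missing <- setdiff(ids, rownames(evolDist))
  if (length(missing) > 0L)
    stop("family members absent from the distance matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  scafOf <- clusterSet@geneScaffolds
  byGene <- clusterOf(clusterSet)

  scopes <- if (identical(scope, "all")) {
    tab <- table(scafOf)
    c(names(tab)[tab >= 2L], "genome")
  } else scope

  oneScope <- function(sc) {
    genes <- if (sc == "genome") ids else ids[scafOf[ids] == sc]
    ng <- length(genes)
    base <- data.frame(scope = sc, n_genes = ng, n_clusters = NA_integer_,
                       D_T = NA_real_, D_C = NA_real_, C_ST = NA_real_,
                       U = NA_real_, p = NA_real_, n_within = 0L,
                       n_other = 0L, reason = "", stringsAsFactors = FALSE)
    if (ng < 2L) { base$reason <- "fewer_than_two_genes"; return(base) }
    pr <- .pairIndices(ng)
    d <- evolDist[genes, genes, drop = FALSE][cbind(pr[, 1L], pr[, 2L])]
    cid1 <- byGene[genes[pr[, 1L]]]; cid2 <- byGene[genes[pr[, 2L]]]
    within <- !is.na(cid1) & !is.na(cid2) & cid1 == cid2
    base$n_clusters <- length(unique(stats::na.omit(byGene[genes])))
    base$n_within <- sum(within); base$n_other <- sum(!within)
    base$D_T <- mean(d)
    if (sum(within) == 0L) { base$reason <- "no_within_cluster_pairs"; return(base) }
    base$D_C <- mean(d[within])
    if (base$D_T == 0) { base$reason <- "D_T_zero"; return(base) }
    base$C_ST <- (base$D_T - base$D_C) / base$D_T
    if (sum(!within) > 0L) {
      mw <- mannWhitneyU(d[within], d[!within], alternative = alternative)
      base$U <- mw$U; base$p <- mw$p
    } else base$reason <- "no_between_pairs"
    base
  }
  out <- do.call(rbind, lapply(scopes, oneScope))
  rownames(out) <- NULL
  out
}

#' Write the per-scope C_ST table
#'
#' @param cst the data.frame returned by [computeCst()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCstTable <- function(cst, path) {
  utils::write.table(cst, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as TSV with gene ids as header row and column
#'
#' @param mat a square matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.findBinary <- function(candidates) {
  for (b in candidates) if (nzchar(Sys.which(b))) return(Sys.which(b))
  NA_character_
}

#' Align proteins and infer a gene-family tree with external tools
#'
#' Optional convenience wrapper: runs MAFFT on the family's protein FASTA,
#' then FastTree (JTT, default parameters) or IQ-TREE (`-fast`), and parses
#' the resulting Newick with [readGeneTree()]. Nothing in the statistics
#' requires it — a user-supplied Newick tree bypasses this entirely.
#'
#' @param fasta path to the protein FASTA; sequence ids must match the
#'   family's gene ids.
#' @param engine `"mafft+fasttree"` or `"mafft+iqtree"`.
#' @param outDir directory for the alignment, tree and logs.
#' @param expectedIDs optional character vector of gene ids; ids present in
#'   the FASTA but absent here raise an error listing the offenders.
#' @return An [ape::phylo] tree.
#' @export
runExternalPhylogeny <- function(fasta,
                                 engine = c("mafft+fasttree", "mafft+iqtree"),
                                 outDir = tempfile("phylo"),
                                 expectedIDs = NULL) {
  engine <- match.arg(engine)
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  if (!is.null(expectedIDs)) {
    heads <- grep("^>", readLines(fasta, warn = FALSE), value = TRUE)
    ids <- sub("^>\\s*(\\S+).*$", "\\1", heads)
    off <- setdiff(ids, expectedIDs)
    if (length(off) > 0L)
      stop("FASTA ids absent from the coordinate file: ",
           paste(off, collapse = ", "))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mafft <- .findBinary("mafft")
  if (is.na(mafft))
    stop("mafft not found on PATH; supply a Newick tree instead")
  aln <- file.path(outDir, "alignment.fasta")
  status <- system2(mafft, c("--auto", "--quiet", shQuote(fasta)),
                    stdout = aln, stderr = file.path(outDir, "mafft.log"))
  if (status != 0L) stop("mafft failed (exit ", status, "); see ",
                         file.path(outDir, "mafft.log"))
  treefile <- file.path(outDir, "tree.nwk")
  if (engine == "mafft+fasttree") {
    ft <- .findBinary(c("fasttree", "FastTree"))
    if (is.na(ft))
      stop("fasttree not found on PATH; supply a Newick tree instead")
    status <- system2(ft, c("-quiet", shQuote(aln)), stdout = treefile,
                      stderr = file.path(outDir, "fasttree.log"))
    if (status != 0L) stop("fasttree failed (exit ", status, "); see ",
                           file.path(outDir, "fasttree.log"))
  } else {
    iq <- .findBinary(c("iqtree2", "iqtree"))
    if (is.na(iq))
      stop("iqtree not found on PATH; supply a Newick tree instead")
    status <- system2(iq, c("-s", shQuote(aln), "-fast", "-nt", "1",
                            "--prefix", shQuote(file.path(outDir, "iqtree"))),
                      stdout = file.path(outDir, "iqtree.log"),
                      stderr = file.path(outDir, "iqtree.log"))
    if (status != 0L) stop("iqtree failed (exit ", status, "); see ",
                           file.path(outDir, "iqtree.log"))
    file.copy(file.path(outDir, "iqtree.treefile"), treefile, overwrite = TRUE)
  }
  readGeneTree(file = treefile)
}
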