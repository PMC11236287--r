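#' @importFrom ape rcoal bind.tree
NULL

# run expr under a fixed RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parameters for the synthetic gene-family generator
#'
#' The generator places gene clusters and singletons on a synthetic genome
#' with unambiguous ground truth: within-cluster intergenic gaps are drawn
#' strictly below the generating threshold `truthG` (uniformly over
#' `withinGapFrac * truthG`), while consecutive units (clusters or
#' singletons) are separated by gaps above `2 * truthG`, so clustering at
#' `truthG` recovers the construction exactly.
#'
#' @param seed integer seed; the same seed gives byte-identical fixtures.
#' @param genomeMb genome size in Mb.
#' @param nScaffolds number of scaffolds (equal sizes).
#' @param clusterSizes integer vector, one entry (>= 2) per true cluster.
#' @param nSingletons number of unclustered members.
#' @param truthG generating gap threshold in bp.
#' @param withinGapFrac range, as fractions of `truthG`, from which
#'   within-cluster gaps are drawn (must stay below 1).
#' @param betweenGapFrac range, as multiples of `truthG`, for gaps between
#'   consecutive units (must stay above 2).
#' @param geneWidth range of gene lengths in bp.
#' @param evolBaseDistance expected patristic distance between members of
#'   different units (replacements per site).
#' @param withinShrink s in (0, 1]: expected within-cluster patristic
#'   distance is `s * evolBaseDistance`; s = 1 means cluster membership is
#'   independent of the phylogeny (the null).
#' @return A list of class `simParams`.
#' @export
simParams <- function(seed = 1L, genomeMb = 100, nScaffolds = 2L,
                      clusterSizes = c(2L, 3L, 5L), nSingletons = 10L,
                      truthG = 1e5, withinGapFrac = c(0.1, 0.9),
                      betweenGapFrac = c(2.5, 6),
                      geneWidth = c(1000L, 3000L),
                      evolBaseDistance = 1, withinShrink = 1) {
  stopifnot(all(clusterSizes >= 2L), nSingletons >= 0L, truthG > 0,
            withinGapFrac[1] >= 0, withinGapFrac[2] < 1,
            betweenGapFrac[1] > 2, withinShrink > 0, withinShrink <= 1,
            evolBaseDistance > 0)
  structure(list(seed = as.integer(seed), genomeMb = genomeMb,
                 nScaffolds = as.integer(nScaffolds),
                 clusterSizes = as.integer(clusterSizes),
                 nSingletons = as.integer(nSingletons), truthG = truthG,
                 withinGapFrac = withinGapFrac,
                 betweenGapFrac = betweenGapFrac,
                 geneWidth = as.integer(geneWidth),
                 evolBaseDistance = evolBaseDistance,
                 withinShrink = withinShrink),
            class = "simParams")
}

#' Simulate a gene family with known cluster ground truth
#'
#' Units (true clusters and singletons) are assigned to scaffolds in a
#' seeded random order and laid out left to right; see [simParams()] for the
#' gap construction that makes the truth partition recoverable. Placement is
#' checked to fit the scaffold before anything is written; infeasible
#' parameters raise an error.
#'
#' @param params a [simParams()] list.
#' @param dir optional directory; when given, the family is serialized as
#'   `family.bed`, `family.gff3`, dummy `proteins.fasta` and a
#'   `truth_partition.tsv`.
#' @param familyLabel label for the generated family.
#' @return A list with elements `family` (a [GeneFamily-class]), `truth`
#'   (list with `clusters`, a list of member-id vectors, and `singletons`),
#'   `params`, and when `dir` is given, the file paths.
#' @export
simulateFamily <- function(params, dir = NULL, familyLabel = "simfam") {
  stopifnot(inherits(params, "simParams"))
  .withSeed(params$seed, {
    scafLen <- floor(params$genomeMb * 1e6 / params$nScaffolds)
    scafNames <- sprintf("scf%02d", seq_len(params$nScaffolds))
    nCl <- length(params$clusterSizes)
    units <- c(lapply(seq_len(nCl), function(k)
                 list(kind = "cluster", k = k, size = params$clusterSizes[k])),
               lapply(seq_len(params$nSingletons), function(k)
                 list(kind = "singleton", k = k, size = 1L)))
    unitScaf <- sample(rep_len(seq_len(params$nScaffolds), length(units)))
    recs <- list(); truthClusters <- vector("list", nCl); singles <- character(0)
    for (si in seq_len(params$nScaffolds)) {
      mine <- units[unitScaf == si]
      if (length(mine) == 0L) next
      pos <- round(stats::runif(1, params$truthG, 2 * params$truthG))
      for (u in mine) {
        ids <- if (u$kind == "cluster")
          sprintf("%s_cl%02d_g%02d", familyLabel, u$k, seq_len(u$size))
        else sprintf("%s_single%02d", familyLabel, u$k)
        for (m in seq_len(u$size)) {
          w <- round(stats::runif(1, params$geneWidth[1], params$geneWidth[2]))
          recs[[length(recs) + 1L]] <- data.frame(
            scaffold = scafNames[si], start = pos, end = pos + w - 1,
            gene_id = ids[m], strand = sample(c("+", "-"), 1L),
            stringsAsFactors = FALSE)
          pos <- pos + w
          if (m < u$size)        # within-cluster gap, strictly below truthG
            pos <- pos + round(stats::runif(1,
              params$withinGapFrac[1] * params$truthG,
              params$withinGapFrac[2] * params$truthG))
        }
        if (u$kind == "cluster") truthClusters[[u$k]] <- ids
        else singles <- c(singles, ids)
        pos <- pos + round(stats::runif(1,     # unit separation, above 2g
          params$betweenGapFrac[1] * params$truthG,
          params$betweenGapFrac[2] * params$truthG))
      }
      if (pos > scafLen)
        stop(sprintf(
          "infeasible placement: scaffold %s needs %d bp but has %d",
          scafNames[si], as.integer(pos), as.integer(scafLen)))
    }
    df <- do.call(rbind, recs)
    gr <- GRanges(df$scaffold, IRanges::IRanges(df$start, df$end),
                  strand = df$strand)
    names(gr) <- df$gene_id
    fam <- geneFamily(gr, familyLabel)
    out <- list(family = fam,
                truth = list(clusters = truthClusters, singletons = singles),
                genome = genomeSpec(params$genomeMb, scafNames),
                params = params)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$bedPath <- writeFamilyBED(fam, file.path(dir, "family.bed"))
      out$gffPath <- .writeFamilyGFF3(fam, file.path(dir, "family.gff3"))
      out$fastaPath <- .writeDummyProteins(
        geneIDs(fam), file.path(dir, "proteins.fasta"))
      tp <- data.frame(
        gene_id = c(unlist(truthClusters), singles),
        truth_cluster = c(rep(sprintf("truth_c%02d", seq_len(nCl)),
                              lengths(truthClusters)),
                          rep("", length(singles))))
      utils::write.table(tp, file.path(dir, "truth_partition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$truthPath <- file.path(dir, "truth_partition.tsv")
    }
    out
  })
}

# GFF3 serialization of a family (gene rows only)
.writeFamilyGFF3 <- function(fam, path) {
  gr <- familyRanges(fam)
  std <- as.character(strand(gr)); std[std == "*"] <- "."
  lines <- c("##gff-version 3",
             sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     as.character(seqnames(gr)), start(gr), end(gr), std,
                     names(gr)))
  writeLines(lines, path)
  invisible(path)
}

# random amino-acid sequences; placeholders for pipeline smoke tests only,
# not an evolutionary simulation
.writeDummyProteins <- function(ids, path, nSites = 60L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lines <- unlist(lapply(ids, function(id)
    c(paste0(">", id), paste(sample(aa, nSites, replace = TRUE),
                             collapse = ""))))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a gene-family phylogeny tied to a cluster ground truth
#'
#' With `withinShrink = 1` the genes are assigned uniformly at random to the
#' leaves of a random coalescent tree, making cluster membership independent
#' of the phylogeny (the exchangeable null for the Mann-Whitney test). With
#' `withinShrink = s < 1`, a coalescent backbone is drawn over the units
#' (clusters and singletons), rescaled so its mean pairwise patristic
#' distance equals `evolBaseDistance`, and each cluster's members are
#' grafted as a shallow star clade whose pendant lengths average
#' `s * evolBaseDistance / 2`, so the expected within-cluster patristic
#' distance is `s * evolBaseDistance`; the backbone terminal edge is
#' shortened by the same amount (floored at 1% of the base distance) to keep
#' between-unit distances near the base.
#'
#' @param truth the `truth` element returned by [simulateFamily()].
#' @param params the same [simParams()] list (fields `seed`,
#'   `evolBaseDistance`, `withinShrink` are used). Supply a different seed
#'   via `seed` to vary the tree for a fixed family.
#' @param seed optional override of `params$seed`.
#' @return An [ape::phylo] tree over all gene ids, with branch lengths.
#' @export
simulateTree <- function(truth, params, seed = params$seed) {
  stopifnot(inherits(params, "simParams"))
  ids <- c(unlist(truth$clusters), truth$singletons)
  base <- params$evolBaseDistance
  s <- params$withinShrink
  .withSeed(seed, {
    if (s == 1) {                                 # exchangeable null
      tr <- ape::rcoal(length(ids), tip.label = sample(ids))
      return(.scaleTreeToMeanDistance(tr, base))
    }
    unitLabels <- c(sprintf("UNIT_c%03d", seq_along(truth$clusters)),
                    sprintf("UNIT_s%03d", seq_along(truth$singletons)))
    nu <- length(unitLabels)
    bb <- if (nu >= 2L) {
      .scaleTreeToMeanDistance(
        ape::rcoal(nu, tip.label = sample(unitLabels)), base)
    } else {
      ape::read.tree(text = sprintf("(%s:%g);", unitLabels, base / 2))
    }
    pend <- s * base / 2
    for (k in seq_along(truth$clusters)) {
      lab <- sprintf("UNIT_c%03d", k)
      tip <- which(bb$tip.label == lab)
      eidx <- which(bb$edge[, 2] == tip)
      bb$edge.length[eidx] <- max(bb$edge.length[eidx] - pend, 0.01 * base)
      members <- truth$clusters[[k]]
      pl <- pend * stats::runif(length(members), 0.8, 1.2)
      star <- ape::read.tree(text = paste0(
        "(", paste(sprintf("%s:%g", members, pl), collapse = ","), ");"))
      bb <- ape::bind.tree(bb, star, where = which(bb$tip.label == lab))
    }
    for (k in seq_along(truth$singletons))
      bb$tip.label[bb$tip.label == sprintf("UNIT_s%03d", k)] <-
        truth$singletons[k]
    bb
  })
}

.scaleTreeToMeanDistance <- function(tree, target) {
  m <- ape::cophenetic.phylo(tree)
  cur <- mean(m[upper.tri(m)])
  tree$edge.length <- tree$edge.length * (target / cur)
  tree
}
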