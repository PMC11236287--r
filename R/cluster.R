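#' Pairwise physical distances between family members
#'
#' The physical distance between two genes on one scaffold is the intergenic
#' gap: the number of base pairs strictly between the two loci, clamped at 0
#' for overlapping or book-ended genes. Genes on different scaffolds have no
#' defined physical distance and get `NA`. Distances are returned in bp; the
#' plots convert to Mb at render time only.
#'
#' @param fam a [GeneFamily-class].
#' @return A symmetric numeric matrix (bp) with zero diagonal, dimnames =
#'   gene ids in canonical order, `NA` for cross-scaffold pairs.
#' @examples
#' gr <- GenomicRanges::GRanges("s1", IRanges::IRanges(c(101, 501), c(200, 600)))
#' names(gr) <- c("a", "b")
#' physicalDistances(geneFamily(gr, "f"))  # gap a-b = 300 bp
#' @export
physicalDistances <- function(fam) {
  stopifnot(is(fam, "GeneFamily"))
  gr <- familyRanges(fam)
  if (length(gr) == 0L) stop("empty gene family")
  s <- start(gr); e <- end(gr)
  # gap in 1-based closed coordinates: bases strictly between the loci
  d <- pmax(outer(s, s, pmax) - outer(e, e, pmin) - 1, 0)
  scaf <- as.character(seqnames(gr))
  d[outer(scaf, scaf, "!=")] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(names(gr), names(gr))
  d
}

# intergenic gaps between genes consecutive in start order on one scaffold
.consecutiveGaps <- function(s, e) {
  n <- length(s)
  if (n < 2L) return(numeric(0))
  i <- seq_len(n - 1L)
  pmax(pmax(s[i], s[i + 1L]) - pmin(e[i], e[i + 1L]) - 1, 0)
}

#' Identify gene clusters under the gap threshold g
#'
#' Per scaffold, genes sorted by start are chained whenever the intergenic
#' gap between consecutive genes is at most `g` (single-linkage along the
#' scaffold). Maximal chains of two or more genes become clusters, named
#' `"<family>_<scaffold>_c<k>"` left to right; chains of one gene are
#' singletons. Because every consecutive gap is at most g, the summed gap
#' span of an n-gene cluster never exceeds the cutoff C_L = g(n-1).
#'
#' @param fam a [GeneFamily-class].
#' @param params a [ClusterParams-class]; its genome size is checked against
#'   the largest gene coordinate (warning if exceeded).
#' @return A [GeneClusterSet-class].
#' @seealso [clusterParams()], [clusterLengthCutoff()]
#' @export
findClusters <- function(fam, params) {
  stopifnot(is(fam, "GeneFamily"), is(params, "ClusterParams"))
  gr <- familyRanges(fam)
  if (length(gr) > 0L && params@genome@sizeBp < max(end(gr)))
    warning(sprintf(
      "genome size (%d bp) is smaller than the largest gene coordinate (%d bp)",
      as.integer(params@genome@sizeBp), max(end(gr))))
  g <- params@g
  scaf <- as.character(seqnames(gr))
  rows <- list(); singles <- character(0)
  for (sc in unique(scaf)) {           # unique() keeps canonical order
    idx <- which(scaf == sc)
    s <- start(gr)[idx]; e <- end(gr)[idx]; ids <- names(gr)[idx]
    gaps <- .consecutiveGaps(s, e)
    chain <- cumsum(c(0L, as.integer(gaps > g)))   # chain index per gene
    k <- 0L
    for (ch in split(seq_along(idx), factor(chain, levels = unique(chain)))) {
      if (length(ch) < 2L) { singles <- c(singles, ids[ch]); next }
      k <- k + 1L
      gapSpan <- sum(.consecutiveGaps(s[ch], e[ch]))
      rows[[length(rows) + 1L]] <- DataFrame(
        cluster_id = sprintf("%s_%s_c%d", familyName(fam), sc, k),
        scaffold = sc, n = length(ch),
        first_start = s[ch[1L]], last_end = max(e[ch]),
        span_bp = max(e[ch]) - s[ch[1L]] + 1L,
        gap_span_bp = gapSpan,
        max_len_CL = clusterLengthCutoff(g, length(ch)),
        members = CharacterList(list(ids[ch])))
    }
  }
  clusterDF <- if (length(rows) > 0L) do.call(rbind, rows) else
    DataFrame(cluster_id = character(0), scaffold = character(0),
              n = integer(0), first_start = integer(0), last_end = integer(0),
              span_bp = integer(0), gap_span_bp = numeric(0),
              max_len_CL = numeric(0), members = CharacterList())
  new("GeneClusterSet", family = familyName(fam), genes = names(gr),
      geneScaffolds = setNames(scaf, names(gr)), params = params,
      clusters = clusterDF, singletons = singles)
}

#' Maximum genomic span of an n-member cluster
#'
#' The cutoff C_L = g(n-1): with every one of the n-1 consecutive gaps at
#' most g, an n-member cluster can span at most g(n-1) bp of intergenic DNA.
#'
#' @param g gap threshold in bp (> 0).
#' @param n cluster size (>= 2).
#' @return C_L in bp.
#' @examples
#' clusterLengthCutoff(1e5, 3)  # 2e5
#' @export
clusterLengthCutoff <- function(g, n) {
  if (any(n < 2)) stop("a cluster needs at least 2 copies (n >= 2)")
  if (any(g <= 0)) stop("g must be positive")
  g * (n - 1)
}

#' Null probability that an adjacent pair lies within g
#'
#' Under uniform placement of the N family members on a genome of
#' `genome@sizeBp` bases (a homogeneous Poisson process with rate
#' lambda = N / size), inter-member gaps are exponentially distributed, and
#' the probability that a given adjacent pair is closer than g is
#' p = 1 - exp(-lambda g). This is the false-positive probability attached
#' to a user-chosen g: lower p means chance proximity is less likely to be
#' called a cluster.
#'
#' @param g gap threshold in bp (>= 0, < genome size).
#' @param N family size (>= 2).
#' @param genome a [GenomeSpec-class].
#' @return The null probability p.
#' @examples
#' gapPValue(1e5, 100, genomeSpec(1000))  # 1 - exp(-0.01) ~ 0.00995
#' @export
gapPValue <- function(g, N, genome) {
  stopifnot(is(genome, "GenomeSpec"))
  if (N < 2) stop("the null model needs at least N = 2 members")
  if (g < 0) stop("g must be non-negative")
  if (g >= genome@sizeBp) stop("g must be smaller than the genome size")
  lambda <- N / genome@sizeBp
  if (lambda * g > 50) {
    warning("lambda * g > 50: degenerate regime, p reported as 1")
    return(1)
  }
  -expm1(-lambda * g)
}

#' Gap threshold g corresponding to a null probability
#'
#' Inverse of [gapPValue()]: g = -ln(1 - p) / lambda, rounded to the nearest
#' base pair.
#'
#' @param p null probability, strictly inside (0, 1).
#' @param N family size (>= 2).
#' @param genome a [GenomeSpec-class].
#' @return g in bp.
#' @export
gFromPValue <- function(p, N, genome) {
  stopifnot(is(genome, "GenomeSpec"))
  if (length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("p must lie strictly inside (0, 1)")
  if (N < 2) stop("the null model needs at least N = 2 members")
  lambda <- N / genome@sizeBp
  round(-log1p(-p) / lambda)
}

#' Gene cluster size frequency spectrum
#'
#' Counts clusters by size, per scaffold and pooled over the genome;
#' singletons appear as the size-1 class.
#'
#' @param clusterSet a [GeneClusterSet-class].
#' @param scope `"both"` (default), `"scaffold"` or `"genome"`.
#' @return A data.frame with columns scaffold (`"genome"` for the pooled
#'   rows), size and count. Counts weighted by size sum to the family size.
#' @export
clusterSizeSpectrum <- function(clusterSet,
                                scope = c("both", "scaffold", "genome")) {
  stopifnot(is(clusterSet, "GeneClusterSet"))
  scope <- match.arg(scope)
  cl <- clusters(clusterSet)
  sizes <- c(cl$n, rep(1L, length(singletons(clusterSet))))
  scafs <- c(cl$scaffold,
             unname(clusterSet@geneScaffolds[singletons(clusterSet)]))
  if (length(sizes) == 0L)
    return(data.frame(scaffold = character(0), size = integer(0),
                      count = integer(0)))
  perScaffold <- as.data.frame(table(scaffold = scafs, size = sizes),
                               stringsAsFactors = FALSE)
  perScaffold <- perScaffold[perScaffold$Freq > 0L, ]
  perScaffold <- data.frame(scaffold = perScaffold$scaffold,
                            size = as.integer(perScaffold$size),
                            count = perScaffold$Freq)
  pooled <- stats::aggregate(count ~ size, perScaffold, sum)
  pooled <- data.frame(scaffold = "genome", size = pooled$size,
                       count = pooled$count)
  out <- switch(scope,
    both = rbind(perScaffold, pooled),
    scaffold = perScaffold,
    genome = pooled)
  out <- out[order(out$scaffold, out$size), ]
  rownames(out) <- NULL
  out
}
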