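# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's code paths: plain data.frame arithmetic instead of GRanges,
# enumeration instead of closed forms.

toyGRanges <- function(scaffold, start, end, ids, strand = "*") {
  gr <- GenomicRanges::GRanges(scaffold,
                               IRanges::IRanges(start, end), strand = strand)
  names(gr) <- ids
  gr
}

# 4 genes on one scaffold: consecutive gaps 10 kb, 15 kb, 485 kb
toyFamily <- function() {
  geneFamily(toyGRanges("chr1",
                        start = c(1001, 13001, 31001, 518001),
                        end   = c(3000, 16000, 33000, 520000),
                        ids = c("g1", "g2", "g3", "g4")), "toy")
}

toyGenome <- function() genomeSpec(10, "chr1")

# random family instance for property tests: n genes over 1-2 scaffolds
randomFamilyDF <- function(n, seed) {
  set.seed(seed)
  scaffold <- sample(c("sA", "sB"), n, replace = TRUE)
  start <- sample.int(5e5, n)
  width <- sample(500:3000, n, replace = TRUE)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), scaffold = scaffold,
             start = start, end = start + width, stringsAsFactors = FALSE)
}

dfToFamily <- function(df, label = "rand") {
  geneFamily(toyGRanges(df$scaffold, df$start, df$end, df$gene_id), label)
}

# ORACLE: single-linkage chains from plain arithmetic on a data.frame.
# Genes sorted by (scaffold, start, end, id); consecutive intergenic gap
# (1-based closed: next start - running end - 1, floored at 0) <= g chains.
oracleClusterMembership <- function(df, g) {
  df <- df[order(df$scaffold, df$start, df$end, df$gene_id), ]
  out <- list()
  for (sc in unique(df$scaffold)) {
    d <- df[df$scaffold == sc, ]
    chain <- list(d$gene_id[1L])
    if (nrow(d) > 1L) for (i in 2:nrow(d)) {
      gap <- max(max(d$start[i], d$start[i - 1L]) -
                 min(d$end[i], d$end[i - 1L]) - 1, 0)
      if (gap <= g) chain[[length(chain)]] <- c(chain[[length(chain)]],
                                                d$gene_id[i])
      else chain[[length(chain) + 1L]] <- d$gene_id[i]
    }
    out <- c(out, chain)
  }
  list(clusters = Filter(function(x) length(x) >= 2L, out),
       singletons = unlist(Filter(function(x) length(x) == 1L, out)))
}

# canonical form of a partition for comparison
canonicalPartition <- function(clusters, singletons) {
  if (is.null(singletons)) singletons <- character(0)
  cl <- lapply(clusters, sort)
  cl <- cl[order(vapply(cl, `[`, "", 1L))]
  list(clusters = cl, singletons = sort(unname(singletons)))
}

partitionOf <- function(cs) {
  canonicalPartition(as.list(clusters(cs)$members), singletons(cs))
}

# ORACLE: exact two-sided Mann-Whitney p by enumerating all rank
# assignments (choose(n1 + n2, n1) must be small)
oracleMWU <- function(within, between) {
  n1 <- length(within); n2 <- length(between)
  pooled <- c(within, between)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  Uall <- apply(combos, 2L, function(ix) sum(seq_len(n1 + n2)[ix]) -
                              n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- mean(abs(Uall - mu) >= abs(Uobs - mu))
  list(U = Uobs, p = p)
}

writeTempLines <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
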