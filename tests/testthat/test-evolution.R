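test_that("Newick parsing validates labels and branch lengths", {
  tr <- readGeneTree(text = "((A:1,B:2):1,C:4);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_error(readGeneTree(text = "((A:1,A:2):1,C:4);"), "duplicate")
  expect_error(readGeneTree(text = "((A,B):1,C:4);"), "branch")
  poly <- readGeneTree(text = "((A:1,B:2,C:0.5):1,D:4);")
  expect_equal(length(poly$tip.label), 4L)
  expect_error(readGeneTree(text = "((A:1,B:2:1,C:4);"), "parse")
  expect_error(readGeneTree(), "exactly one")
})

test_that("patristic distances equal hand-summed path lengths", {
  m <- patristicMatrix(readGeneTree(text = "((A:1,B:2):1,C:4);"))
  expect_equal(m["A", "B"], 3)
  expect_equal(m["A", "C"], 6)
  expect_equal(m["B", "C"], 7)
  expect_identical(m, t(m))
  # star tree: all pairwise distances are 2
  star <- readGeneTree(text = "(A:1,B:1,C:1,D:1);")
  ms <- patristicMatrix(star)
  expect_true(all(ms[upper.tri(ms)] == 2))
})

test_that("patristic matrix is invariant to root placement", {
  for (seed in 1:100) {
    set.seed(seed)
    tr <- ape::rtree(8)
    m1 <- patristicMatrix(tr)
    out <- sample(tr$tip.label, 1L)
    tr2 <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    m2 <- patristicMatrix(tr2)
    ids <- rownames(m1)
    expect_equal(m2[ids, ids], m1, tolerance = 1e-9)
  }
})

test_that("patristic distances satisfy the triangle inequality", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- patristicMatrix(ape::rtree(7))
    n <- nrow(m)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
  }
})

# two 2-gene clusters + one singleton on one scaffold
cstFixture <- function() {
  fam <- geneFamily(toyGRanges("chr1",
    start = c(1000, 2000, 500000, 501000, 900000),
    end   = c(1500, 2500, 500500, 501500, 900500),
    ids = c("a1", "a2", "b1", "b2", "s1")), "f")
  findClusters(fam, clusterParams(genomeSpec(10), 5, g = 5e4))
}

test_that("C_ST hits its boundary values", {
  cs <- cstFixture()
  ids <- geneIDs(cs)
  # all pairwise distances equal -> D_C = D_T -> C_ST = 0
  eq <- matrix(0.4, 5, 5, dimnames = list(ids, ids)); diag(eq) <- 0
  res <- computeCst(eq, cs, scope = "genome")
  expect_equal(res$C_ST, 0)
  expect_equal(res$D_T, 0.4)
  # identical clustered copies (D_C = 0) with D_T > 0 -> C_ST = 1
  d0 <- eq
  d0["a1", "a2"] <- d0["a2", "a1"] <- 0
  d0["b1", "b2"] <- d0["b2", "b1"] <- 0
  res0 <- computeCst(d0, cs, scope = "genome")
  expect_equal(res0$C_ST, 1)
})

test_that("C_ST equals its formula with independently averaged distances", {
  cs <- cstFixture()
  ids <- geneIDs(cs)
  set.seed(11)
  m <- matrix(0, 5, 5, dimnames = list(ids, ids))
  vals <- runif(10, 0.05, 1)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  res <- computeCst(m, cs, scope = "genome")
  # oracle: direct loops over the 10 unordered pairs
  byGene <- clusterOf(cs)
  dAll <- c(); dWithin <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    dAll <- c(dAll, m[ids[i], ids[j]])
    if (!is.na(byGene[ids[i]]) && !is.na(byGene[ids[j]]) &&
        byGene[ids[i]] == byGene[ids[j]])
      dWithin <- c(dWithin, m[ids[i], ids[j]])
  }
  expect_equal(res$D_T, mean(dAll))
  expect_equal(res$D_C, mean(dWithin))          # pooled across clusters
  expect_equal(res$C_ST, (mean(dAll) - mean(dWithin)) / mean(dAll))
  expect_equal(res$n_within, 2L)
  expect_equal(res$n_other, 8L)
})

test_that("C_ST is invariant to gene order and missing-case reasons are set", {
  cs <- cstFixture()
  ids <- geneIDs(cs)
  set.seed(12)
  m <- matrix(0, 5, 5, dimnames = list(ids, ids))
  m[upper.tri(m)] <- runif(10)
  m <- m + t(m)
  perm <- sample(ids)
  expect_equal(computeCst(m[perm, perm], cs, scope = "genome"),
               computeCst(m, cs, scope = "genome"))
  # zero matrix -> D_T = 0 reason
  z <- matrix(0, 5, 5, dimnames = list(ids, ids))
  rz <- computeCst(z, cs, scope = "genome")
  expect_true(is.na(rz$C_ST))
  expect_equal(rz$reason, "D_T_zero")
  # missing rows are an error
  expect_error(computeCst(m[1:4, 1:4], cs, scope = "genome"), "absent")
})

test_that("per-scaffold scopes are reported alongside the genome scope", {
  fam <- geneFamily(toyGRanges(c("c1", "c1", "c2", "c2"),
    start = c(1000, 3000, 1000, 300000),
    end = c(1500, 3500, 1500, 300500),
    ids = c("x1", "x2", "y1", "y2")), "f")
  cs <- findClusters(fam, clusterParams(genomeSpec(10), 4, g = 5e4))
  m <- patristicMatrix(readGeneTree(
    text = "((x1:0.1,x2:0.1):0.5,(y1:0.4,y2:0.4):0.2);"))
  res <- computeCst(m, cs)
  expect_setequal(res$scope, c("c1", "c2", "genome"))
  c2row <- res[res$scope == "c2", ]
  expect_equal(c2row$reason, "no_within_cluster_pairs")
  expect_true(is.na(c2row$C_ST))
  expect_false(is.na(res$C_ST[res$scope == "genome"]))
})

test_that("Mann-Whitney matches the enumeration oracle", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_true(mw$exact)
  orc <- oracleMWU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, orc$U)
  expect_equal(mw$p, orc$p)

  for (seed in 1:100) {
    set.seed(seed)
    n1 <- sample(3:8, 1L); n2 <- sample(4:8, 1L)
    w <- rnorm(n1); b <- rnorm(n2, mean = 0.5)
    mw <- mannWhitneyU(w, b)
    orc <- oracleMWU(w, b)
    expect_equal(mw$U, orc$U, tolerance = 1e-12)
    expect_equal(mw$p, orc$p, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney handles ties, sidedness and empty input", {
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$exact)                 # ties -> approximation
  expect_gt(same$p, 0.9)
  less <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(less$p, 0.05)
  expect_error(mannWhitneyU(numeric(0), c(1, 2)), "non-empty")
})

test_that("Mann-Whitney p-values are uniform under the null", {
  ps <- vapply(1:500, function(seed) {
    set.seed(1000 + seed)
    mannWhitneyU(rnorm(8), rnorm(12))$p
  }, 0)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("external phylogeny wrapper validates inputs and names tools", {
  fasta <- writeTempLines(c(">gA", "MKVLITA", ">gB", "MKVLISA"), ".fasta")
  expect_error(
    runExternalPhylogeny(fasta, engine = "mafft+iqtree",
                         expectedIDs = c("gA", "gB")),
    "iqtree not found")
  expect_error(
    runExternalPhylogeny(fasta, expectedIDs = c("gA")),
    "absent from the coordinate file.*gB")
  expect_error(runExternalPhylogeny(tempfile(fileext = ".fa")), "not found")
})

test_that("mafft + fasttree infer a tree over the family ids", {
  ids <- sprintf("g%02d", 1:6)
  set.seed(3)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- sample(aa, 50, replace = TRUE)
  fasta <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(ids, function(id) {
    s <- base
    mut <- sample(50, 8)
    s[mut] <- sample(aa, 8, replace = TRUE)
    c(paste0(">", id), paste(s, collapse = ""))
  }))
  writeLines(lines, fasta)
  tr <- runExternalPhylogeny(fasta, engine = "mafft+fasttree",
                             expectedIDs = ids)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, ids)
  m <- patristicMatrix(tr)
  expect_true(all(is.finite(m)))
})
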