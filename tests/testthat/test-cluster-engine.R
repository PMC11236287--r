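test_that("physical distances are intergenic gaps, clamped at overlaps", {
  fam <- geneFamily(toyGRanges(c("chr1", "chr1", "chr1", "chr2"),
                               start = c(101, 501, 151, 11),
                               end = c(200, 600, 400, 60),
                               ids = c("A", "B", "C", "D")), "f")
  d <- physicalDistances(fam)
  expect_equal(d["A", "B"], 300)          # [100,200) to [500,600) in BED terms
  expect_equal(d["A", "C"], 0)            # overlapping genes
  expect_true(is.na(d["A", "D"]))         # cross-scaffold undefined
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_error(physicalDistances(geneFamily(GenomicRanges::GRanges(), "e")),
               "empty")
})

test_that("chaining at g groups the toy family as expected", {
  fam <- toyFamily()                       # gaps 10 kb, 15 kb, 485 kb
  cs <- findClusters(fam, clusterParams(toyGenome(), 4, g = 5e4))
  expect_equal(nrow(clusters(cs)), 1L)
  expect_equal(clusters(cs)$n, 3L)
  expect_equal(sort(clusters(cs)$members[[1L]]), c("g1", "g2", "g3"))
  expect_equal(singletons(cs), "g4")
  expect_equal(clusters(cs)$cluster_id, "toy_chr1_c1")
})

test_that("boundary cases: single gene, gap exactly g, zero gaps", {
  single <- geneFamily(toyGRanges("s", 1, 100, "only"), "f")
  cs <- findClusters(single, clusterParams(toyGenome(), 1, g = 1e5))
  expect_equal(nrow(clusters(cs)), 0L)
  expect_equal(singletons(cs), "only")

  # gap exactly equal to g is chained (<= comparison)
  atG <- geneFamily(toyGRanges("s", c(1, 1101), c(100, 1200),
                               c("a", "b")), "f")
  csAt <- findClusters(atG, clusterParams(toyGenome(), 2, g = 1000))
  expect_equal(clusters(csAt)$n, 2L)
  csBelow <- findClusters(atG, clusterParams(toyGenome(), 2, g = 999))
  expect_equal(nrow(clusters(csBelow)), 0L)

  # overlapping genes have gap 0 and cluster at any positive g
  over <- geneFamily(toyGRanges("s", c(1, 50), c(100, 150),
                                c("a", "b")), "f")
  csOver <- findClusters(over, clusterParams(toyGenome(), 2, g = 1))
  expect_equal(clusters(csOver)$n, 2L)
})

test_that("cluster length cutoff C_L = g(n-1)", {
  expect_equal(clusterLengthCutoff(1e5, 3), 2e5)
  expect_equal(clusterLengthCutoff(1e5, 2), 1e5)
  expect_error(clusterLengthCutoff(1e5, 1), "at least 2")
})

test_that("gap p-value matches the exponential closed form", {
  G <- genomeSpec(1000)                    # 1e9 bp
  expect_equal(gapPValue(1e5, 100, G), 1 - exp(-0.01), tolerance = 1e-12)
  expect_equal(gapPValue(0, 100, G), 0)
  expect_warning(p1 <- gapPValue(6e8, 100, G), "degenerate")
  expect_equal(p1, 1)
  expect_error(gapPValue(1e5, 1, G), "N = 2")
})

test_that("g and p are mutual inverses", {
  G <- genomeSpec(1000)
  for (g in c(1e4, 1e5, 1e6))
    expect_equal(gFromPValue(gapPValue(g, 100, G), 100, G), g,
                 tolerance = 1)
  expect_equal(gFromPValue(0.00995, 100, G), 1e5, tolerance = 60)
  expect_error(gFromPValue(0, 100, G), "inside")
  expect_error(gFromPValue(1, 100, G), "inside")
})

test_that("clusterParams enforces the g/p exclusivity and defaults", {
  G <- genomeSpec(1000)
  expect_error(clusterParams(G, 100, g = 1e5, p = 0.01), "exactly one")
  cp <- clusterParams(G, 100)              # default g
  expect_equal(gapThreshold(cp), 1e5)
  cpP <- clusterParams(G, 100, p = gapPValue(1e5, 100, G))
  expect_equal(gapThreshold(cpP), 1e5, tolerance = 1)
})

test_that("size spectrum counts clusters and singletons", {
  fam <- toyFamily()
  cs <- findClusters(fam, clusterParams(toyGenome(), 4, g = 5e4))
  spec <- clusterSizeSpectrum(cs, scope = "genome")
  expect_equal(spec$count[spec$size == 1], 1L)
  expect_equal(spec$count[spec$size == 3], 1L)
  expect_equal(sum(spec$size * spec$count), length(fam))

  empty <- findClusters(geneFamily(GenomicRanges::GRanges(), "e"),
                        clusterParams(toyGenome(), 1, g = 5e4))
  expect_equal(nrow(clusterSizeSpectrum(empty)), 0L)
})

test_that("random instances match the arithmetic chaining oracle", {
  G <- genomeSpec(10)
  for (seed in 1:60) {
    n <- sample(2:12, 1L)
    df <- randomFamilyDF(n, seed)
    g <- sample(c(1e3, 1e4, 5e4, 2e5), 1L)
    cs <- findClusters(dfToFamily(df), clusterParams(G, n, g = g))
    expect_identical(partitionOf(cs),
                     canonicalPartition(oracleClusterMembership(df, g)$clusters,
                                        oracleClusterMembership(df, g)$singletons),
                     label = sprintf("seed %d g %g", seed, g))
  }
})

test_that("partition, span bound and g-monotonicity hold on random input", {
  G <- genomeSpec(10)
  for (seed in 61:90) {
    n <- sample(3:12, 1L)
    df <- randomFamilyDF(n, seed)
    fam <- dfToFamily(df)
    gs <- sort(sample(c(1e3, 5e3, 2e4, 1e5, 3e5), 3L))
    prevClustered <- -1L
    prevPart <- NULL
    for (g in gs) {
      cs <- findClusters(fam, clusterParams(G, n, g = g))
      cl <- clusters(cs)
      # partition property
      expect_equal(sum(cl$n) + length(singletons(cs)), n)
      # every cluster satisfies its span bound
      if (nrow(cl) > 0L)
        expect_true(all(cl$gap_span_bp <= cl$max_len_CL + 1e-9))
      # increasing g never de-clusters genes nor splits clusters
      nowClustered <- sum(cl$n)
      expect_gte(nowClustered, prevClustered)
      if (!is.null(prevPart))
        for (members in prevPart)
          expect_true(any(vapply(as.list(cl$members), function(m)
            all(members %in% m), TRUE)))
      prevClustered <- nowClustered
      prevPart <- as.list(cl$members)
    }
  }
})
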