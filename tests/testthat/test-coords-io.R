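test_that("BED parsing follows the 0-based half-open convention", {
  f <- writeTempLines(c("# a comment",
                        "chr1\t100\t200\tgeneA",
                        "chr2\t0\t50",
                        "chr1\t500\t600\tgeneB\t0\t-"), ".bed")
  fam <- readFamilyBED(f, "fam")
  expect_s4_class(fam, "GeneFamily")
  gr <- familyRanges(fam)
  expect_equal(geneIDs(fam), c("geneA", "geneB", "chr2:0-50"))
  expect_equal(GenomicRanges::width(gr)[geneIDs(fam) == "geneA"], 100)
  expect_equal(GenomicRanges::start(gr)[geneIDs(fam) == "geneA"], 101)
  expect_equal(as.character(GenomicRanges::strand(gr)),
               c("*", "-", "*"))
})

test_that("malformed BED lines raise parse errors naming the line", {
  bad <- writeTempLines(c("chr1\t100\t200\tok", "chr1\t200\t100\tgeneB"),
                        ".bed")
  expect_error(readFamilyBED(bad, "f"), "line 2.*start >= end")
  nonint <- writeTempLines("chr1\txx\t200\tg", ".bed")
  expect_error(readFamilyBED(nonint, "f"), "non-integer")
  dup <- writeTempLines(c("chr1\t1\t10\tg1", "chr1\t20\t30\tg1"), ".bed")
  expect_error(readFamilyBED(dup, "f"), "duplicate gene ids.*g1")
  short <- writeTempLines("chr1\t100", ".bed")
  expect_error(readFamilyBED(short, "f"), "fewer than 3")
})

test_that("GFF3 and BED encodings of one interval are identical internally", {
  gff <- writeTempLines(c("##gff-version 3",
                          "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1"),
                        ".gff3")
  bed <- writeTempLines("chr1\t100\t200\tg1\t0\t+", ".bed")
  famG <- readFamilyGFF3(gff, "fam")
  famB <- readFamilyBED(bed, "fam")
  expect_identical(GenomicRanges::start(familyRanges(famG)),
                   GenomicRanges::start(familyRanges(famB)))
  expect_identical(GenomicRanges::end(familyRanges(famG)),
                   GenomicRanges::end(familyRanges(famB)))
  expect_identical(geneIDs(famG), geneIDs(famB))
})

test_that("GFF3 feature filtering and attribute selection work", {
  onlyMRNA <- writeTempLines(c("##gff-version 3",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=m1"), ".gff3")
  expect_error(readFamilyGFF3(onlyMRNA, "f"), "mRNA")

  named <- writeTempLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=x"), ".gff3")
  fam <- readFamilyGFF3(named, "f", idAttribute = "Name")
  expect_equal(geneIDs(fam), "x")

  noattr <- writeTempLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tName=x"), ".gff3")
  expect_error(readFamilyGFF3(noattr, "f"), "without attribute 'ID'")
})

test_that("discontinuous GFF3 annotation collapses to the covering interval", {
  gff <- writeTempLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t501\t700\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t901\t950\t.\t-\t.\tID=g2"), ".gff3")
  expect_warning(fam <- readFamilyGFF3(gff, "f"), "discontinuous")
  gr <- familyRanges(fam)
  expect_equal(GenomicRanges::start(gr)[geneIDs(fam) == "g1"], 101)
  expect_equal(GenomicRanges::end(gr)[geneIDs(fam) == "g1"], 700)
  expect_equal(length(fam), 2L)
})

test_that("BED write -> read -> write round trip is byte identical", {
  fam <- toyFamily()
  f1 <- tempfile(fileext = ".bed")
  writeFamilyBED(fam, f1)
  fam2 <- readFamilyBED(f1, "toy")
  f2 <- tempfile(fileext = ".bed")
  writeFamilyBED(fam2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(geneIDs(fam), geneIDs(fam2))
  expect_identical(GenomicRanges::start(familyRanges(fam)),
                   GenomicRanges::start(familyRanges(fam2)))
})

test_that("gene table reports status, cluster ids and sizes consistently", {
  fam <- toyFamily()
  cs <- findClusters(fam, clusterParams(toyGenome(), length(fam), g = 5e4))
  path <- tempfile(fileext = ".tsv")
  tab <- writeGeneTable(fam, cs, path)
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$status == "clustered"), 3L)
  expect_equal(length(unique(tab$cluster_id[tab$status == "clustered"])), 1L)
  expect_equal(tab$cluster_size[tab$status == "singleton"], 1L)
  onDisk <- read.delim(path)
  expect_equal(nrow(onDisk), 4L)

  # cluster set from a different family -> consistency error
  other <- geneFamily(toyGRanges("chr1", 1, 100, "zz"), "other")
  csOther <- findClusters(other, clusterParams(toyGenome(), 1, g = 5e4))
  expect_error(writeGeneTable(fam, csOther, tempfile()), "mismatch")
})

test_that("an empty family yields a header-only gene table", {
  gr <- GenomicRanges::GRanges()
  fam <- geneFamily(gr, "empty")
  cs <- findClusters(fam, clusterParams(toyGenome(), 1, g = 5e4))
  path <- tempfile(fileext = ".tsv")
  writeGeneTable(fam, cs, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^gene_id\t")
})

test_that("duplicate gene ids are rejected at construction", {
  expect_error(geneFamily(toyGRanges("c1", c(1, 10), c(5, 20),
                                     c("a", "a")), "f"),
               "duplicate gene ids")
})
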