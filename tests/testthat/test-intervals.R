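test_that("BED parsing preserves half-open coordinates and names", {
  tmp <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1", "chr1\t500\t800\tp2",
               "chr2\t0\t50\tp3"), tmp)
  gr <- readBed(tmp)
  expect_equal(length(gr), 3L)
  expect_equal(GenomicRanges::start(gr)[1], 101L)  # 1-based internally
  expect_equal(GenomicRanges::end(gr)[1], 200L)
  expect_equal(names(gr), c("p1", "p2", "p3"))

  out <- tempfile(fileext = ".bed")
  writeBed(gr, out)
  expect_identical(readLines(out), readLines(tmp))
})

test_that("malformed BED records error with a line number", {
  tmp <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t200\t100"), tmp)
  expect_error(readBed(tmp), "line 1")
  tmp2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\tabc\t30"), tmp2)
  expect_error(readBed(tmp2), "line 2")
})

test_that("GTF export carries the literal 'peak' source column", {
  gr <- bedToGRanges(bedDF("chr1", c(100, 300), c(200, 400)))
  names(gr) <- c("a", "b")
  tmp <- tempfile(fileext = ".gtf")
  exportPeaksGTF(gr, tmp)
  fields <- strsplit(readLines(tmp), "\t")
  expect_true(all(vapply(fields, `[`, "", 2) == "peak"))
  expect_true(all(grepl("gene_id", vapply(fields, `[`, "", 9))))
})

test_that("fractional overlap follows the intersection arithmetic", {
  a <- bedToGRanges(bedDF("chr1", 100, 200))
  b <- bedToGRanges(bedDF("chr1", 150, 250))
  fo <- fractionalOverlap(a, b)
  expect_equal(fo$fracA, 0.5)
  expect_equal(fo$fracB, 0.5)

  expect_equal(unlist(fractionalOverlap(a, a)), c(fracA = 1, fracB = 1))
  c2 <- bedToGRanges(bedDF("chr2", 100, 200))
  expect_equal(unlist(fractionalOverlap(a, c2)), c(fracA = 0, fracB = 0))
})

test_that("fractional overlap is symmetric with fractions exchanged", {
  set.seed(42)
  x <- bedToGRanges(randomIntervalSet(50))
  y <- bedToGRanges(randomIntervalSet(50))
  fxy <- fractionalOverlap(x, y)
  fyx <- fractionalOverlap(y, x)
  expect_equal(fxy$fracA, fyx$fracB)
  expect_equal(fxy$fracB, fyx$fracA)
})

test_that("consensus merging joins reciprocal overlaps at the threshold", {
  s1 <- bedToGRanges(bedDF("chr1", 100, 200))
  s2 <- bedToGRanges(bedDF("chr1", 150, 250))
  merged <- mergeConsensus(list(s1, s2))
  expect_equal(length(merged), 1L)
  expect_equal(GenomicRanges::start(merged), 101L)
  expect_equal(GenomicRanges::end(merged), 250L)
  expect_equal(names(merged), "chr1:100-250")

  ## 10/100 = 0.1 < 0.5: stays apart
  s3 <- bedToGRanges(bedDF("chr1", 190, 400))
  expect_equal(length(mergeConsensus(list(s1, s3))), 2L)

  ## a single non-self-overlapping set is unchanged
  one <- bedToGRanges(bedDF("chr1", c(0, 500), c(100, 700)))
  m1 <- mergeConsensus(list(one))
  expect_equal(grToBed(m1), grToBed(one))

  expect_error(mergeConsensus(list(s1), minFraction = 0), "minFraction")
  expect_error(mergeConsensus(list(s1), minFraction = 1.5), "minFraction")
})

test_that("consensus merging is idempotent and order-invariant", {
  set.seed(7)
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i) bedToGRanges(randomIntervalSet(40)))
    m <- mergeConsensus(sets)
    expect_equal(grToBed(mergeConsensus(list(m))), grToBed(m))
    mRev <- mergeConsensus(rev(sets))
    expect_equal(grToBed(mRev), grToBed(m))
  }
})

test_that("chromosome filtering removes the default exclusion set", {
  gr <- bedToGRanges(bedDF(c("chr1", "chrX", "chrY", "chrM", "chr2"),
                           c(0, 0, 0, 0, 0), c(10, 10, 10, 10, 10)))
  kept <- filterChromosomes(gr)
  expect_equal(as.character(GenomicRanges::seqnames(kept)), c("chr1", "chr2"))
  expect_equal(length(filterChromosomes(gr, exclude = character(0))), 5L)
  onlyY <- bedToGRanges(bedDF("chrY", 0, 10))
  expect_equal(length(filterChromosomes(onlyY)), 0L)
})

test_that("TAD assignment applies the 90% containment gate", {
  tads <- bedToGRanges(bedDF("chr1", 0, 95)); names(tads) <- "t1"
  peak <- bedToGRanges(bedDF("chr1", 0, 100)); names(peak) <- "p"
  expect_equal(assignToTAD(peak, tads), c(p = "t1"))  # 0.95 >= 0.9

  tads2 <- bedToGRanges(bedDF("chr1", 20, 100)); names(tads2) <- "t1"
  expect_equal(length(assignToTAD(peak, tads2)), 0L)  # 0.80 < 0.9

  inside <- bedToGRanges(bedDF("chr1", 30, 60)); names(inside) <- "q"
  expect_equal(assignToTAD(inside, tads2), c(q = "t1"))
})

test_that("nearest gene minimizes TSS distance with deterministic ties", {
  peak <- bedToGRanges(bedDF("chr1", 100, 200)); names(peak) <- "p"  # mid 150
  genes <- bedToGRanges(bedDF("chr1", c(100, 500), c(400, 900)))
  names(genes) <- c("g1", "g2")
  nn <- nearestGeneTSS(peak, genes)
  expect_equal(nn$gene_id, "g1")
  expect_equal(nn$distance, 50)

  atMid <- bedToGRanges(bedDF("chr1", 150, 400)); names(atMid) <- "gm"
  expect_equal(nearestGeneTSS(peak, atMid)$distance, 0)

  tie <- bedToGRanges(bedDF("chr1", c(200, 100), c(500, 400)))
  names(tie) <- c("gB", "gA")  # TSS at 200 and 100, both 50 bp from mid
  expect_equal(nearestGeneTSS(peak, tie)$gene_id, "gA")

  ## minus-strand gene: TSS at the end coordinate
  neg <- bedToGRanges(bedDF("chr1", 10, 151)); names(neg) <- "gneg"
  GenomicRanges::strand(neg) <- "-"
  expect_equal(nearestGeneTSS(peak, neg)$distance, 0)

  offChrom <- bedToGRanges(bedDF("chr9", 0, 10)); names(offChrom) <- "p9"
  nn2 <- nearestGeneTSS(offChrom, genes)
  expect_true(is.na(nn2$gene_id))
})

test_that("merging and TAD assignment agree with exhaustive oracles", {
  set.seed(11)
  for (rep in 1:20) {
    df <- randomIntervalSet(sample(10:60, 1))
    mine <- grToBed(mergeConsensus(list(bedToGRanges(df))))
    oracle <- oracleMergeConsensus(df)
    expect_equal(mine, oracle)
  }
  for (rep in 1:20) {
    peakDF <- randomIntervalSet(30)
    peakDF$name <- sprintf("p%02d", seq_len(nrow(peakDF)))
    tadDF <- randomIntervalSet(10, maxWidth = 2000)
    tadDF$name <- sprintf("t%02d", seq_len(nrow(tadDF)))
    mine <- assignToTAD(bedToGRanges(peakDF), bedToGRanges(tadDF), 0.5)
    oracle <- oracleAssignToTAD(peakDF, tadDF, 0.5)
    expect_equal(mine[order(names(mine))], oracle[order(names(oracle))])
  }
})
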