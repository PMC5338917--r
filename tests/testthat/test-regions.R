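chromLens <- c(chr1 = 5000L, chr2 = 4000L)

test_that("mergePeaks handles trivial inputs and rejects invalid records", {
  expect_length(mergePeaks(GenomicRanges::GRanges()), 0L)

  disjoint <- GenomicRanges::GRanges(c("chr1", "chr1"),
                                     IRanges::IRanges(c(31, 11), c(40, 20)))
  merged <- mergePeaks(disjoint)
  expect_equal(GenomicRanges::start(merged), c(11, 31))
  expect_equal(GenomicRanges::end(merged), c(20, 40))

  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 9))
  expect_error(mergePeaks(bad), "start >= end")
})

test_that("mergePeaks merges abutting intervals and matches the per-base oracle", {
  # half-open BED [10,20) + [20,30) abut; in 1-based closed terms 11-20, 21-30
  abut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 21), c(20, 30)))
  expect_length(mergePeaks(abut), 1L)

  set.seed(101)
  for (rep in 1:10) {
    gr <- randomRegionSet(500L, chromLens)
    merged <- mergePeaks(gr)
    expectMatchesCoverageOracle(merged, gr, chromLens)
    # idempotent under re-merge
    expect_identical(GenomicRanges::granges(mergePeaks(merged)),
                     GenomicRanges::granges(merged))
  }
})

test_that("unionTFPeaks annotates support counts matching the per-base source oracle", {
  expect_length(unionTFPeaks(list()), 0L)

  one <- list(AR = GenomicRanges::GRanges("chr1",
                                          IRanges::IRanges(c(5, 50), c(20, 70))))
  u1 <- unionTFPeaks(one)
  expect_identical(GenomicRanges::granges(u1),
                   GenomicRanges::granges(mergePeaks(one$AR)))
  expect_true(all(u1$support_count == 1L))

  # overlap of two TFs becomes one region with support 2 (0-based [0,100) +
  # [50,150) -> 1-based 1-150)
  two <- list(TF1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)),
              TF2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)))
  u2 <- unionTFPeaks(two)
  expect_length(u2, 1L)
  expect_equal(GenomicRanges::start(u2), 1)
  expect_equal(GenomicRanges::end(u2), 150)
  expect_equal(u2$support_count, 2L)
  expect_equal(u2$support_tfs, "TF1,TF2")

  set.seed(202)
  tfSets <- list(A = randomRegionSet(200L, chromLens),
                 B = randomRegionSet(200L, chromLens),
                 C = randomRegionSet(200L, chromLens))
  u <- unionTFPeaks(tfSets)
  expectMatchesCoverageOracle(u, do.call(c, unname(tfSets)), chromLens)
  expect_equal(u$support_count, oracleSupport(u, tfSets, chromLens))
})

test_that("intersectRegions is the exact per-base AND and respects half-open abutment", {
  a <- mergePeaks(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)))
  expect_identical(GenomicRanges::granges(intersectRegions(a, a)),
                   GenomicRanges::granges(a))

  # BED [0,100) and [100,200) share no base
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_length(intersectRegions(a, b), 0L)

  set.seed(303)
  for (rep in 1:10) {
    x <- mergePeaks(randomRegionSet(300L, chromLens))
    y <- mergePeaks(randomRegionSet(300L, chromLens))
    z <- intersectRegions(x, y)
    for (chr in names(chromLens)) {
      vx <- oracleCoverageVec(x, chr, chromLens[[chr]])
      vy <- oracleCoverageVec(y, chr, chromLens[[chr]])
      runs <- oracleRuns(vx & vy)
      got <- z[as.character(GenomicRanges::seqnames(z)) == chr]
      expect_equal(GenomicRanges::start(got), runs$start)
      expect_equal(GenomicRanges::end(got), runs$end)
    }
    # intersection coverage never exceeds either input's coverage
    expect_lte(sum(GenomicRanges::width(z)), sum(GenomicRanges::width(x)))
    expect_lte(sum(GenomicRanges::width(z)), sum(GenomicRanges::width(y)))
  }
})

test_that("snpsInRegions applies the 1-based/half-open conversion and matches a scan oracle", {
  regions <- mergePeaks(GenomicRanges::GRanges("chr1",
                                               IRanges::IRanges(101, 200)))
  snps <- data.frame(snp_id = c("in", "edge_out", "edge_in", "off_chrom"),
                     chrom = c("chr1", "chr1", "chr1", "chrX"),
                     pos = c(150L, 100L, 101L, 150L),
                     allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  kept <- snpsInRegions(snps, regions)
  # 1-based 150 and 101 lie in BED [100,200); 1-based 100 (0-based 99) does
  # not; absent chromosome is silently dropped
  expect_equal(kept$snp_id, c("in", "edge_in"))
  expect_equal(kept$region_start, c(100L, 100L))
  expect_equal(kept$region_end, c(200L, 200L))

  set.seed(404)
  regions <- mergePeaks(randomRegionSet(400L, chromLens))
  snps <- data.frame(snp_id = sprintf("rs%04d", 1:1000),
                     chrom = sample(names(chromLens), 1000L, replace = TRUE),
                     pos = sample.int(4000L, 1000L, replace = TRUE),
                     allele_a = "A", allele_b = "C",
                     stringsAsFactors = FALSE)
  kept <- snpsInRegions(snps, regions)
  expect_equal(kept$snp_id, snps$snp_id[oracleSnpMembership(snps, regions)])

  # membership invariant to shuffling peak order before merging
  shuf <- mergePeaks(randomRegionSet(0L, chromLens))
  perm <- sample(length(regions))
  regions2 <- mergePeaks(regions[perm])
  expect_equal(snpsInRegions(snps, regions2)$snp_id, kept$snp_id)
})

test_that("mixed chromosome naming is reported, not silently normalized", {
  expect_error(checkChromNaming(c("chr1", "chr2"), c("1", "2")), "mixed")
  expect_silent(checkChromNaming(c("chr1"), c("chr2", "chr3")))
})
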