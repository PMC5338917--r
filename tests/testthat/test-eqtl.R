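test_that("dropSilentGenes removes exactly the all-zero genes", {
  set.seed(11)
  mat <- matrix(stats::rpois(50 * 10, 5), 50, 10)
  zero <- sample(50, 7)
  mat[zero, ] <- 0
  single <- setdiff(seq_len(50), zero)[1L]
  mat[single, ] <- c(3, rep(0, 9))  # one nonzero value retains the gene
  rownames(mat) <- sprintf("G%02d", 1:50)
  se <- makeSE(mat[, 1:6], mat[, 7:10])
  kept <- dropSilentGenes(se)
  expect_equal(nrow(kept), 50 - 7)
  expect_true(rownames(mat)[single] %in% rownames(kept))
  expect_identical(rownames(kept), setdiff(rownames(mat),
                                           rownames(mat)[zero]))
})

test_that("genesNearSnp uses an inclusive SNP-to-TSS window ordered by distance", {
  snp <- data.frame(chrom = "chr1", pos = 100000L)
  genes <- data.frame(
    gene_id = c("at_snp", "at_edge", "past_edge", "near", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    tss = c(100000L, 125000L, 125001L, 99000L, 100000L),
    strand = "+", stringsAsFactors = FALSE)
  hit <- genesNearSnp(snp, genes, window = 25000L)
  expect_equal(hit$gene_id, c("at_snp", "near", "at_edge"))
  expect_equal(hit$distance, c(0L, 1000L, 25000L))

  # agreement with an exhaustive distance filter on random annotations
  set.seed(22)
  genes <- data.frame(gene_id = sprintf("G%03d", 1:200),
                      chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                      tss = sample.int(3e5, 200), strand = "+",
                      stringsAsFactors = FALSE)
  snp <- data.frame(chrom = "chr1", pos = 150000L)
  want <- genes$gene_id[genes$chrom == "chr1" &
                          abs(genes$tss - 150000L) <= 25000L]
  expect_setequal(genesNearSnp(snp, genes)$gene_id, want)
})

test_that("anovaEqtl reproduces hand-computed F and flags degenerate cases", {
  # identical groups: between-group SS is 0
  res <- anovaEqtl(rep(0:2, each = 3), rep(c(1, 2, 3), 3))
  expect_equal(res$f_stat, 0)

  # hand-worked sums of squares: SSB = 54, SSW = 6 -> F = 27, df (2, 6)
  res <- anovaEqtl(rep(0:2, each = 3), c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_equal(res$f_stat, 27)
  expect_equal(res$df1, 2L)
  expect_equal(res$df2, 6L)

  # fewer than 2 eligible groups -> untestable, never a crash
  res <- anovaEqtl(rep(0L, 10), rnorm(10))
  expect_false(res$testable)
  expect_true(is.na(res$p_value))

  # zero within-group variance with unequal means -> explicit p = 0
  res <- anovaEqtl(rep(0:1, each = 4), rep(c(1, 5), each = 4))
  expect_equal(res$p_value, 0)
  expect_equal(res$f_stat, Inf)

  # groups below minGroupSize are dropped before testing
  res <- anovaEqtl(c(rep(0L, 6), rep(1L, 6), 2L, 2L),
                   c(rnorm(12), 100, 101), minGroupSize = 3L)
  expect_equal(names(res$group_sizes), c("0", "1"))
})

test_that("anovaEqtl agrees with the from-scratch sums-of-squares oracle", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(20:80, 1)
    g <- sample(0:2, n, replace = TRUE)
    e <- rnorm(n, mean = g %% 2, sd = 1)
    g[sample(n, 2)] <- NA  # missing calls are dropped pairwise
    res <- anovaEqtl(g, e, minGroupSize = 1L)
    orc <- oracleAnova(g, e)
    expect_equal(res$f_stat, orc$f, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
    expect_equal(res$df1, orc$df1)
    expect_equal(res$df2, orc$df2)
  }
})

# small in-memory scan fixture: nSnps SNPs, one gene within the window of
# each, optional planted additive effect on the first SNP's gene
makeScanData <- function(nSnps = 20L, n = 100L, beta = 0, maf = 0.3,
                         noiseSd = 1) {
  samples <- sprintf("T%03d", seq_len(n))
  gt <- vapply(seq_len(nSnps), function(j) rbinom(n, 2L, maf), integer(n))
  dimnames(gt) <- list(samples, sprintf("rs%03d", seq_len(nSnps)))
  snps <- data.frame(snp_id = colnames(gt), chrom = "chr1",
                     pos = seq_len(nSnps) * 100000L,
                     allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = sprintf("G%03d", seq_len(nSnps)),
                      chrom = "chr1", tss = snps$pos + 5000L, strand = "+",
                      stringsAsFactors = FALSE)
  expr <- vapply(seq_len(nSnps), function(j) {
    eff <- if (j == 1L) beta * noiseSd * gt[, j] else 0
    2 ^ (5 + eff + rnorm(n, 0, noiseSd))
  }, numeric(n))
  mat <- t(expr)
  rownames(mat) <- genes$gene_id
  colnames(mat) <- samples
  se <- makeSE(mat, matrix(2 ^ rnorm(nSnps * 4, 5), nSnps, 4,
                           dimnames = list(genes$gene_id, NULL)))
  list(snps = snps, gt = gt, se = se, genes = genes)
}

test_that("runEqtlScan recovers a planted cis effect and honors empty inputs", {
  empty <- runEqtlScan(data.frame(snp_id = character(), chrom = character(),
                                  pos = integer()),
                       matrix(0L, 2, 0,
                              dimnames = list(c("T1", "T2"), NULL)),
                       makeSE(matrix(1, 1, 2,
                                     dimnames = list("G1", NULL)),
                              matrix(1, 1, 2,
                                     dimnames = list("G1", NULL))),
                       data.frame(gene_id = "G1", chrom = "chr1",
                                  tss = 1L, strand = "+"))
  expect_equal(nrow(empty), 0L)

  set.seed(44)
  d <- makeScanData(nSnps = 50L, n = 200L, beta = 1.5)
  res <- runEqtlScan(d$snps, d$gt, d$se, d$genes)
  planted <- res[res$snp_id == "rs001" & res$gene_id == "G001", ]
  expect_true(planted$significant)
  expect_equal(res$snp_id[which.min(res$p_value)], "rs001")

  # no shared samples is a configuration error
  gt2 <- d$gt
  rownames(gt2) <- paste0("X", rownames(gt2))
  expect_error(runEqtlScan(d$snps, gt2, d$se, d$genes), "overlapping")
})

test_that("scan results are invariant to sample-order permutation", {
  set.seed(55)
  d <- makeScanData(nSnps = 10L, n = 80L, beta = 1)
  res1 <- runEqtlScan(d$snps, d$gt, d$se, d$genes)
  perm <- sample(nrow(d$gt))
  res2 <- runEqtlScan(d$snps, d$gt[perm, ], d$se, d$genes)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-12)
  expect_equal(res1$significant, res2$significant)
})

test_that("an all-null scan makes essentially no BH discoveries", {
  set.seed(66)
  fp <- vapply(1:10, function(r) {
    d <- makeScanData(nSnps = 40L, n = 60L, beta = 0)
    sum(runEqtlScan(d$snps, d$gt, d$se, d$genes)$significant)
  }, numeric(1L))
  # expected false discoveries under BH at 0.05 on null data is ~0
  expect_lte(mean(fp), 0.5)
})
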