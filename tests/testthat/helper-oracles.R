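# Independent brute-force oracles. Each re-derives the quantity under test
# from first principles (per-base membership, explicit sums of squares,
# exhaustive placement enumeration, risk-set counting), sharing no code with
# the implementation paths they check.

# per-base coverage vector of a GRanges on one chromosome (1-based closed)
oracleCoverageVec <- function(gr, chr, len) {
  v <- logical(len)
  keep <- as.character(GenomicRanges::seqnames(gr)) == chr
  s <- GenomicRanges::start(gr)[keep]
  e <- GenomicRanges::end(gr)[keep]
  for (i in seq_along(s)) v[s[i]:e[i]] <- TRUE
  v
}

# maximal covered runs of a logical vector -> data.frame(start, end)
oracleRuns <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# compare a merged GRanges to the per-base oracle over all chromosomes
expectMatchesCoverageOracle <- function(merged, input, chromLens) {
  for (chr in names(chromLens)) {
    runs <- oracleRuns(oracleCoverageVec(input, chr, chromLens[[chr]]))
    got <- merged[as.character(GenomicRanges::seqnames(merged)) == chr]
    expect_equal(GenomicRanges::start(got), runs$start)
    expect_equal(GenomicRanges::end(got), runs$end)
  }
}

# random interval set on the given chromosomes
randomRegionSet <- function(n, chromLens, maxWidth = 100L) {
  chr <- sample(names(chromLens), n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(chromLens[[chr[i]]] - maxWidth, 1L), integer(1L))
  GenomicRanges::GRanges(chr, IRanges::IRanges(s, width = w))
}

# per-base distinct-source support over each merged run (each source's
# coverage vector is materialized once per chromosome)
oracleSupport <- function(merged, tfSets, chromLens) {
  cov <- lapply(tfSets, function(g)
    lapply(stats::setNames(names(chromLens), names(chromLens)),
           function(chr) oracleCoverageVec(g, chr, chromLens[[chr]])))
  chr <- as.character(GenomicRanges::seqnames(merged))
  s <- GenomicRanges::start(merged)
  e <- GenomicRanges::end(merged)
  vapply(seq_along(merged), function(i) {
    sum(vapply(names(tfSets), function(nm)
      any(cov[[nm]][[chr[i]]][s[i]:e[i]]), logical(1L)))
  }, integer(1L))
}

# linear-scan SNP membership oracle against a region set
oracleSnpMembership <- function(snps, regions) {
  chr <- as.character(GenomicRanges::seqnames(regions))
  s <- GenomicRanges::start(regions)
  e <- GenomicRanges::end(regions)
  vapply(seq_len(nrow(snps)), function(i) {
    any(chr == snps$chrom[i] & s <= snps$pos[i] & snps$pos[i] <= e)
  }, logical(1L))
}

# one-way ANOVA from explicit sums of squares
oracleAnova <- function(g, e) {
  ok <- !is.na(g) & !is.na(e)
  g <- g[ok]; e <- e[ok]
  groups <- split(e, g)
  N <- length(e); k <- length(groups)
  gm <- mean(e)
  ssb <- sum(vapply(groups, function(x)
    length(x) * (mean(x) - gm)^2, numeric(1L)))
  ssw <- sum(vapply(groups, function(x)
    sum((x - mean(x))^2), numeric(1L)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1L, df2 = N - k)
}

# exhaustive (offset x strand) motif placement enumeration, written with
# plain loops and its own complement table
oracleBestAlleleScore <- function(pwm, flank, allele) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  probs <- motifProbs(pwm)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  scoreSeq <- function(chars) {
    s <- 0
    for (i in seq_along(chars)) {
      if (chars[i] == "N") {
        s <- s + min(log2(pmax(probs[i, ], 1e-3) / bg))
      } else {
        s <- s + log2(max(probs[i, chars[i]], 1e-3) / bg[chars[i]])
      }
    }
    s
  }
  chars <- strsplit(flank, "")[[1]]
  center <- (length(chars) + 1L) %/% 2L
  chars[center] <- allele
  L <- nrow(probs)
  best <- NULL
  for (off in (-(L - 1L)):0L) {
    win <- chars[(center + off):(center + off + L - 1L)]
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") scoreSeq(win)
        else scoreSeq(rev(unname(comp[win])))
      sc <- unname(sc)
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, offset = off, strand = strand)
    }
  }
  best
}

# Kaplan-Meier product-limit estimate by direct risk-set counting
oracleKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    atRisk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / atRisk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# random PWM with moderate information content
randomPWM <- function(L = 8L, name = "TFX", threshold = 0) {
  probs <- matrix(stats::rgamma(L * 4L, shape = 0.8), L, 4L)
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  PWMModel(name, probs, threshold)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal SNP context builder for motif tests
makeCtx <- function(flank, alleleA, alleleB, id = "rs1") {
  list(snp = data.frame(snp_id = id, chrom = "chr1",
                        pos = (nchar(flank) + 1L) %/% 2L,
                        allele_a = alleleA, allele_b = alleleB,
                        stringsAsFactors = FALSE),
       flank = flank)
}

# small expression SummarizedExperiment from tumor/normal matrices;
# existing column names are preserved so genotype alignment survives
makeSE <- function(tumor, normal) {
  if (is.null(colnames(tumor)))
    colnames(tumor) <- paste0("T", seq_len(ncol(tumor)))
  if (is.null(colnames(normal)))
    colnames(normal) <- paste0("N", seq_len(ncol(normal)))
  mat <- cbind(tumor, normal)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    colData = S4Vectors::DataFrame(
      class = rep(c("tumor", "normal"), c(ncol(tumor), ncol(normal))),
      row.names = colnames(mat)))
}
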