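test_that("PWMModel validity and HOMER round trip", {
  expect_error(PWMModel("bad", matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4), 0),
               "do not sum to 1")
  flat <- PWMModel("flat", matrix(0.25, 1, 4), threshold = 0)
  expect_equal(motifLength(flat), 1L)
  expect_equal(scoreWindow(flat, "G"), 0)

  path <- tempfile(fileext = ".motifs")
  set.seed(7)
  pwms <- list(randomPWM(6L, "TF_A", threshold = 3.5),
               randomPWM(9L, "TF_B", threshold = -1.2))
  writeHomerMotifs(pwms, path)
  back <- readHomerMotifs(path)
  expect_named(back, c("TF_A", "TF_B"))
  for (i in 1:2) {
    expect_equal(motifProbs(back[[i]]), motifProbs(pwms[[i]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(motifThreshold(back[[i]]), motifThreshold(pwms[[i]]))
  }

  # malformed rows are reported with their line number
  writeLines(c(">AAAA TFX 1.0", "0.25 0.25 0.5"), path)
  expect_error(readHomerMotifs(path), "line 2")
  writeLines(c(">AAAA TFX 1.0", "0.25 0.25 0.25 x"), path)
  expect_error(readHomerMotifs(path), "non-numeric")
})

test_that("scoreWindow matches hand log-ratios and the per-position oracle", {
  onePos <- PWMModel("one", matrix(c(0.5, 0.25, 0.125, 0.125), 1, 4), 0)
  expect_equal(scoreWindow(onePos, "A"), 1)          # log2(0.5/0.25)
  expect_equal(scoreWindow(onePos, "G"), -1)         # log2(0.125/0.25)

  expect_error(scoreWindow(onePos, "AC"), "length")

  set.seed(17)
  for (rep in 1:25) {
    pwm <- randomPWM(sample(4:12, 1))
    seq <- randomDNA(motifLength(pwm))
    probs <- motifProbs(pwm)
    chars <- strsplit(seq, "")[[1]]
    want <- sum(vapply(seq_along(chars), function(i)
      log2(max(probs[i, chars[i]], 1e-3) / 0.25), numeric(1L)))
    expect_equal(scoreWindow(pwm, seq), want, tolerance = 1e-12)
  }

  # N scores as the worst-case base: never higher than any concrete base
  pwm <- randomPWM(3L)
  sN <- scoreWindow(pwm, "ANT")
  for (b in c("A", "C", "G", "T"))
    expect_lte(sN, scoreWindow(pwm, paste0("A", b, "T")))
})

test_that("scoring is monotone in the probability of the observed base", {
  set.seed(27)
  pwm <- randomPWM(5L)
  seq <- randomDNA(5L)
  base <- scoreWindow(pwm, seq)
  probs <- motifProbs(pwm)
  i <- 3L
  b <- substr(seq, i, i)
  # raise p at the observed base (renormalizing the others down)
  probs[i, ] <- probs[i, ] * 0.5
  probs[i, b] <- 1 - sum(probs[i, -match(b, colnames(probs))])
  up <- PWMModel("up", probs, 0)
  expect_gte(scoreWindow(up, seq), base)
})

test_that("bestAlleleScore equals the exhaustive placement enumeration oracle", {
  # an L = 1 motif admits exactly one offset per strand, both at the SNP base
  onePos <- PWMModel("one", matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4), 0)
  ctx <- makeCtx("AAAAA", "A", "T")
  best <- bestAlleleScore(onePos, ctx, "A")
  expect_equal(best$offset, 0L)
  expect_equal(best$score, log2(0.7 / 0.25))

  set.seed(37)
  for (rep in 1:40) {
    pwm <- randomPWM(sample(3:10, 1))
    ctx <- makeCtx(randomDNA(2L * 12L + 1L), "A", "G")
    for (allele in c("A", "G")) {
      got <- bestAlleleScore(pwm, ctx, allele)
      want <- oracleBestAlleleScore(pwm, ctx$flank, allele)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }

  # context too short for all placements is an explicit error
  long <- randomPWM(10L)
  expect_error(bestAlleleScore(long, makeCtx("ACGTACGTA", "G", "T"), "G"),
               "flank")
})

test_that("reverse-complementing the context preserves scores and swaps strands", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])),
                          collapse = "")
  set.seed(47)
  for (rep in 1:20) {
    pwm <- randomPWM(sample(3:8, 1))
    flank <- randomDNA(25L)
    allele <- sample(c("A", "C", "G", "T"), 1)
    fwd <- bestAlleleScore(pwm, makeCtx(flank, allele, "N"), allele)
    rev <- bestAlleleScore(pwm, makeCtx(rc(flank), comp[[allele]], "N"),
                           comp[[allele]])
    expect_equal(fwd$score, rev$score, tolerance = 1e-12)
  }
})

test_that("alleleEffect classifies planted disruptions and neutral ties", {
  set.seed(57)
  cfg <- simConfig(seed = 57)
  pwm <- simulateMotifs(cfg)[[1]]
  L <- motifLength(pwm)
  core <- as.integer(ceiling(L / 2))
  consensus <- strsplit(motifConsensus(pwm), "")[[1]]
  probs <- motifProbs(pwm)

  flankChars <- strsplit(randomDNA(41L), "")[[1]]
  flankChars[(21L - core + 1L):(21L - core + L)] <- consensus
  ctx <- makeCtx(paste(flankChars, collapse = ""), consensus[core],
                 colnames(probs)[which.min(probs[core, ])])
  eff <- alleleEffect(pwm, ctx)
  expect_equal(eff$call, "disrupt")
  expect_gte(eff$score_a, motifThreshold(pwm))
  expect_lt(eff$score_b, motifThreshold(pwm))

  # SNP far from any matching placement: both alleles below threshold
  ctxBg <- makeCtx(randomDNA(41L), "A", "C")
  effBg <- alleleEffect(pwm, ctxBg)
  expect_equal(effBg$call, "none")
})

test_that("scanSnpMotifEffects flags motif-change SNPs independent of motif order", {
  expect_equal(nrow(scanSnpMotifEffects(list(), list())), 0L)

  set.seed(67)
  cfg <- simConfig(seed = 67)
  pwms <- simulateMotifs(cfg)[1:2]
  # one planted disruption for pwm 1, one background SNP
  pwm <- pwms[[1]]
  L <- motifLength(pwm)
  core <- as.integer(ceiling(L / 2))
  consensus <- strsplit(motifConsensus(pwm), "")[[1]]
  fl <- strsplit(randomDNA(41L), "")[[1]]
  fl[(21L - core + 1L):(21L - core + L)] <- consensus
  ctxs <- list(
    hit = makeCtx(paste(fl, collapse = ""), consensus[core],
                  colnames(motifProbs(pwm))[
                    which.min(motifProbs(pwm)[core, ])], id = "hit"),
    bg = makeCtx(randomDNA(41L), "A", "G", id = "bg"))

  res <- scanSnpMotifEffects(ctxs, pwms)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$motif_change[res$snp_id == "hit"]))
  expect_false(any(res$motif_change[res$snp_id == "bg"]))

  resRev <- scanSnpMotifEffects(ctxs, rev(pwms))
  key <- function(d) d[order(d$snp_id, d$tf),
                       c("snp_id", "tf", "score_a", "score_b", "call")]
  expect_equal(key(res), key(resRev), ignore_attr = TRUE)
})
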