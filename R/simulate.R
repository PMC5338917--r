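# Seeded synthetic-data generator. Emits every input the pipeline consumes
# (peak BEDs, SNP manifest, reference FASTA, motif models, genotype and
# expression matrices, clinical follow-up) with planted ground truth:
# regulatory SNPs that simultaneously sit in a regulatory region, break a
# high-information TF motif, drive cis expression of a nearby gene, and mark
# a recurrence-risk gene.

#' Simulation configuration
#'
#' All generator randomness flows from `seed` through one child stream per
#' artifact (motifs, regions/SNPs, genes, genotypes, expression, survival),
#' so regenerating one artifact never perturbs the others.
#'
#' @param seed integer master seed.
#' @param n_tumor,n_normal tumor / normal sample counts.
#' @param n_snps total SNPs in the manifest (planted + decoys).
#' @param n_genes genes in the annotation.
#' @param n_planted planted regulatory SNPs.
#' @param maf_range minor-allele-frequency bounds for decoy SNPs.
#' @param planted_maf MAF of planted SNPs.
#' @param eqtl_beta additive genotype effect on log2 expression, in units of
#'   the expression noise SD.
#' @param noise_sd expression noise SD on the log2 scale.
#' @param hazard_ratio recurrence hazard ratio of the planted high-risk
#'   expression tail versus the rest.
#' @param censor_rate expected fraction of tumors randomly censored.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param motif_info_bits total information content of each planted PWM.
#' @param motif_length planted motif length (positions).
#' @param flank SNP context half-width (bp).
#' @param missing_rate genotype missingness rate.
#' @param n_de_planted planted target genes additionally given a
#'   tumor-versus-normal shift.
#' @param de_log2fc log2 fold change of the planted DE genes.
#' @param baseline_hazard baseline recurrence hazard (events per month).
#' @param followup_cap administrative censoring time (months).
#' @param tf_names names of the TF peak sets / motifs.
#' @return a validated `SimulationConfig` list.
#' @export
simConfig <- function(seed = 1L, n_tumor = 200L, n_normal = 52L,
                      n_snps = 500L, n_genes = 300L, n_planted = 5L,
                      maf_range = c(0.1, 0.5), planted_maf = 0.3,
                      eqtl_beta = 1.0, noise_sd = 0.5, hazard_ratio = 3,
                      censor_rate = 0.3,
                      chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                      motif_info_bits = 20, motif_length = 12L,
                      flank = 20L, missing_rate = 0.02,
                      n_de_planted = 2L, de_log2fc = 1.6,
                      baseline_hazard = log(2) / 60, followup_cap = 150,
                      tf_names = c("AR", "FOXA1", "GATA2", "NKX3-1",
                                   "HOXB13")) {
  cfg <- list(seed = as.integer(seed), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal), n_snps = as.integer(n_snps),
              n_genes = as.integer(n_genes),
              n_planted = as.integer(n_planted), maf_range = maf_range,
              planted_maf = planted_maf, eqtl_beta = eqtl_beta,
              noise_sd = noise_sd, hazard_ratio = hazard_ratio,
              censor_rate = censor_rate, chrom_lengths = chrom_lengths,
              motif_info_bits = motif_info_bits,
              motif_length = as.integer(motif_length),
              flank = as.integer(flank), missing_rate = missing_rate,
              n_de_planted = as.integer(n_de_planted),
              de_log2fc = de_log2fc, baseline_hazard = baseline_hazard,
              followup_cap = followup_cap, tf_names = tf_names)
  stopifnot(cfg$n_tumor > 0, cfg$n_normal > 0, cfg$n_snps > 0,
            cfg$n_genes > 0, cfg$n_planted >= 0,
            cfg$n_planted <= cfg$n_snps, cfg$n_genes >= cfg$n_planted,
            length(cfg$maf_range) == 2L, all(cfg$maf_range > 0),
            all(cfg$maf_range <= 0.5),
            cfg$planted_maf > 0, cfg$planted_maf <= 0.5,
            cfg$hazard_ratio > 0, cfg$censor_rate >= 0, cfg$censor_rate < 1,
            !is.null(names(cfg$chrom_lengths)),
            all(cfg$chrom_lengths > 2e5), cfg$noise_sd > 0,
            cfg$motif_length >= 4L, cfg$flank >= cfg$motif_length - 1L,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

# one child stream per artifact; documented scheme so artifact k is
# reproducible in isolation
.childSeed <- function(seed, k) (seed * 1009L + k * 7919L) %% 2147483647L

.randomSeq <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# per-position major-base probability giving the requested total information
# content for an L-position PWM with distribution (p, (1-p)/3, ...)
.majorProb <- function(totalBits, L) {
  perPos <- min(max(totalBits / L, 0.05), 1.995)
  f <- function(p) {
    q <- (1 - p) / 3
    2 + p * log2(p) + 3 * q * log2(q) - perPos
  }
  stats::uniroot(f, c(0.2501, 1 - 1e-9), tol = 1e-12)$root
}

#' Planted high-information PWMs, one per TF
#'
#' Each motif has a random consensus and uniform per-position information;
#' the detection threshold is set at 85% of the consensus score, so the
#' consensus matches while a single worst-base substitution at any position
#' falls below threshold.
#'
#' @param config a [simConfig()] object.
#' @return named list of [PWMModel-class].
#' @export
simulateMotifs <- function(config) {
  set.seed(.childSeed(config$seed, 1L))
  L <- config$motif_length
  p <- .majorProb(config$motif_info_bits, L)
  lapply(setNames(config$tf_names, config$tf_names), function(tf) {
    consensus <- .randomSeq(L)
    probs <- matrix((1 - p) / 3, L, 4L,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
    probs[cbind(seq_len(L), match(consensus, colnames(probs)))] <- p
    maxScore <- L * log2(p / 0.25)
    PWMModel(tf, probs, threshold = 0.85 * maxScore)
  })
}

.randomPeaks <- function(chromLengths, density, widthRange) {
  chrom <- integer(); start <- integer(); width <- integer()
  chrs <- character()
  for (chr in names(chromLengths)) {
    len <- chromLengths[[chr]]
    n <- max(1L, round(len / density))
    width <- c(width, sample(widthRange[1L]:widthRange[2L], n,
                             replace = TRUE))
    start <- c(start, sample.int(len - widthRange[2L], n, replace = TRUE))
    chrs <- c(chrs, rep(chr, n))
  }
  GenomicRanges::GRanges(chrs, IRanges::IRanges(start, width = width))
}

#' Simulate peak sets, reference sequence and the SNP manifest
#'
#' Generates random open-chromatin (DHS), H3K27ac and per-TF peak sets over
#' random reference chromosomes; plants `n_planted` SNPs at loci covered by
#' a DHS peak, a mark peak and one TF peak simultaneously, with the TF's
#' motif consensus written into the reference so that the SNP sits at a
#' motif core position (allele A = consensus base, allele B = the worst
#' base); and adds decoy SNPs both inside regulatory regions (away from any
#' planted motif) and outside them (rejection-sampled against the region
#' set).
#'
#' @param config a [simConfig()] object.
#' @param pwms planted motifs from [simulateMotifs()].
#' @return list with `peaks` (list: `dhs`, `mark`, `tf` named list),
#'   `reference` (`DNAStringSet`), `snps` (manifest `data.frame`),
#'   `regions` (the [buildRegulatoryRegions()] output used for decoy
#'   placement) and `truth` (planted SNP table plus decoy id vectors).
#' @export
simulateRegionsAndSnps <- function(config, pwms) {
  set.seed(.childSeed(config$seed, 2L))
  cl <- config$chrom_lengths
  refChars <- lapply(cl, .randomSeq)

  dhs <- .randomPeaks(cl, density = 3000, widthRange = c(200L, 800L))
  mark <- .randomPeaks(cl, density = 4000, widthRange = c(500L, 2000L))
  tfPeaks <- lapply(setNames(config$tf_names, config$tf_names), function(tf)
    .randomPeaks(cl, density = 5000, widthRange = c(100L, 400L)))

  L <- config$motif_length
  core <- as.integer(ceiling(L / 2))
  chromCycle <- rep(names(cl), length.out = config$n_planted)
  planted <- NULL
  for (i in seq_len(config$n_planted)) {
    chr <- chromCycle[i]
    len <- cl[[chr]]
    onChrom <- sum(chromCycle[seq_len(i)] == chr)
    nOnChrom <- sum(chromCycle == chr)
    pos <- round(len * onChrom / (nOnChrom + 1)) +
      sample.int(20000L, 1L) - 10000L
    tf <- config$tf_names[(i - 1L) %% length(config$tf_names) + 1L]
    pwm <- pwms[[tf]]
    consensus <- strsplit(motifConsensus(pwm), "")[[1]]
    alleleA <- consensus[core]
    probs <- motifProbs(pwm)
    alleleB <- colnames(probs)[which.min(probs[core, ])]
    span <- (pos - core + 1L):(pos - core + L)
    refChars[[chr]][span] <- consensus
    dhs <- c(dhs, GenomicRanges::GRanges(chr,
      IRanges::IRanges(pos - 500L, pos + 500L)))
    mark <- c(mark, GenomicRanges::GRanges(chr,
      IRanges::IRanges(pos - 700L, pos + 700L)))
    tfPeaks[[tf]] <- c(tfPeaks[[tf]], GenomicRanges::GRanges(chr,
      IRanges::IRanges(pos - 200L, pos + 200L)))
    planted <- rbind(planted, data.frame(
      snp_id = sprintf("rsP%04d", i), chrom = chr, pos = pos,
      allele_a = alleleA, allele_b = alleleB, tf = tf,
      stringsAsFactors = FALSE))
  }

  reference <- Biostrings::DNAStringSet(
    vapply(refChars, paste, character(1L), collapse = ""))
  names(reference) <- names(cl)

  regions <- buildRegulatoryRegions(dhs, mark, tfPeaks)

  guard <- config$flank + L  # keep decoys clear of planted motifs and edges
  nearPlanted <- function(chr, pos) {
    if (is.null(planted)) return(FALSE)
    any(planted$chrom == chr & abs(planted$pos - pos) < guard)
  }
  sampleDecoys <- function(n, inside) {
    reg <- regions$regulatory
    out <- NULL
    while (NROW(out) < n) {
      m <- max(2L * (n - NROW(out)), 50L)
      if (inside) {
        k <- sample.int(length(reg), m, replace = TRUE)
        chr <- as.character(GenomicRanges::seqnames(reg))[k]
        st <- GenomicRanges::start(reg)[k]
        en <- GenomicRanges::end(reg)[k]
        pos <- st + as.integer(floor(runif(m) * (en - st + 1L)))
      } else {
        chr <- sample(names(cl), m, replace = TRUE)
        pos <- guard + as.integer(floor(runif(m) *
                                          (cl[chr] - 2 * guard))) + 1L
      }
      ok <- pos > guard & pos <= cl[chr] - guard &
        !vapply(seq_len(m), function(i) nearPlanted(chr[i], pos[i]),
                logical(1L))
      loci <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos))
      ok <- ok & (IRanges::overlapsAny(loci, reg,
                                       ignore.strand = TRUE) == inside)
      if (any(ok))
        out <- rbind(out, data.frame(chrom = chr[ok], pos = pos[ok],
                                     stringsAsFactors = FALSE))
    }
    out <- out[seq_len(n), , drop = FALSE]
    out$allele_a <- vapply(seq_len(n), function(i)
      refChars[[out$chrom[i]]][out$pos[i]], character(1L))
    out$allele_b <- vapply(out$allele_a, function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1L))
    out
  }
  nInside <- min(40L, max(0L, config$n_snps - config$n_planted))
  nOutside <- config$n_snps - config$n_planted - nInside
  inside <- if (nInside > 0L) sampleDecoys(nInside, inside = TRUE)
  outside <- if (nOutside > 0L) sampleDecoys(nOutside, inside = FALSE)
  decoys <- rbind(inside, outside)
  if (!is.null(decoys))
    decoys <- data.frame(snp_id = sprintf("rsD%05d", seq_len(nrow(decoys))),
                         decoys, stringsAsFactors = FALSE)
  insideIds <- if (nInside > 0L) decoys$snp_id[seq_len(nInside)] else
    character()
  outsideIds <- setdiff(decoys$snp_id, insideIds)

  snps <- rbind(if (!is.null(planted))
    planted[, c("snp_id", "chrom", "pos", "allele_a", "allele_b")], decoys)
  snps <- snps[sample.int(nrow(snps)), , drop = FALSE]
  rownames(snps) <- NULL
  validateSnps(snps)

  # generation-time guarantees: planted SNPs overlap the regulatory set and
  # their intact-allele context scores at or above the motif threshold
  if (!is.null(planted)) {
    stopifnot(nrow(snpsInRegions(planted, regions$regulatory)) ==
                nrow(planted))
    ctxs <- snpContexts(planted, reference, flank = config$flank)
    for (i in seq_len(nrow(planted))) {
      pwm <- pwms[[planted$tf[i]]]
      sc <- bestAlleleScore(pwm, ctxs[[i]], planted$allele_a[i])
      stopifnot(sc$score >= motifThreshold(pwm))
    }
  }

  list(peaks = list(dhs = dhs, mark = mark, tf = tfPeaks),
       reference = reference, snps = snps, regions = regions,
       truth = list(planted = planted, decoy_inside = insideIds,
                    decoy_outside = outsideIds))
}

#' Simulate a gene annotation with planted cis targets
#'
#' Random TSS positions over the simulated chromosomes; the first
#' `n_planted` genes are relocated so each planted SNP has one target gene
#' with a TSS 2-20 kb away (inside the default 25 kb cis window).
#'
#' @param config a [simConfig()] object.
#' @param truth planted-SNP table from [simulateRegionsAndSnps()].
#' @return list with `genes` (annotation `data.frame`) and `targets`
#'   (named character: planted snp_id -> target gene_id).
#' @export
simulateGenes <- function(config, truth) {
  set.seed(.childSeed(config$seed, 3L))
  cl <- config$chrom_lengths
  chrom <- sample(names(cl), config$n_genes, replace = TRUE)
  tss <- vapply(chrom, function(ch) sample.int(cl[[ch]], 1L), integer(1L))
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(config$n_genes)),
                      chrom = chrom, tss = tss,
                      strand = sample(c("+", "-"), config$n_genes,
                                      replace = TRUE),
                      stringsAsFactors = FALSE)
  targets <- character()
  planted <- truth$planted
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      off <- sample(2000:20000, 1L) * sample(c(-1L, 1L), 1L)
      genes$chrom[i] <- planted$chrom[i]
      genes$tss[i] <- planted$pos[i] + off
      targets[planted$snp_id[i]] <- genes$gene_id[i]
    }
  }
  rownames(genes) <- NULL
  list(genes = genes, targets = targets)
}

#' Simulate a genotype matrix under Hardy-Weinberg proportions
#'
#' Per SNP, a minor-allele frequency is drawn uniformly from `maf_range`
#' (planted SNPs use `planted_maf`), genotypes are the sum of two Bernoulli
#' allele draws (Hardy-Weinberg proportions), and calls are masked missing
#' at `missing_rate`.
#'
#' @param config a [simConfig()] object.
#' @param snpIds SNP identifiers (manifest order).
#' @param plantedIds ids of planted SNPs (never masked missing, so planted
#'   effects keep their nominal sample size).
#' @return list with `observed` (samples x SNPs integer matrix with NAs)
#'   and `complete` (the unmasked matrix used to generate expression).
#' @export
simulateGenotypes <- function(config, snpIds, plantedIds = character()) {
  set.seed(.childSeed(config$seed, 4L))
  n <- config$n_tumor
  samples <- sprintf("T%03d", seq_len(n))
  maf <- runif(length(snpIds), config$maf_range[1L], config$maf_range[2L])
  maf[snpIds %in% plantedIds] <- config$planted_maf
  gt <- vapply(maf, function(q) rbinom(n, 2L, q), integer(n))
  dimnames(gt) <- list(samples, snpIds)
  observed <- gt
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(gt)) < config$missing_rate, nrow = n)
    mask[, snpIds %in% plantedIds] <- FALSE
    observed[mask] <- NA_integer_
  }
  list(observed = observed, complete = gt)
}

#' Simulate the expression matrix with planted cis effects
#'
#' Gene values are generated on the log2 scale — per-gene baseline plus
#' Gaussian noise (`noise_sd`), plus `eqtl_beta * noise_sd * genotype` for
#' planted SNP-target pairs in tumors, plus `de_log2fc` in tumors for the
#' planted DE genes — then exponentiated to a nonnegative normalized scale.
#' Normal samples carry baseline and noise only.
#'
#' @param config a [simConfig()] object.
#' @param genotypes `complete` genotype matrix from [simulateGenotypes()].
#' @param targets planted snp_id -> gene_id map from [simulateGenes()].
#' @param genes gene annotation `data.frame`.
#' @return list with `se` (a `SummarizedExperiment`, genes x samples, assay
#'   `expr`, `colData$class`), `de_genes` (planted DE gene ids) and
#'   `risk_gene` (the planted recurrence-risk gene, the first target).
#' @export
simulateExpression <- function(config, genotypes, targets, genes) {
  set.seed(.childSeed(config$seed, 5L))
  nG <- config$n_genes
  tumorIds <- rownames(genotypes)
  normalIds <- sprintf("N%03d", seq_len(config$n_normal))
  baseline <- rnorm(nG, mean = 5, sd = 1.5)
  tum <- baseline + matrix(rnorm(nG * length(tumorIds), 0, config$noise_sd),
                           nG)
  nor <- baseline + matrix(rnorm(nG * length(normalIds), 0, config$noise_sd),
                           nG)
  rownames(tum) <- rownames(nor) <- genes$gene_id
  colnames(tum) <- tumorIds
  colnames(nor) <- normalIds
  for (snp in names(targets)) {
    g <- genotypes[, snp]
    tum[targets[[snp]], ] <- tum[targets[[snp]], ] +
      config$eqtl_beta * config$noise_sd * g
  }
  # the risk gene (last target) is kept free of the tumor-wide DE shift: a
  # strongly DE gene has nearly all-positive z-scores versus normals, which
  # leaves no low-expression stratum to contrast in the survival analysis
  nDe <- min(config$n_de_planted, max(0L, length(targets) - 1L))
  deGenes <- unname(targets[seq_len(nDe)])
  for (g in deGenes) tum[g, ] <- tum[g, ] + config$de_log2fc
  mat <- 2 ^ cbind(tum, nor)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    colData = S4Vectors::DataFrame(
      class = rep(c("tumor", "normal"),
                  c(length(tumorIds), length(normalIds))),
      row.names = c(tumorIds, normalIds)))
  list(se = se, de_genes = deGenes,
       risk_gene = if (length(targets))
         unname(targets[[length(targets)]]) else NA_character_)
}

#' Simulate biochemical-recurrence follow-up
#'
#' Exponential event times with baseline hazard `baseline_hazard`; tumors in
#' the planted high-risk tail (positive z-score of the risk gene versus
#' normals) have their hazard multiplied by `hazard_ratio`. Follow-up is
#' capped administratively at `followup_cap` months and additionally
#' censored uniformly at rate `censor_rate`.
#'
#' @param config a [simConfig()] object.
#' @param se expression `SummarizedExperiment` from [simulateExpression()].
#' @param riskGene the planted risk gene id.
#' @return clinical `data.frame` (`sample_id`, `time`, `event`).
#' @export
simulateSurvival <- function(config, se, riskGene) {
  set.seed(.childSeed(config$seed, 6L))
  cls <- SummarizedExperiment::colData(se)$class
  mat <- SummarizedExperiment::assay(se, "expr")
  tumorIds <- colnames(se)[cls == "tumor"]
  highTail <- if (!is.na(riskGene)) {
    z <- zscoreVsNormals(mat[riskGene, tumorIds],
                         mat[riskGene, cls == "normal"])
    z > 0
  } else rep(FALSE, length(tumorIds))
  hazard <- config$baseline_hazard *
    ifelse(highTail, config$hazard_ratio, 1)
  t <- rexp(length(tumorIds), rate = hazard)
  event <- rep(1L, length(tumorIds))
  over <- t > config$followup_cap
  t[over] <- config$followup_cap
  event[over] <- 0L
  cens <- runif(length(tumorIds)) < config$censor_rate
  event[cens] <- 0L
  t[cens] <- runif(sum(cens), 0, t[cens])
  data.frame(sample_id = tumorIds, time = t, event = event,
             stringsAsFactors = FALSE)
}

#' Run the full synthetic-data generator
#'
#' @param config a [simConfig()] object.
#' @return list with elements `config`, `pwms`, `peaks`, `reference`,
#'   `snps`, `regions`, `genes`, `genotypes` (observed matrix), `se`
#'   (expression), `clinical`, and `truth` (planted SNP table with target
#'   genes and effect descriptors, decoy id vectors, `de_genes`,
#'   `risk_gene`, `risk_direction`).
#' @export
simulateRegSnpData <- function(config = simConfig()) {
  pwms <- simulateMotifs(config)
  rs <- simulateRegionsAndSnps(config, pwms)
  gn <- simulateGenes(config, rs$truth)
  plantedIds <- if (is.null(rs$truth$planted)) character() else
    rs$truth$planted$snp_id
  gt <- simulateGenotypes(config, rs$snps$snp_id, plantedIds)
  ex <- simulateExpression(config, gt$complete, gn$targets, gn$genes)
  clinical <- simulateSurvival(config, ex$se, ex$risk_gene)
  planted <- rs$truth$planted
  if (!is.null(planted)) {
    planted$target_gene <- unname(gn$targets[planted$snp_id])
    planted$eqtl_beta <- config$eqtl_beta
    planted$de_planted <- planted$target_gene %in% ex$de_genes
    planted$risk_planted <- planted$target_gene %in% ex$risk_gene
  }
  list(config = config, pwms = pwms, peaks = rs$peaks,
       reference = rs$reference, snps = rs$snps, regions = rs$regions,
       genes = gn$genes, genotypes = gt$observed, se = ex$se,
       clinical = clinical,
       truth = list(planted = planted,
                    decoy_inside = rs$truth$decoy_inside,
                    decoy_outside = rs$truth$decoy_outside,
                    de_genes = ex$de_genes, risk_gene = ex$risk_gene,
                    risk_direction = "high"))
}

#' Write all simulated artifacts to a directory
#'
#' Emits the plain-text interchange files the pipeline reads: peak BEDs,
#' SNP manifest, gene annotation, genotype/expression/class/clinical TSVs,
#' reference FASTA, HOMER-style motif file, and a machine-readable
#' ground-truth JSON sidecar.
#'
#' @param sim output of [simulateRegSnpData()].
#' @param dir output directory (created if needed).
#' @return named list of written file paths (element `tfs` is a named
#'   vector, one BED per TF).
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writePeaksBed(sim$peaks$dhs, p("dhs.bed"))
  writePeaksBed(sim$peaks$mark, p("h3k27ac.bed"))
  tfPaths <- vapply(names(sim$peaks$tf), function(tf) {
    writePeaksBed(sim$peaks$tf[[tf]], p(paste0("tf_", tf, ".bed")))
  }, character(1L))
  .writeTsv(sim$snps, p("snps.tsv"))
  .writeTsv(sim$genes, p("genes.tsv"))
  .writeTsv(data.frame(sample_id = rownames(sim$genotypes),
                       sim$genotypes, check.names = FALSE),
            p("genotypes.tsv"))
  mat <- SummarizedExperiment::assay(sim$se, "expr")
  .writeTsv(data.frame(gene_id = rownames(mat), round(mat, 4L),
                       check.names = FALSE), p("expression.tsv"))
  .writeTsv(data.frame(sample_id = colnames(sim$se),
                       class = SummarizedExperiment::colData(sim$se)$class),
            p("classes.tsv"))
  .writeTsv(data.frame(sample_id = sim$clinical$sample_id,
                       time_months = round(sim$clinical$time, 4L),
                       event = sim$clinical$event), p("clinical.tsv"))
  Biostrings::writeXStringSet(sim$reference, p("reference.fa"))
  writeHomerMotifs(sim$pwms, p("motifs.txt"))
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  list(dhs = p("dhs.bed"), mark = p("h3k27ac.bed"), tfs = tfPaths,
       snps = p("snps.tsv"), genes = p("genes.tsv"),
       genotypes = p("genotypes.tsv"), expr = p("expression.tsv"),
       classes = p("classes.tsv"), clinical = p("clinical.tsv"),
       fasta = p("reference.fa"), motifs = p("motifs.txt"),
       truth = p("truth.json"))
}
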