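# End-to-end orchestration: regions -> SNP filter -> eQTL -> motif -> DE ->
# risk, with per-stage attrition counts and a joined candidate report.

.defaultParams <- function() {
  list(window = 25000L, fdr = 0.05, minGroupSize = 3L, flank = 20L,
       deltaMin = 2, fcThreshold = 1.5, pThreshold = 0.01,
       keepFraction = 0.75, promoterWindow = 2000L)
}

#' Run the regulatory-SNP prioritization pipeline
#'
#' Executes the full workflow from plain-text inputs: (1) build the
#' regulatory region set from open-chromatin, histone-mark and per-TF peak
#' BEDs; (2) keep manifest SNPs falling inside it; (3) cis-eQTL ANOVA scan
#' of retained SNPs against genes within the window, BH-corrected; (4)
#' allele-specific motif scan of the eQTL-significant SNPs; (5) candidate
#' SNPs are those passing the region filter AND carrying a significant eQTL
#' AND a disrupt/create motif call; (6) candidate target genes are
#' annotated (not filtered) with tumor-versus-normal differential
#' expression and recurrence-risk log-rank results.
#'
#' @param paths named list of input paths: `dhs`, `mark` (one or more
#'   BEDs), `tfs` (named vector of per-TF BEDs), `snps`, `genes`,
#'   `genotypes`, `expr`, `classes`, `clinical`, `fasta`, `motifs`.
#' @param params named list overriding pipeline thresholds: `window`
#'   (cis half-window, bp), `fdr`, `minGroupSize`, `flank`, `deltaMin`
#'   (bits), `fcThreshold`, `pThreshold`, `keepFraction`,
#'   `promoterWindow` (bp for the promoter/distal annotation).
#' @param outDir optional directory; when given, per-stage artifacts
#'   (regulatory.bed, eqtl.tsv, motif.tsv, de.tsv, risk.tsv), the candidate
#'   report, the attrition table and the resolved parameters are written
#'   there.
#' @return list with `report` (candidate table, one row per candidate
#'   SNP-gene pair), `attrition` (per-stage counts), `stages` (the raw
#'   per-stage outputs) and `params` (resolved thresholds).
#' @export
runPipeline <- function(paths, params = list(), outDir = NULL) {
  pr <- utils::modifyList(.defaultParams(), params)

  dhs <- readPeaksBed(paths$dhs)
  marks <- lapply(unlist(paths$mark), readPeaksBed)
  tfPeaks <- lapply(unlist(paths$tfs), readPeaksBed)
  names(tfPeaks) <- names(unlist(paths$tfs))
  snps <- readSnpManifest(paths$snps)
  genes <- readGeneAnnotation(paths$genes)
  genotypes <- readGenotypeMatrix(paths$genotypes)
  se <- readExpressionMatrix(paths$expr, paths$classes)
  clinical <- readClinical(paths$clinical)
  pwms <- readHomerMotifs(paths$motifs)

  regions <- buildRegulatoryRegions(dhs, marks, tfPeaks)
  se <- dropSilentGenes(se)

  snpsReg <- snpsInRegions(snps, regions$regulatory)
  eqtl <- runEqtlScan(snpsReg, genotypes, se, genes, window = pr$window,
                      fdr = pr$fdr, minGroupSize = pr$minGroupSize)
  sigPairs <- eqtl[eqtl$significant, , drop = FALSE]
  eqtlSnps <- unique(sigPairs$snp_id)

  motif <- if (length(eqtlSnps) > 0L) {
    ctxs <- snpContexts(snps[snps$snp_id %in% eqtlSnps, , drop = FALSE],
                        paths$fasta, flank = pr$flank)
    scanSnpMotifEffects(ctxs, pwms, deltaMin = pr$deltaMin)
  } else {
    scanSnpMotifEffects(list(), pwms, deltaMin = pr$deltaMin)
  }
  motifSnps <- unique(motif$snp_id[motif$motif_change])

  candidates <- sigPairs[sigPairs$snp_id %in% motifSnps, , drop = FALSE]
  candGenes <- unique(candidates$gene_id)

  de <- if (length(candGenes)) deCall(se, candGenes,
                                      fcThreshold = pr$fcThreshold,
                                      pThreshold = pr$pThreshold)
    else deCall(se, character())
  risk <- riskScan(se, clinical, candGenes, keepFraction = pr$keepFraction)

  report <- .buildReport(candidates, snpsReg, motif, de, risk, genes,
                         pr$promoterWindow)
  attrition <- data.frame(
    stage = c("snps_in_manifest", "snps_in_regions", "snps_eqtl_significant",
              "snps_motif_change", "candidate_snps", "candidate_genes_de",
              "candidate_genes_risk"),
    n_in = c(nrow(snps), nrow(snps), nrow(snpsReg), length(eqtlSnps),
             length(eqtlSnps), length(candGenes), length(candGenes)),
    n_out = c(nrow(snps), nrow(snpsReg), length(eqtlSnps),
              length(motifSnps), length(unique(report$snp_id)),
              sum(de$is_de), sum(risk$risk_assoc)),
    stringsAsFactors = FALSE)

  res <- list(report = report, attrition = attrition,
              stages = list(regions = regions, snps_in_regions = snpsReg,
                            eqtl = eqtl, motif = motif, de = de,
                            risk = risk),
              params = pr)
  if (!is.null(outDir)) .writePipelineOutputs(res, outDir)
  res
}

.buildReport <- function(candidates, snpsReg, motif, de, risk, genes,
                         promoterWindow) {
  empty <- data.frame(snp_id = character(), region_chrom = character(),
                      region_start = integer(), region_end = integer(),
                      support_tfs = character(), gene_id = character(),
                      eqtl_p = numeric(), eqtl_fdr = numeric(),
                      motif_tf = character(), motif_call = character(),
                      motif_delta = numeric(), promoter = logical(),
                      is_de = logical(), de_log2_fc = numeric(),
                      risk_p = numeric(), risk_assoc = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    sid <- candidates$snp_id[i]
    gid <- candidates$gene_id[i]
    reg <- snpsReg[snpsReg$snp_id == sid, , drop = FALSE][1L, ]
    mt <- motif[motif$snp_id == sid &
                  motif$call %in% c("disrupt", "create"), , drop = FALSE]
    mt <- mt[order(-abs(mt$delta)), , drop = FALSE][1L, ]
    deRow <- de[de$gene_id == gid, , drop = FALSE]
    rkRow <- risk[risk$gene_id == gid, , drop = FALSE]
    tss <- genes$tss[genes$gene_id == gid][1L]
    data.frame(snp_id = sid, region_chrom = reg$region_chrom,
               region_start = reg$region_start, region_end = reg$region_end,
               support_tfs = if ("support_tfs" %in% names(reg))
                 reg$support_tfs else NA_character_,
               gene_id = gid, eqtl_p = candidates$p_value[i],
               eqtl_fdr = candidates$p_adj[i], motif_tf = mt$tf,
               motif_call = mt$call, motif_delta = mt$delta,
               promoter = abs(reg$pos - tss) <= promoterWindow,
               is_de = deRow$is_de[1L], de_log2_fc = deRow$log2_fc[1L],
               risk_p = rkRow$p_value[1L], risk_assoc = rkRow$risk_assoc[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$eqtl_p, out$snp_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writePeaksBed(res$stages$regions$regulatory,
                file.path(outDir, "regulatory.bed"))
  .writeTsv(res$stages$snps_in_regions,
            file.path(outDir, "snps_in_regions.tsv"))
  .writeTsv(res$stages$eqtl, file.path(outDir, "eqtl.tsv"))
  .writeTsv(res$stages$motif, file.path(outDir, "motif.tsv"))
  .writeTsv(res$stages$de, file.path(outDir, "de.tsv"))
  .writeTsv(res$stages$risk, file.path(outDir, "risk.tsv"))
  .writeTsv(res$report, file.path(outDir, "report.tsv"))
  .writeTsv(res$attrition, file.path(outDir, "attrition.tsv"))
  jsonlite::write_json(res$params, file.path(outDir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Per-stage attrition counts recomputed from pipeline stage outputs
#'
#' Recounts items entering and leaving each SNP-centric stage directly from
#' the stage artifacts of a [runPipeline()] result, so the table can be
#' checked against the pipeline's own bookkeeping.
#'
#' @param res a [runPipeline()] result.
#' @return `data.frame` with columns `stage`, `n_in`, `n_out`.
#' @export
attritionSummary <- function(res) {
  st <- res$stages
  nManifest <- res$attrition$n_in[1L]
  nReg <- nrow(st$snps_in_regions)
  eqtlSnps <- unique(st$eqtl$snp_id[st$eqtl$significant])
  motifSnps <- unique(st$motif$snp_id[st$motif$motif_change])
  data.frame(
    stage = c("snps_in_manifest", "snps_in_regions", "snps_eqtl_significant",
              "snps_motif_change", "candidate_snps", "candidate_genes_de",
              "candidate_genes_risk"),
    n_in = c(nManifest, nManifest, nReg, length(eqtlSnps),
             length(eqtlSnps), nrow(st$de), nrow(st$risk)),
    n_out = c(nManifest, nReg, length(eqtlSnps), length(motifSnps),
              length(unique(res$report$snp_id)), sum(st$de$is_de),
              sum(st$risk$risk_assoc)),
    stringsAsFactors = FALSE)
}
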