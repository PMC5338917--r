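# cis-eQTL scan: one-way ANOVA of expression across genotype groups for
# every SNP-gene pair within a +/- 25 kb window around the SNP.

#' Drop genes that are zero across all samples
#'
#' @param se a `SummarizedExperiment` with assay `expr`.
#' @return `se` with all-zero genes removed, order otherwise preserved.
#' @export
dropSilentGenes <- function(se) {
  mat <- SummarizedExperiment::assay(se, "expr")
  se[rowSums(mat != 0) > 0L, ]
}

#' Genes with a TSS within a window of a SNP
#'
#' Distance is SNP position to TSS, boundary inclusive; results are ordered
#' by distance ascending with ties broken by `gene_id`.
#'
#' @param snp one-row SNP manifest slice (needs `chrom`, `pos`).
#' @param genes gene annotation `data.frame` (`gene_id`, `chrom`, `tss`).
#' @param window half-window in bp (default 25000, i.e. a 50 kb interval).
#' @return the qualifying rows of `genes` with a `distance` column.
#' @export
genesNearSnp <- function(snp, genes, window = 25000L) {
  stopifnot(window > 0)
  hit <- genes[genes$chrom == snp$chrom &
                 abs(genes$tss - snp$pos) <= window, , drop = FALSE]
  hit$distance <- abs(hit$tss - snp$pos)
  hit <- hit[order(hit$distance, hit$gene_id), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' One-way ANOVA of expression across genotype groups
#'
#' Groups samples by observed genotype class (0/1/2 copies of allele B),
#' drops samples with missing genotype and classes with fewer than
#' `minGroupSize` members, and tests equality of group means with a one-way
#' ANOVA. With fewer than two eligible groups the pair is flagged
#' untestable rather than erroring. If every group has zero within-group
#' variance but the means differ, the F statistic is unbounded and the
#' p-value is reported as 0.
#'
#' @param genotype integer vector of per-sample allele-B copy counts
#'   (0/1/2/NA).
#' @param expression numeric vector of per-sample expression, same order.
#' @param minGroupSize smallest genotype class retained (default 3).
#' @return list with `testable`, `f_stat`, `p_value`, `df1`, `df2`,
#'   `group_sizes` and `group_means` (both named by genotype class).
#' @export
anovaEqtl <- function(genotype, expression, minGroupSize = 3L) {
  stopifnot(length(genotype) == length(expression))
  ok <- !is.na(genotype) & !is.na(expression)
  g <- genotype[ok]; e <- expression[ok]
  sizes <- table(g)
  keep <- names(sizes)[sizes >= minGroupSize]
  sel <- g %in% keep
  g <- g[sel]; e <- e[sel]
  groups <- sort(unique(g))
  means <- vapply(groups, function(k) mean(e[g == k]), numeric(1L))
  names(means) <- groups
  ns <- vapply(groups, function(k) sum(g == k), integer(1L))
  names(ns) <- groups
  out <- list(testable = FALSE, f_stat = NA_real_, p_value = NA_real_,
              df1 = NA_integer_, df2 = NA_integer_,
              group_sizes = ns, group_means = means)
  if (length(groups) < 2L)
    return(out)
  fit <- stats::lm(e ~ factor(g))
  # anova.lm warns on a perfect fit; that degenerate case is handled
  # explicitly below
  an <- suppressWarnings(stats::anova(fit))
  ssw <- an$`Sum Sq`[2L]
  ssb <- an$`Sum Sq`[1L]
  out$testable <- TRUE
  out$df1 <- an$Df[1L]
  out$df2 <- an$Df[2L]
  if (ssw <= .Machine$double.eps * (ssb + ssw)) {
    # degenerate: no within-group variance
    if (ssb > 0) { out$f_stat <- Inf; out$p_value <- 0 }
    else { out$f_stat <- 0; out$p_value <- 1 }
  } else {
    out$f_stat <- an$`F value`[1L]
    out$p_value <- an$`Pr(>F)`[1L]
  }
  out
}

#' cis-eQTL scan over all SNP-gene pairs within a window
#'
#' Restricts to tumor samples present in both the genotype and expression
#' matrices, tests every SNP-gene pair whose TSS lies within `window` bp of
#' the SNP with [anovaEqtl()], and applies Benjamini-Hochberg FDR control
#' across all testable pairs.
#'
#' @param snps SNP manifest `data.frame`; only SNPs present as genotype
#'   columns are scanned.
#' @param genotypes samples x SNPs integer matrix (see
#'   [readGenotypeMatrix()]).
#' @param se expression `SummarizedExperiment` with `colData$class`.
#' @param genes gene annotation `data.frame`.
#' @param window cis half-window in bp (default 25000).
#' @param fdr Benjamini-Hochberg FDR level for the `significant` flag
#'   (default 0.05). Set `pCutoff` instead to use a raw p threshold.
#' @param pCutoff optional raw p-value threshold overriding the FDR rule.
#' @param minGroupSize passed to [anovaEqtl()].
#' @param log2Transform if `TRUE`, expression is log2(x+1)-transformed
#'   before the ANOVA (default `FALSE`: values are used as provided).
#' @return `data.frame` with one row per tested pair: `snp_id`, `gene_id`,
#'   `distance`, `n_groups`, `group_sizes`, `group_means`, `f_stat`,
#'   `p_value`, `p_adj` (BH across testable pairs), `significant`,
#'   `testable`.
#' @export
runEqtlScan <- function(snps, genotypes, se, genes, window = 25000L,
                        fdr = 0.05, pCutoff = NULL, minGroupSize = 3L,
                        log2Transform = FALSE) {
  tumor <- colnames(se)[SummarizedExperiment::colData(se)$class == "tumor"]
  samples <- intersect(tumor, rownames(genotypes))
  if (length(samples) == 0L)
    stop("no overlapping tumor samples between genotype and expression data")
  mat <- SummarizedExperiment::assay(se, "expr")[, samples, drop = FALSE]
  if (log2Transform) mat <- log2(mat + 1)
  gt <- genotypes[samples, , drop = FALSE]
  empty <- data.frame(snp_id = character(), gene_id = character(),
                      distance = integer(), n_groups = integer(),
                      group_sizes = character(), group_means = character(),
                      f_stat = numeric(), p_value = numeric(),
                      p_adj = numeric(), significant = logical(),
                      testable = logical(), stringsAsFactors = FALSE)
  snps <- snps[snps$snp_id %in% colnames(gt), , drop = FALSE]
  if (nrow(snps) == 0L || nrow(genes) == 0L)
    return(empty)
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    near <- genesNearSnp(snps[i, ], genes, window = window)
    near <- near[near$gene_id %in% rownames(mat), , drop = FALSE]
    if (nrow(near) == 0L) next
    gvec <- gt[, snps$snp_id[i]]
    for (j in seq_len(nrow(near))) {
      res <- anovaEqtl(gvec, mat[near$gene_id[j], ],
                       minGroupSize = minGroupSize)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snps$snp_id[i], gene_id = near$gene_id[j],
        distance = near$distance[j],
        n_groups = length(res$group_sizes),
        group_sizes = paste(names(res$group_sizes), res$group_sizes,
                            sep = ":", collapse = ","),
        group_means = paste(names(res$group_means),
                            signif(res$group_means, 6L),
                            sep = ":", collapse = ","),
        f_stat = res$f_stat, p_value = res$p_value,
        testable = res$testable, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[out$testable] <- p.adjust(out$p_value[out$testable], "BH")
  out$significant <- if (is.null(pCutoff)) {
    !is.na(out$p_adj) & out$p_adj <= fdr
  } else {
    out$testable & out$p_value < pCutoff
  }
  rownames(out) <- NULL
  out[, c("snp_id", "gene_id", "distance", "n_groups", "group_sizes",
          "group_means", "f_stat", "p_value", "p_adj", "significant",
          "testable")]
}
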