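# Tumor-versus-normal differential expression call for SNP-associated genes.

#' Differential expression call for a set of genes
#'
#' For each gene, the fold change is the ratio of class means on the linear
#' scale with an offset guarding zero means, `(mean_tumor + c) /
#' (mean_normal + c)` with `c = 1`, and the p-value comes from Welch's
#' two-sample t-test on log2(x+1)-transformed values (a Wilcoxon rank-sum
#' option is available). A gene is called differentially expressed when
#' |log2 fold change| exceeds `log2(fcThreshold)` and p is below
#' `pThreshold`. Fold change above 1 means tumor-high.
#'
#' @param se expression `SummarizedExperiment` with `colData$class` in
#'   tumor/normal.
#' @param geneIds genes to test (default: all genes in `se`).
#' @param fcThreshold linear fold-change cutoff (default 1.5).
#' @param pThreshold p-value cutoff (default 0.01).
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param offset linear-scale offset `c` guarding zero means (default 1).
#' @return `data.frame` with `gene_id`, `mean_tumor`, `mean_normal`,
#'   `fold_change`, `log2_fc`, `p_value`, `is_de`, `testable`. A class with
#'   fewer than 2 samples makes every gene untestable (flagged, not an
#'   error).
#' @export
deCall <- function(se, geneIds = rownames(se), fcThreshold = 1.5,
                   pThreshold = 0.01, test = c("welch", "wilcoxon"),
                   offset = 1) {
  test <- match.arg(test)
  missing <- setdiff(geneIds, rownames(se))
  if (length(missing))
    stop("genes absent from expression matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  cls <- SummarizedExperiment::colData(se)$class
  mat <- SummarizedExperiment::assay(se, "expr")
  tum <- mat[geneIds, cls == "tumor", drop = FALSE]
  nor <- mat[geneIds, cls == "normal", drop = FALSE]
  testable <- ncol(tum) >= 2L && ncol(nor) >= 2L
  out <- data.frame(gene_id = geneIds,
                    mean_tumor = rowMeans(tum),
                    mean_normal = rowMeans(nor),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$fold_change <- (out$mean_tumor + offset) / (out$mean_normal + offset)
  out$log2_fc <- log2(out$fold_change)
  out$p_value <- rep(NA_real_, nrow(out))
  if (testable && nrow(out) > 0L) {
    lt <- log2(tum + 1); ln <- log2(nor + 1)
    out$p_value <- vapply(seq_along(geneIds), function(i) {
      x <- lt[i, ]; y <- ln[i, ]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        # t-test undefined with no variance; equal constants are null
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      }
      if (test == "welch") stats::t.test(x, y)$p.value
      else stats::wilcox.test(x, y, exact = FALSE)$p.value
    }, numeric(1L))
  }
  out$is_de <- testable & abs(out$log2_fc) > log2(fcThreshold) &
    !is.na(out$p_value) & out$p_value < pThreshold
  out$testable <- rep(testable, nrow(out))
  out
}
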