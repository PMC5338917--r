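# Readers and writers for the plain-text interchange formats the pipeline
# consumes: BED peak files, TSV matrices and manifests, FASTA reference.

#' Read a BED peak file as GRanges
#'
#' @param path BED3+ file (chrom, start, end, optional name/score).
#' @return [GenomicRanges::GRanges] in 1-based closed in-memory coordinates.
#' @export
readPeaksBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  .validateRegions(gr, basename(path))
  gr
}

#' Write GRanges as BED
#'
#' @param gr a `GRanges`.
#' @param path output path (0-based half-open on disk).
#' @return `path`, invisibly.
#' @export
writePeaksBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a SNP manifest
#'
#' TSV with columns `snp_id`, `chrom`, `pos` (1-based), `allele_a`,
#' `allele_b`. Alleles must be distinct single bases in A/C/G/T.
#'
#' @param path manifest path.
#' @return validated `data.frame`.
#' @export
readSnpManifest <- function(path) {
  snps <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(pos = "integer"))
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(snps)))
    stop("SNP manifest must have columns ", paste(need, collapse = ", "))
  validateSnps(snps)
}

#' Validate a SNP manifest data.frame
#' @param snps `data.frame` with manifest columns.
#' @return `snps`, invisibly unchanged, or an error naming the bad record.
#' @export
validateSnps <- function(snps) {
  bad <- which(snps$pos < 1L | !snps$allele_a %in% c("A", "C", "G", "T") |
               !snps$allele_b %in% c("A", "C", "G", "T") |
               snps$allele_a == snps$allele_b | !nzchar(snps$chrom))
  if (length(bad))
    stop("invalid SNP record(s): ",
         paste(head(snps$snp_id[bad], 5L), collapse = ", "))
  snps
}

#' Read a genotype matrix
#'
#' TSV with samples as rows (first column `sample_id`) and SNP identifiers
#' as columns; cells are allele-B copy counts in \{0, 1, 2\} or NA.
#'
#' @param path genotype TSV path.
#' @return integer matrix, samples x SNPs, with sample rownames.
#' @export
readGenotypeMatrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gt <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(gt) <- "integer"
  rownames(gt) <- df[[1L]]
  if (any(!is.na(gt) & !gt %in% 0:2))
    stop("genotype calls must be in {0, 1, 2, NA}")
  gt
}

#' Read an expression matrix with tumor/normal labels
#'
#' Expression TSV has genes as rows (first column `gene_id`) and samples as
#' columns; the sidecar class TSV has columns `sample_id`, `class` with
#' class in \{tumor, normal\}.
#'
#' @param exprPath expression TSV path.
#' @param classPath sample-class sidecar TSV path.
#' @return [SummarizedExperiment::SummarizedExperiment] with assay `expr`
#'   and `colData$class`.
#' @export
readExpressionMatrix <- function(exprPath, classPath) {
  df <- read.delim(exprPath, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  cls <- read.delim(classPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(cls)))
    stop("class sidecar needs columns sample_id, class")
  if (!all(colnames(mat) %in% cls$sample_id))
    stop("samples missing from class sidecar: ",
         paste(head(setdiff(colnames(mat), cls$sample_id), 5L),
               collapse = ", "))
  cls <- cls[match(colnames(mat), cls$sample_id), ]
  if (!all(cls$class %in% c("tumor", "normal")))
    stop("sample class must be 'tumor' or 'normal'")
  if (any(mat < 0, na.rm = TRUE))
    stop("expression values must be nonnegative")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    colData = S4Vectors::DataFrame(class = cls$class,
                                   row.names = cls$sample_id))
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `chrom`, `tss` (1-based), `strand` (+/-).
#'
#' @param path annotation TSV path.
#' @return `data.frame`.
#' @export
readGeneAnnotation <- function(path) {
  genes <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(tss = "integer"))
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes)))
    stop("gene annotation must have columns ", paste(need, collapse = ", "))
  if (any(genes$tss < 1L)) stop("TSS positions must be 1-based (>= 1)")
  genes
}

#' Read a clinical follow-up table
#'
#' TSV with columns `sample_id`, `time_months` (>= 0) and `event` (0/1
#' biochemical-recurrence indicator).
#'
#' @param path clinical TSV path.
#' @return `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
readClinical <- function(path) {
  cl <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "time_months", "event") %in% names(cl)))
    stop("clinical table needs columns sample_id, time_months, event")
  if (any(cl$time_months < 0)) stop("negative follow-up time")
  if (!all(cl$event %in% c(0L, 1L))) stop("event must be 0/1")
  data.frame(sample_id = cl$sample_id, time = cl$time_months,
             event = as.integer(cl$event), stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
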