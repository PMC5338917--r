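# Interval algebra building the tissue-specific regulatory region set and
# filtering array SNPs into it. Regions are GRanges; on disk they are BED
# (0-based half-open), in memory 1-based closed — rtracklayer converts.

.validateRegions <- function(gr, what = "regions") {
  if (any(GenomicRanges::width(gr) < 1L))
    stop("invalid ", what, ": record(s) ",
         paste(head(which(GenomicRanges::width(gr) < 1L), 5L), collapse = ", "),
         " have start >= end")
  invisible(gr)
}

#' Detect mixed chromosome naming across inputs
#'
#' Chromosome names are matched by exact string equality throughout; mixing
#' UCSC-style `chr1` with bare `1` across inputs silently empties overlaps,
#' so it is reported as an error instead of being normalized away.
#'
#' @param ... character vectors (or objects with seqnames) of chromosome
#'   names, one per input source.
#' @return invisibly `TRUE`; errors on mixed naming.
#' @export
checkChromNaming <- function(...) {
  pools <- lapply(list(...), function(x) {
    if (methods::is(x, "GenomicRanges"))
      x <- as.character(GenomicRanges::seqnames(x))
    unique(as.character(x))
  })
  all_names <- unique(unlist(pools))
  pref <- grepl("^chr", all_names)
  if (any(pref) && !all(pref))
    stop("mixed chromosome naming across inputs: ",
         paste(head(all_names[pref], 3L), collapse = ", "), " vs ",
         paste(head(all_names[!pref], 3L), collapse = ", "),
         "; harmonize names before running")
  invisible(TRUE)
}

#' Merge peak intervals into a sorted, non-overlapping region set
#'
#' Collapses a peak set to the maximal runs of covered base pairs: the
#' result is sorted by (chromosome, start), non-overlapping, and covers
#' exactly the union of the input base pairs. Abutting intervals are merged,
#' giving the non-redundant region collection the downstream SNP filter
#' expects.
#'
#' @param peaks a [GenomicRanges::GRanges] of peak intervals (may be
#'   unsorted and overlapping).
#' @return merged, sorted `GRanges`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(30, 10), c(45, 31)))
#' mergePeaks(gr)
#' @export
mergePeaks <- function(peaks) {
  .validateRegions(peaks, "peaks")
  GenomicRanges::sort(GenomicRanges::reduce(peaks, ignore.strand = TRUE))
}

#' Union per-TF peak sets with support counts
#'
#' Merges the peak sets of several transcription factors into one region set
#' and annotates every merged region with `support_count`: the number of
#' distinct input TF sets overlapping it by at least 1 bp anywhere in the
#' region ("bound by one or more TFs" is a per-region criterion).
#'
#' @param tfPeakSets named list of [GenomicRanges::GRanges], one per TF.
#' @return merged `GRanges` with metadata columns `support_count` (integer)
#'   and `support_tfs` (comma-separated contributing set names).
#' @export
unionTFPeaks <- function(tfPeakSets) {
  if (length(tfPeakSets) == 0L)
    return(GenomicRanges::GRanges())
  if (is.null(names(tfPeakSets)))
    names(tfPeakSets) <- paste0("TF", seq_along(tfPeakSets))
  for (gr in tfPeakSets) .validateRegions(gr, "TF peaks")
  merged <- mergePeaks(do.call(c, unname(lapply(tfPeakSets, function(gr) {
    GenomicRanges::granges(gr)
  }))))
  hits <- vapply(tfPeakSets, function(gr)
    IRanges::overlapsAny(merged, gr, ignore.strand = TRUE),
    logical(length(merged)))
  hits <- matrix(hits, nrow = length(merged))
  S4Vectors::mcols(merged)$support_count <- as.integer(rowSums(hits))
  S4Vectors::mcols(merged)$support_tfs <- apply(hits, 1L, function(h)
    paste(names(tfPeakSets)[h], collapse = ","))
  merged
}

#' Intersect two region sets base pair by base pair
#'
#' Returns the merged, sorted set of intervals covering exactly the base
#' pairs present in both inputs. Metadata (e.g. TF support) of `x` is
#' carried onto each output interval from the `x` interval containing it.
#'
#' @param x,y [GenomicRanges::GRanges], typically already merged.
#' @return merged `GRanges` of the base-pair intersection, with `x`'s
#'   metadata columns propagated.
#' @export
intersectRegions <- function(x, y) {
  .validateRegions(x); .validateRegions(y)
  out <- GenomicRanges::sort(
    GenomicRanges::intersect(GenomicRanges::granges(x),
                             GenomicRanges::granges(y),
                             ignore.strand = TRUE))
  if (ncol(S4Vectors::mcols(x)) > 0L && length(out) > 0L) {
    hit <- GenomicRanges::findOverlaps(out, x, select = "first",
                                       ignore.strand = TRUE)
    S4Vectors::mcols(out) <- S4Vectors::mcols(x)[hit, , drop = FALSE]
  }
  out
}

#' Filter SNPs to those inside a region set
#'
#' Keeps the SNPs whose position falls inside some region. SNP manifests
#' store 1-based positions while BED regions are 0-based half-open; a SNP at
#' 1-based position p is inside [start, end) exactly when start < p <= end
#' in the 1-based closed coordinates used in memory, which is the test
#' applied here.
#'
#' @param snps SNP manifest `data.frame` (`snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`).
#' @param regions merged [GenomicRanges::GRanges].
#' @return the retained rows of `snps`, in input order, with columns
#'   `region_chrom`, `region_start` (0-based), `region_end` and any region
#'   metadata (e.g. `support_count`) appended. SNPs on chromosomes absent
#'   from `regions` are simply dropped.
#' @export
snpsInRegions <- function(snps, regions) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)))
  if (nrow(snps) == 0L || length(regions) == 0L)
    return(cbind(snps[0L, , drop = FALSE],
                 region_chrom = character(), region_start = integer(),
                 region_end = integer()))
  if (any(snps$pos < 1L))
    stop("SNP positions must be 1-based (>= 1)")
  loci <- GenomicRanges::GRanges(snps$chrom,
                                 IRanges::IRanges(snps$pos, snps$pos))
  hit <- GenomicRanges::findOverlaps(loci, regions, select = "first",
                                     ignore.strand = TRUE)
  keep <- !is.na(hit)
  out <- snps[keep, , drop = FALSE]
  reg <- regions[hit[keep]]
  ann <- data.frame(region_chrom = as.character(GenomicRanges::seqnames(reg)),
                    region_start = GenomicRanges::start(reg) - 1L,
                    region_end = GenomicRanges::end(reg),
                    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(reg)
  if (ncol(mc) > 0L)
    ann <- cbind(ann, as.data.frame(mc, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  cbind(out, ann)
}

#' Build the tissue-specific regulatory region set
#'
#' Implements the region-integration front of the workflow: open-chromatin
#' and active-mark peaks are unioned into the "active" set, the per-TF peak
#' sets are unioned with support counts, and the two are intersected to give
#' the non-redundant regulatory regions (TF-bound base pairs lying in open
#' chromatin or active enhancers).
#'
#' @param dhs `GRanges` of open-chromatin (DNase hypersensitivity) peaks.
#' @param marks `GRanges` (or list of `GRanges`) of active histone-mark
#'   peaks, e.g. H3K27ac.
#' @param tfPeakSets named list of per-TF peak `GRanges`.
#' @return list with `active` (merged open/active regions), `tf` (TF union
#'   with support counts) and `regulatory` (their intersection).
#' @export
buildRegulatoryRegions <- function(dhs, marks, tfPeakSets) {
  if (methods::is(marks, "GenomicRanges")) marks <- list(marks)
  checkChromNaming(dhs, do.call(c, lapply(marks, function(g)
    as.character(GenomicRanges::seqnames(g)))),
    do.call(c, lapply(tfPeakSets, function(g)
      as.character(GenomicRanges::seqnames(g)))))
  active <- mergePeaks(do.call(c, c(list(GenomicRanges::granges(dhs)),
                                    lapply(marks, GenomicRanges::granges))))
  tf <- unionTFPeaks(tfPeakSets)
  list(active = active, tf = tf, regulatory = intersectRegions(tf, active))
}
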