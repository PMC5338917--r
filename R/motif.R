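# Allele-specific PWM motif scoring: decide whether a SNP disrupts or creates
# a transcription-factor binding motif by scoring every motif placement that
# overlaps the SNP, on both strands, under each allele.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# log2-odds contribution matrix (L x 4), probabilities floored at `floorProb`
# so near-zero matrix entries keep scores finite.
.logOdds <- function(pwm, floorProb = 1e-3) {
  log2(pmax(pwm@probs, floorProb) /
         matrix(pwm@background, nrow(pwm@probs), 4L, byrow = TRUE))
}

#' Score one sequence window against a PWM
#'
#' Computes the summed log2-odds score
#' \eqn{\sum_i \log_2(\max(p_i[b_i],\epsilon)/q[b_i])} of a sequence window
#' whose length equals the motif length, with probability floor
#' \eqn{\epsilon = 10^{-3}} and background \eqn{q}. An `N` base contributes
#' the worst-case (minimum) log-odds at its position, so ambiguity can never
#' create a spurious motif match.
#'
#' @param pwm a [PWMModel-class].
#' @param seq character scalar (or character vector of single bases) over
#'   `A,C,G,T,N`, length equal to `motifLength(pwm)`.
#' @return single numeric log2-odds score.
#' @examples
#' pwm <- PWMModel("flat", matrix(0.25, 3, 4), threshold = 0)
#' scoreWindow(pwm, "ACG")  # 0: log-ratio of equals
#' @export
scoreWindow <- function(pwm, seq) {
  b <- if (length(seq) == 1L) strsplit(seq, "")[[1]] else seq
  L <- motifLength(pwm)
  if (length(b) != L)
    stop("sequence length ", length(b), " does not match motif length ", L)
  lo <- .logOdds(pwm)
  idx <- match(b, BASES)
  bad <- is.na(idx) & b != "N"
  if (any(bad))
    stop("invalid base(s): ", paste(unique(b[bad]), collapse = ", "))
  contrib <- numeric(L)
  known <- !is.na(idx)
  contrib[known] <- lo[cbind(which(known), idx[known])]
  if (any(!known))
    contrib[!known] <- apply(lo[!known, , drop = FALSE], 1L, min)
  sum(contrib)
}

#' Build SNP flanking-sequence contexts from a reference FASTA
#'
#' Cuts the `+/- flank` bp of reference sequence centered on each SNP's
#' 1-based position. The center base is checked against the SNP's two
#' alleles; a mismatch is reported with a warning (the context is still
#' returned, since allele substitution overwrites the center base anyway).
#'
#' @param snps SNP manifest `data.frame` with columns `snp_id`, `chrom`,
#'   `pos` (1-based), `allele_a`, `allele_b` (see [readSnpManifest()]).
#' @param reference a [Biostrings::DNAStringSet] of chromosome sequences, or
#'   the path of a FASTA file to read.
#' @param flank half-width F of the context in bp (default 20, giving a
#'   2F+1 = 41 bp window).
#' @return named list of contexts, one per SNP: each a list with elements
#'   `snp` (one-row manifest slice) and `flank` (character sequence of
#'   2F+1 bases, center base at position F+1).
#' @export
snpContexts <- function(snps, reference, flank = 20L) {
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  ctxs <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    chrom <- snps$chrom[i]
    if (!chrom %in% names(reference))
      stop("chromosome '", chrom, "' of SNP ", snps$snp_id[i],
           " absent from reference")
    pos <- snps$pos[i]
    len <- length(reference[[chrom]])
    if (pos - flank < 1L || pos + flank > len)
      stop("SNP ", snps$snp_id[i], " too close to the ", chrom,
           " boundary for a ", flank, " bp flank")
    fl <- as.character(Biostrings::subseq(reference[[chrom]],
                                          pos - flank, pos + flank))
    center <- substr(fl, flank + 1L, flank + 1L)
    if (!center %in% c(snps$allele_a[i], snps$allele_b[i]))
      warning("reference base '", center, "' at SNP ", snps$snp_id[i],
              " matches neither allele (", snps$allele_a[i], "/",
              snps$allele_b[i], ")")
    ctxs[[i]] <- list(snp = snps[i, , drop = FALSE], flank = fl)
  }
  names(ctxs) <- snps$snp_id
  ctxs
}

.revcomp <- function(chars) rev(unname(COMPLEMENT[chars]))

#' Best motif placement score for one allele of a SNP
#'
#' Substitutes `allele` at the center of the SNP context, then scores every
#' motif placement whose window covers the SNP position, on the forward
#' sequence and on its reverse complement (scored with the same PWM), and
#' returns the maximum. Ties are broken by the smallest offset, then by the
#' forward strand.
#'
#' @param pwm a [PWMModel-class].
#' @param ctx one SNP context from [snpContexts()].
#' @param allele single base to substitute at the SNP position.
#' @return list with `score` (max log2-odds), `offset` (placement start
#'   relative to the SNP position, in `-(L-1) .. 0`), and `strand`
#'   (`"+"` or `"-"`).
#' @export
bestAlleleScore <- function(pwm, ctx, allele) {
  chars <- strsplit(ctx$flank, "")[[1]]
  F <- (length(chars) - 1L) %/% 2L
  L <- motifLength(pwm)
  if (F < L - 1L)
    stop("flank half-width ", F, " too short for motif length ", L,
         "; extract contexts with flank >= ", L - 1L)
  center <- F + 1L
  chars[center] <- allele
  offs <- seq.int(-(L - 1L), 0L)
  n <- length(offs)
  score <- numeric(2L * n)
  strand <- rep(c("+", "-"), each = n)
  for (k in seq_len(n)) {
    s <- center + offs[k]
    win <- chars[s:(s + L - 1L)]
    score[k] <- scoreWindow(pwm, win)
    score[n + k] <- scoreWindow(pwm, .revcomp(win))
  }
  ord <- order(-score, rep(offs, 2L), strand)
  best <- ord[1L]
  list(score = score[best],
       offset = rep(offs, 2L)[best],
       strand = strand[best])
}

#' Classify the allele-specific effect of a SNP on one motif
#'
#' Scores both alleles with [bestAlleleScore()] and classifies the SNP's
#' effect on the motif relative to the PWM's detection threshold:
#' `disrupt` if allele A matches (score >= threshold) but allele B does not;
#' `create` for the reverse; `none` if neither allele matches; and, when both
#' alleles match, `neutral` if the absolute score difference is below
#' `deltaMin`, otherwise the higher-scoring side labels the direction.
#'
#' @inheritParams bestAlleleScore
#' @param deltaMin minimum |score A - score B| (bits) to call a direction
#'   when both alleles pass the threshold; default 2 bits, roughly a strong
#'   single-base preference.
#' @return one-row `data.frame` with columns `snp_id`, `tf`, `score_a`,
#'   `score_b`, `offset_a`, `strand_a`, `offset_b`, `strand_b`, `delta`
#'   (`score_a - score_b`) and `call` in `disrupt`/`create`/`neutral`/`none`.
#' @export
alleleEffect <- function(pwm, ctx, deltaMin = 2) {
  a <- bestAlleleScore(pwm, ctx, ctx$snp$allele_a)
  b <- bestAlleleScore(pwm, ctx, ctx$snp$allele_b)
  thr <- motifThreshold(pwm)
  delta <- a$score - b$score
  call <- if (a$score >= thr && b$score < thr) "disrupt"
    else if (b$score >= thr && a$score < thr) "create"
    else if (a$score < thr && b$score < thr) "none"
    else if (abs(delta) < deltaMin) "neutral"
    else if (delta > 0) "disrupt"
    else "create"
  data.frame(snp_id = ctx$snp$snp_id, tf = tfName(pwm),
             score_a = a$score, score_b = b$score,
             offset_a = a$offset, strand_a = a$strand,
             offset_b = b$offset, strand_b = b$strand,
             delta = delta, call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan SNP contexts against a set of motifs
#'
#' Evaluates every SNP x PWM combination with [alleleEffect()]. SNPs with at
#' least one `disrupt` or `create` call are motif-change candidates.
#'
#' @param ctxs list of SNP contexts from [snpContexts()].
#' @param pwms list of [PWMModel-class] objects.
#' @inheritParams alleleEffect
#' @return `data.frame` with one row per SNP x motif (columns as in
#'   [alleleEffect()]), plus a logical `motif_change` column marking rows of
#'   SNPs that received at least one disrupt/create call for any motif.
#' @export
scanSnpMotifEffects <- function(ctxs, pwms, deltaMin = 2) {
  cols <- c("snp_id", "tf", "score_a", "score_b", "offset_a", "strand_a",
            "offset_b", "strand_b", "delta", "call")
  if (length(ctxs) == 0L || length(pwms) == 0L) {
    out <- data.frame(snp_id = character(), tf = character(),
                      score_a = numeric(), score_b = numeric(),
                      offset_a = integer(), strand_a = character(),
                      offset_b = integer(), strand_b = character(),
                      delta = numeric(), call = character(),
                      motif_change = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- vector("list", length(ctxs) * length(pwms))
  k <- 0L
  for (ctx in ctxs) {
    for (pwm in pwms) {
      k <- k + 1L
      rows[[k]] <- alleleEffect(pwm, ctx, deltaMin = deltaMin)
    }
  }
  out <- do.call(rbind, rows)[, cols]
  hit <- tapply(out$call %in% c("disrupt", "create"), out$snp_id, any)
  out$motif_change <- unname(hit[out$snp_id])
  out
}

#' Read HOMER-style motif files
#'
#' Parses the plain-text motif dialect: each record starts with a header line
#' `>consensus<TAB>name<TAB>threshold` (whitespace-separated), followed by
#' one line per motif position holding 4 probabilities in A, C, G, T order.
#' Rows whose probabilities deviate from sum 1 by at most 1e-3 are
#' renormalized; larger deviations, wrong column counts or non-numeric
#' entries are reported with the offending line number.
#'
#' @param path motif file path.
#' @param background background base probabilities passed to each model.
#' @return named list of [PWMModel-class] objects.
#' @export
readHomerMotifs <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L)
    stop("no motif header ('>') lines found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  pwms <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[m]]), "[ \t]+")[[1]]
    if (length(hdr) < 3L)
      stop("motif header at line ", starts[m],
           " needs consensus, name and threshold fields")
    name <- hdr[2L]
    thr <- suppressWarnings(as.numeric(hdr[3L]))
    if (is.na(thr))
      stop("non-numeric threshold '", hdr[3L], "' at line ", starts[m])
    body <- (starts[m] + 1L):ends[m]
    if (length(body) < 1L || starts[m] == ends[m])
      stop("motif '", name, "' at line ", starts[m], " has no matrix rows")
    probs <- matrix(NA_real_, length(body), 4L)
    for (j in seq_along(body)) {
      fields <- strsplit(trimws(lines[body[j]]), "[ \t]+")[[1]]
      if (length(fields) != 4L)
        stop("expected 4 probabilities at line ", body[j], ", got ",
             length(fields))
      vals <- suppressWarnings(as.numeric(fields))
      if (anyNA(vals))
        stop("non-numeric matrix entry at line ", body[j])
      probs[j, ] <- vals
    }
    pwms[[m]] <- tryCatch(
      PWMModel(name, probs, thr, background = background),
      error = function(e)
        stop("motif '", name, "' starting at line ", starts[m], ": ",
             conditionMessage(e)))
  }
  names(pwms) <- vapply(pwms, tfName, character(1L))
  pwms
}

#' Write motifs in the HOMER-style dialect read by [readHomerMotifs()]
#'
#' @param pwms list of [PWMModel-class] objects.
#' @param path output file path.
#' @param digits significant digits for probabilities.
#' @return `path`, invisibly.
#' @export
writeHomerMotifs <- function(pwms, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pwm in pwms) {
    writeLines(paste(paste0(">", motifConsensus(pwm)), tfName(pwm),
                     format(motifThreshold(pwm), digits = digits),
                     sep = "\t"), con)
    apply(motifProbs(pwm), 1L, function(row)
      writeLines(paste(format(row, digits = digits, trim = TRUE),
                       collapse = "\t"), con))
  }
  invisible(path)
}
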