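#' @import methods
#' @importFrom stats anova lm p.adjust pchisq rbinom rexp rnorm runif sd
#'   t.test wilcox.test setNames uniroot
#' @importFrom utils read.delim write.table modifyList head
NULL

#' PWMModel: a position probability matrix with a detection threshold
#'
#' A transcription-factor binding motif model in the HOMER dialect: one row of
#' base probabilities (A, C, G, T) per motif position, plus a log-odds
#' detection threshold on the same log2 scale the scorer uses, and a
#' background base composition (uniform by default).
#'
#' @slot tfName single character, the transcription factor the motif models.
#' @slot probs numeric matrix, L positions x 4 bases, columns named
#'   `A`, `C`, `G`, `T`; each row sums to 1 (tolerance 1e-6).
#' @slot threshold single numeric log2 odds detection threshold: a window
#'   scoring at or above it is considered a motif match.
#' @slot background numeric length-4 base probabilities used in the log-odds
#'   denominator, default uniform 0.25.
#'
#' @seealso [PWMModel()], [scoreWindow()], [readHomerMotifs()]
#' @exportClass PWMModel
setClass("PWMModel",
  representation(
    tfName = "character",
    probs = "matrix",
    threshold = "numeric",
    background = "numeric"
  )
)

setValidity("PWMModel", function(object) {
  msgs <- character()
  if (length(object@tfName) != 1L || !nzchar(object@tfName))
    msgs <- c(msgs, "tfName must be a single non-empty string")
  p <- object@probs
  if (!is.numeric(p) || ncol(p) != 4L || nrow(p) < 1L)
    msgs <- c(msgs, "probs must be a numeric matrix with >= 1 row and 4 columns")
  else {
    if (!identical(colnames(p), c("A", "C", "G", "T")))
      msgs <- c(msgs, "probs columns must be named A, C, G, T")
    if (any(p < 0))
      msgs <- c(msgs, "probs must be nonnegative")
    if (any(abs(rowSums(p) - 1) > 1e-6))
      msgs <- c(msgs, "each probs row must sum to 1 (tolerance 1e-6)")
  }
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msgs <- c(msgs, "threshold must be a single finite numeric")
  if (length(object@background) != 4L || any(object@background <= 0) ||
      abs(sum(object@background) - 1) > 1e-6)
    msgs <- c(msgs, "background must be 4 positive probabilities summing to 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PWMModel
#'
#' @param tfName transcription factor name.
#' @param probs L x 4 matrix of per-position base probabilities in A, C, G, T
#'   column order (column names are set if absent). Rows whose sums deviate
#'   from 1 by at most `renormTol` are renormalized; larger deviations error.
#' @param threshold log2-odds detection threshold.
#' @param background length-4 background base probabilities (A, C, G, T).
#' @param renormTol maximum tolerated row-sum deviation before renormalizing.
#'
#' @return A [PWMModel-class] object.
#' @examples
#' pwm <- PWMModel("TF1", matrix(0.25, 2, 4), threshold = 0)
#' motifLength(pwm)
#' @export
PWMModel <- function(tfName, probs, threshold,
                     background = rep(0.25, 4), renormTol = 1e-3) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L)
    stop("probs must have 4 columns (A, C, G, T)")
  colnames(probs) <- c("A", "C", "G", "T")
  rs <- rowSums(probs)
  off <- abs(rs - 1)
  if (any(off > renormTol))
    stop("probability rows ", paste(which(off > renormTol), collapse = ", "),
         " of motif '", tfName, "' do not sum to 1 (max deviation ",
         signif(max(off), 3), ")")
  probs <- probs / rs
  new("PWMModel", tfName = as.character(tfName), probs = probs,
      threshold = as.numeric(threshold), background = as.numeric(background))
}

#' @describeIn PWMModel-class motif length (number of positions).
#' @param x a `PWMModel`.
#' @export
motifLength <- function(x) nrow(x@probs)

#' @describeIn PWMModel-class transcription factor name.
#' @export
tfName <- function(x) x@tfName

#' @describeIn PWMModel-class per-position base probability matrix.
#' @export
motifProbs <- function(x) x@probs

#' @describeIn PWMModel-class log2-odds detection threshold.
#' @export
motifThreshold <- function(x) x@threshold

#' Consensus sequence of a PWM (highest-probability base per position)
#' @param pwm a [PWMModel-class].
#' @return character scalar of length `motifLength(pwm)`.
#' @export
motifConsensus <- function(pwm) {
  paste(colnames(pwm@probs)[apply(pwm@probs, 1L, which.max)], collapse = "")
}

setMethod("show", "PWMModel", function(object) {
  cat("PWMModel for", object@tfName, "\n")
  cat("  length:", nrow(object@probs), "positions;",
      "consensus:", motifConsensus(object), "\n")
  cat("  log2-odds threshold:", format(object@threshold, digits = 4), "\n")
  invisible(NULL)
})
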