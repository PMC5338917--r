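# Expression z-score stratification against normals plus Kaplan-Meier /
# log-rank analysis of biochemical-recurrence-free survival.

#' z-scores of tumor expression relative to normal samples
#'
#' `z = (x - mu) / sigma` where `mu` and `sigma` are the mean and sample
#' (n-1) standard deviation of the normal samples; positive z means
#' expression above the normal mean.
#'
#' @param tumorValues named numeric vector of tumor expression.
#' @param normalValues numeric vector of normal expression (>= 2 values).
#' @return named numeric z-scores, one per tumor sample; if the normal
#'   standard deviation is 0 the gene is unusable and all-NA is returned
#'   with a warning.
#' @export
zscoreVsNormals <- function(tumorValues, normalValues) {
  if (length(normalValues) < 2L)
    stop("need at least 2 normal samples for a z-score reference")
  s <- stats::sd(normalValues)
  if (s == 0) {
    warning("zero variance across normal samples; gene excluded")
    return(setNames(rep(NA_real_, length(tumorValues)), names(tumorValues)))
  }
  (tumorValues - mean(normalValues)) / s
}

#' Stratify tumors into high/low expression by the 75% z-score rule
#'
#' Tumors are split by z-score sign; within the positive group the
#' `floor(keepFraction * n)` highest (at least 1) are labeled `high`, within
#' the negative group the `floor(keepFraction * n)` lowest (at least 1) are
#' labeled `low`, and the remaining tumors — those with z-scores nearest
#' zero, which carry little information — are `excluded`. Ties are broken by
#' stable sample-id order, so the assignment is invariant to input
#' permutation.
#'
#' @param z named z-score vector (names are sample ids); NAs are excluded.
#' @param keepFraction fraction of each sign group retained (default 0.75).
#' @return list with `assignments` (named character in high/low/excluded),
#'   `n_high`, `n_low` and `testable` (`FALSE` when all usable z-scores
#'   share one sign).
#' @export
stratifyByZscore <- function(z, keepFraction = 0.75) {
  if (is.null(names(z))) names(z) <- paste0("S", seq_along(z))
  assignments <- setNames(rep("excluded", length(z)), names(z))
  usable <- z[!is.na(z)]
  pos <- usable[usable > 0]
  neg <- usable[usable < 0]
  if (length(pos) == 0L || length(neg) == 0L)
    return(list(assignments = assignments, n_high = 0L, n_low = 0L,
                testable = FALSE))
  kHigh <- max(1L, floor(keepFraction * length(pos)))
  kLow <- max(1L, floor(keepFraction * length(neg)))
  hi <- names(pos)[order(-pos, names(pos))][seq_len(kHigh)]
  lo <- names(neg)[order(neg, names(neg))][seq_len(kLow)]
  assignments[hi] <- "high"
  assignments[lo] <- "low"
  list(assignments = assignments, n_high = kHigh, n_low = kLow,
       testable = TRUE)
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time nonnegative follow-up / time-to-recurrence values.
#' @param event logical or 0/1 event indicator (recurrence observed).
#' @return `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`: the product-limit estimate at each distinct observed time.
#'   An all-censored input yields a constant-1 curve.
#' @export
kmCurve <- function(time, event) {
  if (length(time) == 0L) stop("empty survival data")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and nonnegative")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom chi-square log-rank test over the pooled
#' event times, with tied events handled by the aggregated risk-set
#' formulation. With no events in either group the comparison is flagged
#' untestable.
#'
#' @param timeHigh,eventHigh survival data of the high-expression group.
#' @param timeLow,eventLow survival data of the low-expression group.
#' @return list with `statistic`, `p_value`, `testable`, and `direction`
#'   (+1 when the high group has more events than expected under the null,
#'   -1 when fewer, 0 when equal).
#' @export
logrankTest <- function(timeHigh, eventHigh, timeLow, eventLow) {
  if (length(timeHigh) == 0L || length(timeLow) == 0L)
    stop("both groups must be nonempty")
  ev <- c(as.integer(eventHigh), as.integer(eventLow))
  if (sum(ev) == 0L)
    return(list(statistic = NA_real_, p_value = NA_real_, testable = FALSE,
                direction = 0))
  grp <- factor(rep(c("high", "low"), c(length(timeHigh), length(timeLow))))
  tm <- c(timeHigh, timeLow)
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ grp)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       testable = TRUE,
       direction = sign(sd$obs[1L] - sd$exp[1L]))
}

#' Per-gene recurrence-risk scan
#'
#' For each gene: z-scores of tumor expression versus normals
#' ([zscoreVsNormals()]), the 75% stratification ([stratifyByZscore()]),
#' and a log-rank comparison of biochemical-recurrence-free survival
#' between the high and low strata ([logrankTest()]).
#'
#' @param se expression `SummarizedExperiment` with `colData$class`.
#' @param clinical `data.frame` with `sample_id`, `time`, `event` (see
#'   [readClinical()]); tumors without clinical records are dropped from
#'   the comparison.
#' @param geneIds genes to scan.
#' @param keepFraction passed to [stratifyByZscore()].
#' @return `data.frame` with `gene_id`, `n_high`, `n_low`, `logrank_stat`,
#'   `p_value`, `direction` (sign of the high-group excess event count,
#'   reported without resolving which direction is "risk"), `risk_assoc`
#'   (p < 0.05) and `testable`.
#' @export
riskScan <- function(se, clinical, geneIds = rownames(se),
                     keepFraction = 0.75) {
  cls <- SummarizedExperiment::colData(se)$class
  mat <- SummarizedExperiment::assay(se, "expr")
  tumorIds <- colnames(se)[cls == "tumor"]
  if (length(geneIds) == 0L)
    return(data.frame(gene_id = character(), n_high = integer(),
                      n_low = integer(), logrank_stat = numeric(),
                      p_value = numeric(), direction = numeric(),
                      risk_assoc = logical(), testable = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(geneIds, function(g) {
    base <- data.frame(gene_id = g, n_high = 0L, n_low = 0L,
                       logrank_stat = NA_real_, p_value = NA_real_,
                       direction = 0, risk_assoc = FALSE, testable = FALSE,
                       stringsAsFactors = FALSE)
    z <- tryCatch(
      suppressWarnings(zscoreVsNormals(mat[g, tumorIds],
                                       mat[g, cls == "normal"])),
      error = function(e) NULL)
    if (is.null(z) || all(is.na(z))) return(base)
    strat <- stratifyByZscore(z, keepFraction = keepFraction)
    if (!strat$testable) return(base)
    hi <- clinical[clinical$sample_id %in%
                     names(strat$assignments)[strat$assignments == "high"], ]
    lo <- clinical[clinical$sample_id %in%
                     names(strat$assignments)[strat$assignments == "low"], ]
    if (nrow(hi) == 0L || nrow(lo) == 0L) return(base)
    lr <- logrankTest(hi$time, hi$event, lo$time, lo$event)
    base$n_high <- nrow(hi); base$n_low <- nrow(lo)
    base$logrank_stat <- lr$statistic
    base$p_value <- lr$p_value
    base$direction <- lr$direction
    base$risk_assoc <- isTRUE(lr$testable) && !is.na(lr$p_value) &&
      lr$p_value < 0.05
    base$testable <- lr$testable
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
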