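#' Benchmark statistics
#'
#' The evaluation toolkit used across the framework: ROC / precision-recall
#' summaries (tie-corrected AUROC, average precision), rank correlations
#' with per-element subsample bootstrap, variant-count-weighted averaging,
#' reporter-assay (MPRA) readout filtering, and the allele-frequency
#' correlation protocol.
#'
#' @name evaluation
NULL

#' Filter MPRA variant readouts
#'
#' Keeps readouts with at least `min_barcodes` barcodes, p-value below
#' `alpha`, and variant class SNV or 1-bp deletion.
#'
#' @param readouts A tibble with columns `ref`, `alt`, `barcodes`,
#'   `p_value` (other columns are carried through).
#' @param min_barcodes Minimum barcode count (default 10).
#' @param alpha P-value cutoff (default 1e-5, exclusive).
#' @return The filtered tibble.
#' @export
filter_mpra <- function(readouts, min_barcodes = 10L, alpha = 1e-5) {
  keep_class <- (nchar(readouts$ref) == 1 & nchar(readouts$alt) == 1) |
    (nchar(readouts$ref) == 2 & nchar(readouts$alt) == 1)
  readouts[keep_class & readouts$barcodes >= min_barcodes &
             readouts$p_value < alpha, , drop = FALSE]
}

#' Correlate scores with experimental effects
#'
#' Spearman (average ranks for ties) or Pearson correlation; with
#' `absolute = TRUE` the absolute effect is used, appropriate for scores
#' that predict deleteriousness magnitude but not expression direction.
#'
#' @param scores,effects Paired numeric vectors (length >= 3).
#' @param absolute Use `abs(effects)`?
#' @param method `"spearman"` or `"pearson"`.
#' @return A single correlation coefficient.
#' @export
correlate <- function(scores, effects, absolute = FALSE,
                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(scores) != length(effects)) abort("scores and effects differ in length")
  if (length(scores) < 3) abort("need at least 3 paired values")
  if (absolute) effects <- abs(effects)
  if (sd(scores) == 0 || sd(effects) == 0) {
    abort("correlation undefined for constant input")
  }
  cor(scores, effects, method = method)
}

#' Subsample bootstrap of a correlation
#'
#' Repeatedly subsamples `floor(fraction * n)` pairs without replacement,
#' computes [correlate()], and reports the mean and standard deviation over
#' runs. Deterministic per seed.
#'
#' @inheritParams correlate
#' @param n_runs Number of runs (default 1000).
#' @param fraction Subsample fraction in (0, 1] (default 0.8).
#' @param seed Integer seed.
#' @return A tibble of class `bootstrap_result` with `estimate`, `sd`,
#'   `n_runs`, `fraction`, `seed`.
#' @export
bootstrap_correlation <- function(scores, effects, n_runs = 1000L,
                                  fraction = 0.8, seed = 1L,
                                  method = c("spearman", "pearson"),
                                  absolute = FALSE) {
  method <- match.arg(method)
  if (length(scores) < 5) abort("need at least 5 paired values")
  m <- floor(fraction * length(scores))
  if (m < 3) abort("subsample size below 3; increase fraction or n")
  withr::local_seed(seed)
  vals <- vapply(seq_len(n_runs), function(i) {
    idx <- sample.int(length(scores), m)
    correlate(scores[idx], effects[idx], absolute = absolute, method = method)
  }, 0)
  structure(tibble(estimate = mean(vals),
                   sd = if (n_runs > 1) stats::sd(vals) else 0,
                   n_runs = n_runs, fraction = fraction, seed = seed),
            class = c("bootstrap_result", class(tibble())))
}

#' Variant-count-weighted mean correlation
#'
#' @param per_element A tibble with columns `correlation` and `n_variants`
#'   (one row per element).
#' @return The weighted mean `sum(n * rho) / sum(n)`.
#' @export
weighted_average <- function(per_element) {
  if (nrow(per_element) == 0) abort("no elements")
  sum(per_element$correlation * per_element$n_variants) / sum(per_element$n_variants)
}

#' ROC and precision-recall summary
#'
#' AUROC is computed as the tie-corrected Mann-Whitney statistic
#' (equivalent to the trapezoid over the exact step ROC); average
#' precision is the step-curve sum `sum((R_k - R_{k-1}) * P_k)` with tied
#' scores processed as one block. The positive class is `label == 1`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels.
#' @return A list of class `roc_pr`: `auroc`, `aps`, `roc` (tibble `fpr`,
#'   `tpr`), `pr` (tibble `recall`, `precision`).
#' @export
roc_pr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes required")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  auroc <- auroc_u(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  blk <- cumsum(!duplicated(s))
  tp <- tapply(y, blk, sum); np <- tapply(rep(1, length(y)), blk, sum)
  TP <- cumsum(tp); Nc <- cumsum(np); FP <- Nc - TP
  prec <- TP / Nc; rec <- TP / n1
  aps <- sum(diff(c(0, rec)) * prec)
  list_out <- list(
    auroc = auroc, aps = aps,
    roc = tibble(fpr = c(0, FP / n0), tpr = c(0, TP / n1)),
    pr = tibble(recall = c(0, rec), precision = c(1, prec))
  )
  structure(list_out, class = "roc_pr")
}

#' @export
print.roc_pr <- function(x, ...) {
  cat(sprintf("<roc_pr> AUROC %.4f | APS %.4f\n", x$auroc, x$aps))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.roc_pr <- function(x, ...) tibble(auroc = x$auroc, aps = x$aps)

#' @exportS3Method ggplot2::autoplot
autoplot.roc_pr <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC (AUC = %.3f)", object$auroc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (APS = %.3f)", object$aps)) +
      ggplot2::theme_minimal()
  }
}

#' Correlation of scores with minor allele frequencies
#'
#' Pearson correlation of raw scores against MAF; a negative value is the
#' expected signature of deleteriousness tracking rarity.
#'
#' @param scores Numeric raw scores.
#' @param mafs Minor allele frequencies in `[0, 0.5]`.
#' @return A single Pearson correlation.
#' @export
maf_correlation <- function(scores, mafs) {
  if (any(mafs < 0 | mafs > 0.5)) abort("MAF values must lie in [0, 0.5]")
  correlate(scores, mafs, absolute = FALSE, method = "pearson")
}
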