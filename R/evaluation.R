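# Residue-level evaluation for heavily imbalanced binary labels: confusion
# counts over valid residues, MCC / precision / recall, threshold sweeps,
# and dataset audits. Metrics are micro-averaged: residues are pooled
# across proteins before counting.

#' Confusion counts over valid residues
#'
#' @param labels Integer vector of true binary labels.
#' @param predictions Integer vector of predicted binary labels.
#' @param mask Optional logical vector; only `TRUE` positions are counted.
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn` and
#'   a `degenerate` flag (set when no position was counted).
#' @export
confusion_counts <- function(labels, predictions, mask = NULL) {
  n <- length(labels)
  if (length(predictions) != n) {
    stop("confusion_counts: labels (", n, ") and predictions (",
         length(predictions), ") differ in length")
  }
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) {
    stop("confusion_counts: mask length ", length(mask), " != ", n)
  }
  y <- labels[mask]
  p <- predictions[mask]
  structure(list(tp = sum(y == 1L & p == 1L),
                 fp = sum(y == 0L & p == 1L),
                 tn = sum(y == 0L & p == 0L),
                 fn = sum(y == 1L & p == 0L),
                 degenerate = sum(mask) == 0L),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any factor of
#' the denominator is zero the coefficient is defined as 0.
#'
#' @param counts A [confusion_counts()] or list with `tp`, `fp`, `tn`, `fn`.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' mcc(list(tp = 6, fp = 2, tn = 8, fn = 4))  # 40 / sqrt(9600)
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0)) stop("mcc: counts must be nonnegative")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Precision and recall as percentages
#'
#' `precision = 100 * TP/(TP+FP)`, `recall = 100 * TP/(TP+FN)`. A zero
#' denominator yields 0 with the `"degenerate"` attribute naming the
#' affected metric(s).
#'
#' @inheritParams mcc
#' @return Named numeric vector `c(precision = ..., recall = ...)`.
#' @export
precision_recall <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, fn) < 0)) stop("precision_recall: counts must be nonnegative")
  degenerate <- character(0)
  if (tp + fp == 0) degenerate <- c(degenerate, "precision")
  if (tp + fn == 0) degenerate <- c(degenerate, "recall")
  out <- c(precision = if (tp + fp > 0) 100 * tp / (tp + fp) else 0,
           recall = if (tp + fn > 0) 100 * tp / (tp + fn) else 0)
  if (length(degenerate)) attr(out, "degenerate") <- degenerate
  out
}

#' Metrics across a grid of decision thresholds
#'
#' For each threshold, residues with positive-class probability at or above
#' it are called binding and precision, recall and MCC are computed. As the
#' threshold increases the predicted-positive count and the recall are
#' non-increasing.
#'
#' @param probabilities Numeric vector of positive-class probabilities.
#' @param labels Integer vector of true labels.
#' @param mask Optional logical validity mask.
#' @param grid Thresholds in (0, 1); default `seq(0.1, 0.9, by = 0.1)`.
#' @return Data frame with columns `threshold`, `n_pos_pred`, `precision`,
#'   `recall`, `mcc`.
#' @export
threshold_sweep <- function(probabilities, labels, mask = NULL,
                            grid = seq(0.1, 0.9, by = 0.1)) {
  if (length(grid) == 0L) stop("threshold_sweep: empty threshold grid")
  if (any(grid <= 0 | grid >= 1)) {
    stop("threshold_sweep: thresholds must lie in (0, 1)")
  }
  rows <- lapply(grid, function(thr) {
    pred <- as.integer(probabilities >= thr)
    cc <- confusion_counts(labels, pred, mask)
    pr <- precision_recall(cc)
    data.frame(threshold = thr, n_pos_pred = cc$tp + cc$fp,
               precision = pr[["precision"]], recall = pr[["recall"]],
               mcc = mcc(cc))
  })
  do.call(rbind, rows)
}

# Round half away from zero to `digits` decimals (matches printed tables;
# base round() rounds half to even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a labeled dataset
#'
#' Counts proteins, binding residues (BR) and non-binding residues (NBR),
#' and reports the binding-residue percentage `P_BR = 100 * BR / NBR`
#' (rounded half-up to 2 decimals). Note the ratio is taken against the
#' non-binding count, which is the convention the benchmark summary tables
#' in this field print.
#'
#' @param proteins List of protein records with `labels`, or a list/data
#'   frame with fields `n_prot`, `n_br`, `n_nbr` to audit printed counts.
#' @return List of class `dataset_summary` with `n_prot`, `n_br`, `n_nbr`,
#'   `p_br` and a `degenerate` flag when `n_nbr` is 0.
#' @export
#' @examples
#' dataset_summary(list(n_prot = 151, n_br = 1340, n_nbr = 45126))$p_br  # 2.97
dataset_summary <- function(proteins) {
  if (!is.null(proteins$n_br)) {
    n_prot <- proteins$n_prot; n_br <- proteins$n_br; n_nbr <- proteins$n_nbr
  } else {
    labs <- lapply(proteins, function(pr) {
      if (is.null(pr$labels)) {
        stop("dataset_summary: protein ", pr$id, " has no labels")
      }
      pr$labels
    })
    n_prot <- length(proteins)
    n_br <- sum(vapply(labs, function(l) sum(l == 1L), 0L))
    n_nbr <- sum(vapply(labs, function(l) sum(l == 0L), 0L))
  }
  degenerate <- n_nbr == 0
  structure(list(n_prot = n_prot, n_br = n_br, n_nbr = n_nbr,
                 p_br = if (degenerate) NA_real_ else
                   round_half_up(100 * n_br / n_nbr, 2L),
                 degenerate = degenerate),
            class = "dataset_summary")
}

#' Evaluate predictions against labels
#'
#' Convenience wrapper pooling residues across proteins: computes confusion
#' counts, MCC, precision and recall at one threshold, and optionally a
#' threshold sweep.
#'
#' @param probabilities Positive-class probabilities over valid residues.
#' @param labels Matching true labels.
#' @param threshold Decision threshold. Default 0.4.
#' @param sweep Also compute a [threshold_sweep()]? Default `FALSE`.
#' @return List with `counts`, `mcc`, `precision`, `recall`, `threshold`,
#'   and `sweep` (or `NULL`).
#' @export
evaluate_predictions <- function(probabilities, labels, threshold = 0.4,
                                 sweep = FALSE) {
  cc <- confusion_counts(labels, as.integer(probabilities >= threshold))
  pr <- precision_recall(cc)
  list(counts = cc, mcc = mcc(cc), precision = pr[["precision"]],
       recall = pr[["recall"]], threshold = threshold,
       sweep = if (sweep) threshold_sweep(probabilities, labels) else NULL)
}
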