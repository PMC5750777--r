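#' Precision, recall and F1 from a pair of precision/recall values
#'
#' The F1 score is the harmonic mean of precision and recall,
#' `2 * P * R / (P + R)`, defined as 0 when both are 0.
#'
#' @param precision,recall Numeric vectors in \[0, 1\] (recycled).
#' @return Numeric vector of F1 scores.
#' @examples
#' f1_score(0.8, 0.5)   # 0.6154
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' One-vs-rest confusion counts
#'
#' Tabulates true-positive, false-positive and false-negative counts per
#' class from paired label vectors.
#'
#' @param truth,pred Equal-length vectors of class labels (factors or
#'   coercible). `levels` fixes the class set and its order; by default the
#'   union of observed labels.
#' @param levels Optional character vector of class levels.
#' @return Data frame with columns `class`, `tp`, `fp`, `fn`, `n_true`.
#' @export
confusion_counts <- function(truth, pred, levels = NULL) {
  if (length(truth) != length(pred)) stopf("truth and pred lengths differ")
  if (length(truth) == 0L) stopf("empty label vectors")
  if (is.null(levels))
    levels <- sort(unique(c(as.character(truth), as.character(pred))))
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(pred), levels = levels)
  tab <- table(t_f, p_f)
  tp <- diag(tab)
  data.frame(
    class = levels,
    tp = as.integer(tp),
    fp = as.integer(colSums(tab) - tp),
    fn = as.integer(rowSums(tab) - tp),
    n_true = as.integer(rowSums(tab)),
    stringsAsFactors = FALSE
  )
}

#' Per-class and macro-averaged precision / recall / F1
#'
#' Computes one-vs-rest `P = tp/(tp+fp)`, `R = tp/(tp+fn)` and their
#' harmonic mean per class, plus the unweighted (macro) average over
#' classes. A class with a zero denominator contributes 0 for the affected
#' metric rather than NaN.
#'
#' @param truth,pred Label vectors, or pass a data frame of counts from
#'   [confusion_counts()] as `counts`.
#' @param counts Optional precomputed confusion counts.
#' @param levels Optional class levels (ignored when `counts` is given).
#' @return List with `per_class` (data frame: class, tp, fp, fn, precision,
#'   recall, f1) and `macro` (named vector: precision, recall, f1).
#' @examples
#' prf <- precision_recall_f1(c("a", "a", "b"), c("a", "b", "b"))
#' prf$macro
#' @export
precision_recall_f1 <- function(truth = NULL, pred = NULL, counts = NULL,
                                levels = NULL) {
  if (is.null(counts)) counts <- confusion_counts(truth, pred, levels)
  prec <- ifelse(counts$tp + counts$fp > 0,
                 counts$tp / (counts$tp + counts$fp), 0)
  rec <- ifelse(counts$tp + counts$fn > 0,
                counts$tp / (counts$tp + counts$fn), 0)
  per <- data.frame(counts[c("class", "tp", "fp", "fn")],
                    precision = prec, recall = rec,
                    f1 = f1_score(prec, rec),
                    stringsAsFactors = FALSE)
  list(per_class = per,
       macro = c(precision = mean(prec), recall = mean(rec),
                 f1 = mean(per$f1)))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label vectors:
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o} (fraction of identical labels) and chance agreement
#' \eqn{p_e = \sum_c \hat p_{true}(c)\, \hat p_{pred}(c)}.
#'
#' @param truth,pred Equal-length label vectors.
#' @return List with `po`, `pe`, `kappa`.
#' @details When both raters assign a single identical class to everything,
#'   \eqn{p_e = 1} and the ratio is indeterminate; complete agreement is
#'   reported as \eqn{\kappa = 1}. \eqn{p_e = 1} without complete agreement
#'   cannot occur (identical constant marginals force \eqn{p_o = 1}), and
#'   any other degenerate input raises an error.
#' @examples
#' cohen_kappa(c(1, 1, 2, 2), c(1, 1, 2, 1))$kappa
#' @export
cohen_kappa <- function(truth, pred) {
  if (length(truth) != length(pred)) stopf("truth and pred lengths differ")
  n <- length(truth)
  if (n == 0L) stopf("empty label vectors")
  truth <- as.character(truth); pred <- as.character(pred)
  po <- mean(truth == pred)
  levels <- sort(unique(c(truth, pred)))
  pt <- tabulate(factor(truth, levels), length(levels)) / n
  pp <- tabulate(factor(pred, levels), length(levels)) / n
  pe <- sum(pt * pp)
  if (pe >= 1) {
    if (po == 1) return(list(po = 1, pe = pe, kappa = 1))
    stopf("chance agreement is 1 but observed agreement is not; kappa undefined")
  }
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}

#' Stratified k-fold partition
#'
#' Splits sample indices into `r` disjoint folds such that each class's
#' members are spread as evenly as possible (per-class fold counts differ by
#' at most one). Classes with fewer than `r` members simply appear in fewer
#' folds. Reproducible from `seed`; the caller's RNG stream is left
#' untouched.
#'
#' @param labels Class label vector.
#' @param r Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of `r` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, r = 5L, seed = 1L) {
  if (r < 2L) stopf("need at least 2 folds")
  n <- length(labels)
  if (n < r) stopf("fewer samples than folds")
  folds <- vector("list", r)
  with_seed(seed, {
    offset <- 0L
    for (cl in unique(as.character(labels))) {
      idx <- which(as.character(labels) == cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the fold sequence so leftover samples don't pile into fold 1
      fid <- ((seq_along(idx) - 1L + offset) %% r) + 1L
      for (f in seq_len(r)) folds[[f]] <- c(folds[[f]], idx[fid == f])
      offset <- (offset + length(idx)) %% r
    }
  })
  folds
}
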