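#' Cross-validated macro-F1 of a feature subset
#'
#' The wrapper fitness: restricted to the feature-vector entries marked 1
#' in `mask`, a fuzzy k-NN classifier is trained and evaluated by
#' stratified r-fold cross-validation and the mean across folds of the
#' macro-averaged F1 is returned. The all-zero mask scores 0 by convention.
#' Folds derive deterministically from `seed`, so the fitness is a pure
#' function of `(mask, seed)`.
#'
#' @param x Feature matrix or data frame (rows = samples).
#' @param y Class labels.
#' @param mask Integer/logical 0/1 vector, one entry per column of `x`.
#' @param k Fuzzy k-NN neighbour count (default 4).
#' @param m Fuzzy k-NN weight exponent (default 2).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed fixing the fold assignment (default 1).
#' @return Mean macro-F1 across folds, in \[0, 1\].
#' @export
subset_fitness <- function(x, y, mask, k = 4L, m = 2, folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  mask <- as.integer(as.logical(mask))
  if (length(mask) != ncol(x))
    stopf("mask length %d != number of columns %d", length(mask), ncol(x))
  if (sum(mask) == 0L) return(0)
  y <- factor(y)
  fold_idx <- stratified_kfold(y, r = folds, seed = seed)
  cv_fitness(cv_prepare(x, y, fold_idx), mask, k = k, m = m)
}

# Precompute per-fold normalized feature matrices (training-fold min-max
# statistics, applied column-wise, so restriction to a mask commutes with
# normalization) plus integer labels and crisp memberships. Shared by the
# optimizer's fitness closure so each mask evaluation only subsets columns.
cv_prepare <- function(x, y, fold_idx) {
  x <- as.matrix(x)
  y <- factor(y)
  M_all <- init_memberships(y)
  folds <- lapply(fold_idx, function(test) {
    tr_raw <- x[-test, , drop = FALSE]
    pars <- minmax_fit(tr_raw)
    list(train = minmax_apply(pars, tr_raw),
         test = minmax_apply(pars, x[test, , drop = FALSE]),
         M = M_all[-test, , drop = FALSE],
         truth = as.integer(y[test]))
  })
  list(folds = folds, C = nlevels(y))
}

cv_fitness <- function(prep, mask, k, m) {
  sel <- which(as.logical(mask))
  if (length(sel) == 0L) return(0)
  C <- prep$C
  f1s <- vapply(prep$folds, function(f) {
    u <- knn_core(f$train[, sel, drop = FALSE],
                  f$test[, sel, drop = FALSE], f$M, k, m)$u
    pred <- max.col(u, ties.method = "first")
    macro_f1_int(f$truth, pred, C)
  }, numeric(1))
  mean(f1s)
}

# Macro-averaged F1 over integer labels in 1..C, degenerate classes scoring
# zero; the integer fast path of precision_recall_f1 for the fitness loop.
macro_f1_int <- function(truth, pred, C) {
  tp <- tabulate(truth[truth == pred], C)
  np <- tabulate(pred, C)
  nt <- tabulate(truth, C)
  prec <- ifelse(np > 0, tp / np, 0)
  rec <- ifelse(nt > 0, tp / nt, 0)
  s <- prec + rec
  mean(ifelse(s > 0, 2 * prec * rec / s, 0))
}

# Pooled-fold evaluation of one mask: train/predict per fold, pool the
# held-out predictions and compute confusion-based metrics once.
pooled_cv_evaluation <- function(x, y, mask, k, m, folds, seed) {
  x <- as.matrix(x)
  y <- factor(y)
  mask <- as.integer(as.logical(mask))
  fold_idx <- stratified_kfold(y, r = folds, seed = seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  xm <- x[, mask == 1L, drop = FALSE]
  for (test in fold_idx) {
    fit <- fknn(xm[-test, , drop = FALSE], y[-test], k = k, m = m)
    pred[test] <- predict(fit, xm[test, , drop = FALSE])
  }
  prf <- precision_recall_f1(y, pred, levels = levels(y))
  kap <- cohen_kappa(y, pred)
  list(per_class = prf$per_class, macro = prf$macro,
       po = kap$po, pe = kap$pe, kappa = kap$kappa, predictions = pred)
}

#' Quantum-hybrid wrapper feature selection with fuzzy k-NN
#'
#' Fits the Q-Fuzzy (or, with `optimizer = "pso"`, the P-Fuzzy) model:
#' a binary quantum-behaved particle swarm searches over feature-entry
#' masks, scoring each candidate by the stratified cross-validated
#' macro-F1 of a fuzzy k-NN classifier restricted to the selected entries
#' ([subset_fitness()]). The returned object carries the best mask, its
#' fitness trace, a pooled-fold evaluation of the selected subset
#' (per-class precision/recall/F1, macro averages and Cohen's kappa) and a
#' final fuzzy k-NN model fitted on all rows for predicting new cells.
#'
#' @param x Feature matrix / data frame, or a formula such as
#'   `class ~ .` together with `data`.
#' @param y Class labels (ignored for the formula method).
#' @param optimizer `"qpso"` (default) or `"pso"`.
#' @param k Fuzzy k-NN neighbour count (default 4).
#' @param m Fuzzy k-NN weight exponent (default 2).
#' @param folds Cross-validation folds for the fitness (default 5).
#' @param control A [swarm_control()]; its `seed` drives the optimizer and,
#'   via `seed + 1`, the fold assignment.
#' @param cache Memoize fitness evaluations per mask (default TRUE; the
#'   fitness is deterministic, so caching only saves time).
#' @param ... Method-specific arguments, passed on.
#' @return Object of class `qfuzzy`. Key elements: `mask` (named 0/1
#'   vector over feature entries), `selected` (names of selected entries),
#'   `n_selected`, `fitness` (best cross-validated macro-F1), `trace`,
#'   `evaluation` (pooled-fold metrics incl. `kappa`), `model` (final
#'   [fknn()] fit on the selected entries), and the call parameters.
#' @examples
#' \donttest{
#' syn <- generate_feature_table(150, d_informative = 3, d_noise = 6,
#'                               effect_size = 3, n_classes = 3, seed = 7)
#' fit <- qfuzzy(syn$x, syn$y, control = swarm_control(S = 10, T = 15,
#'                                                     seed = 1))
#' print(fit)
#' summary(fit)
#' }
#' @export
qfuzzy <- function(x, ...) UseMethod("qfuzzy")

#' @rdname qfuzzy
#' @param data Data frame holding the variables of the formula.
#' @export
qfuzzy.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  feats <- mf[, -1, drop = FALSE]
  fit <- qfuzzy.default(feats, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname qfuzzy
#' @export
qfuzzy.default <- function(x, y, optimizer = c("qpso", "pso"), k = 4L,
                           m = 2, folds = 5L, control = swarm_control(),
                           cache = TRUE, ...) {
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  y <- factor(y)
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  fold_seed <- (control$seed %||% 0L) + 1L
  fold_idx <- stratified_kfold(y, r = folds, seed = fold_seed)
  prep <- cv_prepare(x, y, fold_idx)
  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  fitness <- function(mask) {
    key <- paste(mask, collapse = "")
    if (cache && !is.null(memo[[key]])) return(memo[[key]])
    f <- cv_fitness(prep, mask, k = k, m = m)
    n_eval <<- n_eval + 1L
    if (cache) memo[[key]] <- f
    f
  }
  runner <- if (optimizer == "qpso") run_qpso else run_pso
  res <- runner(fitness, d = ncol(x), control = control)
  mask <- stats::setNames(res$mask, colnames(x))
  evaluation <- pooled_cv_evaluation(x, y, mask, k = k, m = m,
                                     folds = folds, seed = fold_seed)
  model <- fknn(x[, mask == 1L, drop = FALSE], y, k = k, m = m)
  structure(
    list(call = match.call(), optimizer = optimizer,
         mask = mask, selected = names(mask)[mask == 1L],
         n_selected = sum(mask), fitness = res$fitness,
         trace = res$trace, evaluation = evaluation,
         unique_evaluations = n_eval, total_evaluations = res$evaluations,
         model = model, k = k, m = m, folds = folds,
         fold_seed = fold_seed, control = control,
         feature_names = colnames(x), n = nrow(x),
         classes = levels(y)),
    class = "qfuzzy"
  )
}

#' Cross-validated baseline using every feature entry
#'
#' The All-Features reference point: the same fuzzy k-NN and fold scheme as
#' [qfuzzy()] but with the all-ones mask, i.e. no selection.
#'
#' @inheritParams subset_fitness
#' @return List with `fitness` (mean across-fold macro-F1) and the
#'   pooled-fold `evaluation` (as in [qfuzzy()]).
#' @export
all_features_baseline <- function(x, y, k = 4L, m = 2, folds = 5L,
                                  seed = 1L) {
  x <- as.matrix(x)
  mask <- rep(1L, ncol(x))
  list(
    fitness = subset_fitness(x, y, mask, k = k, m = m, folds = folds,
                             seed = seed),
    evaluation = pooled_cv_evaluation(x, y, mask, k = k, m = m,
                                      folds = folds, seed = seed)
  )
}

# ---- methods ----------------------------------------------------------------

#' @export
print.qfuzzy <- function(x, ...) {
  cat(sprintf("Q-Fuzzy wrapper feature selection (%s optimizer)\n",
              toupper(x$optimizer)))
  cat(sprintf("  %d of %d feature entries selected; CV macro-F1 = %.4f\n",
              x$n_selected, length(x$mask), x$fitness))
  cat(sprintf("  fuzzy k-NN: k = %d, m = %g; %d-fold CV on %d samples, %d classes\n",
              x$k, x$m, x$folds, x$n, length(x$classes)))
  invisible(x)
}

#' @export
summary.qfuzzy <- function(object, ...) {
  structure(list(fit = object), class = "summary.qfuzzy")
}

#' @export
print.summary.qfuzzy <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nSelected entries:\n")
  cat(" ", paste(f$selected, collapse = ", "), "\n")
  cat("\nPooled-fold evaluation of the selected subset:\n")
  per <- f$evaluation$per_class
  per[c("precision", "recall", "f1")] <-
    round(per[c("precision", "recall", "f1")], 3)
  print(per, row.names = FALSE)
  cat(sprintf("\nMacro: precision %.3f, recall %.3f, F1 %.3f; Cohen's kappa %.3f\n",
              f$evaluation$macro["precision"], f$evaluation$macro["recall"],
              f$evaluation$macro["f1"], f$evaluation$kappa))
  invisible(x)
}

#' @export
coef.qfuzzy <- function(object, ...) object$mask

#' Predict classes for new cells from a fitted Q-Fuzzy model
#'
#' Applies the final fuzzy k-NN model (trained on all rows, selected
#' entries only) to new feature rows.
#'
#' @param object A fitted [qfuzzy()] object.
#' @param newdata Feature matrix / data frame containing at least the
#'   selected columns (a full 54-entry table works).
#' @param type `"class"` or `"membership"`.
#' @param ... Unused.
#' @return Factor of classes or a membership matrix.
#' @export
predict.qfuzzy <- function(object, newdata,
                           type = c("class", "membership"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$selected, names(newdata))
  if (length(miss))
    stopf("newdata lacks %d selected columns (first: %s)",
          length(miss), miss[1])
  predict(object$model, newdata[, object$selected, drop = FALSE],
          type = type)
}

#' Plot the global-best fitness trace of a Q-Fuzzy run
#'
#' @param x A fitted [qfuzzy()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.qfuzzy <- function(x, ...) {
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "s",
                 xlab = "iteration", ylab = "global-best CV macro-F1",
                 main = sprintf("%s fitness trace", toupper(x$optimizer)),
                 ...)
  graphics::abline(h = x$fitness, lty = 3, col = "grey50")
  invisible(x)
}

#' Serialize a Q-Fuzzy selection result to JSON
#'
#' Writes mask, selected names, fitness, trace, evaluation metrics and the
#' full run configuration (including seed and package version) for
#' provenance.
#'
#' @param object A fitted [qfuzzy()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
qfuzzy_to_json <- function(object, path) {
  stopifnot(inherits(object, "qfuzzy"))
  payload <- list(
    package_version = as.character(utils::packageVersion("qfuzzy")),
    optimizer = object$optimizer,
    config = list(k = object$k, m = object$m, folds = object$folds,
                  S = object$control$S, T = object$control$T,
                  alpha = object$control$alpha,
                  seed = object$control$seed),
    mask = as.integer(object$mask),
    feature_names = object$feature_names,
    selected = object$selected,
    n_selected = object$n_selected,
    fitness = object$fitness,
    trace = object$trace,
    evaluation = list(
      per_class = object$evaluation$per_class,
      macro = as.list(object$evaluation$macro),
      kappa = object$evaluation$kappa,
      po = object$evaluation$po,
      pe = object$evaluation$pe
    )
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
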