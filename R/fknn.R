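#' Min-max normalization
#'
#' `minmax_fit` records per-column minima and maxima of a training matrix;
#' `minmax_apply` rescales columns to \[0, 1\] with those statistics,
#' mapping constant columns to 0 and clipping values outside the training
#' range.
#'
#' @param x Numeric matrix or data frame of features.
#' @return `minmax_fit`: a list with `min` and `max` vectors.
#' @export
minmax_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stopf("need at least one row")
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

#' @rdname minmax_fit
#' @param params Output of `minmax_fit`.
#' @return `minmax_apply`: the rescaled matrix.
#' @export
minmax_apply <- function(params, x) {
  x <- as.matrix(x)
  rng <- params$max - params$min
  out <- sweep(x, 2, params$min, "-")
  scale <- ifelse(rng > 0, rng, 1)
  out <- sweep(out, 2, scale, "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Initial class memberships for training samples
#'
#' The crisp scheme assigns each training sample full membership (1) in its
#' own class and 0 elsewhere, i.e. one-hot rows. A hook is kept for future
#' fuzzified schemes; only `"crisp"` is implemented.
#'
#' @param labels Factor (or coercible) of training class labels.
#' @param scheme Membership initialization scheme.
#' @param classes Optional class level order; defaults to `levels(labels)`.
#' @return n x C row-stochastic matrix with one column per class.
#' @export
init_memberships <- function(labels, scheme = "crisp", classes = NULL) {
  if (!identical(scheme, "crisp"))
    stopf("unknown membership scheme '%s'", scheme)
  labels <- factor(labels, levels = classes %||% levels(factor(labels)))
  if (anyNA(labels)) stopf("labels outside the supplied class set")
  u <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  u[cbind(seq_along(labels), as.integer(labels))] <- 1
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fuzzy k-nearest-neighbour classifier
#'
#' Fits a fuzzy k-NN model: queries receive class memberships as a
#' distance-weighted convex combination of their k nearest training
#' samples' memberships,
#' \deqn{u(x, c_i) = \frac{\sum_{k} u(x_k, c_i)\, d(x, x_k)^{-2/(m-1)}}
#'                        {\sum_{k} d(x, x_k)^{-2/(m-1)}},}
#' with Euclidean distance on min-max-normalized features and weight
#' exponent `m > 1`. The predicted class is the membership argmax (ties
#' resolved to the lowest class index).
#'
#' @param x Numeric feature matrix or data frame (rows = samples).
#' @param y Class labels, one per row.
#' @param k Number of neighbours (default 4).
#' @param m Weight exponent, must exceed 1 (default 2).
#' @param scale Min-max-normalize features using training statistics
#'   (default TRUE).
#' @return Object of class `fknn` with `predict`, `print` methods.
#' @details A query at zero distance from one or more of its k neighbours
#'   inherits the mean membership row of those exact matches (the limit of
#'   the weighting formula). Neighbour ties at the k-th rank are broken by
#'   training-row order.
#' @examples
#' fit <- fknn(iris[, 1:4], iris$Species, k = 5)
#' table(predict(fit, iris[, 1:4]), iris$Species)
#' @export
fknn <- function(x, y, k = 4L, m = 2, scale = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (m <= 1) stopf("weight exponent m must be > 1 (got %g)", m)
  if (k < 1L || k > nrow(x))
    stopf("k must be in 1..n (k = %d, n = %d)", k, nrow(x))
  if (nrow(x) != length(y)) stopf("x and y sizes differ")
  params <- if (scale) minmax_fit(x) else NULL
  xs <- if (scale) minmax_apply(params, x) else x
  structure(
    list(x = xs, y = y, classes = levels(y),
         memberships = init_memberships(y),
         k = as.integer(k), m = m, scale = scale, params = params),
    class = "fknn"
  )
}

#' @export
print.fknn <- function(x, ...) {
  cat(sprintf("Fuzzy k-NN: n = %d, d = %d, classes = %d, k = %d, m = %g\n",
              nrow(x$x), ncol(x$x), length(x$classes), x$k, x$m))
  invisible(x)
}

#' Class memberships of query points under a fuzzy k-NN model
#'
#' @param object A fitted [fknn()] model.
#' @param newdata Query matrix / data frame with the training columns.
#' @return List with `memberships` (q x C row-stochastic matrix), `class`
#'   (factor of argmax predictions), `neighbours` and `distances`
#'   (q x k matrices of the selected training-row indices and their
#'   Euclidean distances).
#' @export
fknn_membership <- function(object, newdata) {
  stopifnot(inherits(object, "fknn"))
  q <- as.matrix(newdata)
  storage.mode(q) <- "double"
  if (ncol(q) != ncol(object$x))
    stopf("query has %d columns, model expects %d", ncol(q), ncol(object$x))
  if (object$scale) q <- minmax_apply(object$params, q)
  core <- knn_core(object$x, q, object$memberships, object$k, object$m)
  u_out <- core$u
  colnames(u_out) <- object$classes
  nb_out <- core$nb
  d_out <- core$d
  cls <- factor(object$classes[max.col(u_out, ties.method = "first")],
                levels = object$classes)
  list(memberships = u_out, class = cls,
       neighbours = nb_out, distances = d_out)
}

# Shared fuzzy k-NN kernel: nearest neighbours of the query rows `q` among
# training rows `tr` (both already normalized), membership aggregation with
# weight exponent m. The k selection passes use max.col with ties.method =
# "first", which realises the stable (distance, training index) neighbour
# order at C speed.
knn_core <- function(tr, q, M, k, m) {
  expo <- -2 / (m - 1)
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(q^2), rowSums(tr^2), "+") - 2 * tcrossprod(q, tr)
  d2[d2 < 0] <- 0
  nq <- nrow(q)
  nb_out <- matrix(NA_integer_, nq, k)
  d_out <- matrix(NA_real_, nq, k)
  rows <- seq_len(nq)
  for (j in seq_len(k)) {
    nb <- max.col(-d2, ties.method = "first")
    nb_out[, j] <- nb
    d_out[, j] <- sqrt(d2[cbind(rows, nb)])
    d2[cbind(rows, nb)] <- Inf
  }
  w <- d_out^expo
  u <- matrix(0, nq, ncol(M))
  for (j in seq_len(k))
    u <- u + w[, j] * M[nb_out[, j], , drop = FALSE]
  u <- u / rowSums(w)
  exact <- which(rowSums(d_out == 0) > 0)
  for (i in exact) {             # zero-distance limit: inherit exact matches
    hit <- nb_out[i, d_out[i, ] == 0]
    u[i, ] <- colMeans(M[hit, , drop = FALSE])
  }
  list(u = u, nb = nb_out, d = d_out)
}

#' Predict method for fuzzy k-NN models
#'
#' @param object A fitted [fknn()] model.
#' @param newdata Query feature matrix / data frame.
#' @param type `"class"` for predicted labels, `"membership"` for the full
#'   membership matrix.
#' @param ... Unused.
#' @return Factor of predicted classes, or the membership matrix.
#' @export
predict.fknn <- function(object, newdata,
                         type = c("class", "membership"), ...) {
  type <- match.arg(type)
  res <- fknn_membership(object, newdata)
  if (type == "class") res$class else res$memberships
}

#' Serialize / restore a fuzzy k-NN model as JSON
#'
#' @param object A fitted [fknn()] model.
#' @param path JSON file path.
#' @return `fknn_to_json` returns `path` invisibly; `fknn_from_json` the
#'   restored model.
#' @export
fknn_to_json <- function(object, path) {
  stopifnot(inherits(object, "fknn"))
  payload <- list(
    x = unclass(as.data.frame(object$x)), y = as.character(object$y),
    classes = object$classes, k = object$k, m = object$m,
    scale = object$scale, params = object$params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname fknn_to_json
#' @export
fknn_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- as.matrix(as.data.frame(p$x))
  # the stored training matrix is already normalized; restore the params so
  # queries are rescaled, without touching the stored rows again
  fit <- fknn(x, factor(p$y, levels = p$classes), k = p$k, m = p$m,
              scale = FALSE)
  fit$scale <- isTRUE(p$scale)
  if (fit$scale)
    fit$params <- list(min = unlist(p$params$min), max = unlist(p$params$max))
  fit
}
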