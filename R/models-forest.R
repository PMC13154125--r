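# Random-forest model track: ensemble-of-trees classifier over feature
# tables, with per-class probabilities given by tree-vote shares, an optional
# random-search tuning hook, and deterministic behaviour under a fixed seed.

#' Train the random-forest space-group classifier
#'
#' @param table an `xtal_features` table (rows = molecules).
#' @param labels integer space-group labels aligned with the table rows.
#' @param hyperparams list of randomForest hyperparameters (`ntree`, `mtry`,
#'   `nodesize`, ...). Defaults: 500 trees, unlimited depth, default `mtry`.
#' @param seed integer seed; the fitted ensemble is reproducible bit-for-bit.
#' @param tune optional tuning hook: a list with `grid` (named list of
#'   candidate values per hyperparameter) and `budget` (number of random
#'   configurations to evaluate on an internal 80/20 split by top-1
#'   accuracy). The winning configuration is refitted on all rows.
#' @return Object of class `xtal_forest` with the fitted ensemble, ordered
#'   class levels and training-frequency table (used for prediction
#'   tie-breaks).
#' @export
train_forest <- function(table, labels, hyperparams = list(), seed = 1L,
                         tune = NULL) {
  stopifnot(inherits(table, "xtal_features"))
  X <- table$values
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) stop("labels must align with table rows")
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  if (nrow(X) < length(unique(labels))) stop("fewer rows than classes")
  y <- factor(labels, levels = sort(unique(labels)))

  if (!is.null(tune)) {
    hyperparams <- .tune_forest(X, y, tune, seed)
  }
  hp <- utils::modifyList(list(ntree = 500L), hyperparams)
  set.seed(seed)
  fit <- do.call(randomForest::randomForest,
                 c(list(x = X, y = y), hp))
  freq <- table(labels)
  structure(list(fit = fit,
                 class_levels = as.integer(levels(y)),
                 train_freq = stats::setNames(as.integer(freq), names(freq)),
                 feature_names = colnames(X),
                 hyperparams = hp,
                 seed = as.integer(seed)),
            class = "xtal_forest")
}

.tune_forest <- function(X, y, tune, seed) {
  stopifnot(is.list(tune$grid), length(tune$grid) > 0)
  budget <- if (is.null(tune$budget)) 10L else as.integer(tune$budget)
  set.seed(seed + 1L)
  n <- nrow(X)
  hold <- sample.int(n, max(1L, round(0.2 * n)))
  best <- NULL; best_acc <- -Inf
  for (b in seq_len(budget)) {
    cand <- lapply(tune$grid, function(v) v[[sample.int(length(v), 1L)]])
    set.seed(seed + 1000L + b)
    fit <- do.call(randomForest::randomForest,
                   c(list(x = X[-hold, , drop = FALSE], y = y[-hold]), cand))
    acc <- mean(predict(fit, X[hold, , drop = FALSE]) == y[hold])
    if (acc > best_acc) { best_acc <- acc; best <- cand }
  }
  best
}

#' @export
print.xtal_forest <- function(x, ...) {
  cat(sprintf("<xtal_forest: %d trees, %d classes, %d features>\n",
              x$fit$ntree, length(x$class_levels), length(x$feature_names)))
  invisible(x)
}

#' Per-class probabilities from a trained model
#'
#' For the forest these are tree-vote shares; rows sum to 1.
#'
#' @param object an `xtal_forest`.
#' @param table an `xtal_features` table (same feature columns).
#' @param ... unused.
#' @return Numeric matrix (rows = molecules, columns = space-group numbers).
#' @export
predict.xtal_forest <- function(object, table, ...) {
  stopifnot(inherits(table, "xtal_features"))
  X <- table$values[, object$feature_names, drop = FALSE]
  P <- predict(object$fit, X, type = "prob")
  rownames(P) <- rownames(X)
  P
}

#' Top-N classes from a probability vector
#'
#' Returns the classes of the `n` largest probabilities. Ties are broken by
#' higher global training frequency, then by lower space-group number.
#'
#' @param probs named numeric probability vector (names = space-group
#'   numbers), or a matrix with one such row per example.
#' @param n number of classes to return (1 <= n <= number of classes).
#' @param train_freq optional named count vector used for tie-breaking.
#' @return Integer vector of `n` space-group numbers (for a matrix input, an
#'   n-column integer matrix, one row per example).
#' @export
top_n_classes <- function(probs, n, train_freq = NULL) {
  if (is.matrix(probs)) {
    return(t(apply(probs, 1, function(p)
      top_n_classes(stats::setNames(p, colnames(probs)), n, train_freq))))
  }
  k <- length(probs)
  if (n < 1 || n > k) stop("n must lie in 1..", k)
  cls <- as.integer(names(probs))
  freq <- if (is.null(train_freq)) rep(0, k) else {
    f <- train_freq[as.character(cls)]
    f[is.na(f)] <- 0
    as.numeric(f)
  }
  ord <- order(-as.numeric(probs), -freq, cls)
  cls[ord[seq_len(n)]]
}
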