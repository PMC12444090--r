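#' Model adapter contract
#'
#' An adapter packages a learner behind a uniform `fit`/`predict` surface so
#' the sampling machinery never touches model internals. `fit(x, y)` receives
#' a standardized numeric feature matrix and target vector and returns an
#' opaque model object; `predict(model, x)` returns numeric predictions.
#' Optionally an adapter may override `score(model, x, y)` to substitute any
#' scalar accuracy for the default R-squared.
#'
#' @param name Short identifier used in outputs.
#' @param fit Function `(x, y) -> model`.
#' @param predict Function `(model, x) -> numeric predictions`.
#' @param score Optional function `(model, x, y) -> scalar accuracy`;
#'   default computes the coefficient of determination of `predict`.
#' @param block_eval Optional vectorized fast path used by the samplers:
#'   function `(features, target, idx, n_tr, perm)` scoring a whole block of
#'   repetitions at once, where `idx` is a (repetitions x d_n) matrix of
#'   subsample row indices (first `n_tr` columns = training rows) and `perm`
#'   an optional matrix of training-target permutations; must return
#'   `list(tr =, te =)` of accuracy vectors and agree with the
#'   `fit`/`predict`/`score` path.
#'
#' @return An object of class `model_adapter`.
#' @export
model_adapter <- function(name, fit, predict, score = NULL, block_eval = NULL) {
  stopifnot(is.character(name), is.function(fit), is.function(predict),
            is.null(score) || is.function(score),
            is.null(block_eval) || is.function(block_eval))
  structure(list(name = name, fit = fit, predict = predict, score = score,
                 block_eval = block_eval),
            class = "model_adapter")
}

#' @export
print.model_adapter <- function(x, ...) {
  cat(sprintf("<model_adapter> %s\n", x$name))
  invisible(x)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` with SST taken about the mean of the observed values of
#' the split being scored. Zero-variance observations yield `NA`.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A scalar; 1 for a perfect fit, <= 0 for a model no better than the
#'   split mean.
#' @export
r_squared <- function(observed, predicted) {
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / sst
}

#' Ordinary least squares adapter
#'
#' Linear regression with an intercept. Rank-deficient training sets (fewer
#' samples than coefficients) fall back to the minimum-norm least-squares
#' solution via the singular value decomposition, so the adapter remains
#' defined in the heavily overparameterized regime where training accuracy
#' saturates at 1.
#'
#' @return A [model_adapter()].
#' @export
ols_adapter <- function() {
  model_adapter(
    name = "ols",
    fit = function(x, y) {
      a <- cbind(1, x)
      fit <- stats::lm.fit(a, y)
      coef <- fit$coefficients
      if (anyNA(coef)) {
        sv <- svd(a)
        pos <- sv$d > max(sv$d) * 1e-10
        coef <- sv$v[, pos, drop = FALSE] %*%
          ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
        coef <- drop(coef)
      }
      coef
    },
    predict = function(model, x) drop(cbind(1, x) %*% model),
    block_eval = function(features, target, idx, n_tr, perm = NULL) {
      .ols_block_eval(features, target, idx, n_tr, perm)
    }
  )
}

#' k-nearest-neighbors regression adapter
#'
#' Uniform-weight KNN regression: each prediction is the mean target of the
#' exactly `k` nearest training rows by Euclidean distance (distance ties
#' broken by row index, as in the common array-partition implementations).
#' The effective neighbor count is capped at the training-set size, so the
#' adapter stays defined on subsamples smaller than `n_neighbors`. When
#' scoring the training split a point is its own nearest neighbor.
#'
#' @param n_neighbors Number of neighbors (default 25).
#' @return A [model_adapter()].
#' @export
knn_adapter <- function(n_neighbors = 25L) {
  stopifnot(is_count(n_neighbors))
  n_neighbors <- as.integer(n_neighbors)
  model_adapter(
    name = sprintf("knn%d", n_neighbors),
    fit = function(x, y) {
      list(x = x, y = y, k = min(n_neighbors, nrow(x)))
    },
    predict = function(model, x) {
      # squared distances via the Gram trick, one query row per matrix row
      d2 <- outer(rowSums(x^2), rowSums(model$x^2), "+") -
        2 * tcrossprod(x, model$x)
      apply(d2, 1L, function(d) mean(model$y[order(d)[seq_len(model$k)]]))
    },
    block_eval = function(features, target, idx, n_tr, perm = NULL) {
      .knn_block_eval(features, target, idx, n_tr, n_neighbors, perm)
    }
  )
}

#' Constant-score diagnostic adapter
#'
#' Ignores the data and reports a fixed accuracy on both splits. Its accuracy
#' distributions have zero variance, so any tolerance is met after the first
#' repetition block — useful for exercising and testing the adaptive loop.
#'
#' @param value The accuracy to report.
#' @return A [model_adapter()].
#' @export
fixed_score_adapter <- function(value = 0.5) {
  stopifnot(is_number(value))
  model_adapter(
    name = sprintf("fixed_score(%g)", value),
    fit = function(x, y) NULL,
    predict = function(model, x) rep(0, nrow(x)),
    score = function(model, x, y) value
  )
}

#' Fit and score an adapter on one train/test split
#'
#' A standardizer (per-feature mean and standard deviation) is fit on the
#' training split only and applied to both splits; the adapter is then fit on
#' the standardized training data and scored on both splits (default score:
#' [r_squared()]). Features with zero training variance are centred and left
#' unscaled. Adapter failures are re-raised with the sampling context
#' (size index, repetition, instance) attached.
#'
#' @param adapter A [model_adapter()].
#' @param train,test Objects with `$features` (numeric matrix) and `$target`
#'   (numeric vector), e.g. [data_pool()]s.
#' @param context Optional list with elements `n`, `i`, `j` for error messages.
#' @return A list with elements `acc_tr` and `acc_te`.
#' @export
evaluate_once <- function(adapter, train, test, context = NULL) {
  n_tr <- nrow(train$features)
  mu <- colMeans(train$features)
  s <- sqrt(pmax(colSums(train$features^2) / n_tr - mu^2, 0))
  s[s == 0] <- 1
  xtr <- t((t(train$features) - mu) / s)
  xte <- t((t(test$features) - mu) / s)
  res <- tryCatch({
    model <- adapter$fit(xtr, train$target)
    if (is.function(adapter$score)) {
      c(adapter$score(model, xtr, train$target),
        adapter$score(model, xte, test$target))
    } else {
      c(r_squared(train$target, adapter$predict(model, xtr)),
        r_squared(test$target, adapter$predict(model, xte)))
    }
  }, error = function(e) {
    ctx <- if (is.null(context)) "" else
      sprintf(" [n = %s, i = %s, j = %s]",
              context$n, context$i, context$j)
    abort_adaptsize(
      sprintf("adapter '%s' failed%s: %s", adapter$name, ctx,
              conditionMessage(e)),
      "adaptsize_adapter_error")
  })
  list(acc_tr = res[[1]], acc_te = res[[2]])
}
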