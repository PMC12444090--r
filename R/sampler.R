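#' Number of samples drawn at a ladder percentage
#'
#' Converts a pool percentage into a subsample count: `n_percent/100 *
#' pool_size`, rounded half up, floored at 2 so a train/test split is always
#' possible.
#'
#' @param pool_size Number of samples in the pool.
#' @param n_percent Percentage in (0, 100].
#' @return Integer subsample size `d_n`.
#' @export
#' @examples
#' subsample_size(442, 2.5)  # 11
subsample_size <- function(pool_size, n_percent) {
  stopifnot(is_count(pool_size))
  if (!is_number(n_percent) || n_percent <= 0 || n_percent > 100) {
    abort_adaptsize("n_percent must lie in (0, 100]", "adaptsize_bad_config")
  }
  max(2L, as.integer(floor(n_percent / 100 * pool_size + 0.5)))
}

#' Draw a random subsample from a pool
#'
#' Selects `d_n` rows uniformly without replacement, in randomized order,
#' using the current RNG stream (seed it with [set.seed()] for
#' reproducibility).
#'
#' @param pool A [data_pool()].
#' @param d_n Number of rows to draw, between 2 and the pool size.
#' @return A [data_pool()] with `d_n` rows.
#' @export
draw_subsample <- function(pool, d_n) {
  stopifnot(inherits(pool, "data_pool"))
  if (!is_count(d_n) || d_n < 2 || d_n > pool$sample_count) {
    abort_adaptsize(
      sprintf("d_n must lie in [2, %d]", pool$sample_count),
      "adaptsize_bad_draw")
  }
  pool_rows(pool, sample.int(pool$sample_count, d_n))
}

#' Split a subsample into training and test pools
#'
#' The first `floor(c * d_n)` rows become the training set and the remainder
#' the test set. Subsamples from [draw_subsample()] arrive in randomized row
#' order, so this is a uniformly random partition.
#'
#' @param sub A [data_pool()] (typically a fresh subsample).
#' @param c Train fraction in (0, 1).
#' @return A list with elements `train` and `test`, both [data_pool()]s.
#' @export
split_train_test <- function(sub, c) {
  stopifnot(inherits(sub, "data_pool"))
  if (!is_number(c) || c <= 0 || c >= 1) {
    abort_adaptsize("split fraction must lie strictly between 0 and 1",
                    "adaptsize_bad_config")
  }
  d_n <- sub$sample_count
  n_tr <- floor(c * d_n)
  if (n_tr < 1 || d_n - n_tr < 1) {
    abort_adaptsize(
      sprintf("degenerate split: %d samples with c = %g leaves an empty side",
              d_n, c),
      "adaptsize_degenerate_split")
  }
  list(train = pool_rows(sub, seq_len(n_tr)),
       test = pool_rows(sub, (n_tr + 1L):d_n))
}

#' Summarize an accuracy distribution
#'
#' The four characteristics whose pairwise agreement across sampling instances
#' defines stability: mean, median, and the 25th/75th percentiles (linear
#' interpolation between order statistics, [stats::quantile()] type 7).
#'
#' @param values Nonempty numeric vector.
#' @return A one-row data frame with columns `mean`, `median`, `q25`, `q75`,
#'   `count`.
#' @export
#' @examples
#' summarize_dist(c(1, 2, 3, 4))  # q25 = 1.75, q75 = 3.25
summarize_dist <- function(values) {
  if (length(values) < 1L || !is.numeric(values)) {
    abort_adaptsize("cannot summarize an empty distribution",
                    "adaptsize_empty_distribution")
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(mean = mean(values), median = q[[2]], q25 = q[[1]], q75 = q[[3]],
             count = length(values))
}

#' Pairwise similarity of distribution characteristics
#'
#' TRUE iff for every pair of instances and every characteristic the absolute
#' difference is at most the tolerance (inclusive, so exact ties on the
#' boundary pass). The worst observed pairwise difference is attached as
#' attribute `"worst_diff"` for progress reporting.
#'
#' @param summaries Data frame of characteristic rows (one per instance), as
#'   produced by [summarize_dist()].
#' @param tolerance Positive number, or named vector with entries `mean`,
#'   `median`, `q25`, `q75`.
#' @return Logical scalar with attribute `worst_diff`.
#' @export
characteristics_similar <- function(summaries, tolerance) {
  chars <- c("mean", "median", "q25", "q75")
  if (length(tolerance) == 1L) {
    tolerance <- stats::setNames(rep(as.numeric(tolerance), 4L), chars)
  }
  stopifnot(nrow(summaries) >= 2L, all(tolerance > 0))
  ok <- TRUE
  worst <- 0
  for (ch in chars) {
    d <- max(abs(outer(summaries[[ch]], summaries[[ch]], "-")))
    worst <- max(worst, d)
    if (d > tolerance[[ch]]) ok <- FALSE
  }
  structure(ok, worst_diff = worst)
}

# Linear-interpolation quantile read directly off a sorted vector
# (equivalent to stats::quantile type 7).
quantile_sorted <- function(sorted, p) {
  n <- length(sorted)
  h <- (n - 1) * p
  lo <- floor(h)
  val <- sorted[lo + 1]
  frac <- h - lo
  up <- sorted[pmin(lo + 2, n)]
  val + frac * (up - val)
}

# ---- the adaptive repetition loop (shared by model mode and statistic mode) --
#
# round_fun(block) must return list[[j]][[split]] = numeric(k0) of new values
# for instance j, deterministically as a function of `block` alone, so that
# reruns and extensions are append-only and schedule-independent.
#
# The repetition count can reach ~1e6, and the characteristics are re-tested
# after every block, so the loop keeps each distribution both as an
# append-only raw buffer (amortized growth, in an environment so
# subassignment stays in place) and as an incrementally merged sorted copy
# from which mean and quantiles are read in O(1)/O(n) instead of re-sorting.
stabilize_loop <- function(round_fun, splits, config, label, verbose = FALSE) {
  m <- config$instances
  k0 <- config$base_reps
  st <- new.env(parent = emptyenv())
  st$len <- 0L
  st$buf <- list()    # raw values in arrival order, [[j]][[s]]
  st$sorted <- list() # the same values, kept sorted
  for (j in seq_len(m)) {
    st$buf[[j]] <- stats::setNames(
      lapply(splits, function(s) numeric(k0 * 4L)), splits)
    st$sorted[[j]] <- stats::setNames(
      lapply(splits, function(s) numeric(0)), splits)
  }
  chars <- c("mean", "median", "q25", "q75")
  block <- 0L
  converged <- FALSE
  worst <- NA_real_
  repeat {
    if (block >= 1L && (block + 1L) * k0 > config$max_reps) {
      warning(sprintf(
        "%s: repetition cap %d reached before stabilization (worst diff %.3g)",
        label, config$max_reps, worst), call. = FALSE)
      break
    }
    block <- block + 1L
    new <- round_fun(block)
    need <- st$len + k0
    for (j in seq_len(m)) {
      for (s in splits) {
        if (need > length(st$buf[[j]][[s]])) {
          length(st$buf[[j]][[s]]) <- max(2L * length(st$buf[[j]][[s]]), need)
        }
        st$buf[[j]][[s]][(st$len + 1L):need] <- new[[j]][[s]]
        st$sorted[[j]][[s]] <- .merge_sorted(st$sorted[[j]][[s]],
                                             sort(new[[j]][[s]]))
      }
    }
    st$len <- need
    ok <- TRUE
    worst <- 0
    for (s in splits) {
      sums <- vapply(seq_len(m), function(j) {
        srt <- st$sorted[[j]][[s]]
        c(sum(srt) / st$len, quantile_sorted(srt, c(0.5, 0.25, 0.75)))
      }, numeric(4))
      for (ch in seq_along(chars)) {
        d <- max(sums[ch, ]) - min(sums[ch, ])
        worst <- max(worst, d)
        if (d > config$tolerance[[chars[ch]]]) ok <- FALSE
      }
    }
    if (verbose) {
      message(sprintf("%s: k_n = %d, worst pairwise diff = %.4g",
                      label, block * k0, worst))
    }
    if (ok) {
      converged <- TRUE
      break
    }
  }
  values <- lapply(seq_len(m), function(j) {
    stats::setNames(lapply(splits, function(s) {
      st$buf[[j]][[s]][seq_len(st$len)]
    }), splits)
  })
  summaries <- do.call(rbind, lapply(seq_len(m), function(j) {
    do.call(rbind, lapply(splits, function(s) {
      cbind(data.frame(instance = j, split = s), summarize_dist(values[[j]][[s]]))
    }))
  }))
  list(values = values, final_k_n = block * k0, converged = converged,
       summaries = summaries, worst_diff = worst)
}

# One block of repetitions for instance j: draw -> split -> (optionally
# shuffle train targets) -> standardize -> fit -> score, `nreps` times from
# the deterministic per-(size, instance, block) stream. Kept lean: runs up to
# ~1e6 times per study.
model_block <- function(pool, adapter, config, d_n, n_index, shuffle,
                        j, block, nreps) {
  n_pool <- pool$sample_count
  n_tr <- floor(config$split_fraction * d_n)
  phase <- if (shuffle) 1L else 0L
  x <- pool$features
  y <- pool$target
  set.seed(mix_seed(config$seed, phase, n_index, j, block))
  if (is.function(adapter$block_eval)) {
    # vectorized fast path: draw all indices (and shuffle permutations) from
    # the block stream in the same order as the per-repetition path below
    idx <- matrix(0L, nrow = nreps, ncol = d_n)
    perm <- if (shuffle) matrix(0L, nrow = nreps, ncol = n_tr) else NULL
    for (i in seq_len(nreps)) {
      idx[i, ] <- sample.int(n_pool, d_n)
      if (shuffle) perm[i, ] <- sample.int(n_tr)
    }
    res <- tryCatch(
      adapter$block_eval(x, y, idx, n_tr, perm),
      error = function(e) {
        abort_adaptsize(
          sprintf("adapter '%s' failed [n = %s, block = %s, j = %s]: %s",
                  adapter$name, n_index, block, j, conditionMessage(e)),
          "adaptsize_adapter_error")
      })
    return(list(tr = as.numeric(res$tr), te = as.numeric(res$te)))
  }
  tr <- numeric(nreps)
  te <- numeric(nreps)
  for (i in seq_len(nreps)) {
    idx <- sample.int(n_pool, d_n)
    itr <- idx[seq_len(n_tr)]
    ite <- idx[(n_tr + 1L):d_n]
    ytr <- y[itr]
    if (shuffle) ytr <- ytr[sample.int(n_tr)]
    acc <- evaluate_once(
      adapter,
      list(features = x[itr, , drop = FALSE], target = ytr),
      list(features = x[ite, , drop = FALSE], target = y[ite]),
      context = list(n = n_index, i = (block - 1L) * config$base_reps + i, j = j))
    tr[i] <- acc$acc_tr
    te[i] <- acc$acc_te
  }
  list(tr = tr, te = te)
}

model_round_fun <- function(pool, adapter, config, d_n, n_index, shuffle) {
  function(block) {
    lapply(seq_len(config$instances), function(j) {
      model_block(pool, adapter, config, d_n, n_index, shuffle,
                  j, block, config$base_reps)
    })
  }
}

#' Stabilize the accuracy distributions at one ladder size
#'
#' Runs the adaptive repetition loop at a single pool percentage: each round
#' adds `k0` fresh draw/split/fit/score repetitions per sampling instance
#' (previous values are always kept), then tests whether the mean, median and
#' 25th/75th percentiles of the per-instance accuracy distributions agree
#' pairwise within tolerance on both the training and test split. On
#' agreement the loop breaks; if the repetition cap would be exceeded the
#' size is reported unconverged with a warning.
#'
#' @param pool A [data_pool()].
#' @param n_percent Ladder percentage in (0, 100].
#' @param adapter A [model_adapter()].
#' @param config A [study_config()].
#' @param shuffle If TRUE, training targets are randomly permuted before each
#'   fit (the no-signal baseline).
#' @param n_index Integer index of this size within the ladder, used to derive
#'   the per-(size, instance, block) random streams. Defaults to the position
#'   of `n_percent` in `config$ladder`.
#' @param verbose Print a progress line (current `k_n`, worst pairwise
#'   difference) after each round.
#'
#' @return An object of class `stabilized_size`: the drawn size `d_n`, train
#'   and test sizes, the final repetition count, the per-instance summaries,
#'   all raw accuracy values, and a convergence flag.
#' @export
stabilize_size <- function(pool, n_percent, adapter, config,
                           shuffle = FALSE, n_index = NULL, verbose = FALSE) {
  stopifnot(inherits(pool, "data_pool"), inherits(adapter, "model_adapter"),
            inherits(config, "study_config"))
  if (is.null(n_index)) {
    n_index <- match(n_percent, config$ladder)
    if (is.na(n_index)) n_index <- 0L
  }
  d_n <- subsample_size(pool$sample_count, n_percent)
  n_tr <- floor(config$split_fraction * d_n)
  n_te <- d_n - n_tr
  if (n_tr < 1 || n_te < 1) {
    abort_adaptsize(
      sprintf("ladder entry %g%% gives a degenerate split", n_percent),
      "adaptsize_degenerate_split")
  }
  res <- stabilize_loop(
    model_round_fun(pool, adapter, config, d_n, n_index, shuffle),
    splits = c("tr", "te"), config = config,
    label = sprintf("n = %g%%%s", n_percent, if (shuffle) " (shuffled)" else ""),
    verbose = verbose)
  structure(
    list(n_percent = n_percent, d_n = d_n, train_size = n_tr, test_size = n_te,
         final_k_n = res$final_k_n, converged = res$converged,
         summaries = res$summaries, values = res$values,
         worst_diff = res$worst_diff, shuffled = shuffle),
    class = "stabilized_size")
}

#' @export
print.stabilized_size <- function(x, ...) {
  cat(sprintf(
    "<stabilized_size> n = %g%% (d_n = %d: %d train / %d test), k_n = %d, %s\n",
    x$n_percent, x$d_n, x$train_size, x$test_size, x$final_k_n,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Run an adaptive subsampling study over the whole size ladder
#'
#' Applies [stabilize_size()] to every ladder entry in ascending order. The
#' full run is a pure function of the pool, the adapter and the configuration
#' (including its master seed).
#'
#' @inheritParams stabilize_size
#' @return An object of class `size_study`: the configuration, adapter name,
#'   pool dimensions, and one `stabilized_size` per ladder entry.
#' @export
#' @examples
#' pool <- generate_pool(synthetic_spec(300, weight_vector = 1, noise_sd = 1))
#' cfg <- study_config(ladder = c(50, 100), base_reps = 20, tolerance = 0.05,
#'                     seed = 7)
#' study <- run_study(pool, ols_adapter(), cfg)
run_study <- function(pool, adapter, config, verbose = FALSE) {
  stopifnot(inherits(pool, "data_pool"), inherits(adapter, "model_adapter"),
            inherits(config, "study_config"))
  validate_config_for_pool(config, pool)
  sizes <- lapply(seq_along(config$ladder), function(i) {
    stabilize_size(pool, config$ladder[i], adapter, config,
                   n_index = i, verbose = verbose)
  })
  structure(
    list(config = config, adapter = adapter$name,
         pool_size = pool$sample_count, n_features = ncol(pool$features),
         sizes = sizes, mode = "model"),
    class = "size_study")
}

#' @export
print.size_study <- function(x, ...) {
  cat(sprintf("<size_study> adapter '%s', pool %d x %d, %d ladder sizes\n",
              x$adapter, x$pool_size, x$n_features, length(x$sizes)))
  for (s in x$sizes) {
    cat(sprintf("  n = %5.1f%%  d_n = %5d  k_n = %6d  %s\n",
                s$n_percent, s$d_n, s$final_k_n,
                if (s$converged) "converged" else "capped"))
  }
  invisible(x)
}
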