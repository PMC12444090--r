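#' Shuffle the targets of a pool
#'
#' Returns the pool with its target vector replaced by a uniform random
#' permutation of itself (features untouched), using the current RNG stream.
#' This severs any feature-target relationship while preserving the target's
#' marginal distribution exactly, giving a no-signal reference model.
#'
#' @param pool A [data_pool()].
#' @return A [data_pool()] with permuted targets.
#' @export
shuffle_targets <- function(pool) {
  stopifnot(inherits(pool, "data_pool"))
  data_pool(pool$features, pool$target[sample.int(pool$sample_count)])
}

#' One-sided Mann-Whitney U test
#'
#' p-value for the alternative that `greater_sample` is stochastically larger
#' than `lesser_sample`. Small tie-free samples use the exact U distribution;
#' otherwise the normal approximation with tie correction is used
#' (delegated to [stats::wilcox.test()], which implements exactly this
#' switch).
#'
#' @param greater_sample,lesser_sample Nonempty numeric vectors.
#' @return A p-value in \[0, 1\].
#' @export
#' @examples
#' mwu_one_sided(c(4, 5, 6), c(1, 2, 3))  # 0.05: complete separation of 3 vs 3
mwu_one_sided <- function(greater_sample, lesser_sample) {
  if (length(greater_sample) < 1L || length(lesser_sample) < 1L) {
    abort_adaptsize("both samples must be nonempty", "adaptsize_empty_sample")
  }
  suppressWarnings(
    stats::wilcox.test(greater_sample, lesser_sample,
                       alternative = "greater")$p.value
  )
}

#' Determine the minimum learning size n0
#'
#' Scans the size ladder in ascending order. At each size the shuffled-target
#' accuracy distributions are stabilized with the same adaptive machinery as
#' the main study; then, per instance, the unshuffled test accuracies are
#' compared against the shuffled ones with a one-sided Mann-Whitney U test.
#' The first size at which every instance rejects (p below the significance
#' level) *and* has a larger unshuffled mean test accuracy becomes `n0` — the
#' percentage at which reasonable model learning starts. If no size
#' qualifies, `n0` keeps its initial sentinel value above 100 ("not found").
#'
#' @param study A completed [run_study()] result.
#' @param pool The same [data_pool()] the study ran on.
#' @param adapter The same [model_adapter()].
#' @param verbose Print per-size progress.
#'
#' @return An object of class `baseline_result`: `n0_percent`, `n0_found`,
#'   a data frame `p_values` (size x instance), and the shuffled
#'   `stabilized_size` objects.
#' @export
determine_n0 <- function(study, pool, adapter, verbose = FALSE) {
  stopifnot(inherits(study, "size_study"))
  config <- study$config
  n0 <- config$n0_init
  found <- FALSE
  p_rows <- list()
  shuffled_sizes <- list()
  for (i in seq_along(config$ladder)) {
    n <- config$ladder[i]
    if (n >= n0) break
    shuf <- stabilize_size(pool, n, adapter, config,
                           shuffle = TRUE, n_index = i, verbose = verbose)
    shuffled_sizes[[as.character(n)]] <- shuf
    main <- study$sizes[[i]]
    p <- vapply(seq_len(config$instances), function(j) {
      mwu_one_sided(main$values[[j]]$te, shuf$values[[j]]$te)
    }, numeric(1))
    better <- vapply(seq_len(config$instances), function(j) {
      mean(main$values[[j]]$te) > mean(shuf$values[[j]]$te)
    }, logical(1))
    p_rows[[length(p_rows) + 1L]] <-
      data.frame(n_percent = n, instance = seq_len(config$instances),
                 p_value = p, unshuffled_better = better)
    if (all(p < config$sig_level) && all(better)) {
      n0 <- n
      found <- TRUE
      break
    }
  }
  structure(
    list(n0_percent = n0, n0_found = found,
         p_values = if (length(p_rows)) do.call(rbind, p_rows) else
           data.frame(n_percent = numeric(0), instance = integer(0),
                      p_value = numeric(0), unshuffled_better = logical(0)),
         shuffled_sizes = shuffled_sizes,
         sig_level = config$sig_level),
    class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  if (x$n0_found) {
    cat(sprintf("<baseline_result> n0 = %g%% (learning starts here)\n",
                x$n0_percent))
  } else {
    cat(sprintf("<baseline_result> n0 not found (sentinel %g > 100)\n",
                x$n0_percent))
  }
  invisible(x)
}
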