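#' Specify a test statistic to stabilize
#'
#' Statistic mode replaces model fitting by a scalar statistic of the target:
#' each repetition draws a subsample, partitions it into `m` equally large
#' sub-samples (remainder rows dropped), and evaluates the statistic once per
#' sub-sample, populating one value per sampling instance. Built-ins: `mean`,
#' `median`, `sd`; any pure function of a numeric sample can be registered via
#' `fun`.
#'
#' @param statistic Name of a built-in (`"mean"`, `"median"`, `"sd"`), or an
#'   arbitrary identifier when `fun` is supplied.
#' @param fun Optional function `(numeric vector) -> scalar` overriding the
#'   built-in lookup.
#' @return An object of class `stat_spec`.
#' @export
stat_spec <- function(statistic = "mean", fun = NULL) {
  builtins <- list(mean = mean, median = stats::median, sd = stats::sd)
  if (is.null(fun)) {
    if (!statistic %in% names(builtins)) {
      abort_adaptsize(
        sprintf("unknown statistic '%s' (built-ins: %s); pass `fun` to register",
                statistic, paste(names(builtins), collapse = ", ")),
        "adaptsize_bad_spec")
    }
    fun <- builtins[[statistic]]
  }
  stopifnot(is.function(fun))
  structure(list(statistic = statistic, fun = fun), class = "stat_spec")
}

stat_round_fun <- function(pool, spec, config, d_n, n_index) {
  n_pool <- pool$sample_count
  m <- config$instances
  sub_size <- floor(d_n / m)
  k0 <- config$base_reps
  y <- pool$target
  f <- spec$fun
  function(block) {
    # one draw feeds all m instances, so the stream is per-(size, block)
    set.seed(mix_seed(config$seed, 2L, n_index, block))
    vals <- matrix(NA_real_, nrow = k0, ncol = m)
    for (i in seq_len(k0)) {
      idx <- sample.int(n_pool, d_n)
      for (j in seq_len(m)) {
        sub <- idx[((j - 1L) * sub_size + 1L):(j * sub_size)]
        vals[i, j] <- f(y[sub])
      }
    }
    lapply(seq_len(m), function(j) list(stat = vals[, j]))
  }
}

#' Stabilize a test statistic's sampling distribution at one ladder size
#'
#' The statistic-mode analogue of [stabilize_size()]: no model, no train/test
#' split. Each repetition draws `d_n` rows and partitions them into `m`
#' equally large sub-samples of size `floor(d_n / m)` (remainder rows, already
#' in random order, are dropped); the statistic evaluated on sub-sample `j`
#' extends instance `j`'s distribution. The adaptive tolerance loop —
#' repetition blocks of `k0`, the four characteristics, the inclusive
#' pairwise test, the cap — is the same shared code path.
#'
#' @param pool A [data_pool()].
#' @param n_percent Ladder percentage.
#' @param spec A [stat_spec()].
#' @param config A [study_config()].
#' @param n_index Ladder index for stream derivation (defaults to the position
#'   of `n_percent` in the ladder).
#' @param verbose Print per-round progress.
#' @return A `stabilized_size` with single split `"stat"` and field
#'   `sub_size`.
#' @export
stabilize_statistic <- function(pool, n_percent, spec, config,
                                n_index = NULL, verbose = FALSE) {
  stopifnot(inherits(pool, "data_pool"), inherits(spec, "stat_spec"),
            inherits(config, "study_config"))
  if (is.null(n_index)) {
    n_index <- match(n_percent, config$ladder)
    if (is.na(n_index)) n_index <- 0L
  }
  d_n <- subsample_size(pool$sample_count, n_percent)
  if (d_n < config$instances) {
    abort_adaptsize(
      sprintf("d_n = %d is smaller than the %d sub-samples required",
              d_n, config$instances),
      "adaptsize_bad_draw")
  }
  res <- stabilize_loop(
    stat_round_fun(pool, spec, config, d_n, n_index),
    splits = "stat", config = config,
    label = sprintf("n = %g%% (statistic %s)", n_percent, spec$statistic),
    verbose = verbose)
  structure(
    list(n_percent = n_percent, d_n = d_n,
         sub_size = floor(d_n / config$instances),
         train_size = NA_integer_, test_size = NA_integer_,
         final_k_n = res$final_k_n, converged = res$converged,
         summaries = res$summaries, values = res$values,
         worst_diff = res$worst_diff, shuffled = FALSE),
    class = "stabilized_size")
}

#' Run a statistic-mode study over the whole ladder
#'
#' @inheritParams stabilize_statistic
#' @return A `size_study` with `mode = "statistic"`.
#' @export
run_statistic_study <- function(pool, spec, config, verbose = FALSE) {
  stopifnot(inherits(pool, "data_pool"), inherits(spec, "stat_spec"),
            inherits(config, "study_config"))
  sizes <- lapply(seq_along(config$ladder), function(i) {
    stabilize_statistic(pool, config$ladder[i], spec, config,
                        n_index = i, verbose = verbose)
  })
  structure(
    list(config = config, adapter = paste0("statistic:", spec$statistic),
         pool_size = pool$sample_count, n_features = ncol(pool$features),
         sizes = sizes, mode = "statistic"),
    class = "size_study")
}

#' Per-size effect difference between two stabilized studies
#'
#' For power analysis: the difference, at each ladder size, of the stabilized
#' mean statistic (averaged over instances) between two populations — e.g.
#' treated vs untreated — with each study's stabilized quartile spread
#' carried alongside. This is the effect-strength input for a downstream
#' power calculation; computing power itself is out of scope.
#'
#' @param result_a,result_b Two statistic-mode [run_statistic_study()] results
#'   on the same ladder and configuration.
#' @return Data frame with one row per ladder size: `n_percent`, `sub_size_a`,
#'   `sub_size_b`, `mean_a`, `mean_b`, `difference`, `width_a`, `width_b`
#'   (q75 - q25, averaged over instances).
#' @export
effect_difference <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "size_study"), inherits(result_b, "size_study"))
  la <- vapply(result_a$sizes, `[[`, numeric(1), "n_percent")
  lb <- vapply(result_b$sizes, `[[`, numeric(1), "n_percent")
  if (length(la) != length(lb) || any(la != lb)) {
    abort_adaptsize("the two studies ran on different ladders",
                    "adaptsize_mismatched_ladders")
  }
  do.call(rbind, lapply(seq_along(la), function(i) {
    sa <- result_a$sizes[[i]]$summaries
    sb <- result_b$sizes[[i]]$summaries
    data.frame(
      n_percent = la[i],
      sub_size_a = result_a$sizes[[i]]$sub_size,
      sub_size_b = result_b$sizes[[i]]$sub_size,
      mean_a = mean(sa$mean), mean_b = mean(sb$mean),
      difference = mean(sa$mean) - mean(sb$mean),
      width_a = mean(sa$q75 - sa$q25), width_b = mean(sb$q75 - sb$q25))
  }))
}
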