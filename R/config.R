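#' Study configuration
#'
#' Bundles every parameter of an adaptive subsampling study: the train/test
#' split fraction, the ladder of pool percentages at which subsampled studies
#' run, the number of parallel sampling instances whose accuracy distributions
#' are compared, the base repetition count, the stabilization tolerance, and
#' the master seed from which all random streams derive.
#'
#' @param split_fraction Fraction `c` in (0, 1) of each subsample used for
#'   training; the remainder is the test set. Default 0.7.
#' @param ladder Strictly ascending percentages of the pool (each in
#'   (0, 100\]) at which studies are run. Default `seq(10, 100, by = 10)`.
#' @param instances Number `m >= 2` of parallel sampling instances per size.
#' @param base_reps Base repetition count `k0`: each instance starts with this
#'   many subsample/fit/score repetitions, and each failed stability round adds
#'   another `k0` per instance.
#' @param tolerance Maximum allowed absolute pairwise difference between
#'   corresponding distribution characteristics (mean, median, 25th, 75th
#'   percentile) of the instances. A single number applied to all four, or a
#'   named vector with entries `mean`, `median`, `q25`, `q75`.
#' @param max_reps Safety cap on the repetition count per instance; when the
#'   next increment would exceed it the size is reported unconverged (with a
#'   warning) instead of looping forever. Default `100 * base_reps`.
#' @param n0_init Initial value of the minimum learning size `n0`, a
#'   percentage > 100 so it is larger than any ladder entry ("not found").
#' @param sig_level Significance level for the one-sided Mann-Whitney U test
#'   of the shuffled-target baseline.
#' @param seed Master seed; one deterministic stream is derived per
#'   (size, instance, repetition block), so runs are reproducible and
#'   independent of execution order.
#'
#' @return An object of class `study_config`.
#' @export
#' @examples
#' cfg <- study_config(ladder = c(25, 50, 100), base_reps = 20, tolerance = 0.01)
study_config <- function(split_fraction = 0.7,
                         ladder = seq(10, 100, by = 10),
                         instances = 2L,
                         base_reps = 300L,
                         tolerance = 0.001,
                         max_reps = NULL,
                         n0_init = 101,
                         sig_level = 0.05,
                         seed = 1L) {
  if (!is_number(split_fraction) || split_fraction <= 0 || split_fraction >= 1) {
    abort_adaptsize("split_fraction must lie strictly between 0 and 1",
                    "adaptsize_bad_config")
  }
  ladder <- as.numeric(ladder)
  if (length(ladder) < 1L || anyNA(ladder) ||
      any(ladder <= 0) || any(ladder > 100) ||
      is.unsorted(ladder, strictly = TRUE)) {
    abort_adaptsize("ladder must be strictly ascending percentages in (0, 100]",
                    "adaptsize_bad_config")
  }
  if (!is_count(instances) || instances < 2) {
    abort_adaptsize("instances must be an integer >= 2", "adaptsize_bad_config")
  }
  if (!is_count(base_reps)) {
    abort_adaptsize("base_reps must be a positive integer", "adaptsize_bad_config")
  }
  chars <- c("mean", "median", "q25", "q75")
  if (length(tolerance) == 1L) {
    tolerance <- stats::setNames(rep(as.numeric(tolerance), 4L), chars)
  }
  if (!is.numeric(tolerance) || length(tolerance) != 4L ||
      !all(chars %in% names(tolerance)) || any(tolerance <= 0)) {
    abort_adaptsize(
      "tolerance must be one positive number or a named vector (mean, median, q25, q75)",
      "adaptsize_bad_config")
  }
  tolerance <- tolerance[chars]
  if (is.null(max_reps)) max_reps <- 100L * as.integer(base_reps)
  if (!is_count(max_reps) || max_reps < base_reps) {
    abort_adaptsize("max_reps must be an integer >= base_reps",
                    "adaptsize_bad_config")
  }
  if (!is_number(n0_init) || n0_init <= 100) {
    abort_adaptsize("n0_init must exceed 100 (larger than any ladder entry)",
                    "adaptsize_bad_config")
  }
  if (!is_number(sig_level) || sig_level <= 0 || sig_level >= 1) {
    abort_adaptsize("sig_level must lie strictly between 0 and 1",
                    "adaptsize_bad_config")
  }
  structure(
    list(split_fraction = split_fraction,
         ladder = ladder,
         instances = as.integer(instances),
         base_reps = as.integer(base_reps),
         tolerance = tolerance,
         max_reps = as.integer(max_reps),
         n0_init = as.numeric(n0_init),
         sig_level = sig_level,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  split c = %.3g, m = %d instances, k0 = %d (cap %d)\n",
              x$split_fraction, x$instances, x$base_reps, x$max_reps))
  cat(sprintf("  ladder: %s %%\n", paste(x$ladder, collapse = ", ")))
  cat(sprintf("  tolerance: %s\n",
              paste(sprintf("%s=%g", names(x$tolerance), x$tolerance),
                    collapse = ", ")))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

# Every ladder entry must leave at least one sample on each side of the split.
validate_config_for_pool <- function(config, pool) {
  for (n in config$ladder) {
    d_n <- subsample_size(pool$sample_count, n)
    n_tr <- floor(config$split_fraction * d_n)
    if (n_tr < 1 || d_n - n_tr < 1) {
      abort_adaptsize(
        sprintf("ladder entry %g%% gives a degenerate train/test split (d_n = %d)",
                n, d_n),
        "adaptsize_bad_config")
    }
  }
  invisible(TRUE)
}
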