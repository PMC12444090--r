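#' Construct a data pool
#'
#' A data pool is the full currently-available dataset, treated as a surrogate
#' population: subsampled studies simulate the measurement process by drawing
#' from it at random. It couples a numeric feature matrix with a numeric
#' target vector.
#'
#' @param features Numeric matrix (rows = samples, columns = features).
#' @param target Numeric vector, one entry per feature row.
#'
#' @return An object of class `data_pool` with elements `features`, `target`
#'   and `sample_count`.
#' @export
#' @examples
#' pool <- data_pool(matrix(rnorm(20), 10), rnorm(10))
#' pool$sample_count
data_pool <- function(features, target) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  target <- as.numeric(target)
  if (nrow(features) != length(target)) {
    abort_adaptsize("features and target must have the same number of samples",
                    "adaptsize_bad_pool")
  }
  if (nrow(features) < 2L) {
    abort_adaptsize("a data pool needs at least 2 samples", "adaptsize_bad_pool")
  }
  if (anyNA(features) || anyNA(target) ||
      any(!is.finite(features)) || any(!is.finite(target))) {
    abort_adaptsize("data pool must not contain missing or non-finite values",
                    "adaptsize_bad_pool")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  structure(
    list(features = features, target = target, sample_count = nrow(features)),
    class = "data_pool"
  )
}

#' @export
print.data_pool <- function(x, ...) {
  cat(sprintf("<data_pool> %d samples, %d features\n",
              x$sample_count, ncol(x$features)))
  invisible(x)
}

#' Load a data pool from a CSV file
#'
#' Reads a comma-separated file with a header row; every cell must be numeric.
#' The named column becomes the target, all remaining columns (in file order)
#' the features.
#'
#' @param path Path to a CSV file.
#' @param target_column Name of the target column.
#'
#' @return A [data_pool()].
#' @export
load_pool <- function(path, target_column) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_adaptsize(sprintf("pool file not found: %s", path),
                    "adaptsize_missing_file")
  }
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  if (!target_column %in% names(df)) {
    abort_adaptsize(sprintf("target column '%s' not present in %s",
                            target_column, path),
                    "adaptsize_missing_column")
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort_adaptsize(
      sprintf("non-numeric cell in column(s): %s", paste(bad, collapse = ", ")),
      "adaptsize_non_numeric")
  }
  if (anyNA(df)) {
    abort_adaptsize("non-numeric cell (missing value) in pool file",
                    "adaptsize_non_numeric")
  }
  target <- df[[target_column]]
  features <- as.matrix(df[setdiff(names(df), target_column)])
  data_pool(features, target)
}

#' Specify a synthetic regression pool
#'
#' Describes a linear-Gaussian pool: features are i.i.d. standard normal and
#' the target is `features %*% weight_vector` plus Gaussian noise. Under this
#' design the best achievable (asymptotic) test-set R-squared is known in
#' closed form as `sum(w^2) / (sum(w^2) + noise_sd^2)`, which makes
#' parameter-recovery checks of fitted learning-curve asymptotes possible.
#'
#' @param n_samples Number of samples to generate.
#' @param weight_vector Numeric vector of true linear coefficients; its length
#'   sets the number of features.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param seed Integer seed; the generated pool is a pure function of the spec.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, weight_vector, noise_sd = 1, seed = 1L) {
  if (!is_count(n_samples) || n_samples < 2) {
    abort_adaptsize("n_samples must be an integer >= 2", "adaptsize_bad_spec")
  }
  weight_vector <- as.numeric(weight_vector)
  if (length(weight_vector) < 1L || anyNA(weight_vector)) {
    abort_adaptsize("weight_vector must be a non-empty numeric vector",
                    "adaptsize_bad_spec")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    abort_adaptsize("noise_sd must be a nonnegative number", "adaptsize_bad_spec")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_features = length(weight_vector),
         weight_vector = weight_vector, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Asymptotic R-squared of a synthetic spec
#'
#' The test-set R-squared an ideal model approaches as the training size grows
#' without bound on a pool generated from `spec`.
#'
#' @param spec A [synthetic_spec()].
#' @return A number in \[0, 1\].
#' @export
asymptotic_r2 <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  v <- sum(spec$weight_vector^2)
  if (v == 0 && spec$noise_sd == 0) return(NaN)
  v / (v + spec$noise_sd^2)
}

#' Generate a synthetic pool
#'
#' Deterministic in the spec (including its seed): calling twice with the same
#' spec returns bit-identical pools, and the caller's RNG state is untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return A [data_pool()].
#' @export
#' @examples
#' spec <- synthetic_spec(100, weight_vector = c(1, 1), noise_sd = 0)
#' pool <- generate_pool(spec)
generate_pool <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    x <- matrix(stats::rnorm(spec$n_samples * spec$n_features),
                nrow = spec$n_samples, ncol = spec$n_features)
    y <- drop(x %*% spec$weight_vector)
    if (spec$noise_sd > 0) y <- y + stats::rnorm(spec$n_samples, sd = spec$noise_sd)
    data_pool(x, y)
  })
}

# Row-subset helper shared by the samplers. Skips full validation (already
# guaranteed by the parent pool) and allows single-row subsets: a test split
# may legitimately hold one sample even though a pool must hold two.
pool_rows <- function(pool, idx) {
  structure(
    list(features = pool$features[idx, , drop = FALSE],
         target = pool$target[idx], sample_count = length(idx)),
    class = "data_pool")
}
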