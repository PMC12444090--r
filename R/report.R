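#' Fixed-repetition comparator study
#'
#' The non-adaptive baseline: the identical subsampling pipeline, but every
#' size uses exactly `reps` repetitions per instance instead of the adaptive
#' loop. The convergence flag on each size reports — purely informationally —
#' whether the tolerances would have been met at that repetition count.
#' Because nothing controls the distribution characteristics, fitted limit
#' accuracies vary considerably more between runs than in the adaptive mode.
#'
#' @inheritParams run_study
#' @param reps Repetition count per instance (>= 2).
#' @return A `size_study` with `mode = "fixed"`.
#' @export
fixed_reps_study <- function(pool, adapter, config, reps = 50L, verbose = FALSE) {
  stopifnot(inherits(pool, "data_pool"), inherits(adapter, "model_adapter"),
            inherits(config, "study_config"))
  if (!is_count(reps) || reps < 2) {
    abort_adaptsize("reps must be an integer >= 2", "adaptsize_bad_config")
  }
  reps <- as.integer(reps)
  validate_config_for_pool(config, pool)
  k0 <- config$base_reps
  sizes <- lapply(seq_along(config$ladder), function(i) {
    n <- config$ladder[i]
    d_n <- subsample_size(pool$sample_count, n)
    n_tr <- floor(config$split_fraction * d_n)
    # same per-block streams as the adaptive loop, so reps = k0 reproduces
    # its first round bit-exactly
    n_blocks <- ceiling(reps / k0)
    values <- lapply(seq_len(config$instances), function(j) {
      tr <- numeric(0)
      te <- numeric(0)
      for (b in seq_len(n_blocks)) {
        nb <- min(k0, reps - (b - 1L) * k0)
        blk <- model_block(pool, adapter, config, d_n, i, FALSE, j, b, nb)
        tr <- c(tr, blk$tr)
        te <- c(te, blk$te)
      }
      list(tr = tr, te = te)
    })
    summaries <- do.call(rbind, lapply(seq_len(config$instances), function(j) {
      do.call(rbind, lapply(c("tr", "te"), function(s) {
        cbind(data.frame(instance = j, split = s),
              summarize_dist(values[[j]][[s]]))
      }))
    }))
    would_pass <- all(vapply(c("tr", "te"), function(s) {
      as.logical(characteristics_similar(
        summaries[summaries$split == s, ], config$tolerance))
    }, logical(1)))
    if (verbose) message(sprintf("n = %g%%: fixed k_n = %d", n, reps))
    structure(
      list(n_percent = n, d_n = d_n, train_size = n_tr, test_size = d_n - n_tr,
           final_k_n = reps, converged = would_pass, summaries = summaries,
           values = values, worst_diff = NA_real_, shuffled = FALSE),
      class = "stabilized_size")
  })
  structure(
    list(config = config, adapter = adapter$name,
         pool_size = pool$sample_count, n_features = ncol(pool$features),
         sizes = sizes, mode = "fixed", reps = reps),
    class = "size_study")
}

#' Tidy table of all recorded accuracies
#'
#' One row per (size, instance, repetition, split) with the recorded accuracy
#' (or statistic value), plus a `shuffled` flag for baseline distributions.
#'
#' @param study A `size_study`.
#' @param baseline Optional [determine_n0()] result whose shuffled
#'   distributions are appended.
#' @return A data frame with columns `n_percent`, `instance`, `repetition`,
#'   `split`, `accuracy`, `shuffled`.
#' @export
accuracy_table <- function(study, baseline = NULL) {
  stopifnot(inherits(study, "size_study"))
  one_size <- function(s, shuffled) {
    do.call(rbind, lapply(seq_along(s$values), function(j) {
      do.call(rbind, lapply(names(s$values[[j]]), function(sp) {
        v <- s$values[[j]][[sp]]
        data.frame(n_percent = s$n_percent, instance = j,
                   repetition = seq_along(v), split = sp, accuracy = v,
                   shuffled = shuffled)
      }))
    }))
  }
  out <- do.call(rbind, lapply(study$sizes, one_size, shuffled = FALSE))
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "baseline_result"))
    out <- rbind(out, do.call(rbind, lapply(baseline$shuffled_sizes,
                                            one_size, shuffled = TRUE)))
  }
  rownames(out) <- NULL
  out
}

#' Write the tidy accuracy CSV
#'
#' @inheritParams accuracy_table
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(study, path, baseline = NULL) {
  utils::write.csv(accuracy_table(study, baseline), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce the run bit-exactly given the same
#' pool: the full configuration (master seed included), the mode, per-size
#' repetition counts and convergence flags, the baseline result and fitted
#' curve coefficients when available, and the package version.
#'
#' @param study A `size_study`.
#' @param path Output file path.
#' @param baseline Optional [determine_n0()] result.
#' @param curves Optional [fit_learning_curves()] result.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(study, path, baseline = NULL, curves = NULL) {
  stopifnot(inherits(study, "size_study"))
  cfg <- study$config
  manifest <- list(
    tool = "adaptsize",
    version = as.character(utils::packageVersion("adaptsize")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    mode = study$mode,
    adapter = study$adapter,
    pool = list(sample_count = study$pool_size, n_features = study$n_features),
    config = list(
      split_fraction = cfg$split_fraction, ladder = cfg$ladder,
      instances = cfg$instances, base_reps = cfg$base_reps,
      tolerance = as.list(cfg$tolerance), max_reps = cfg$max_reps,
      n0_init = cfg$n0_init, sig_level = cfg$sig_level, seed = cfg$seed),
    sizes = lapply(study$sizes, function(s) {
      list(n_percent = s$n_percent, d_n = s$d_n, train_size = s$train_size,
           test_size = s$test_size, k_n = s$final_k_n, converged = s$converged)
    })
  )
  if (identical(study$mode, "fixed")) manifest$reps <- study$reps
  if (!is.null(baseline)) {
    manifest$baseline <- list(n0_percent = baseline$n0_percent,
                              n0_found = baseline$n0_found,
                              sig_level = baseline$sig_level,
                              p_values = baseline$p_values)
  }
  if (!is.null(curves)) manifest$curves <- curves$table
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Re-run a study from a manifest
#'
#' Rebuilds the configuration echoed in a manifest and re-executes the study
#' on the given pool; with the same pool this reproduces the original
#' accuracy table bit-exactly.
#'
#' @param path Path to a manifest written by [write_manifest()].
#' @param pool The [data_pool()] the original run used.
#' @param adapter A [model_adapter()] matching the manifest's adapter.
#' @return A `size_study`.
#' @export
run_from_manifest <- function(path, pool, adapter) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  config <- study_config(
    split_fraction = cfg$split_fraction, ladder = cfg$ladder,
    instances = cfg$instances, base_reps = cfg$base_reps,
    tolerance = unlist(cfg$tolerance), max_reps = cfg$max_reps,
    n0_init = cfg$n0_init, sig_level = cfg$sig_level, seed = cfg$seed)
  if (identical(m$mode, "fixed")) {
    fixed_reps_study(pool, adapter, config, reps = m$reps)
  } else {
    run_study(pool, adapter, config)
  }
}

#' Plot stabilized characteristics and fitted learning curves
#'
#' Optional diagnostic figure: the per-size characteristic values (points) and
#' the fitted power-law curves (lines), one panel per split, coloured by
#' characteristic. Requires ggplot2.
#'
#' @param study A `size_study`.
#' @param curves A [fit_learning_curves()] result for it.
#' @param instance Instance to display.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(study, curves, instance = 1L) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_adaptsize("plot_learning_curves requires ggplot2",
                    "adaptsize_missing_suggest")
  }
  splits <- if (identical(study$mode, "statistic")) "stat" else c("tr", "te")
  chars <- c("mean", "median", "q25", "q75")
  pts <- do.call(rbind, lapply(splits, function(s) {
    do.call(rbind, lapply(chars, function(ch) {
      p <- build_curve_points(study, split = s, characteristic = ch,
                              instance = instance)
      cbind(p, split = s, characteristic = ch)
    }))
  }))
  lines <- do.call(rbind, lapply(splits, function(s) {
    do.call(rbind, lapply(chars, function(ch) {
      fit <- curves$fits[[paste(s, ch, instance, sep = ".")]]
      if (is.null(fit) || !fit$converged) return(NULL)
      d <- seq(fit$x_range[1], fit$x_range[2], length.out = 200)
      data.frame(sample_count = d,
                 value = as.numeric(predict_accuracy(fit, d)),
                 split = s, characteristic = ch)
    }))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = sample_count, y = value,
                                    colour = characteristic)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lines) +
    ggplot2::facet_wrap(~split, scales = "free") +
    ggplot2::labs(x = "samples", y = "accuracy",
                  title = sprintf("learning curves (instance %d)", instance))
}
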