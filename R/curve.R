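#' Build learning-curve points from a study
#'
#' Extracts one (sample count, characteristic value) point per stabilized
#' ladder size for one split, one characteristic and one sampling instance.
#' The abscissa is the training-set size for the training split, the test-set
#' size for the test split, and the sub-sample size in statistic mode.
#'
#' @param study A [run_study()] (or statistic-mode) result.
#' @param split `"tr"`, `"te"` or `"stat"`.
#' @param characteristic `"mean"`, `"median"`, `"q25"` or `"q75"`.
#' @param instance Instance index `j`.
#' @param n0 Optional minimum learning size (a ladder percentage) used to
#'   exclude pre-learning points.
#' @param n0_rule How to apply `n0`: `"below"` (default) drops ladder sizes
#'   below `n0`, where learning has not started; `"at_and_above"` drops sizes
#'   `>= n0` (the literal reading of the exclusion clause; it discards the
#'   informative points and is provided for comparison only).
#' @param first_points If given, keep only the first `first_points` ladder
#'   entries (hold-out curve validation: fit on the early points, judge the
#'   prediction on the rest).
#'
#' @return A data frame with columns `sample_count`, `value`, `n_percent`.
#' @export
build_curve_points <- function(study, split = c("te", "tr", "stat"),
                               characteristic = c("mean", "median", "q25", "q75"),
                               instance = 1L, n0 = NULL,
                               n0_rule = c("below", "at_and_above"),
                               first_points = NULL) {
  split <- match.arg(split)
  characteristic <- match.arg(characteristic)
  n0_rule <- match.arg(n0_rule)
  stopifnot(inherits(study, "size_study"))
  sizes <- study$sizes
  if (!is.null(first_points)) {
    stopifnot(is_count(first_points))
    sizes <- sizes[seq_len(min(first_points, length(sizes)))]
  }
  if (!is.null(n0)) {
    keep <- if (n0_rule == "below") {
      vapply(sizes, function(s) s$n_percent >= n0, logical(1))
    } else {
      vapply(sizes, function(s) s$n_percent < n0, logical(1))
    }
    sizes <- sizes[keep]
  }
  pts <- do.call(rbind, lapply(sizes, function(s) {
    xs <- switch(split, tr = s$train_size, te = s$test_size, stat = s$sub_size)
    row <- s$summaries[s$summaries$instance == instance &
                         s$summaries$split == split, ]
    if (nrow(row) != 1L) {
      abort_adaptsize(
        sprintf("no '%s' summaries for instance %d at n = %g%%",
                split, instance, s$n_percent),
        "adaptsize_bad_curve")
    }
    data.frame(sample_count = xs, value = row[[characteristic]],
               n_percent = s$n_percent)
  }))
  if (is.null(pts) || nrow(pts) < 3L) {
    abort_adaptsize(
      "under-determined fit: need at least 3 curve points after exclusion",
      "adaptsize_underdetermined")
  }
  pts
}

#' Fit a three-parameter power law to learning-curve points
#'
#' Fits `f(d) = alpha * d^beta + gamma` by unweighted least squares (all
#' residuals weighted equally, since every point is stabilized to the same
#' tolerance). Uses Levenberg-Marquardt ([minpack.lm::nlsLM()]) from multiple
#' starts: `gamma` starts at the last observed value, `alpha` at the
#' first-minus-last difference, and `beta` at -0.25, -0.5 and -1; the start
#' with the lowest residual sum of squares wins. `beta`'s sign is not
#' constrained, so both saturating and rising curves are representable.
#' `gamma` is the accuracy limit approached as `d` grows without bound
#' (when `beta < 0`).
#'
#' @param points Data frame with columns `sample_count` and `value` (at least
#'   3 distinct sample counts).
#' @param split,characteristic,instance Optional labels carried on the fit.
#' @return An object of class `power_law_fit` with elements `alpha`, `beta`,
#'   `gamma`, `rss`, `converged`, `degenerate`, `x_range` and the labels.
#' @export
#' @examples
#' d <- c(10, 20, 40, 80, 160, 320)
#' fit <- fit_power_law(data.frame(sample_count = d,
#'                                 value = 0.3 * d^-0.5 + 0.5))
#' unlist(fit[c("alpha", "beta", "gamma")])
fit_power_law <- function(points, split = NA_character_,
                          characteristic = NA_character_, instance = NA_integer_) {
  x <- as.numeric(points$sample_count)
  y <- as.numeric(points$value)
  if (length(x) < 3L || length(unique(x)) < 3L) {
    abort_adaptsize(
      "under-determined fit: need at least 3 points with 3 distinct sample counts",
      "adaptsize_underdetermined")
  }
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  mk <- function(alpha, beta, gamma, rss, converged, degenerate = FALSE) {
    structure(
      list(alpha = alpha, beta = beta, gamma = gamma, rss = rss,
           converged = converged, degenerate = degenerate,
           x_range = range(x), split = split,
           characteristic = characteristic, instance = instance,
           n_points = length(x)),
      class = "power_law_fit")
  }
  if (stats::var(y) == 0) {
    # constant data: gamma carries the level, the transient is unidentifiable
    return(mk(alpha = 0, beta = NA_real_, gamma = y[1], rss = 0,
              converged = TRUE, degenerate = TRUE))
  }
  a0 <- y[1] - y[length(y)]
  if (a0 == 0) a0 <- stats::sd(y)
  best <- NULL
  df <- data.frame(x = x, y = y)
  for (b0 in c(-0.25, -0.5, -1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ alpha * x^beta + gamma,
        data = df,
        start = list(alpha = a0, beta = b0, gamma = y[length(y)]),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      co <- stats::coef(fit)
      best <- list(alpha = co[["alpha"]], beta = co[["beta"]],
                   gamma = co[["gamma"]], rss = rss)
    }
  }
  if (is.null(best)) {
    return(mk(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
              rss = NA_real_, converged = FALSE))
  }
  mk(best$alpha, best$beta, best$gamma, best$rss, converged = TRUE)
}

#' @export
print.power_law_fit <- function(x, ...) {
  lab <- if (!is.na(x$split)) {
    sprintf(" [%s/%s j=%s]", x$split, x$characteristic, x$instance)
  } else ""
  if (!x$converged) {
    cat(sprintf("<power_law_fit>%s NOT converged\n", lab))
  } else if (x$degenerate) {
    cat(sprintf("<power_law_fit>%s constant: gamma = %.6g (beta unidentifiable)\n",
                lab, x$gamma))
  } else {
    cat(sprintf("<power_law_fit>%s f(d) = %.6g * d^%.6g + %.6g (rss %.3g)\n",
                lab, x$alpha, x$beta, x$gamma, x$rss))
  }
  invisible(x)
}

#' Predict accuracy at a sample size
#'
#' Evaluates `alpha * d^beta + gamma`. Values of `d` beyond the largest fitted
#' sample count are extrapolations; the result then carries attribute
#' `extrapolated = TRUE`.
#'
#' @param fit A converged [fit_power_law()] result.
#' @param d Positive sample size(s).
#' @return Predicted accuracy values.
#' @export
predict_accuracy <- function(fit, d) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!fit$converged) {
    abort_adaptsize("cannot predict from an unconverged fit",
                    "adaptsize_bad_fit")
  }
  if (any(d <= 0)) {
    abort_adaptsize("sample size must be positive", "adaptsize_bad_input")
  }
  out <- if (fit$degenerate) rep(fit$gamma, length(d))
         else fit$alpha * d^fit$beta + fit$gamma
  structure(out, extrapolated = any(d > fit$x_range[2]))
}

#' Invert a learning curve for a target accuracy
#'
#' Solves `alpha * d^beta + gamma = target` for the sample size `d`:
#' `d = ((target - gamma)/alpha)^(1/beta)`. Targets on the far side of the
#' asymptote `gamma` (or exactly on it) can never be reached by the fitted
#' curve, in which case `"unreachable"` is returned.
#'
#' @param fit A converged, non-degenerate [fit_power_law()] result with
#'   `alpha != 0`.
#' @param target_value Desired accuracy.
#' @return The required sample size (a positive real), or the character string
#'   `"unreachable"`.
#' @export
#' @examples
#' fit <- structure(list(alpha = -0.3, beta = -0.5, gamma = 0.5, converged = TRUE,
#'                       degenerate = FALSE, x_range = c(10, 320)),
#'                  class = "power_law_fit")
#' required_sample_size(fit, 0.49)  # 900
required_sample_size <- function(fit, target_value) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!fit$converged || fit$degenerate || is.na(fit$alpha) || fit$alpha == 0 ||
      is.na(fit$beta) || fit$beta == 0) {
    abort_adaptsize("cannot invert a degenerate or unconverged fit",
                    "adaptsize_bad_fit")
  }
  ratio <- (target_value - fit$gamma) / fit$alpha
  if (ratio <= 0) return("unreachable")
  ratio^(1 / fit$beta)
}

#' Predicted uncertainty width at a sample size
#'
#' The spread of the accuracy distribution predicted at size `d`: the fitted
#' 75th-percentile curve minus the fitted 25th-percentile curve. A negative
#' width means the curves have crossed and the fits are outside their region
#' of validity (see [percentile_crossing_check()]).
#'
#' @param fit_q25,fit_q75 Converged fits of the `q25` and `q75`
#'   characteristics for the same split and instance.
#' @param d Positive sample size(s).
#' @return Numeric width(s), possibly negative.
#' @export
uncertainty_width <- function(fit_q25, fit_q75, d) {
  stopifnot(inherits(fit_q25, "power_law_fit"), inherits(fit_q75, "power_law_fit"))
  same <- function(a, b) (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  if (!same(fit_q25$split, fit_q75$split) ||
      !same(fit_q25$instance, fit_q75$instance)) {
    abort_adaptsize("q25/q75 fits belong to different splits or instances",
                    "adaptsize_mismatched_fits")
  }
  as.numeric(predict_accuracy(fit_q75, d)) - as.numeric(predict_accuracy(fit_q25, d))
}

#' Locate the crossing of the quartile curves
#'
#' Sanity check for extrapolations: finds the smallest sample size, between
#' the smallest fitted size and `d_max_search`, at which the fitted
#' 25th-percentile curve meets or exceeds the 75th-percentile curve. Beyond
#' that point the fitted curves are no longer reliable. If the curves are
#' already crossed at the start of the search range, the start is reported;
#' if they never cross in range, `NULL` is returned.
#'
#' @inheritParams uncertainty_width
#' @param d_max_search Upper end of the search range.
#' @return The crossing sample size, or `NULL` if no crossing occurs in range.
#' @export
percentile_crossing_check <- function(fit_q25, fit_q75, d_max_search) {
  stopifnot(is_number(d_max_search), d_max_search > 0)
  d_min <- max(1, min(fit_q25$x_range[1], fit_q75$x_range[1]))
  if (d_max_search <= d_min) {
    abort_adaptsize("d_max_search must exceed the smallest fitted sample size",
                    "adaptsize_bad_input")
  }
  w <- function(d) uncertainty_width(fit_q25, fit_q75, d)
  if (w(d_min) <= 0) return(d_min)
  # bracket a sign change on a log-spaced grid, then bisect
  grid <- exp(seq(log(d_min), log(d_max_search), length.out = 512))
  ws <- vapply(grid, w, numeric(1))
  cross <- which(ws <= 0)
  if (length(cross) == 0L) return(NULL)
  hi <- grid[cross[1]]
  lo <- grid[cross[1] - 1L]
  stats::uniroot(w, lower = lo, upper = hi, tol = 1e-9)$root
}

#' Fit learning curves for every split, characteristic and instance
#'
#' Convenience wrapper running [build_curve_points()] and [fit_power_law()]
#' over the full grid, returning the fits plus a tidy coefficient table.
#'
#' @inheritParams build_curve_points
#' @param study A [run_study()] result.
#' @return An object of class `curve_set`: list of `power_law_fit`s (named
#'   `split.characteristic.instance`) and a data frame `table` of
#'   coefficients.
#' @export
fit_learning_curves <- function(study, n0 = NULL,
                                n0_rule = c("below", "at_and_above"),
                                first_points = NULL) {
  n0_rule <- match.arg(n0_rule)
  stopifnot(inherits(study, "size_study"))
  splits <- if (identical(study$mode, "statistic")) "stat" else c("tr", "te")
  chars <- c("mean", "median", "q25", "q75")
  fits <- list()
  rows <- list()
  for (s in splits) {
    for (ch in chars) {
      for (j in seq_len(study$config$instances)) {
        pts <- build_curve_points(study, split = s, characteristic = ch,
                                  instance = j, n0 = n0, n0_rule = n0_rule,
                                  first_points = first_points)
        fit <- fit_power_law(pts, split = s, characteristic = ch, instance = j)
        key <- paste(s, ch, j, sep = ".")
        fits[[key]] <- fit
        rows[[key]] <- data.frame(
          split = s, characteristic = ch, instance = j,
          alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
          rss = fit$rss, converged = fit$converged, degenerate = fit$degenerate)
      }
    }
  }
  structure(list(fits = fits, table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 n0 = n0, n0_rule = n0_rule, first_points = first_points),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> %d fitted curves\n", length(x$fits)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Summarize limit accuracies across instances
#'
#' Mean and standard deviation of the fitted asymptote `gamma` over sampling
#' instances (and over multiple curve sets, e.g. repeated study runs), per
#' split and characteristic — the reporting convention for limit-accuracy
#' tables.
#'
#' @param ... One or more `curve_set` objects.
#' @return Data frame with columns `split`, `characteristic`, `gamma_mean`,
#'   `gamma_sd`, `n_fits`.
#' @export
limit_accuracy_table <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "curve_set")))
  tab <- do.call(rbind, lapply(sets, `[[`, "table"))
  out <- do.call(rbind, lapply(split(tab, tab[c("split", "characteristic")],
                                     drop = TRUE), function(g) {
    data.frame(split = g$split[1], characteristic = g$characteristic[1],
               gamma_mean = mean(g$gamma), gamma_sd = stats::sd(g$gamma),
               n_fits = nrow(g))
  }))
  rownames(out) <- NULL
  out
}
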