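test_that("subsample_size rounds half up and floors at 2", {
  expect_equal(subsample_size(100, 10), 10L)
  expect_equal(subsample_size(442, 100), 442L)
  expect_equal(subsample_size(442, 2.5), 11L)  # 11.05 rounds down
  expect_equal(subsample_size(100, 2.5), 3L)   # 2.5 rounds half up
  expect_equal(subsample_size(100, 0.1), 2L)   # floor at 2
})

test_that("draw_subsample is uniform, exhaustive at 100% and stream-deterministic", {
  pool <- tiny_pool(10)
  set.seed(5)
  full <- draw_subsample(pool, 10)
  expect_equal(sort(full$target), sort(pool$target))
  set.seed(8); a <- draw_subsample(pool, 4)
  set.seed(8); b <- draw_subsample(pool, 4)
  expect_identical(a, b)
  expect_error(draw_subsample(pool, 11), class = "adaptsize_bad_draw")
  expect_error(draw_subsample(pool, 1), class = "adaptsize_bad_draw")
  # binomial frequency check: each row lands in the first drawn slot ~1/10
  # of the time
  set.seed(21)
  first <- replicate(10000, draw_subsample(pool, 2)$target[1])
  counts <- vapply(pool$target, function(t) sum(first == t), numeric(1))
  se <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(counts - 1000) < 3 * se))
})

test_that("split_train_test partitions with floor(c * d_n) training rows", {
  pool <- tiny_pool(100)
  set.seed(2)
  sub <- draw_subsample(pool, 100)
  parts <- split_train_test(sub, 0.7)
  expect_equal(parts$train$sample_count, 70L)
  expect_equal(parts$test$sample_count, 30L)
  both <- rbind(parts$train$features, parts$test$features)
  expect_equal(both[order(both[, 1]), ],
               sub$features[order(sub$features[, 1]), ])
  sub3 <- draw_subsample(pool, 3)
  parts3 <- split_train_test(sub3, 0.7)
  expect_equal(parts3$train$sample_count, 2L)
  expect_equal(parts3$test$sample_count, 1L)
  expect_error(split_train_test(sub3, 0.1), class = "adaptsize_degenerate_split")
})

test_that("summarize_dist matches the linear-interpolation percentile convention", {
  s <- summarize_dist(c(1, 1, 1, 1))
  expect_equal(unlist(s[c("mean", "median", "q25", "q75")]),
               c(mean = 1, median = 1, q25 = 1, q75 = 1))
  s2 <- summarize_dist(c(1, 2, 3, 4))
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$median, 2.5)
  expect_equal(s2$q25, 1.75)
  expect_equal(s2$q75, 3.25)
  expect_error(summarize_dist(numeric(0)), class = "adaptsize_empty_distribution")
  # order-statistic monotonicity on random inputs
  set.seed(4)
  for (i in 1:20) {
    s3 <- summarize_dist(rnorm(sample(1:50, 1)))
    expect_true(s3$q25 <= s3$median && s3$median <= s3$q75)
  }
})

test_that("characteristics_similar tests every pair and every characteristic", {
  base <- summarize_dist(c(0.1, 0.2, 0.3, 0.4))
  expect_true(as.logical(characteristics_similar(rbind(base, base), 1e-9)))
  off <- base; off$q75 <- off$q75 + 0.002
  expect_false(as.logical(characteristics_similar(rbind(base, off), 0.001)))
  # the comparison is inclusive: a difference exactly at tolerance passes
  # (0.25 is exactly representable, so the boundary is genuinely hit)
  off2 <- base; off2$q75 <- off2$q75 + 0.25
  expect_true(as.logical(characteristics_similar(rbind(base, off2), 0.25)))
  # only the (1,3) pair exceeds tolerance
  mid <- base; mid$mean <- mid$mean + 0.0006
  far <- base; far$mean <- far$mean + 0.0012
  expect_false(as.logical(characteristics_similar(rbind(base, mid, far), 0.001)))
  expect_true(as.logical(characteristics_similar(rbind(base, mid), 0.001)))
  expect_true(as.logical(characteristics_similar(rbind(mid, far), 0.001)))
})

test_that("a constant-accuracy adapter converges in one round with k_n = k0", {
  pool <- tiny_pool(60)
  cfg <- study_config(ladder = c(50, 100), base_reps = 25, tolerance = 1e-6,
                      seed = 2)
  s <- stabilize_size(pool, 50, fixed_score_adapter(0.5), cfg)
  expect_true(s$converged)
  expect_equal(s$final_k_n, 25L)
  expect_true(all(unlist(s$values) == 0.5))
})

test_that("an unstabilizable stream stops unconverged at the cap", {
  pool <- tiny_pool(60)
  cfg <- study_config(ladder = 100, base_reps = 10, tolerance = 1e-9,
                      max_reps = 30, seed = 3)
  expect_warning(
    s <- stabilize_size(pool, 100, uniform_score_adapter(), cfg),
    "cap")
  expect_false(s$converged)
  expect_equal(s$final_k_n, 30L)
})

test_that("decreasing the tolerance never decreases k_n on the same stream", {
  pool <- tiny_pool(80)
  ks <- vapply(c(0.025, 0.01, 0.001), function(tol) {
    cfg <- study_config(ladder = 100, base_reps = 10, tolerance = tol,
                        max_reps = 5000, seed = 17)
    suppressWarnings(
      stabilize_size(pool, 100, uniform_score_adapter(), cfg)$final_k_n)
  }, numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_gt(ks[3], ks[1])  # uniform(0,1) scores cannot meet 0.001 at k = 10
})

test_that("the store is append-only: early repetitions are preserved as k_n grows", {
  pool <- tiny_pool(80)
  cfg_loose <- study_config(ladder = 100, base_reps = 10, tolerance = 0.5,
                            seed = 17)
  cfg_tight <- study_config(ladder = 100, base_reps = 10, tolerance = 0.005,
                            max_reps = 5000, seed = 17)
  a <- stabilize_size(pool, 100, uniform_score_adapter(), cfg_loose)
  b <- suppressWarnings(
    stabilize_size(pool, 100, uniform_score_adapter(), cfg_tight))
  expect_gt(b$final_k_n, a$final_k_n)
  for (j in 1:2) {
    expect_identical(b$values[[j]]$te[seq_len(a$final_k_n)], a$values[[j]]$te)
  }
})

test_that("run_study is bit-reproducible from the master seed", {
  pool <- tiny_pool(80)
  cfg <- study_config(ladder = c(50, 100), base_reps = 20, tolerance = 0.02,
                      seed = 31)
  a <- run_study(pool, ols_adapter(), cfg)
  b <- run_study(pool, ols_adapter(), cfg)
  expect_identical(accuracy_table(a), accuracy_table(b))
  expect_equal(vapply(a$sizes, `[[`, numeric(1), "n_percent"), c(50, 100))
  expect_equal(vapply(a$sizes, `[[`, numeric(1), "d_n"),
               c(subsample_size(80, 50), subsample_size(80, 100)))
  for (s in a$sizes) expect_equal(s$train_size + s$test_size, s$d_n)
})

test_that("compiled block kernels agree with the pure-R adapter path", {
  pool <- generate_pool(synthetic_spec(120, weight_vector = c(1, -1, 0.5),
                                       noise_sd = 1, seed = 5))
  cfg <- study_config(ladder = c(60, 100), base_reps = 15, tolerance = 0.5,
                      seed = 23)
  for (mk in list(function() ols_adapter(), function() knn_adapter(7L))) {
    fast <- mk()
    slow <- mk()
    slow$block_eval <- NULL
    a <- run_study(pool, fast, cfg)
    b <- run_study(pool, slow, cfg)
    expect_equal(accuracy_table(a)$accuracy, accuracy_table(b)$accuracy,
                 tolerance = 1e-10)
  }
})

test_that("1-nearest-neighbor reproduces stored targets when test equals train", {
  x <- matrix(seq(0, 2, length.out = 11), ncol = 1)
  pool <- data_pool(x, drop(2 * x))
  ad <- knn_adapter(1L)
  acc <- evaluate_once(ad, pool, pool)
  expect_equal(acc$acc_tr, 1.0)
  expect_equal(acc$acc_te, 1.0)
})

test_that("a constant-prediction model scores non-positive test R2", {
  pool <- tiny_pool(50)
  const <- model_adapter("const", fit = function(x, y) mean(y),
                         predict = function(m, x) rep(m, nrow(x)))
  set.seed(9)
  parts <- split_train_test(draw_subsample(pool, 40), 0.7)
  acc <- evaluate_once(const, parts$train, parts$test)
  expect_lte(acc$acc_te, 0)
})

test_that("adapter failures carry sampling context", {
  pool <- tiny_pool(50)
  bad <- model_adapter("boom", fit = function(x, y) stop("singular"),
                       predict = function(m, x) rep(0, nrow(x)))
  cfg <- study_config(ladder = 100, base_reps = 5, tolerance = 0.5, seed = 1)
  expect_error(stabilize_size(pool, 100, bad, cfg),
               class = "adaptsize_adapter_error")
})
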