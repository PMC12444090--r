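test_that("fixed-repetition mode uses exactly the requested repetitions", {
  pool <- tiny_pool(80)
  cfg <- study_config(ladder = c(50, 100), base_reps = 30, tolerance = 0.02,
                      seed = 12)
  st <- fixed_reps_study(pool, ols_adapter(), cfg, reps = 50)
  expect_true(all(vapply(st$sizes, `[[`, numeric(1), "final_k_n") == 50))
  tab <- accuracy_table(st)
  expect_equal(max(tab$repetition), 50L)
  expect_error(fixed_reps_study(pool, ols_adapter(), cfg, reps = 1),
               class = "adaptsize_bad_config")
})

test_that("fixed mode with reps = k0 reproduces the adaptive first round", {
  pool <- tiny_pool(80)
  cfg <- study_config(ladder = c(50, 100), base_reps = 25, tolerance = 1e-6,
                      seed = 13)
  adaptive <- run_study(pool, fixed_score_adapter(0.5), cfg)
  fixed <- fixed_reps_study(pool, fixed_score_adapter(0.5), cfg, reps = 25)
  expect_equal(accuracy_table(adaptive), accuracy_table(fixed))
})

test_that("the manifest round trip reproduces the tidy CSV bit-exactly", {
  pool <- tiny_pool(80)
  cfg <- study_config(ladder = c(25, 50, 100), base_reps = 20, tolerance = 0.05,
                      seed = 77)
  st <- run_study(pool, ols_adapter(), cfg)
  curves <- fit_learning_curves(st)
  manifest <- tempfile(fileext = ".json")
  csv1 <- tempfile(fileext = ".csv")
  write_manifest(st, manifest, curves = curves)
  write_accuracy_csv(st, csv1)
  st2 <- run_from_manifest(manifest, pool, ols_adapter())
  csv2 <- tempfile(fileext = ".csv")
  write_accuracy_csv(st2, csv2)
  expect_identical(readLines(csv1), readLines(csv2))
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(m$config$seed, 77)
  expect_equal(nrow(m$curves), 16L)  # 2 splits x 4 characteristics x 2 instances
})

test_that("adaptive stabilization at a tight tolerance beats 50 fixed repetitions", {
  # run-to-run spread of the fitted limit accuracy: the comparator with 50
  # repetitions per size varies more across seeds than the adaptive mode at
  # tolerance 0.001 on the same synthetic pool
  pool <- generate_pool(synthetic_spec(500, weight_vector = 1, noise_sd = 1,
                                       seed = 900))
  gamma_of <- function(study) {
    fit_learning_curves(study)$table
  }
  seeds <- c(1, 2, 3)
  g_adaptive <- numeric(0)
  g_fixed <- numeric(0)
  for (s in seeds) {
    cfg <- study_config(ladder = seq(20, 100, by = 20), base_reps = 100,
                        tolerance = 0.001, max_reps = 1000000L, seed = s)
    tab_a <- gamma_of(run_study(pool, ols_adapter(), cfg))
    g_adaptive <- c(g_adaptive,
                    tab_a$gamma[tab_a$split == "te" &
                                  tab_a$characteristic == "mean"])
    tab_f <- gamma_of(fixed_reps_study(pool, ols_adapter(), cfg, reps = 50))
    g_fixed <- c(g_fixed,
                 tab_f$gamma[tab_f$split == "te" &
                               tab_f$characteristic == "mean"])
  }
  expect_gt(stats::sd(g_fixed), stats::sd(g_adaptive))
})

test_that("the CLI smoke-runs a synthetic study end to end", {
  cli <- system.file("cli", "adaptsize.R", package = "adaptsize")
  expect_true(nzchar(cli))
  config <- tempfile(fileext = ".yaml")
  prefix <- file.path(tempdir(), "cli_smoke")
  writeLines(c(
    "synthetic:",
    "  n_samples: 120",
    "  weights: [1.0]",
    "  noise_sd: 1.0",
    "  seed: 5",
    "ladder: [50, 75, 100]",
    "base_reps: 20",
    "tolerance: 0.05",
    "seed: 9",
    sprintf("out_prefix: %s", prefix)), config)
  out <- system2("Rscript", c(cli, "fit", "--config", config),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  expect_true(file.exists(paste0(prefix, "_accuracies.csv")))
  expect_true(file.exists(paste0(prefix, "_manifest.json")))
  # missing target column: nonzero exit naming the column
  bad <- tempfile(fileext = ".yaml")
  pool_csv <- write_pool_csv(data.frame(x = 1:10, y = rnorm(10)))
  writeLines(c(sprintf("pool: %s", pool_csv), "target_column: zz"), bad)
  out2 <- suppressWarnings(system2("Rscript", c(cli, "fit", "--config", bad),
                                   stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(out2, "status")))
  expect_true(any(grepl("zz", out2)))
})
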