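small_study_cfg <- function(seed = 1)
  study_config(sim = tiny_sim(n_replicates = 2, checkpoints = c(0L, 6L, 12L),
                              seed = seed, n_loci = 80),
               subsample_n = 15, k_fit = 3, k_range = 1:4, cv_folds = 3,
               cv_replicates = 2, cv_generations = c(0L, 12L),
               n_restarts = 1, hatchery_pop = "z")

test_that("a small study produces every report component", {
  st <- run_study(small_study_cfg(), progress = FALSE)
  expect_named(st$mean_q, c("0", "6", "12"))
  expect_equal(dim(st$mean_q[["12"]]), c(3, 3))
  expect_equal(unname(rowSums(st$mean_q[["0"]])), rep(1, 3), tolerance = 1e-6)
  expect_equal(sort(unname(st$cluster_of)), 1:3)
  # wild populations only (hatchery analog excluded), all checkpoints
  expect_equal(nrow(st$distinct_data), 2 * 3)
  expect_equal(nrow(st$hatchery_data), 2 * 3)
  expect_equal(nrow(st$distinct_models$table), 5)
  expect_equal(nrow(st$hatchery_models$table), 5)
  expect_s3_class(st$trajectories, "data.frame")
  expect_equal(st$cv$best_k$generation, c(0L, 12L))
})

test_that("the study is deterministic under a fixed master seed", {
  s1 <- run_study(small_study_cfg(seed = 9), progress = FALSE)
  s2 <- run_study(small_study_cfg(seed = 9), progress = FALSE)
  expect_identical(s1$mean_q, s2$mean_q)
  expect_identical(s1$distinct_models$table, s2$distinct_models$table)
  expect_identical(s1$cv$curves, s2$cv$curves)
})

test_that("trajectory summaries aggregate correctly and flag single replicates", {
  cfg1 <- tiny_sim(n_replicates = 1, checkpoints = c(0L, 5L), seed = 3)
  ts1 <- trajectory_summaries(cfg1, n_per_pop = 10)
  expect_true(all(is.na(ts1$summary$sd_theta)))

  cfg2 <- tiny_sim(n_replicates = 3, checkpoints = c(0L, 5L), seed = 3)
  ts2 <- trajectory_summaries(cfg2, n_per_pop = 10)
  expect_false(any(is.na(ts2$summary$sd_theta)))
  expect_lt(abs(ts2$summary$mean_theta[1]), 0.03)
  expect_lt(abs(ts2$summary$mean_hs[1] - 0.5), 0.03)
})

test_that("the empirical path reproduces study-stage statistics on simulated data", {
  sim <- run_drift_sim(tiny_sim(n_replicates = 1, checkpoints = 12L, seed = 5,
                                n_loci = 120), store_genotypes = TRUE)
  g <- sim$genotypes[[1]][["12"]]
  rep <- suppressWarnings(run_empirical(g, k_range = 1:3, n_boot = 30,
                                        seed = 4))
  expect_equal(sort(rep$diversity$population), sort(unique(g$pop_labels)))
  expect_equal(rep$fst$global_theta,
               wc_fst(g, pairwise = FALSE)$global_theta)
  expect_true(!is.null(rep$nj_newick))
  expect_true(rep$cv$best_k %in% 1:3)
  expect_s3_class(rep$fit, "ancestry_fit")
})

test_that("single-population input skips multi-population stages with warnings", {
  g <- sim_wf_population(n = 30, n_loci = 60, n_gen = 4, seed = 6)
  w <- capture_warnings(rep <- run_empirical(g, k_range = NULL))
  expect_true(any(grepl("FST stage skipped", w)))
  expect_true(any(grepl("NJ stage skipped", w)))
  expect_null(rep$fst)
  expect_false(is.null(rep$diversity))
})

test_that("a malformed genepop file propagates a contextual error", {
  f <- withr::local_tempfile()
  writeLines(c("just one line"), f)
  expect_error(read_genepop(f), "genepop")
})
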