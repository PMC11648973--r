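test_that("configuration invariants are enforced", {
  expect_error(sim_config(init_freq = 1), "init_freq")
  expect_error(sim_config(pop_sizes = c(1, 50)), "pop_sizes")
  expect_error(sim_config(checkpoints = c(5, 0)), "checkpoints")
})

test_that("founding frequencies scatter around init_freq by binomial error", {
  cfg <- sim_config(pop_sizes = c(a = 10000L), n_loci = 2000, seed = 1)
  f <- with_seed(1, init_founder_freqs(cfg))
  sdev <- sqrt(0.25 / (2 * 10000))
  expect_lt(abs(mean(f) - 0.5), 4 * sdev / sqrt(2000))
  # ~99% of loci within 2.58 binomial SDs
  expect_gt(mean(abs(f - 0.5) < 2.58 * sdev), 0.97)
  expect_identical(f, with_seed(1, init_founder_freqs(cfg)))
})

test_that("fixed loci are absorbing and drift is a fair martingale", {
  freqs <- matrix(c(0, 1, 0.5), 1, 3)
  stepped <- with_seed(2, wf_step(freqs, 50))
  expect_equal(stepped[1, 1:2], c(0, 1))

  # one-step mean and variance at p = 0.5, N = 50 over many replicate loci
  p <- matrix(0.5, 1, 10000)
  nxt <- with_seed(3, wf_step(p, 50))
  expect_lt(abs(mean(nxt) - 0.5), 4 * sqrt(0.25 / 100) / sqrt(10000))
  v <- 0.5 * 0.5 / (2 * 50)
  expect_lt(abs(var(as.vector(nxt)) - v), 5 * v / sqrt(10000))
})

test_that("local heterozygosity decays as H0 (1 - 1/(2N))^t", {
  # small-population analog (N = 26) after 50 generations
  cfg <- sim_config(pop_sizes = c(ash = 26L), n_loci = 500,
                    checkpoints = c(0L, 50L), n_replicates = 30, seed = 5)
  res <- run_drift_sim(cfg)
  he50 <- res$trajectories$mean_he[res$trajectories$generation == 50]
  # binomial founding adds one drift episode: t + 1 decay factors
  expected <- 0.5 * (1 - 1 / (2 * 26))^51
  expect_lt(abs(mean(he50) - expected), 3 * sd(he50) / sqrt(length(he50)))

  he0 <- res$trajectories$mean_he[res$trajectories$generation == 0]
  expect_lt(abs(mean(he0) - 0.5), 0.01)
})

test_that("two equal-size populations reach the drift-expected FST", {
  cfg <- sim_config(pop_sizes = c(a = 50L, b = 50L), n_loci = 500,
                    checkpoints = 20L, n_replicates = 30, seed = 6)
  thetas <- numeric(0)
  run_drift_sim(cfg, callback = function(r, gen, g)
    thetas[r] <<- wc_fst(g, pairwise = FALSE)$global_theta)
  expected <- 1 - (1 - 1 / (2 * 50))^20
  # the drift expectation is approximate for the estimator (finite samples,
  # binomially sampled founders), so allow estimator bias of a few permille
  # on top of Monte Carlo error
  expect_lt(abs(mean(thetas) - expected),
            3 * sd(thetas) / sqrt(length(thetas)) + 0.005)
})

test_that("global expected heterozygosity stays stable while local Ho collapses", {
  # the 13-analog metapopulation: pooled He barely moves over 25 generations
  # while mean within-population Ho drops steeply
  cfg <- sim_config(n_loci = 200, checkpoints = c(0L, 25L),
                    n_replicates = 3, seed = 8)
  ht <- hs <- c()
  run_drift_sim(cfg, n_per_pop = 25, callback = function(r, gen, g) {
    if (gen == 25) {
      p <- colMeans(g$dosages) / 2
      ht <<- c(ht, mean(2 * p * (1 - p)))
      hs <<- c(hs, mean(vapply(unique(g$pop_labels), function(pp)
        mean(g$dosages[g$pop_labels == pp, ] == 1L), 0)))
    }
  })
  expect_gt(mean(ht), 0.45)
  expect_lt(mean(hs), mean(ht) - 0.05)
})

test_that("fixation probability equals the founding frequency", {
  cfg <- sim_config(pop_sizes = c(a = 5L), n_loci = 2000, init_freq = 0.3,
                    checkpoints = 200L, n_replicates = 1, seed = 9)
  res <- run_drift_sim(cfg, record_freqs = TRUE)
  f <- res$freqs[[1]][["200"]]
  fixed <- f[f %in% c(0, 1)]
  expect_gt(length(fixed) / length(f), 0.99)
  expect_lt(abs(mean(fixed) - 0.3), 3 * sqrt(0.3 * 0.7 / length(fixed)))
})

test_that("locus trajectories are independent", {
  cfg <- sim_config(pop_sizes = c(a = 30L), n_loci = 200,
                    checkpoints = 10L, n_replicates = 1, seed = 10)
  res <- run_drift_sim(cfg, record_freqs = TRUE)
  f <- as.vector(res$freqs[[1]][["10"]])
  r <- cor(f[seq(1, 199, 2)], f[seq(2, 200, 2)])
  expect_lt(abs(r), 2.5 / sqrt(100))
})

test_that("identical seeds reproduce the simulation exactly", {
  cfg <- tiny_sim(seed = 42)
  r1 <- run_drift_sim(cfg, store_genotypes = TRUE)
  r2 <- run_drift_sim(cfg, store_genotypes = TRUE)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_identical(r1$trajectories, r2$trajectories)
})

test_that("individual-based WF drift generates LD consistent with 1/(3Ne)", {
  g <- sim_wf_population(n = 50, n_loci = 300, n_gen = 10, seed = 11)
  keep <- which(maf(g) >= 0.05)
  r2 <- popdrift:::mean_pairwise_r2(g$dosages[, keep])
  # expectation ~ 1/(3Ne) + 1/S for unlinked loci (Waples 2006)
  expected <- 1 / (3 * 50) + 1 / 50
  expect_lt(abs(r2$r2_mean - expected) / expected, 0.35)
})
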