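perm_cost <- function(cost, perm) sum(cost[cbind(seq_len(nrow(cost)), perm)])

test_that("the assignment solver matches exhaustive search", {
  perms5 <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms5(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i)
      cbind(i, matrix(seq_len(n)[-i][p], nrow(p)))))
  }
  for (seed in 1:10) {
    n <- sample(3:6, 1)
    cost <- with_seed(60 + seed, matrix(runif(n * n), n, n))
    got <- solve_assignment(cost)
    all_p <- perms5(n)
    best <- min(apply(all_p, 1, function(p) perm_cost(cost, p)))
    expect_equal(perm_cost(cost, got), best, tolerance = 1e-12)
    expect_equal(sort(got), seq_len(n))
  }
})

test_that("alignment inverts a manual column permutation exactly", {
  g <- structured_genotypes(n_per_pop = 12, L = 120, K = 4, seed = 1)
  fit <- fit_admixture(g, 4, seed = 2)
  shuffled <- fit
  perm <- c(3, 1, 4, 2)
  shuffled$Q <- fit$Q[, perm]
  shuffled$F <- fit$F[perm, ]
  aligned <- align_replicates(list(fit, shuffled))
  expect_equal(aligned[[2]]$Q, fit$Q, tolerance = 1e-12)
})

test_that("alignment reduces between-replicate disagreement", {
  g <- structured_genotypes(n_per_pop = 12, L = 120, K = 3, seed = 3)
  fits <- lapply(1:5, function(s) fit_admixture(g, 3, seed = 10 + s,
                                                n_restarts = 1))
  dis <- function(fits) {
    ref <- fits[[1]]$Q
    mean(vapply(fits[-1], function(f) mean(abs(f$Q - ref)), 0))
  }
  expect_lte(dis(align_replicates(fits)), dis(fits) + 1e-12)
})

test_that("mismatched K cannot be aligned", {
  g <- structured_genotypes(n_per_pop = 10, L = 60, K = 2, seed = 4)
  f2 <- fit_admixture(g, 2, seed = 1)
  f3 <- fit_admixture(g, 3, seed = 1)
  expect_error(align_replicates(list(f2, f3)), "same K")
})

test_that("average_q of a single one-individual-per-pop fit is the Q matrix", {
  g <- random_genotypes(n = 3, L = 20, pops = c("a", "b", "c"), miss = 0,
                        seed = 5)
  fit <- fit_admixture(g, 2, seed = 6)
  mq <- average_q(fit, g$pop_labels)
  expect_equal(unname(mq), unname(fit$Q), tolerance = 1e-12)
})

test_that("averaging and aligning commute", {
  g <- structured_genotypes(n_per_pop = 10, L = 100, K = 3, seed = 7)
  fits <- align_replicates(lapply(1:3, function(s)
    fit_admixture(g, 3, seed = 20 + s, n_restarts = 1)))
  avg_then <- average_q(fits, g$pop_labels)
  per_fit <- lapply(fits, function(f) average_q(f, g$pop_labels))
  then_avg <- Reduce(`+`, per_fit) / length(per_fit)
  expect_equal(avg_then, then_avg, tolerance = 1e-12)
})

test_that("distinct-cluster assignment matches brute force on a 3-pop table", {
  mq <- rbind(c(0.6, 0.3, 0.1),
              c(0.5, 0.4, 0.1),
              c(0.2, 0.3, 0.5))
  rownames(mq) <- c("a", "b", "c")
  got <- distinct_cluster_assignment(mq)
  # exhaustive search over all 3! one-to-one matchings
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  scores <- vapply(perms, function(p) sum(mq[cbind(1:3, p)]), 0)
  expect_equal(unname(got), perms[[which.max(scores)]])
})

test_that("ties in the assignment cost break deterministically", {
  mq <- matrix(0.5, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(unname(distinct_cluster_assignment(mq)), c(1, 2))
})
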