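test_that("constant y = 0.5 gives a zero intercept", {
  y <- rep(0.5, 20)
  f <- fit_beta(y, cbind(intercept = rep(1, 20)))
  expect_equal(unname(f$coefficients["intercept"]), 0, tolerance = 1e-6)
})

test_that("the MLE improves on the moment start and recovers known parameters", {
  with_seed(1, {
    n <- 91
    x <- runif(n, 0, 50)
    mu <- plogis(-1 + 0.1 * x)
    y <- rbeta(n, mu * 50, (1 - mu) * 50)
  })
  X <- cbind(intercept = rep(1, n), x = x)
  f <- fit_beta(y, X)
  # moment-start log-likelihood for comparison
  beta0 <- qr.solve(X, qlogis(y))
  mu0 <- plogis(drop(X %*% beta0))
  ll0 <- sum(dbeta(y, mu0 * f$phi, (1 - mu0) * f$phi, log = TRUE))
  expect_gte(f$loglik, ll0 - 1e-8)
  expect_lt(abs(f$coefficients["x"] - 0.1), 3 * f$se[2])
  expect_gt(f$phi, 20)
})

test_that("responses at the boundary are rejected with row indices", {
  expect_error(fit_beta(c(0.2, 1, 0.4), cbind(rep(1, 3))), "rows: 2")
  expect_error(fit_beta(c(0, 0.5), cbind(rep(1, 2))), "rows: 1")
})

test_that("rank-deficient designs are rejected", {
  y <- runif(10, 0.3, 0.7)
  X <- cbind(1, 2, seq_len(10))
  expect_error(fit_beta(y, X), "rank")
})

test_that("regression_dataset nudges boundary values inward", {
  expect_message(d <- regression_dataset("a", 50, 0, c(0, 0.5, 1)),
                 "nudged")
  expect_true(all(d$y > 0 & d$y < 1))
  expect_equal(d$y[2], (0.5 * 2 + 0.5) / 3)
})

test_that("model_table ranks five nested models with weights summing to one", {
  with_seed(2, {
    gen <- rep(c(0, 5, 10, 20, 30, 40, 50), each = 6)
    ne <- rep(c(26, 45, 65, 89, 128, 294), 7)
    mu <- plogis(-0.9 + 0.1 * gen - 0.004 * ne - 0.0001 * gen * ne)
    y <- rbeta(length(mu), mu * 60, (1 - mu) * 60)
  })
  ds <- regression_dataset(rep("p", length(y)), ne, gen, y)
  mt <- model_table(ds)
  expect_equal(nrow(mt$table), 5)
  expect_equal(sum(mt$table$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(sum(mt$table$delta_aicc == 0), 1)
  # a strong interaction is detected as the best model with weight near 1
  expect_equal(mt$table$model[1], "generations x ne")
  expect_gt(mt$table$akaike_weight[1], 0.9)
  expect_gt(mt$table$b1[1], 0)
  # df column: 4 coefficients + phi
  expect_equal(mt$table$df[1], 5)
})

test_that("a covariate-free response keeps the null model competitive", {
  with_seed(3, {
    gen <- rep(c(0, 10, 30, 50), each = 8)
    ne <- rep(seq(30, 300, length.out = 8), 4)
    y <- rbeta(32, 0.4 * 30, 0.6 * 30)
  })
  ds <- regression_dataset(rep("p", 32), ne, gen, y)
  mt <- model_table(ds)
  null_delta <- mt$table$delta_aicc[mt$table$model == "null"]
  expect_lt(null_delta, 4)
})

test_that("AICc approaches AIC for large n", {
  ll <- -100; k <- 5
  expect_equal(popdrift:::aicc(ll, k, 1e6), -2 * ll + 2 * k, tolerance = 1e-4)
})

test_that("prediction surfaces respect the fitted coefficients", {
  with_seed(4, {
    gen <- rep(c(0, 5, 20, 50), each = 5)
    ne <- rep(c(26, 54, 89, 137, 294), 4)
    mu <- plogis(-1 + 0.08 * gen)
    y <- rbeta(20, mu * 80, (1 - mu) * 80)
  })
  ds <- regression_dataset(rep("p", 20), ne, gen, y)
  mt <- model_table(ds)
  best <- mt$fits[["generations"]]
  surf <- predict_surface(best, ne_grid = 50, gen_grid = c(0, 10, 20, 40))
  # beta1 > 0: predictions increase with generations at fixed Ne
  expect_true(all(diff(surf$predicted) > 0))
  # prediction at a design point equals the fitted mean there
  at <- predict_surface(best, ne_grid = ne[1], gen_grid = gen[1])
  expect_equal(at$predicted, best$fitted[1], tolerance = 1e-9)
})

test_that("pseudo-R2 is within [0, 1] and undefined only for the null model", {
  with_seed(5, {
    gen <- rep(c(0, 10, 30, 50), each = 6)
    ne <- rep(c(26, 48, 79, 114, 137, 294), 4)
    mu <- plogis(-1 + 0.05 * gen)
    y <- rbeta(24, mu * 40, (1 - mu) * 40)
  })
  mt <- model_table(regression_dataset(rep("p", 24), ne, gen, y))
  r2 <- mt$table$pseudo_r2
  expect_true(all(r2[mt$table$model != "null"] >= 0 &
                    r2[mt$table$model != "null"] <= 1))
  expect_true(is.na(r2[mt$table$model == "null"]))
})
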