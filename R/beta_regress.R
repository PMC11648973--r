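#' Beta regression by maximum likelihood
#'
#' Mean-and-precision parameterization: `y_i ~ Beta(mu_i * phi,
#' (1 - mu_i) * phi)` with a logit link on the mean, `logit(mu_i) = x_i'
#' beta`, and constant precision `phi`. Fitted by BFGS with the analytic
#' score, starting from the least-squares fit of `logit(y)` and a
#' moment-based precision.
#'
#' @param y response strictly inside (0, 1).
#' @param X design matrix (with intercept column).
#' @param tol gradient-norm tolerance declaring convergence.
#' @return a `beta_fit`: `coefficients`, `phi`, `loglik`, `df` (coefficients
#'   + 1 for phi), `se` (coefficient standard errors from the observed
#'   information), `fitted`, `linear_predictor`, `pseudo_r2` (squared
#'   correlation of the linear predictor with logit(y); `NA` for an
#'   intercept-only model), `converged`.
#' @export
fit_beta <- function(y, X, tol = 1e-3) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("design and response lengths differ")
  bad <- which(y <= 0 | y >= 1)
  if (length(bad))
    stop("response outside (0,1) at rows: ", paste(bad, collapse = ", "))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")

  # optimize on column-scaled covariates for conditioning; coefficients are
  # transformed back to the original scale afterwards
  scales <- apply(abs(X), 2, max)
  scales[scales == 0] <- 1
  X_orig <- X
  X <- sweep(X, 2, scales, "/")

  ystar <- qlogis(y)
  beta0 <- qr.solve(X, ystar)
  mu0 <- plogis(drop(X %*% beta0))
  s2 <- max(var(y - mu0), 1e-8)
  phi0 <- max(mean(mu0 * (1 - mu0)) / s2 - 1, 2)

  negll <- function(par) {
    beta <- par[-length(par)]; phi <- exp(par[length(par)])
    mu <- plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
  }
  grad <- function(par) {
    beta <- par[-length(par)]; phi <- exp(par[length(par)])
    mu <- plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    dbeta <- phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
    dphi <- sum(mu * (ystar - mustar) + log1p(-y) -
                  digamma((1 - mu) * phi) + digamma(phi)) * phi
    -c(dbeta, dphi)
  }

  start <- c(beta0, log(phi0))
  opt <- NULL
  for (round in 1:4) {  # restarting BFGS polishes the gradient cheaply
    opt <- optim(if (is.null(opt)) start else opt$par, negll, grad,
                 method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12),
                 hessian = (round == 4))
    if (sqrt(sum(grad(opt$par)^2)) <= tol * (1 + abs(opt$value))) break
  }
  if (is.null(opt$hessian))
    opt$hessian <- optim(opt$par, negll, grad, method = "BFGS",
                         control = list(maxit = 1), hessian = TRUE)$hessian
  gnorm <- sqrt(sum(grad(opt$par)^2))
  if (gnorm > tol * (1 + abs(opt$value)))
    stop(sprintf("beta regression did not converge (gradient norm %.3g)", gnorm))

  k <- ncol(X)
  beta <- opt$par[seq_len(k)] / scales
  names(beta) <- colnames(X_orig)
  eta <- drop(X_orig %*% beta)
  vc <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, k + 1, k + 1))
  structure(list(
    coefficients = beta,
    phi = exp(opt$par[k + 1]),
    loglik = -opt$value,
    df = k + 1L,
    se = sqrt(pmax(diag(vc)[seq_len(k)], 0)) / scales,
    fitted = plogis(eta),
    linear_predictor = eta,
    pseudo_r2 = if (sd(eta) > 0) cor(eta, ystar)^2 else NA_real_,
    n = n,
    converged = TRUE), class = "beta_fit")
}

# Small-sample Akaike information criterion.
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Build the assignment-regression dataset
#'
#' One row per population x generation: its effective size, the number of
#' generations of drift, and the mean assignment probability (a value in
#' (0, 1)). Boundary responses are nudged inward with the standard
#' `(y (n - 1) + 0.5) / n` transform (n = number of rows); a message reports
#' when this is applied.
#'
#' @param population,ne,generations,y equal-length vectors.
#' @return data.frame with columns population, ne, generations, y.
#' @export
regression_dataset <- function(population, ne, generations, y) {
  n <- length(y)
  if (any(y < 0 | y > 1)) stop("assignment probabilities must be in [0, 1]")
  if (any(y <= 0 | y >= 1)) {
    message("boundary responses nudged inward with (y(n-1)+0.5)/n")
    y <- (y * (n - 1) + 0.5) / n
  }
  data.frame(population = population, ne = ne, generations = generations,
             y = y)
}

#' Nested beta-regression model table
#'
#' Fits the five nested candidate models for mean assignment —
#' `~ generations * ne`, `~ generations + ne`, `~ generations`, `~ ne`, and
#' the null model — and ranks them by AICc (`-2LL + 2k + 2k(k+1)/(n-k-1)`,
#' k = regression coefficients + 1 for phi). Reports per-model coefficients,
#' log-likelihood, AICc, delta-AICc, Akaike weights and pseudo-R2.
#'
#' @param dataset a [regression_dataset()]-style data.frame with columns
#'   `y`, `generations`, `ne`.
#' @return list with `table` (ranked data.frame) and `fits` (named list of
#'   `beta_fit` objects, same order as the table).
#' @export
model_table <- function(dataset) {
  y <- dataset$y
  gen <- dataset$generations
  ne <- dataset$ne
  n <- length(y)
  one <- rep(1, n)
  designs <- list(
    "generations x ne" = cbind(intercept = one, generations = gen, ne = ne,
                               "generations:ne" = gen * ne),
    "generations + ne" = cbind(intercept = one, generations = gen, ne = ne),
    "generations"      = cbind(intercept = one, generations = gen),
    "ne"               = cbind(intercept = one, ne = ne),
    "null"             = cbind(intercept = one))

  fits <- list(); rows <- list()
  for (nm in names(designs)) {
    X <- designs[[nm]]
    k <- ncol(X) + 1
    if (n <= k + 1) {
      rows[[nm]] <- data.frame(model = nm, b0 = NA, b1 = NA, b2 = NA, b3 = NA,
                               df = k, loglik = NA, aicc = NA,
                               pseudo_r2 = NA, note = "unfit: n <= k + 1")
      next
    }
    f <- fit_beta(y, X)
    cf <- f$coefficients
    pick <- function(lbl) if (lbl %in% names(cf)) unname(cf[lbl]) else NA_real_
    rows[[nm]] <- data.frame(
      model = nm, b0 = pick("intercept"), b1 = pick("generations"),
      b2 = pick("ne"), b3 = pick("generations:ne"),
      df = f$df, loglik = f$loglik, aicc = aicc(f$loglik, f$df, n),
      pseudo_r2 = f$pseudo_r2, note = "")
    fits[[nm]] <- f
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !is.na(tab$aicc)
  tab$delta_aicc <- tab$aicc - min(tab$aicc[ok])
  w <- exp(-tab$delta_aicc / 2)
  w[!ok] <- 0
  tab$akaike_weight <- w / sum(w, na.rm = TRUE)
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits[intersect(tab$model, names(fits))])
}

#' Prediction surface of a fitted assignment model
#'
#' Inverse-logit predictions of mean assignment on an Ne x generations grid.
#'
#' @param fit a `beta_fit` from [model_table()] (its coefficient names decide
#'   which terms enter the linear predictor).
#' @param ne_grid,gen_grid numeric grids.
#' @return long-format data.frame (ne, generations, predicted).
#' @export
predict_surface <- function(fit, ne_grid, gen_grid) {
  grid <- expand.grid(ne = ne_grid, generations = gen_grid)
  cf <- fit$coefficients
  eta <- rep(unname(cf["intercept"]), nrow(grid))
  if ("generations" %in% names(cf)) eta <- eta + cf["generations"] * grid$generations
  if ("ne" %in% names(cf)) eta <- eta + cf["ne"] * grid$ne
  if ("generations:ne" %in% names(cf))
    eta <- eta + cf["generations:ne"] * grid$generations * grid$ne
  grid$predicted <- plogis(unname(eta))
  grid
}
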