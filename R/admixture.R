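#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of individual ancestry proportions Q
#' (n x K, rows on the simplex) and cluster allele frequencies F (K x L)
#' under the binomial admixture likelihood
#' `sum_ij g_ij log(sum_k q_ik f_kj) + (2 - g_ij) log(sum_k q_ik (1 - f_kj))`
#' for diploid dosages. Optimization is the classical multiplicative EM,
#' whose log-likelihood is non-decreasing; missing genotypes are omitted from
#' the likelihood, and F is clipped to `[f_eps, 1 - f_eps]` so fixed loci
#' cannot produce log(0). The likelihood is multimodal, so several seeded
#' random restarts are run and the best kept.
#'
#' @param g a [genotype_matrix()].
#' @param K number of ancestral clusters (>= 1).
#' @param seed integer seed for the random starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random restarts (best log-likelihood kept).
#' @param f_eps clipping bound for cluster allele frequencies.
#' @param q_eps boundary bound for ancestry proportions: estimated Q entries
#'   are kept at least `q_eps` (rows renormalized), mirroring the boundary
#'   projection of standard admixture software. Individual memberships below
#'   this bound are not meaningfully resolvable from a few hundred loci.
#' @return an `ancestry_fit`: list with `K`, `Q`, `F`, `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `seed`.
#' @export
fit_admixture <- function(g, K, seed = 1, tol = 1e-6, max_iter = 400,
                          n_restarts = 3, f_eps = 1e-6, q_eps = 1e-5) {
  dos <- g$dosages
  n <- nrow(dos); L <- ncol(dos)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of individuals (", n, ")")
  obs <- (!is.na(dos)) * 1
  if (any(rowSums(obs) == 0)) stop("individuals with no observed genotypes")
  G <- dos; G[is.na(G)] <- 0
  storage.mode(G) <- "double"

  if (K == 1) {
    # closed form: Q all ones, F = sample allele frequencies
    p <- colSums(G * obs) / (2 * colSums(obs))
    p <- pmin(pmax(p, f_eps), 1 - f_eps)
    P <- matrix(p, n, L, byrow = TRUE)
    ll <- sum(obs * (G * log(P) + (2 - G) * log(1 - P)))
    return(structure(list(K = 1L, Q = matrix(1, n, 1),
                          F = matrix(p, 1, L), loglik = ll,
                          loglik_trace = ll, n_iter = 0L, converged = TRUE,
                          seed = seed),
                     class = "ancestry_fit"))
  }

  p_hat <- colSums(G * obs) / (2 * colSums(obs))
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(seed, 7L, rs), {
      Q0 <- matrix(rexp(n * K), n, K)
      Q0 <- Q0 / rowSums(Q0)
      F0 <- matrix(pmin(pmax(rep(p_hat, each = K) +
                               rnorm(K * L, 0, 0.1), 0.02), 0.98), K, L)
      admix_em_cpp(G, obs, Q0, F0, tol, max_iter, f_eps)
    })
    if (is.null(best) || max(fit$loglik_trace) > max(best$loglik_trace))
      best <- fit
  }
  trace <- as.numeric(best$loglik_trace)
  if (q_eps > 0) {
    best$Q <- pmax(best$Q, q_eps)
    best$Q <- best$Q / rowSums(best$Q)
  }
  structure(list(K = as.integer(K), Q = best$Q, F = best$F,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = best$n_iter, converged = best$converged,
                 seed = seed),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("ancestry_fit: K = %d, n = %d, loglik = %.2f (%s, %d iterations)\n",
              x$K, nrow(x$Q), x$loglik,
              if (x$converged) "converged" else "iteration cap reached",
              x$n_iter))
  invisible(x)
}

#' Cross-validation error of the admixture model
#'
#' Partitions the non-missing genotype entries into `folds` folds, masks each
#' fold in turn, refits the model on the remainder, and predicts the masked
#' dosages as `2 * sum_k q_ik f_kj`. The error is the mean binomial deviance
#' of the masked entries, averaged over folds. Loci with no observed entries
#' in a training set are unidentifiable and their masked entries are skipped
#' with a warning.
#'
#' @param g a [genotype_matrix()].
#' @param K number of clusters.
#' @param folds number of folds (default 5).
#' @param seed seed controlling the fold partition and the fits.
#' @param ... passed to [fit_admixture()] (e.g. `tol`, `max_iter`,
#'   `n_restarts`).
#' @return mean masked deviance (scalar) with attribute `"by_fold"`.
#' @export
cv_error <- function(g, K, folds = 5, seed = 1, ...) {
  if (folds < 2) stop("folds must be >= 2")
  dos <- g$dosages
  obs_idx <- which(!is.na(dos))
  # the fold partition depends on the seed only, not on K, so errors are
  # paired across the K values being compared
  fold_id <- with_seed(derive_seed(seed, 13L),
                       sample(rep(seq_len(folds), length.out = length(obs_idx))))
  errs <- numeric(folds)
  for (f in seq_len(folds)) {
    masked <- obs_idx[fold_id == f]
    gm <- g
    gm$dosages[masked] <- NA_integer_
    dead_loci <- which(colSums(!is.na(gm$dosages)) == 0)
    if (length(dead_loci)) {
      warning("fold ", f, " masks entire loci; their entries are skipped")
      bad <- masked[(((masked - 1) %/% nrow(dos)) + 1) %in% dead_loci]
      masked <- setdiff(masked, bad)
    }
    fit <- fit_admixture(gm, K, seed = derive_seed(seed, 17L, K, f), ...)
    P <- fit$Q %*% fit$F
    p <- pmin(pmax(P[masked], 1e-9), 1 - 1e-9)
    y <- dos[masked]
    # binomial deviance for size-2 trials, with 0 log 0 = 0
    term <- function(k, mu) ifelse(k == 0, 0, k * log(k / mu))
    errs[f] <- mean(2 * (term(y, 2 * p) + term(2 - y, 2 * (1 - p))))
  }
  structure(mean(errs), by_fold = errs)
}

#' Cross-validated choice of K
#'
#' Runs [cv_error()] over a range of K and returns the per-K mean error and
#' the argmin.
#'
#' @param g a [genotype_matrix()].
#' @param k_range integer vector of K values to test.
#' @param folds,seed,... passed to [cv_error()].
#' @return list with `table` (data.frame K, cv_error) and `best_k`.
#' @export
choose_k <- function(g, k_range = 1:15, folds = 5, seed = 1, ...) {
  errs <- vapply(k_range, function(k)
    as.numeric(cv_error(g, k, folds = folds, seed = seed, ...)), 0)
  list(table = data.frame(K = k_range, cv_error = errs),
       best_k = k_range[which.min(errs)])
}
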