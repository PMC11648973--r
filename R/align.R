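#' Exact solution of the linear assignment problem
#'
#' Hungarian algorithm (O(n^3), the Jonker-style augmenting-path variant) for
#' a square cost matrix; used to resolve label switching between ancestry
#' fits and to map populations to their distinct clusters. Exact cost ties
#' are broken deterministically toward the lowest column index by the scan
#' order.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `perm` such that row `i` is assigned column
#'   `perm[i]`, minimizing `sum(cost[cbind(seq_len(n), perm)])`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) perm[p[j + 1]] <- j
  perm
}

# Permutation of the columns of `q` best matching `ref` (both m x K),
# minimizing summed (1 - Pearson correlation) between matched columns;
# zero-variance columns fall back on mean absolute difference.
match_columns <- function(q, ref) {
  K <- ncol(ref)
  cost <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (sd(ref[, a]) > 0 && sd(q[, b]) > 0)
      cost[a, b] <- 1 - cor(ref[, a], q[, b])
    else
      cost[a, b] <- mean(abs(ref[, a] - q[, b]))
  }
  solve_assignment(cost)  # ref column a takes q column perm[a]
}

#' Align ancestry fits across replicate runs
#'
#' Resolves label switching: the clusters of every fit are permuted to
#' maximize column-wise agreement with the first fit (minimum summed
#' 1 - correlation between Q columns, solved exactly by the Hungarian
#' algorithm). All fits must share K and the same individual ordering.
#'
#' @param fits list of `ancestry_fit` objects with equal K.
#' @return list of fits with `Q` (and `F`) columns permuted; each fit gains a
#'   `perm` element recording the permutation applied (new column k was old
#'   column `perm[k]`).
#' @export
align_replicates <- function(fits) {
  ks <- vapply(fits, function(f) f$K, 0L)
  if (length(unique(ks)) != 1) stop("all fits must share the same K")
  ref <- fits[[1]]$Q
  lapply(fits, function(f) {
    perm <- match_columns(f$Q, ref)
    f$Q <- f$Q[, perm, drop = FALSE]
    f$F <- f$F[perm, , drop = FALSE]
    f$perm <- perm
    f
  })
}

#' Population-averaged ancestry proportions
#'
#' Mean Q per population per cluster across individuals and (aligned)
#' replicate fits. Rows sum to 1.
#'
#' @param fits list of aligned `ancestry_fit` objects (or a single fit).
#' @param pop_labels per-individual population labels shared by all fits.
#' @return matrix `n_pops x K` of mean ancestry proportions, rownames the
#'   populations in order of first appearance.
#' @export
average_q <- function(fits, pop_labels) {
  if (inherits(fits, "ancestry_fit")) fits <- list(fits)
  pops <- unique(pop_labels)
  K <- fits[[1]]$K
  acc <- matrix(0, length(pops), K, dimnames = list(pops, NULL))
  for (f in fits) {
    if (nrow(f$Q) != length(pop_labels))
      stop("pop_labels length does not match Q")
    pm <- rowsum(f$Q, group = factor(pop_labels, levels = pops))
    acc <- acc + pm / as.vector(table(factor(pop_labels, levels = pops)))
  }
  acc / length(fits)
}

#' Assignment of each population to its distinct cluster
#'
#' Maps populations one-to-one onto clusters by maximizing the total mean
#' assignment (exact optimal assignment, never greedy) on a reference
#' population x cluster mean-Q table — normally the final-generation table,
#' where populations have become distinct. Given that mapping, the same
#' cluster's mean Q can be read off tables from earlier generations.
#'
#' @param mean_q reference `n_pops x K` mean-Q table (K >= n_pops).
#' @return named integer vector: cluster index owned by each population.
#' @export
distinct_cluster_assignment <- function(mean_q) {
  n_pops <- nrow(mean_q); K <- ncol(mean_q)
  if (K < n_pops) stop("need at least as many clusters as populations")
  # pad with zero-value dummy rows if K > n_pops to keep the problem square
  cost <- rbind(-mean_q, matrix(0, K - n_pops, K))
  perm <- solve_assignment(cost)[seq_len(n_pops)]
  names(perm) <- rownames(mean_q)
  perm
}
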