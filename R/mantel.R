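#' Mantel test of isolation by distance
#'
#' Linearizes the genetic matrix as `FST / (1 - FST)` and tests its Mantel
#' correlation with a geographic (waterway) distance matrix by permutation.
#' The test is one-tailed for positive association, the ecological convention
#' for isolation by distance: `p = (# permuted r >= observed r + 1) /
#' (n_perm + 1)`. The permutation machinery is `vegan::mantel`.
#'
#' @param fst a [dist_matrix()] of pairwise FST values (must be < 1
#'   everywhere off-diagonal: an FST of 1 has infinite linearized distance
#'   and the offending pair must be dropped by the caller).
#' @param dist a [dist_matrix()] of geographic distances with the same
#'   labels (any order).
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed.
#' @return list with `slope` (regression of linearized FST on distance),
#'   `correlation`, `p_value`, `n_permutations`.
#' @export
mantel_ibd <- function(fst, dist, n_perm = 999, seed = NULL) {
  labs <- rownames(fst)
  if (!setequal(labs, rownames(dist)))
    stop("fst and dist matrices must share the same labels")
  dist <- unclass(dist)[labs, labs]
  fst_m <- unclass(fst)
  off <- fst_m[upper.tri(fst_m)]
  if (any(off >= 1))
    stop("FST = 1 gives an infinite linearized distance; drop the offending pair(s)")
  lin <- fst_m / (1 - fst_m)
  diag(lin) <- 0

  gv <- lin[lower.tri(lin)]
  dv <- dist[lower.tri(dist)]
  if (sd(dv) == 0 || sd(gv) == 0)
    stop("degenerate (constant) matrix: Mantel correlation undefined")

  res <- with_seed(seed,
    vegan::mantel(as.dist(dist), as.dist(lin), method = "pearson",
                  permutations = n_perm))
  list(slope = unname(coef(lm(gv ~ dv))[2]),
       correlation = unname(res$statistic),
       p_value = res$signif,
       n_permutations = n_perm)
}
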