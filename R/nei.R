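#' Nei's DA genetic distance
#'
#' DA of Nei, Tajima & Tateno (1983):
#' `DA = 1 - (1/L) * sum_loci sum_alleles sqrt(x_u * y_u)` over the allele
#' frequency vectors of two populations. For biallelic loci the inner sum is
#' `sqrt(px*py) + sqrt((1-px)*(1-py))`. Loci missing entirely in either
#' population of a pair are dropped from that pair's average.
#'
#' @param g a [genotype_matrix()].
#' @return a [dist_matrix()] of pairwise DA values in \[0, 1\].
#' @export
nei_da <- function(g) {
  pops <- unique(g$pop_labels)
  if (length(pops) < 2) stop("nei_da needs at least 2 populations")
  freq <- sapply(pops, function(p) {
    d <- g$dosages[g$pop_labels == p, , drop = FALSE]
    colMeans(d, na.rm = TRUE) / 2
  })
  freq <- matrix(freq, ncol = length(pops), dimnames = list(NULL, pops))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (pair in combn(seq_along(pops), 2, simplify = FALSE)) {
    x <- freq[, pair[1]]; y <- freq[, pair[2]]
    ok <- is.finite(x) & is.finite(y)
    da <- 1 - mean(sqrt(x[ok] * y[ok]) + sqrt((1 - x[ok]) * (1 - y[ok])))
    m[pair[1], pair[2]] <- m[pair[2], pair[1]] <- da
  }
  dist_matrix(m, labels = pops)
}

#' Neighbor-joining tree with locus-bootstrap support
#'
#' Saitou & Nei neighbor-joining on Nei's DA distances. Bootstrap replicates
#' resample loci with replacement, recompute DA and the NJ topology, and
#' report clade support as a percentage on internal nodes of the returned
#' newick string.
#'
#' @param g a [genotype_matrix()] with at least 3 populations.
#' @param bootstrap number of locus-bootstrap replicates (0 = no support
#'   values).
#' @param seed optional seed for the bootstrap resampling.
#' @return newick string; also returns the `phylo` object and support values
#'   via attributes `"tree"` and `"support"`.
#' @export
nj_tree <- function(g, bootstrap = 1000, seed = NULL) {
  pops <- unique(g$pop_labels)
  if (length(pops) < 3) stop("nj_tree needs at least 3 populations")
  d <- nei_da(g)
  tree <- ape::nj(as.dist(unclass(d)))
  support <- NULL
  if (bootstrap > 0) {
    boots <- with_seed(seed, {
      lapply(seq_len(bootstrap), function(b) {
        cols <- sample.int(ncol(g$dosages), replace = TRUE)
        gb <- genotype_matrix(g$dosages[, cols, drop = FALSE], g$pop_labels)
        ape::nj(as.dist(unclass(nei_da(gb))))
      })
    })
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- round(100 * counts / bootstrap)
    tree$node.label <- as.character(support)
    tree$node.label[1] <- ""  # root of the unrooted representation
  }
  nwk <- ape::write.tree(tree)
  attr(nwk, "tree") <- tree
  attr(nwk, "support") <- support
  nwk
}
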