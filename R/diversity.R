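#' Per-population genetic diversity
#'
#' Computes, per population: observed heterozygosity `Ho` (fraction of
#' heterozygous genotypes), unbiased expected heterozygosity `He`
#' (`2n/(2n-1) * 2p(1-p)` with n the number of genotyped individuals,
#' Nei's small-sample correction), rarefied allelic richness `Ar`
#' (expected allele count in a hypergeometric subsample of `rarefaction_n`
#' gene copies, averaged over loci), and the inbreeding coefficient
#' `Fis = 1 - mean(Ho)/mean(He)`.
#'
#' @param g a [genotype_matrix()].
#' @param rarefaction_n rarefied sample size in gene copies; defaults to the
#'   smallest per-population, per-locus count of non-missing genes.
#' @return data.frame with columns population, n, ar, ho, he, fis. `fis` is
#'   `NA` for populations monomorphic at every locus.
#' @export
diversity <- function(g, rarefaction_n = NULL) {
  pops <- unique(g$pop_labels)
  # per-pop per-locus genotyped counts
  counts <- lapply(pops, function(p) {
    d <- g$dosages[g$pop_labels == p, , drop = FALSE]
    n <- colSums(!is.na(d))
    if (any(n == 0))
      stop("population ", p, " has loci with no non-missing genotypes")
    list(n = n, p = colSums(d, na.rm = TRUE) / (2 * n),
         het = colSums(d == 1L, na.rm = TRUE) / n,
         size = nrow(d))
  })
  names(counts) <- pops
  if (is.null(rarefaction_n))
    rarefaction_n <- min(vapply(counts, function(x) min(2 * x$n), 0))
  if (rarefaction_n < 2) stop("rarefaction_n must be >= 2")

  out <- lapply(pops, function(pn) {
    x <- counts[[pn]]
    n_genes <- 2 * x$n
    c1 <- round(x$p * n_genes)
    c2 <- n_genes - c1
    ok <- n_genes >= rarefaction_n
    # P(allele absent from a rarefied sample of size g) = C(n - c, g) / C(n, g)
    ar_loc <- 2 -
      exp(lchoose(n_genes - c1, rarefaction_n) - lchoose(n_genes, rarefaction_n)) -
      exp(lchoose(n_genes - c2, rarefaction_n) - lchoose(n_genes, rarefaction_n))
    he_loc <- (2 * x$n / (2 * x$n - 1)) * 2 * x$p * (1 - x$p)
    ho <- mean(x$het)
    he <- mean(he_loc)
    data.frame(population = pn, n = x$size,
               ar = mean(ar_loc[ok]),
               ho = ho, he = he,
               fis = if (he > 0) 1 - ho / he else NA_real_)
  })
  do.call(rbind, out)
}
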