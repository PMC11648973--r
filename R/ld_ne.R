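#' Burrows' composite squared correlation between two loci
#'
#' Estimates the composite (gametic + nongametic) disequilibrium Delta from
#' unphased dosages as half the sample covariance of the two dosage vectors,
#' with the heterozygosity-adjusted denominators
#' `(pA qA + DA)(pB qB + DB)` (DA the within-locus Hardy-Weinberg departure),
#' as in the single-sample LD method. With sample quantities this composite
#' measure is algebraically the squared Pearson correlation of the two dosage
#' vectors, computed among individuals genotyped at both loci; a perfectly
#' duplicated locus therefore gives exactly 1.
#'
#' @param g a [genotype_matrix()].
#' @param locus_a,locus_b locus ids or column indices.
#' @return squared correlation (scalar).
#' @export
burrows_r2 <- function(g, locus_a, locus_b) {
  ja <- if (is.character(locus_a)) match(locus_a, g$locus_ids) else locus_a
  jb <- if (is.character(locus_b)) match(locus_b, g$locus_ids) else locus_b
  x <- g$dosages[, ja]; y <- g$dosages[, jb]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("fewer than 2 individuals genotyped at both loci")
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0)
    stop("both loci must be polymorphic among complete individuals")
  unname(cor(x, y)^2)
}

# Mean Burrows r2 over all retained locus pairs, plus the harmonic-mean
# sample size. Fast path for complete data; pairwise loop otherwise.
mean_pairwise_r2 <- function(dosages, pairs_keep = NULL) {
  n <- nrow(dosages); L <- ncol(dosages)
  if (is.null(pairs_keep)) pairs_keep <- matrix(TRUE, L, L)
  if (!anyNA(dosages)) {
    r2 <- cor(dosages)^2
    use <- upper.tri(r2) & pairs_keep & is.finite(r2)
    return(list(r2_mean = mean(r2[use]), n_pairs = sum(use), s_harm = n))
  }
  tot <- 0; k <- 0; inv_s <- 0
  for (a in seq_len(L - 1)) for (b in (a + 1):L) {
    if (!pairs_keep[a, b]) next
    x <- dosages[, a]; y <- dosages[, b]
    ok <- !is.na(x) & !is.na(y)
    m <- sum(ok)
    if (m < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) next
    tot <- tot + cor(x[ok], y[ok])^2
    k <- k + 1; inv_s <- inv_s + 1 / m
  }
  if (k == 0) stop("no usable locus pairs")
  list(r2_mean = tot / k, n_pairs = k, s_harm = k / inv_s)
}

# Waples (2006) random-mating bias correction and Ne solution,
# with the S >= 30 / S < 30 branches used by the LD method.
ne_from_r2 <- function(r2_mean, s) {
  if (s >= 30) {
    r2_drift <- r2_mean - (1 / s + 3.19 / s^2)
    if (r2_drift <= 0) return(Inf)
    (1 / 3 + sqrt(max(1 / 9 - 2.76 * r2_drift, 0))) / (2 * r2_drift)
  } else {
    r2_drift <- r2_mean - (0.0018 + 0.907 / s + 4.44 / s^2)
    if (r2_drift <= 0) return(Inf)
    (0.308 + sqrt(max(0.308^2 - 2.08 * r2_drift, 0))) / (2 * r2_drift)
  }
}

#' Linkage-disequilibrium effective population size
#'
#' Single-sample LD method: mean Burrows' composite r2 over locus pairs,
#' bias-adjusted for sample size with Waples' (2006) random-mating formulas,
#' solved for Ne. A negative or zero adjusted disequilibrium yields an
#' infinite estimate (the sample carries no detectable drift LD). The 95% CI
#' is a delete-one-individual jackknife on the mean r2, transformed through
#' the (monotone decreasing) Ne solution.
#'
#' @param g a [genotype_matrix()]; one population expected (labels ignored).
#' @param maf minimum minor allele frequency for a locus to be used
#'   (default 0.02). Monomorphic-after-threshold loci are dropped silently
#'   and counted in the result.
#' @param exclude_same_group drop pairs of loci on the same linkage group
#'   (requires `g$linkage_group`).
#' @return list (`ne_estimate`): `ne_point`, `ci_low`, `ci_high`,
#'   `r2_mean`, `n_pairs`, `n_loci_used`, `n_loci_dropped`, `maf_threshold`.
#' @export
estimate_ne <- function(g, maf = 0.02, exclude_same_group = FALSE) {
  m <- maf(g)
  keep <- which(!is.na(m) & m >= maf & m > 0)
  dropped <- ncol(g$dosages) - length(keep)
  if (length(keep) < 2) stop("fewer than 2 usable loci after the MAF threshold")
  dos <- g$dosages[, keep, drop = FALSE]
  pairs_keep <- NULL
  if (exclude_same_group) {
    if (is.null(g$linkage_group))
      stop("exclude_same_group requires linkage_group metadata")
    lg <- g$linkage_group[keep]
    pairs_keep <- outer(lg, lg, FUN = "!=")
    if (!any(pairs_keep[upper.tri(pairs_keep)]))
      stop("no between-group locus pairs available")
  }

  # the composite-measure sample correction: the bias formulas of the LD
  # method are calibrated for the estimator carrying an (n/(n-1))^2 factor
  # relative to the plain dosage correlation
  corr <- function(s) (s / (s - 1))^2
  full <- mean_pairwise_r2(dos, pairs_keep)
  ne <- ne_from_r2(full$r2_mean * corr(full$s_harm), full$s_harm)

  # delete-one jackknife on mean r2 (rank-one downdates of the cross-product
  # matrix when the data are complete)
  n <- nrow(dos)
  if (!anyNA(dos)) {
    X <- dos
    storage.mode(X) <- "double"
    S <- crossprod(X)            # L x L sums of products
    cs <- colSums(X)
    use <- upper.tri(S) & (if (is.null(pairs_keep)) TRUE else pairs_keep)
    r2_i <- vapply(seq_len(n), function(i) {
      x <- X[i, ]
      m <- n - 1
      Si <- S - tcrossprod(x)
      csi <- cs - x
      cv <- (Si - tcrossprod(csi) / m) / (m - 1)
      v <- diag(cv)
      r2 <- cv^2 / tcrossprod(v)
      mean(r2[use & is.finite(r2)])
    }, 0)
  } else {
    r2_i <- vapply(seq_len(n), function(i)
      mean_pairwise_r2(dos[-i, , drop = FALSE], pairs_keep)$r2_mean, 0)
  }
  r2_i <- r2_i * corr(full$s_harm - 1)
  se <- sqrt((n - 1) / n * sum((r2_i - mean(r2_i))^2))
  z <- qnorm(0.975)
  r2c <- full$r2_mean * corr(full$s_harm)
  ci_low <- ne_from_r2(r2c + z * se, full$s_harm)
  ci_high <- ne_from_r2(r2c - z * se, full$s_harm)
  structure(list(ne_point = ne, ci_low = min(ci_low, ne),
                 ci_high = max(ci_high, ne),
                 r2_mean = full$r2_mean, n_pairs = full$n_pairs,
                 n_loci_used = length(keep), n_loci_dropped = dropped,
                 maf_threshold = maf),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("LD Ne estimate: %.1f (95%% CI %.1f - %s), %d locus pairs, MAF >= %g\n",
              x$ne_point, x$ci_low,
              if (is.finite(x$ci_high)) sprintf("%.1f", x$ci_high) else "Inf",
              x$n_pairs, x$maf_threshold))
  invisible(x)
}
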