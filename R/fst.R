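#' Weir-Cockerham F-statistics
#'
#' Per-locus variance components (a: among populations, b: among individuals
#' within populations, c: within individuals) of Weir & Cockerham's (1984)
#' theta for biallelic loci, the global ratio estimator
#' `theta = sum(a) / sum(a + b + c)` over loci, and pairwise theta for every
#' population pair. Loci monomorphic across all populations contribute zero
#' components and drop out of the ratio.
#'
#' @param g a [genotype_matrix()].
#' @param pops optional subset of population labels (default: all).
#' @param pairwise also compute the pairwise theta matrix.
#' @return list with `global_theta`, `components` (data.frame locus, a, b,
#'   c), and (if requested) `pairwise`, a [dist_matrix()].
#' @export
wc_fst <- function(g, pops = NULL, pairwise = TRUE) {
  if (is.null(pops)) pops <- unique(g$pop_labels)
  if (length(pops) < 2) stop("wc_fst needs at least 2 populations")
  keep <- g$pop_labels %in% pops
  comp <- wc_components(g$dosages[keep, , drop = FALSE], g$pop_labels[keep])
  res <- list(global_theta = sum(comp$a) / sum(comp$a + comp$b + comp$c),
              components = data.frame(locus = g$locus_ids, comp))
  if (pairwise) {
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (pair in combn(pops, 2, simplify = FALSE)) {
      sel <- g$pop_labels %in% pair
      cc <- wc_components(g$dosages[sel, , drop = FALSE], g$pop_labels[sel])
      th <- sum(cc$a) / sum(cc$a + cc$b + cc$c)
      m[pair[1], pair[2]] <- m[pair[2], pair[1]] <- th
    }
    res$pairwise <- dist_matrix(m, labels = pops)
  }
  res
}

# WC84 variance components for biallelic dosage data, vectorized over loci.
# Returns a data.frame with one row per locus (zeros for loci with no
# variation or with < 2 populations genotyped).
wc_components <- function(dosages, labels) {
  pops <- unique(labels)
  L <- ncol(dosages)
  n_mat <- sapply(pops, function(p)
    colSums(!is.na(dosages[labels == p, , drop = FALSE])))
  p_mat <- sapply(pops, function(p) {
    d <- dosages[labels == p, , drop = FALSE]
    colSums(d, na.rm = TRUE)
  })
  h_mat <- sapply(pops, function(p) {
    d <- dosages[labels == p, , drop = FALSE]
    colSums(d == 1L, na.rm = TRUE)
  })
  n_mat <- matrix(n_mat, nrow = L); p_mat <- matrix(p_mat, nrow = L)
  h_mat <- matrix(h_mat, nrow = L)
  p_mat <- p_mat / (2 * n_mat)    # per-pop allele frequency
  h_mat <- h_mat / n_mat          # per-pop observed het frequency
  p_mat[n_mat == 0] <- 0          # unobserved pop/locus cells drop out
  h_mat[n_mat == 0] <- 0

  r <- rowSums(n_mat > 0)
  nbar <- rowSums(n_mat) / r
  nc <- (r * nbar - rowSums(n_mat^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n_mat * p_mat) / (r * nbar)
  s2 <- rowSums(n_mat * (p_mat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n_mat * h_mat) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  mono <- pbar <= 0 | pbar >= 1
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  bad <- r < 2 | !is.finite(a)
  a[bad] <- 0; b[bad] <- 0; cc[bad] <- 0
  data.frame(a = a, b = b, c = cc)
}

#' Mean global FST trajectory under drift
#'
#' Frequency-level Wright-Fisher simulation on a dense generation grid: at
#' every generation of every replicate a Hardy-Weinberg genotype sample is
#' materialized and the Weir-Cockerham global theta computed; the mean over
#' replicates is returned per generation, together with the first generation
#' whose mean theta reaches `threshold` (linear interpolation between
#' generations).
#'
#' @param cfg a [sim_config()] (its `checkpoints` are ignored; every
#'   generation from 0 to `max_gen` is evaluated).
#' @param max_gen last generation to simulate.
#' @param n_per_pop genotype sample per population (default 25).
#' @param threshold FST level whose first crossing is reported (default
#'   `NULL`: none).
#' @return list with `trajectory` (data.frame generation, mean_theta,
#'   sd_theta) and `first_crossing` (possibly `NA` if never reached).
#' @export
fst_trajectory <- function(cfg, max_gen = 30, n_per_pop = 25,
                           threshold = NULL) {
  gens <- 0:max_gen
  theta <- matrix(NA_real_, length(gens), cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    with_seed(derive_seed(cfg$seed, 211L, r), {
      f <- init_founder_freqs(cfg)
      for (t in gens) {
        if (t > 0) f <- wf_step(f, cfg$pop_sizes)
        g <- hw_genotypes(f, cfg$pop_sizes, n_per_pop)
        comp <- wc_components(g$dosages, g$pop_labels)
        theta[t + 1, r] <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
      }
    })
  }
  mt <- rowMeans(theta)
  out <- data.frame(generation = gens, mean_theta = mt,
                    sd_theta = apply(theta, 1, sd))
  fc <- NA_real_
  if (!is.null(threshold)) fc <- first_crossing(gens, mt, threshold)
  list(trajectory = out, first_crossing = fc)
}

# First point at which y(x) reaches `threshold`, linearly interpolated
# between grid points; NA if never reached.
first_crossing <- function(x, y, threshold) {
  hit <- which(y >= threshold)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(x[1])
  x[i - 1] + (x[i] - x[i - 1]) * (threshold - y[i - 1]) / (y[i] - y[i - 1])
}
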