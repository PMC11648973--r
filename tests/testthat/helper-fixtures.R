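# Shared fixtures and independent oracles for the test suite.

# Random genotype matrix with optional missingness; guarantees both alleles
# appear at every locus so dosage orientation is well defined.
random_genotypes <- function(n = 10, L = 20, pops = c("a", "b"),
                             miss = 0.1, seed = 1) {
  with_seed(seed, {
    repeat {
      d <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
      if (miss > 0) d[runif(n * L) < miss] <- NA
      counts <- colSums(d, na.rm = TRUE)
      tot <- 2 * colSums(!is.na(d))
      if (all(counts > 0 & counts < tot)) break
    }
    genotype_matrix(d, pop_labels = sort(rep(pops, length.out = n)))
  })
}

with_seed <- popdrift:::with_seed

# Straightforward loop implementation of the Weir & Cockerham (1984)
# variance components, written directly from the published definitions as an
# independent oracle for the vectorized version.
wc_theta_oracle <- function(dosages, labels) {
  pops <- unique(labels)
  A <- B <- C <- 0
  for (j in seq_len(ncol(dosages))) {
    n <- p <- h <- numeric(0)
    for (pp in pops) {
      d <- dosages[labels == pp, j]
      d <- d[!is.na(d)]
      if (!length(d)) next
      n <- c(n, length(d))
      p <- c(p, sum(d) / (2 * length(d)))
      h <- c(h, mean(d == 1))
    }
    r <- length(n)
    if (r < 2) next
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# Exhaustive rarefied allelic richness for one locus: enumerate every
# subsample of `g` gene copies from c1 copies of allele 1 and c2 of allele 2
# and count distinct alleles.
ar_oracle <- function(c1, c2, g) {
  genes <- c(rep(1, c1), rep(2, c2))
  subs <- combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# Two diverged populations with cluster-specific allele frequencies; for
# admixture model-selection checks.
structured_genotypes <- function(n_per_pop = 20, L = 150, K = 3,
                                 div = 0.4, seed = 1) {
  with_seed(seed, {
    freqs <- matrix(pmin(pmax(0.5 + matrix(rnorm(K * L, 0, div), K, L), 0.02), 0.98), K, L)
    d <- do.call(rbind, lapply(seq_len(K), function(k)
      matrix(rbinom(n_per_pop * L, 2, rep(freqs[k, ], each = n_per_pop)),
             n_per_pop, L)))
    genotype_matrix(d, pop_labels = rep(paste0("p", seq_len(K)), each = n_per_pop))
  })
}

# Tiny three-population simulation configuration for pipeline smoke tests.
tiny_sim <- function(n_replicates = 2, checkpoints = c(0, 5), seed = 1,
                     n_loci = 80)
  sim_config(pop_sizes = c(x = 20L, y = 30L, z = 40L), n_loci = n_loci,
             checkpoints = checkpoints, n_replicates = n_replicates,
             seed = seed)
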