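#' Effective sizes of the empirical population analogs
#'
#' Point estimates of effective population size for the 12 wild brook trout
#' populations and the hatchery strain used to parameterize the drift
#' simulations (the unnamed tributary is excluded because recent admixture
#' biases its LD-based estimate low). Names are the population codes;
#' `"SCF"` is the hatchery strain analog.
#'
#' @return named integer vector of 13 effective sizes.
#' @export
analog_pop_sizes <- function() {
  c(P1 = 26L,   # Ash Creek
    B1 = 31L,   # Byrds Creek
    P4 = 65L,   # Fancy Creek
    P5 = 114L,  # Gault Hollow
    O1 = 128L,  # Harker Creek
    P2 = 48L,   # Horse Creek
    MR1 = 535L, # Lawrence Creek
    SG1 = 79L,  # Lowery Creek
    P3 = 54L,   # Marshall Creek
    P6 = 45L,   # Melancthon Creek
    SF1 = 294L, # South Fork Hay River
    MC1 = 89L,  # West Branch Mill Creek
    SCF = 137L) # St. Croix Falls hatchery strain
}

#' Configuration for a Wright-Fisher drift simulation
#'
#' Pure drift from a common founding source: isolated diploid populations of
#' constant size, independent neutral biallelic loci, no mutation, migration,
#' or selection. Populations are monoecious with binomial gamete sampling, so
#' the parameterized size is realized exactly as the effective size.
#'
#' @param pop_sizes named vector of diploid population sizes (defaults to the
#'   empirical analogs, [analog_pop_sizes()]).
#' @param n_loci number of independent biallelic loci (default 500).
#' @param init_freq founding allele frequency in (0, 1) (default 0.5, i.e.
#'   maximal founding heterozygosity).
#' @param checkpoints sorted unique non-negative generations at which
#'   genotypes are emitted (default `c(0, 5, 10, 20, 30, 40, 50)`).
#' @param n_replicates number of independent simulation replicates.
#' @param seed master seed; per-replicate generators are derived from it so
#'   each replicate is reproducible in isolation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pop_sizes = analog_pop_sizes(), n_loci = 500,
                       init_freq = 0.5,
                       checkpoints = c(0, 5, 10, 20, 30, 40, 50),
                       n_replicates = 100, seed = 1) {
  if (any(pop_sizes < 2)) stop("pop_sizes must all be >= 2")
  if (!(init_freq > 0 && init_freq < 1)) stop("init_freq must be in (0, 1)")
  if (n_loci < 1) stop("n_loci must be >= 1")
  checkpoints <- as.integer(checkpoints)
  if (any(checkpoints < 0) || is.unsorted(checkpoints, strictly = TRUE))
    stop("checkpoints must be non-negative, sorted, unique")
  if (is.null(names(pop_sizes)))
    names(pop_sizes) <- paste0("pop", seq_along(pop_sizes))
  structure(list(pop_sizes = pop_sizes, n_loci = as.integer(n_loci),
                 init_freq = init_freq, checkpoints = checkpoints,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Founding allele frequencies
#'
#' Each of the 2N gene copies at each locus of each population is an
#' independent Bernoulli(`init_freq`) draw, so realized founding frequencies
#' vary around `init_freq` by binomial sampling error.
#'
#' @param cfg a [sim_config()].
#' @return `n_pops x n_loci` matrix of founding frequencies (uses the current
#'   RNG state; seed externally).
#' @export
init_founder_freqs <- function(cfg) {
  n_pops <- length(cfg$pop_sizes)
  f <- matrix(0, n_pops, cfg$n_loci,
              dimnames = list(names(cfg$pop_sizes), NULL))
  for (i in seq_len(n_pops)) {
    n2 <- 2 * cfg$pop_sizes[i]
    f[i, ] <- rbinom(cfg$n_loci, n2, cfg$init_freq) / n2
  }
  f
}

#' One generation of Wright-Fisher drift on allele frequencies
#'
#' For each population and locus independently the next-generation allele
#' count is Binomial(2N, p). Fixed loci (p = 0 or 1) are absorbing: there is
#' no mutation.
#'
#' @param freqs `n_pops x n_loci` frequency matrix.
#' @param pop_sizes diploid sizes, one per row of `freqs`.
#' @return updated frequency matrix.
#' @export
wf_step <- function(freqs, pop_sizes) {
  for (i in seq_len(nrow(freqs))) {
    n2 <- 2 * pop_sizes[i]
    freqs[i, ] <- rbinom(ncol(freqs), n2, freqs[i, ]) / n2
  }
  freqs
}

#' Materialize Hardy-Weinberg genotypes from population frequencies
#'
#' Samples `n_per_pop` diploid individuals per population (capped at the
#' population size), each genotype two independent gene copies at the current
#' frequency.
#'
#' @param freqs `n_pops x n_loci` frequency matrix with population rownames.
#' @param pop_sizes diploid sizes, one per row.
#' @param n_per_pop individuals to emit per population (default: all N).
#' @return a [genotype_matrix()].
#' @export
hw_genotypes <- function(freqs, pop_sizes, n_per_pop = NULL) {
  n_pops <- nrow(freqs)
  L <- ncol(freqs)
  ns <- if (is.null(n_per_pop)) pop_sizes else pmin(pop_sizes, n_per_pop)
  total <- sum(ns)
  dos <- matrix(0L, total, L)
  labs <- character(total)
  at <- 0
  for (i in seq_len(n_pops)) {
    idx <- at + seq_len(ns[i])
    dos[idx, ] <- matrix(rbinom(ns[i] * L, 2, rep(freqs[i, ], each = ns[i])),
                         ns[i], L)
    labs[idx] <- rownames(freqs)[i]
    at <- at + ns[i]
  }
  genotype_matrix(dos, pop_labels = labs)
}

#' Run the drift simulation
#'
#' Simulates allele-frequency trajectories for every replicate, emitting a
#' Hardy-Weinberg genotype sample at each checkpoint. Frequencies are
#' simulated directly (binomial per generation) between checkpoints: with
#' independent loci and free recombination no LD accrues, which matches the
#' design of independent neutral loci. Genotypes are delivered through
#' `callback(replicate, generation, g)` so large studies need not hold every
#' matrix in memory; when `store_genotypes = TRUE` they are also returned.
#'
#' @param cfg a [sim_config()].
#' @param n_per_pop genotype sample size per population at checkpoints
#'   (capped at N; `NULL` emits whole populations).
#' @param callback optional `function(replicate, generation, g)`.
#' @param store_genotypes keep emitted genotype matrices in the result.
#' @param record_freqs keep checkpoint frequency matrices in the result.
#' @return list with `config`, `trajectories` (data.frame: replicate,
#'   generation, population, mean_ho, mean_he — expected heterozygosity uses
#'   the current frequencies), and optionally `genotypes[[rep]][[gen]]` and
#'   `freqs[[rep]][[gen]]`.
#' @export
run_drift_sim <- function(cfg, n_per_pop = NULL, callback = NULL,
                          store_genotypes = FALSE, record_freqs = FALSE) {
  n_pops <- length(cfg$pop_sizes)
  gens <- cfg$checkpoints
  traj <- vector("list", cfg$n_replicates)
  genos <- if (store_genotypes) vector("list", cfg$n_replicates)
  fr <- if (record_freqs) vector("list", cfg$n_replicates)

  for (r in seq_len(cfg$n_replicates)) {
    rows <- with_seed(derive_seed(cfg$seed, 101L, r), {
      f <- init_founder_freqs(cfg)
      g_now <- 0L
      out <- list()
      for (ck in seq_along(gens)) {
        while (g_now < gens[ck]) {
          f <- wf_step(f, cfg$pop_sizes)
          g_now <- g_now + 1L
        }
        he <- 2 * f * (1 - f)
        out[[ck]] <- data.frame(
          replicate = r, generation = gens[ck],
          population = names(cfg$pop_sizes),
          mean_ho = NA_real_, mean_he = rowMeans(he),
          row.names = NULL)
        g <- hw_genotypes(f, cfg$pop_sizes, n_per_pop)
        out[[ck]]$mean_ho <- sapply(names(cfg$pop_sizes), function(p)
          mean(g$dosages[g$pop_labels == p, , drop = FALSE] == 1L))
        if (!is.null(callback)) callback(r, gens[ck], g)
        if (store_genotypes) {
          if (is.null(genos[[r]])) genos[[r]] <- list()
          genos[[r]][[as.character(gens[ck])]] <- g
        }
        if (record_freqs) {
          if (is.null(fr[[r]])) fr[[r]] <- list()
          fr[[r]][[as.character(gens[ck])]] <- f
        }
      }
      do.call(rbind, out)
    })
    traj[[r]] <- rows
  }

  res <- list(config = cfg, trajectories = do.call(rbind, traj))
  if (store_genotypes) res$genotypes <- genos
  if (record_freqs) res$freqs <- fr
  res
}

#' Individual-based Wright-Fisher simulation of a single population
#'
#' Tracks diploid genotypes explicitly: each offspring draws two parents
#' uniformly at random (monoecious, selfing allowed) and inherits one allele
#' per locus per parent with free recombination. Unlike the frequency-level
#' simulator, finite-size drift here generates the between-locus linkage
#' disequilibrium (E\[r2\] ~ 1/(3Ne) at unlinked loci) that LD-based Ne
#' estimation measures.
#'
#' @param n diploid population size.
#' @param n_loci number of unlinked biallelic loci.
#' @param n_gen generations to simulate.
#' @param init_freq founding allele frequency.
#' @param seed optional seed.
#' @param pop_label population label for the returned matrix.
#' @return a [genotype_matrix()] of the whole final-generation population.
#' @export
sim_wf_population <- function(n, n_loci, n_gen, init_freq = 0.5, seed = NULL,
                              pop_label = "pop1") {
  with_seed(seed, {
    dos <- matrix(rbinom(n * n_loci, 2, init_freq), n, n_loci)
    for (t in seq_len(n_gen)) {
      mothers <- sample.int(n, n, replace = TRUE)
      fathers <- sample.int(n, n, replace = TRUE)
      a1 <- rbinom(n * n_loci, 1, dos[mothers, ] / 2)
      a2 <- rbinom(n * n_loci, 1, dos[fathers, ] / 2)
      dos <- matrix(a1 + a2, n, n_loci)
    }
    genotype_matrix(dos, pop_labels = rep(pop_label, n))
  })
}
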