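#' Configuration of the full drift-confounding study
#'
#' Bundles the simulation design with the analysis settings: subsample size,
#' the K used for the population-assignment analysis (defaults to the number
#' of populations), the K range and folds for cross-validation, EM restarts,
#' and the FST threshold whose first crossing is reported (the empirical
#' overall FST by default).
#'
#' @param sim a [sim_config()].
#' @param subsample_n individuals analysed per population (default 25).
#' @param k_fit K for the assignment analysis (default: number of
#'   populations).
#' @param k_range K values scanned by cross-validation.
#' @param cv_folds folds for cross-validation (default 5).
#' @param cv_replicates simulation replicates used for the CV stage (0 skips
#'   it; it is by far the most expensive stage).
#' @param cv_generations generations at which the CV stage runs (default: all
#'   checkpoints).
#' @param n_restarts EM random restarts per fit.
#' @param em_max_iter,em_tol iteration cap and relative tolerance for the
#'   assignment-stage EM fits. Fits on structured data converge well within
#'   the cap; fits on unstructured (early-generation) data plateau in a flat
#'   likelihood region where population-mean ancestry no longer moves.
#' @param fst_threshold FST level for the first-crossing summary.
#' @param hatchery_pop label of the hatchery-strain analog.
#' @param q_digits optional decimal precision at which per-individual
#'   ancestry proportions enter the averaging stage (emulating the precision
#'   of interchanged ancestry files). `NULL` (default) leaves them as
#'   estimated.
#' @param seed master seed.
#' @return a `study_config` list.
#' @export
study_config <- function(sim = sim_config(), subsample_n = 25,
                         k_fit = length(sim$pop_sizes), k_range = 1:15,
                         cv_folds = 5, cv_replicates = 0,
                         cv_generations = sim$checkpoints,
                         n_restarts = 3, em_max_iter = 400, em_tol = 1e-6,
                         fst_threshold = 0.118,
                         hatchery_pop = "SCF", q_digits = NULL,
                         seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"), subsample_n >= 1, cv_folds >= 2)
  if (!hatchery_pop %in% names(sim$pop_sizes))
    stop("hatchery_pop must name one of the simulated populations")
  structure(list(sim = sim, subsample_n = subsample_n, k_fit = k_fit,
                 k_range = k_range, cv_folds = cv_folds,
                 cv_replicates = cv_replicates,
                 cv_generations = cv_generations,
                 n_restarts = n_restarts, em_max_iter = em_max_iter,
                 em_tol = em_tol, fst_threshold = fst_threshold,
                 hatchery_pop = hatchery_pop, q_digits = q_digits,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the drift-confounding study
#'
#' End-to-end pipeline over the simulated metapopulation: simulate drift,
#' subsample individuals, fit the K = n_pops admixture model per replicate
#' and generation, align clusters within generations and across generations
#' to the final-generation reference, average Q within populations, build
#' both assignment responses (each wild population's own distinct cluster,
#' and the hatchery analog's cluster), and fit the nested beta-regression
#' model tables. Optionally runs the cross-validation stage for the
#' best-supported K per generation.
#'
#' @param cfg a [study_config()].
#' @param progress print stage progress.
#' @return a `drift_study` list: `config`, `trajectories`, `mean_q` (named
#'   list per generation of population x cluster tables, aligned),
#'   `cluster_of` (population -> cluster map from the final generation),
#'   `distinct_data` / `hatchery_data` (regression datasets),
#'   `distinct_models` / `hatchery_models` (model tables), and optionally
#'   `cv` (per-generation CV curves and replicate-mode best K).
#' @export
run_study <- function(cfg, progress = interactive()) {
  sim <- cfg$sim
  pops <- names(sim$pop_sizes)
  gens <- sim$checkpoints
  R <- sim$n_replicates
  say <- function(...) if (progress) message(sprintf(...))

  # stage 1-2: simulate and fit, accumulating per-(generation, replicate)
  # population-mean Q tables
  say("simulating %d replicates and fitting K = %d models", R, cfg$k_fit)
  pm <- lapply(gens, function(g) vector("list", R))
  names(pm) <- as.character(gens)
  # Hardy-Weinberg checkpoint samples of subsample_n individuals are drawn
  # directly from the population frequencies (a random subset of exchangeable
  # HW draws is itself a set of HW draws)
  traj <- run_drift_sim(sim, n_per_pop = cfg$subsample_n,
                        callback = function(r, gen, gs) {
    fit <- fit_admixture(gs, cfg$k_fit,
                         seed = derive_seed(cfg$seed, 29L, r, gen),
                         n_restarts = cfg$n_restarts,
                         max_iter = cfg$em_max_iter, tol = cfg$em_tol)
    if (!is.null(cfg$q_digits)) fit$Q <- round(fit$Q, cfg$q_digits)
    pm[[as.character(gen)]][[r]] <<- average_q(fit, gs$pop_labels)[pops, , drop = FALSE]
  })$trajectories

  # stage 3: build the final-generation reference (where populations are
  # distinct), then align every run of every generation directly to it
  say("aligning replicates and generations")
  last <- pm[[length(pm)]]
  ref0 <- last[[1]]
  final <- Reduce(`+`, lapply(last, function(m)
    m[, match_columns(m, ref0)])) / length(last)
  mean_q <- lapply(pm, function(tables) {
    aligned <- lapply(tables, function(m) m[, match_columns(m, final)])
    Reduce(`+`, aligned) / length(aligned)
  })

  # stage 4: population -> cluster map and the two responses
  cluster_of <- distinct_cluster_assignment(mean_q[[length(mean_q)]])
  wild <- setdiff(pops, cfg$hatchery_pop)
  hatch_cluster <- cluster_of[cfg$hatchery_pop]

  rows_distinct <- do.call(rbind, lapply(names(mean_q), function(gn) {
    m <- mean_q[[gn]]
    data.frame(population = wild, ne = unname(sim$pop_sizes[wild]),
               generations = as.integer(gn),
               y = vapply(wild, function(p) m[p, cluster_of[p]], 0))
  }))
  rows_hatch <- do.call(rbind, lapply(names(mean_q), function(gn) {
    m <- mean_q[[gn]]
    data.frame(population = wild, ne = unname(sim$pop_sizes[wild]),
               generations = as.integer(gn),
               y = m[wild, hatch_cluster])
  }))

  say("fitting nested beta regressions")
  distinct_data <- regression_dataset(rows_distinct$population,
                                      rows_distinct$ne,
                                      rows_distinct$generations,
                                      rows_distinct$y)
  hatchery_data <- regression_dataset(rows_hatch$population, rows_hatch$ne,
                                      rows_hatch$generations, rows_hatch$y)
  res <- list(config = cfg,
              trajectories = traj,
              mean_q = mean_q,
              cluster_of = cluster_of,
              distinct_data = distinct_data,
              hatchery_data = hatchery_data,
              distinct_models = model_table(distinct_data),
              hatchery_models = model_table(hatchery_data))

  # stage 5 (optional): cross-validated K per generation
  if (cfg$cv_replicates > 0) {
    say("cross-validation stage (%d replicates)", cfg$cv_replicates)
    res$cv <- cv_study(cfg)
  }
  class(res) <- "drift_study"
  res
}

#' Cross-validated best K per generation
#'
#' For each requested generation, re-simulates `cv_replicates` replicates,
#' runs K-fold cross-validation over `k_range` on each, and reports the mean
#' CV curve and the replicate-mode best K.
#'
#' @param cfg a [study_config()] with `cv_replicates > 0`.
#' @param generations generations to evaluate (default `cfg$cv_generations`).
#' @return list with `curves` (data.frame generation, K, mean_cv_error),
#'   `best_k` (data.frame generation, best_k_mode, best_k per replicate in
#'   `by_replicate`).
#' @export
cv_study <- function(cfg, generations = cfg$cv_generations) {
  sim <- cfg$sim
  sim$n_replicates <- cfg$cv_replicates
  gens_chr <- as.character(generations)
  errs <- list()  # [[gen]][[rep]] = vector over k_range
  for (gn in gens_chr) errs[[gn]] <- vector("list", cfg$cv_replicates)
  run_drift_sim(sim, n_per_pop = cfg$subsample_n,
                callback = function(r, gen, gs) {
    if (!as.character(gen) %in% gens_chr) return(invisible())
    e <- vapply(cfg$k_range, function(k)
      as.numeric(cv_error(gs, k, folds = cfg$cv_folds,
                          seed = derive_seed(cfg$seed, 37L, r, gen),
                          n_restarts = 1, max_iter = 300, tol = 1e-5)), 0)
    errs[[as.character(gen)]][[r]] <<- e
  })
  curves <- do.call(rbind, lapply(gens_chr, function(gn) {
    m <- do.call(rbind, errs[[gn]])
    data.frame(generation = as.integer(gn), K = cfg$k_range,
               mean_cv_error = colMeans(m))
  }))
  by_rep <- do.call(rbind, lapply(gens_chr, function(gn) {
    data.frame(generation = as.integer(gn),
               replicate = seq_len(cfg$cv_replicates),
               best_k = vapply(errs[[gn]], function(e)
                 cfg$k_range[which.min(e)], 0L))
  }))
  mode_k <- function(x) as.integer(names(which.max(table(x))))
  best <- do.call(rbind, lapply(split(by_rep, by_rep$generation), function(d)
    data.frame(generation = d$generation[1], best_k_mode = mode_k(d$best_k))))
  rownames(best) <- NULL
  list(curves = curves, best_k = best, by_replicate = by_rep)
}

#' Replicate-averaged trajectory summaries
#'
#' Per generation, across replicates: mean and SD of the global
#' Weir-Cockerham theta, pooled expected heterozygosity (Ht), pooled observed
#' heterozygosity (Ho) and mean within-population observed heterozygosity
#' (Hs) of the emitted genotype samples, plus the first crossing of an FST
#' threshold (linear interpolation between checkpoints). SD columns are `NA`
#' with a single replicate.
#'
#' @param cfg a [sim_config()].
#' @param n_per_pop genotype sample per population.
#' @param fst_threshold threshold for the first-crossing summary.
#' @return list with `summary` (data.frame per generation) and
#'   `first_crossing`.
#' @export
trajectory_summaries <- function(cfg, n_per_pop = 25, fst_threshold = 0.118) {
  rows <- list()
  run_drift_sim(cfg, n_per_pop = n_per_pop, callback = function(r, gen, g) {
    comp <- wc_components(g$dosages, g$pop_labels)
    theta <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
    p_all <- colMeans(g$dosages) / 2
    ht <- mean(2 * p_all * (1 - p_all))
    ho <- mean(g$dosages == 1L)
    hs <- mean(vapply(unique(g$pop_labels), function(p)
      mean(g$dosages[g$pop_labels == p, , drop = FALSE] == 1L), 0))
    rows[[length(rows) + 1]] <<- data.frame(replicate = r, generation = gen,
                                            theta = theta, ht = ht, ho = ho,
                                            hs = hs)
  })
  d <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(d, d$generation), function(x) {
    sdx <- function(v) if (nrow(x) > 1) sd(v) else NA_real_
    data.frame(generation = x$generation[1],
               mean_theta = mean(x$theta), sd_theta = sdx(x$theta),
               mean_ht = mean(x$ht), sd_ht = sdx(x$ht),
               mean_ho = mean(x$ho), sd_ho = sdx(x$ho),
               mean_hs = mean(x$hs), sd_hs = sdx(x$hs))
  }))
  agg <- agg[order(agg$generation), ]
  rownames(agg) <- NULL
  list(summary = agg,
       first_crossing = first_crossing(agg$generation, agg$mean_theta,
                                       fst_threshold))
}

#' Empirical-style analysis of a genotype matrix
#'
#' The analysis chain applied to an empirical (or simulated) multi-population
#' genotype matrix: diversity table, LD-based Ne per population, pairwise and
#' global Weir-Cockerham FST, a neighbor-joining tree on Nei's DA with
#' bootstrap support, a Mantel isolation-by-distance test (skipped with a
#' warning if no distance matrix is supplied), and cross-validated admixture
#' fits over a K range. Single-population inputs skip the FST/tree/IBD stages
#' with warnings.
#'
#' @param g a filtered [genotype_matrix()].
#' @param distances optional [dist_matrix()] of waterway distances.
#' @param k_range K values scanned by cross-validation (`NULL` skips the
#'   clustering stage).
#' @param n_boot NJ bootstrap replicates.
#' @param n_perm Mantel permutations.
#' @param seed master seed.
#' @return list with `diversity`, `ne`, `fst`, `nj_newick`, `mantel`, `cv`,
#'   `fit` (admixture fit at the CV-best K).
#' @export
run_empirical <- function(g, distances = NULL, k_range = 1:20,
                          n_boot = 1000, n_perm = 999, seed = 1) {
  pops <- unique(g$pop_labels)
  res <- list(diversity = diversity(g))
  res$ne <- do.call(rbind, lapply(pops, function(p) {
    est <- tryCatch(estimate_ne(subset_genotypes(g, rows = which(g$pop_labels == p)),
                                exclude_same_group = !is.null(g$linkage_group)),
                    error = function(e) NULL)
    if (is.null(est)) return(data.frame(population = p, ne_point = NA,
                                        ci_low = NA, ci_high = NA, n_pairs = NA))
    data.frame(population = p, ne_point = est$ne_point, ci_low = est$ci_low,
               ci_high = est$ci_high, n_pairs = est$n_pairs)
  }))
  if (length(pops) >= 2) {
    res$fst <- wc_fst(g)
  } else warning("single population: FST stage skipped")
  if (length(pops) >= 3) {
    res$nj_newick <- nj_tree(g, bootstrap = n_boot,
                             seed = derive_seed(seed, 41L))
  } else warning("fewer than 3 populations: NJ stage skipped")
  if (!is.null(distances) && length(pops) >= 4) {
    res$mantel <- mantel_ibd(res$fst$pairwise, distances, n_perm = n_perm,
                             seed = derive_seed(seed, 43L))
  } else if (is.null(distances)) {
    warning("no distance matrix supplied: IBD stage skipped")
  }
  if (!is.null(k_range)) {
    res$cv <- choose_k(g, k_range = k_range,
                       seed = derive_seed(seed, 47L), n_restarts = 1,
                       max_iter = 200, tol = 1e-5)
    res$fit <- fit_admixture(g, res$cv$best_k, seed = derive_seed(seed, 53L))
  }
  res
}
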