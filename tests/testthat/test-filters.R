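test_that("loci below the minor allele count threshold are removed", {
  # locus 1: one heterozygote among 6 individuals -> mac = 1 < 3
  d <- cbind(c(1L, 0L, 0L, 0L, 0L, 0L),
             c(1L, 1L, 1L, 0L, 2L, 0L))
  g <- genotype_matrix(d, rep("a", 6))
  out <- filter_genotypes(g, filter_config(min_mac = 3,
                                           min_locus_call_rate_per_pop = 0,
                                           min_ind_call_rate = 0))
  expect_equal(out$locus_ids, "L2")
  rep <- attr(out, "filter_report")
  expect_equal(rep$loci_removed[rep$step == "min_mac"], 1L)
})

test_that("a clean matrix passes through unchanged and filtering is idempotent", {
  with_seed(4, {
    d <- matrix(rbinom(12 * 10, 2, 0.5), 12, 10)
  })
  g <- genotype_matrix(d, rep(c("a", "b"), each = 6))
  stopifnot(all(apply(d, 2, function(x) min(sum(x), 24 - sum(x))) >= 3))
  once <- filter_genotypes(g)
  expect_identical(once$dosages, g$dosages)
  twice <- filter_genotypes(once)
  expect_identical(twice$dosages, once$dosages)
  expect_identical(twice$pop_labels, once$pop_labels)
})

test_that("sequential filters match a manual application on a planted matrix", {
  # 6 individuals (2 pops), 5 loci with planted violations
  d <- rbind(
    c(1L, 1L, NA, 1L, NA),
    c(0L, 1L, NA, 1L, 2L),
    c(0L, 1L, NA, 1L, 0L),
    c(0L, 1L, 1L, NA, NA),   # row with many gaps
    c(0L, 1L, 1L, NA, 2L),
    c(0L, 1L, 1L, NA, 0L))
  g <- genotype_matrix(d, rep(c("a", "b"), each = 3))
  cfg <- filter_config(min_mac = 2, min_locus_call_rate_per_pop = 0.5,
                       min_ind_call_rate = 0.7)

  # manual sequential application of the three rules
  mac <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]; min(sum(x), 2 * length(x) - sum(x))
  })
  keep1 <- mac >= 2                      # locus 1 (mac 1) drops
  d1 <- d[, keep1, drop = FALSE]
  cr_a <- colMeans(!is.na(d1[1:3, , drop = FALSE]))
  cr_b <- colMeans(!is.na(d1[4:6, , drop = FALSE]))
  keep2 <- cr_a >= 0.5 & cr_b >= 0.5     # planted all-NA-in-pop-a locus drops
  d2 <- d1[, keep2, drop = FALSE]
  keep3 <- rowMeans(!is.na(d2)) >= 0.7
  d3 <- d2[keep3, , drop = FALSE]

  out <- filter_genotypes(g, cfg)
  expect_identical(out$dosages, d3)
  rep <- attr(out, "filter_report")
  expect_equal(sum(rep$loci_removed), ncol(d) - ncol(d3))
  expect_equal(sum(rep$individuals_removed), nrow(d) - nrow(d3))
})

test_that("one SNP per contig keeps the highest-MAF SNP", {
  d <- cbind(c(0L, 0L, 1L, 1L), # maf 0.25
             c(0L, 1L, 1L, 1L), # maf 0.375 <- winner on contig c1
             c(1L, 1L, 1L, 1L)) # maf 0.5   <- only SNP on contig c2
  g <- genotype_matrix(d, rep("a", 4), contig_id = c("c1", "c1", "c2"))
  out <- filter_genotypes(g, filter_config(min_mac = 0,
                                           min_locus_call_rate_per_pop = 0,
                                           min_ind_call_rate = 0,
                                           one_snp_per_contig = TRUE))
  expect_equal(out$locus_ids, c("L2", "L3"))
})

test_that("removing every locus is an error, not an empty matrix", {
  d <- matrix(0L, 4, 3); d[1, ] <- 1L
  g <- genotype_matrix(d, rep("a", 4))
  expect_error(filter_genotypes(g, filter_config(min_mac = 3)), "all loci")
})

test_that("subsampling is reproducible, exact, and errors on small populations", {
  g <- random_genotypes(n = 12, L = 6, pops = c("a", "b"), miss = 0, seed = 2)
  s1 <- subsample_individuals(g, 4, seed = 7)
  s2 <- subsample_individuals(g, 4, seed = 7)
  expect_identical(s1$dosages, s2$dosages)
  expect_equal(unname(table(s1$pop_labels)[c("a", "b")]), c(4L, 4L),
               ignore_attr = TRUE)
  expect_error(subsample_individuals(g, 7), "a")
  # n_per_pop equal to the population size is the identity up to ordering
  s3 <- subsample_individuals(g, 6)
  expect_identical(s3$dosages[order(s3$ind_ids), ],
                   g$dosages[order(g$ind_ids), ])
})
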