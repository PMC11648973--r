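#' Genotype filter configuration
#'
#' The standard RAD filtering chain applied sequentially: drop loci with a
#' minor allele count below `min_mac`, drop loci genotyped in fewer than
#' `min_locus_call_rate_per_pop` of individuals in any population, drop
#' individuals genotyped at fewer than `min_ind_call_rate` of loci, then
#' optionally keep one SNP per contig (the one with the highest minor allele
#' frequency).
#'
#' @param min_mac minimum minor allele count (default 3).
#' @param min_locus_call_rate_per_pop minimum per-population locus call rate
#'   (default 0.7).
#' @param min_ind_call_rate minimum per-individual call rate (default 0.5).
#' @param one_snp_per_contig keep only the highest-MAF SNP on each contig.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_mac = 3,
                          min_locus_call_rate_per_pop = 0.7,
                          min_ind_call_rate = 0.5,
                          one_snp_per_contig = FALSE) {
  stopifnot(min_mac >= 0,
            min_locus_call_rate_per_pop >= 0, min_locus_call_rate_per_pop <= 1,
            min_ind_call_rate >= 0, min_ind_call_rate <= 1)
  structure(list(min_mac = min_mac,
                 min_locus_call_rate_per_pop = min_locus_call_rate_per_pop,
                 min_ind_call_rate = min_ind_call_rate,
                 one_snp_per_contig = isTRUE(one_snp_per_contig)),
            class = "filter_config")
}

#' Apply the sequential genotype filters
#'
#' Filters are applied strictly in order (MAC, per-population locus call
#' rate, individual call rate, one SNP per contig); each step sees the matrix
#' left by the previous one. The attached report records how many loci and
#' individuals each step removed.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return a [genotype_matrix()] with attribute `"filter_report"`, a
#'   data.frame of per-step removal counts.
#' @export
filter_genotypes <- function(g, cfg = filter_config()) {
  report <- data.frame(step = character(0), loci_removed = integer(0),
                       individuals_removed = integer(0))
  note <- function(step, loci = 0L, inds = 0L) {
    rbind(report, data.frame(step = step, loci_removed = as.integer(loci),
                             individuals_removed = as.integer(inds)))
  }

  # 1. minor allele count
  mac <- apply(g$dosages, 2, function(d) {
    d <- d[!is.na(d)]
    cnt <- sum(d)
    min(cnt, 2 * length(d) - cnt)
  })
  keep <- mac >= cfg$min_mac
  report <- note("min_mac", sum(!keep))
  g <- subset_genotypes(g, cols = which(keep))
  if (ncol(g$dosages) == 0) stop("all loci removed by the MAC filter")

  # 2. per-population locus call rate
  pops <- unique(g$pop_labels)
  rate <- sapply(pops, function(p)
    colMeans(!is.na(g$dosages[g$pop_labels == p, , drop = FALSE])))
  rate <- matrix(rate, ncol = length(pops))
  keep <- apply(rate >= cfg$min_locus_call_rate_per_pop, 1, all)
  report <- note("locus_call_rate_per_pop", sum(!keep))
  g <- subset_genotypes(g, cols = which(keep))
  if (ncol(g$dosages) == 0) stop("all loci removed by the call-rate filter")

  # 3. individual call rate
  irate <- rowMeans(!is.na(g$dosages))
  keep <- irate >= cfg$min_ind_call_rate
  report <- note("ind_call_rate", 0L, sum(!keep))
  g <- subset_genotypes(g, rows = which(keep))
  if (nrow(g$dosages) == 0) stop("all individuals removed by the call-rate filter")

  # 4. one SNP per contig, keeping the highest-MAF SNP
  if (cfg$one_snp_per_contig && !is.null(g$contig_id)) {
    m <- maf(g)
    ord <- order(g$contig_id, -m, g$locus_ids)  # ties: stable by locus id
    first <- !duplicated(g$contig_id[ord])
    keep_cols <- sort(ord[first])
    report <- note("one_snp_per_contig", ncol(g$dosages) - length(keep_cols))
    g <- subset_genotypes(g, cols = keep_cols)
  }

  attr(g, "filter_report") <- report
  g
}
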