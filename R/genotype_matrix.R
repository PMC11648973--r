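#' Multi-population diploid biallelic genotype matrix
#'
#' The central data container: an `n_individuals x n_loci` integer matrix of
#' allele dosages (0, 1, 2, or `NA` for missing) with per-individual
#' population labels and per-locus metadata. The dosage counts copies of one
#' of the two alleles at each biallelic locus.
#'
#' @param dosages integer matrix (individuals x loci) with values in
#'   \{0, 1, 2\} or `NA`.
#' @param pop_labels character vector of population identifiers, one per row.
#' @param locus_ids unique locus identifiers, one per column. Defaults to
#'   existing column names or `L1..Ln`.
#' @param linkage_group optional per-locus linkage-group labels (used to
#'   exclude within-group comparisons in LD-based Ne estimation).
#' @param contig_id optional per-locus contig labels (used by the
#'   one-SNP-per-contig filter).
#' @param ind_ids optional individual identifiers.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `pop_labels`, `locus_ids`, `linkage_group`, `contig_id`,
#'   `ind_ids`.
#' @export
genotype_matrix <- function(dosages, pop_labels, locus_ids = NULL,
                            linkage_group = NULL, contig_id = NULL,
                            ind_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found invalid values")
  if (length(pop_labels) != nrow(dosages))
    stop("pop_labels must have one entry per individual")
  if (any(is.na(pop_labels)) || any(!nzchar(pop_labels)))
    stop("pop_labels must be non-empty")
  if (is.null(locus_ids)) {
    locus_ids <- colnames(dosages)
    if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(dosages)))
  }
  if (length(locus_ids) != ncol(dosages))
    stop("locus_ids must have one entry per locus")
  if (anyDuplicated(locus_ids))
    stop("locus_ids must be unique")
  if (!is.null(linkage_group) && length(linkage_group) != ncol(dosages))
    stop("linkage_group must have one entry per locus")
  if (!is.null(contig_id) && length(contig_id) != ncol(dosages))
    stop("contig_id must have one entry per locus")
  if (is.null(ind_ids))
    ind_ids <- paste0(pop_labels, "_", stats::ave(seq_along(pop_labels),
                                                  pop_labels, FUN = seq_along))
  dimnames(dosages) <- NULL
  structure(
    list(dosages = dosages,
         pop_labels = as.character(pop_labels),
         locus_ids = as.character(locus_ids),
         linkage_group = if (is.null(linkage_group)) NULL else as.character(linkage_group),
         contig_id = if (is.null(contig_id)) NULL else as.character(contig_id),
         ind_ids = as.character(ind_ids)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d populations\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$pop_labels))))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing: %.1f%%; populations: %s\n", 100 * miss,
              paste(unique(x$pop_labels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Per-locus minor allele frequency
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector in \[0, 0.5\], one value per locus (NaN for loci
#'   with no data).
#' @export
maf <- function(g) {
  p <- colMeans(g$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

# Row/column subset preserving metadata.
subset_genotypes <- function(g, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(g$dosages))
  if (is.null(cols)) cols <- seq_len(ncol(g$dosages))
  genotype_matrix(g$dosages[rows, cols, drop = FALSE],
                  g$pop_labels[rows],
                  g$locus_ids[cols],
                  linkage_group = g$linkage_group[cols],
                  contig_id = g$contig_id[cols],
                  ind_ids = g$ind_ids[rows])
}

#' Random subsample of individuals within each population
#'
#' Draws exactly `n_per_pop` individuals from every population, reproducibly
#' under a fixed seed. Mirrors the study design of analysing a random subset
#' of 25 fish per population.
#'
#' @param g a [genotype_matrix()].
#' @param n_per_pop number of individuals to keep per population.
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] with `n_per_pop` rows per population, in
#'   population order of first appearance.
#' @export
subsample_individuals <- function(g, n_per_pop, seed = NULL) {
  pops <- unique(g$pop_labels)
  sizes <- table(g$pop_labels)[pops]
  small <- pops[sizes[pops] < n_per_pop]
  if (length(small))
    stop("population(s) smaller than n_per_pop: ", paste(small, collapse = ", "))
  rows <- with_seed(seed, {
    unlist(lapply(pops, function(p) {
      idx <- which(g$pop_labels == p)
      sort(sample(idx, n_per_pop))
    }))
  })
  subset_genotypes(g, rows = rows)
}

#' Read a delimited dosage matrix
#'
#' CSV layout: one row per individual; first two columns are `id` and `pop`,
#' remaining columns are per-locus dosages (0/1/2, empty or NA for missing).
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_dosage_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("expected columns id, pop, <loci...>")
  genotype_matrix(as.matrix(d[, -(1:2), drop = FALSE]),
                  pop_labels = d[[2]],
                  locus_ids = colnames(d)[-(1:2)],
                  ind_ids = d[[1]])
}

#' Write a genotype matrix as a delimited dosage CSV
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(g, path) {
  d <- data.frame(id = g$ind_ids, pop = g$pop_labels,
                  g$dosages, check.names = FALSE)
  colnames(d)[-(1:2)] <- g$locus_ids
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
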