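#' Labelled symmetric distance matrix
#'
#' Thin wrapper validating symmetry and a zero diagonal. Genetic distance
#' estimates (e.g. Weir-Cockerham pairwise theta) may be slightly negative;
#' negative off-diagonals are flagged with an attribute rather than rejected,
#' while geographic matrices can be validated strictly via `non_negative`.
#'
#' @param values square numeric matrix.
#' @param labels population identifiers (defaults to rownames).
#' @param non_negative error on negative off-diagonal entries.
#' @return a `dist_matrix`: the numeric matrix with dimnames set and class
#'   attribute.
#' @export
dist_matrix <- function(values, labels = rownames(values), non_negative = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("pop", seq_len(nrow(values)))
  if (length(labels) != nrow(values)) stop("labels must match matrix dimension")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  neg <- any(values[upper.tri(values)] < 0, na.rm = TRUE)
  if (neg && non_negative) stop("negative off-diagonal distances not allowed")
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix"),
            has_negative = neg)
}

#' Read a square distance matrix from CSV
#'
#' Expects a header row and a first column of matching population labels.
#'
#' @param path file path.
#' @param non_negative passed to [dist_matrix()].
#' @return a [dist_matrix()].
#' @export
read_dist_csv <- function(path, non_negative = FALSE) {
  d <- read.csv(path, row.names = 1, check.names = FALSE)
  dist_matrix(as.matrix(d), labels = rownames(d), non_negative = non_negative)
}

#' @export
write_dist_csv <- function(d, path) {
  write.csv(as.matrix(unclass(d)), path, row.names = TRUE)
  invisible(path)
}
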