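#' Read a genepop file
#'
#' Parses the classical genepop dialect: a title line, locus names (one per
#' line or comma-separated on one line), `POP` separators, and individual
#' lines `id , a1a2 a1a2 ...` with 2- or 3-digit allele codes (`00`/`000` =
#' missing). Only biallelic loci are supported; the dosage counts copies of
#' the lexicographically larger allele code, which is deterministic and
#' internal to the format (genepop carries no reference/alternate notion).
#'
#' Population labels: genepop files do not name populations, so each block is
#' labelled by its first individual's id with any trailing `_<number>`
#' stripped (the convention [write_genepop()] emits), making write/read
#' round-trips exact.
#'
#' @param path file path.
#' @return a [genotype_matrix()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("not a genepop file (too short): ", path)
  is_pop <- toupper(trimws(lines)) %in% c("POP", "POPS")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found in ", path)

  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  n_loci <- length(loci)
  if (n_loci == 0) stop("no locus names found in ", path)

  pop_index <- cumsum(is_pop)
  body <- which(!is_pop & seq_along(lines) > first_pop & nzchar(trimws(lines)))
  if (!length(body)) {
    # header-only file: zero individuals
    return(genotype_matrix(matrix(NA_integer_, 0, n_loci),
                           pop_labels = character(0), locus_ids = loci))
  }

  n <- length(body)
  ids <- character(n)
  blocks <- pop_index[body]
  allele1 <- matrix(NA_character_, n, n_loci)
  allele2 <- matrix(NA_character_, n, n_loci)
  for (i in seq_len(n)) {
    ln <- lines[body[i]]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("malformed genepop line %d (no comma): %s", body[i], ln))
    ids[i] <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(gts) != n_loci)
      stop(sprintf("malformed genepop line %d: %d genotypes for %d loci",
                   body[i], length(gts), n_loci))
    w <- nchar(gts)
    if (any(w != w[1]) || !(w[1] %in% c(4L, 6L)))
      stop(sprintf("malformed genepop line %d: allele codes must be 2 or 3 digits",
                   body[i]))
    half <- w[1] / 2
    allele1[i, ] <- substr(gts, 1, half)
    allele2[i, ] <- substr(gts, half + 1, w[1])
  }

  zero <- function(a) grepl("^0+$", a)
  dosages <- matrix(NA_integer_, n, n_loci)
  for (j in seq_len(n_loci)) {
    a <- c(allele1[, j], allele2[, j])
    codes <- sort(unique(a[!zero(a)]))
    if (length(codes) > 2)
      stop(sprintf("locus %s has more than 2 alleles: %s",
                   loci[j], paste(codes, collapse = ", ")))
    if (length(codes) == 0) next
    big <- codes[length(codes)]
    a1 <- allele1[, j]; a2 <- allele2[, j]
    miss <- zero(a1) | zero(a2)
    dosages[, j] <- (a1 == big) + (a2 == big)
    dosages[miss, j] <- NA_integer_
  }

  pop_of_block <- tapply(ids, blocks, function(x) sub("_[0-9]+$", "", x[1]))
  labels <- as.character(pop_of_block[as.character(blocks)])
  # keep distinct blocks distinct even if their derived labels collide
  if (length(unique(labels)) < length(unique(blocks))) {
    labels <- paste0(labels, ".", blocks)
  }
  genotype_matrix(dosages, pop_labels = labels, locus_ids = loci, ind_ids = ids)
}

#' Write a genotype matrix as a genepop file
#'
#' Mirror of [read_genepop()]: emits 2-digit allele codes `01`/`02` (dosage =
#' copies of `02`), `0000` for missing, one `POP` separator per population
#' block, and individual ids `<pop>_<k>`. Output is byte-deterministic for a
#' fixed input.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "popdrift genepop export") {
  code <- c(`0` = "0101", `1` = "0102", `2` = "0202")
  out <- c(title, g$locus_ids)
  pops <- unique(g$pop_labels)
  for (p in pops) {
    out <- c(out, "POP")
    rows <- which(g$pop_labels == p)
    for (k in seq_along(rows)) {
      d <- g$dosages[rows[k], ]
      gt <- ifelse(is.na(d), "0000", code[as.character(d)])
      out <- c(out, paste0(p, "_", k, " ,  ", paste(gt, collapse = " ")))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
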