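#' Construct a count table
#'
#' A `count_table` is a non-negative integer matrix with samples in rows and
#' taxa in columns, tagged with the taxonomic rank of its columns. It is the
#' object every community statistic in the package consumes.
#'
#' @param counts numeric matrix (samples x taxa) of non-negative integers;
#'   must carry row (sample) and column (taxon) names.
#' @param rank taxonomic level of the columns, e.g. "genus" or "OTU".
#' @return a `count_table`.
#' @export
count_table <- function(counts, rank = "genus") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count_table needs sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate sample ids in count table")
  if (any(counts < 0)) stopf("negative counts in count table")
  if (any(abs(counts - round(counts)) > 1e-8))
    stopf("non-integer counts in count table")
  storage.mode(counts) <- "integer"
  structure(counts, rank = rank, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (rank: %s), depth %d-%d\n",
              nrow(x), ncol(x), attr(x, "rank"),
              min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

# subsetting keeps class and rank
#' @export
`[.count_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, rank = attr(x, "rank"),
            class = c("count_table", "matrix", "array"))
}

#' Read / write count tables
#'
#' Interchange format: TSV with taxa in rows; first column `taxon` holds the
#' lineage label, remaining columns are samples. Lines starting with `#` are
#' header metadata and are skipped on read.
#'
#' @param path file path.
#' @param rank taxonomic rank tag to attach.
#' @return a `count_table`.
#' @export
read_counts <- function(path, rank = "genus") {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df[[1]]
  count_table(m, rank = rank)
}

#' @param table a `count_table`.
#' @param header optional character vector of `#`-prefixed metadata lines.
#' @rdname read_counts
#' @export
write_counts <- function(table, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(taxon = colnames(table), t(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_tsv_plain <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Rarefy a count table to even depth
#'
#' Subsamples every sample's reads without replacement (hypergeometric, one
#' draw per sample) so that all totals equal `depth` — the "normalize to the
#' sample with the lowest number of reads" convention.
#'
#' @param table a `count_table`.
#' @param depth target reads per sample; must not exceed any sample's total.
#'   Default: the minimum sample total.
#' @param seed RNG seed for the subsampling draws.
#' @return rarefied `count_table`.
#' @export
rarefy <- function(table, depth = min(rowSums(table)), seed = 1L) {
  depth <- as.integer(depth)
  if (depth < 1) stopf("depth must be >= 1")
  tot <- rowSums(table)
  low <- which(tot < depth)
  if (length(low))
    stopf("sample '%s' has %d reads, fewer than depth %d",
          rownames(table)[low[1]], tot[low[1]], depth)
  out <- unclass(table)
  with_seed(seed, {
    for (i in seq_len(nrow(out))) {
      if (tot[i] == depth) next
      reads <- rep.int(seq_len(ncol(out)), out[i, ])
      keep <- sample(reads, depth, replace = FALSE)
      out[i, ] <- tabulate(keep, nbins = ncol(out))
    }
  })
  count_table(out, rank = attr(table, "rank"))
}

#' Alpha diversity indices
#'
#' Per-sample observed richness, Chao1, Shannon (natural log), Gini-Simpson
#' (1 - sum p^2, larger = more diverse), raw Simpson dominance D, and Good's
#' coverage 1 - F1/N. Chao1 uses S + F1^2/(2 F2), switching to the
#' bias-corrected S + F1(F1-1)/2 when no doubletons exist (flagged).
#'
#' @param table a `count_table`; all sample totals must be positive.
#' @return data.frame, one row per sample: richness, chao1, chao1_bc (logical,
#'   bias-corrected form used), shannon, simpson, dominance, goods_coverage.
#' @export
diversity <- function(table) {
  tot <- rowSums(table)
  if (any(tot == 0))
    stopf("empty sample '%s'", rownames(table)[which(tot == 0)[1]])
  one <- function(x) {
    x <- x[x > 0]
    n <- sum(x)
    p <- x / n
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    s <- length(x)
    bc <- f2 == 0
    chao1 <- if (bc) s + f1 * (f1 - 1) / 2 else s + f1^2 / (2 * f2)
    c(richness = s, chao1 = chao1, chao1_bc = as.numeric(bc),
      shannon = -sum(p * log(p)),
      simpson = 1 - sum(p^2), dominance = sum(p^2),
      goods_coverage = 1 - f1 / n)
  }
  res <- t(apply(unclass(table), 1, one))
  out <- data.frame(sample_id = rownames(table), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$chao1_bc <- as.logical(out$chao1_bc)
  out
}
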