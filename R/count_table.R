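#' Per-ORF read count table
#'
#' Container for per-ORF read counts across screen replicates, in the
#' style of an edgeR/limma count matrix: integer counts with ORF ids as
#' rownames, one column per replicate, plus per-replicate library sizes
#' and (once computed) a CPM matrix.
#'
#' @param counts Non-negative integer matrix, ORFs in rows, replicates in
#'   columns. Rownames are the ORF ids; default column names
#'   `rep1, rep2, ...` are supplied if missing.
#' @param orf_ids Optional character vector of ORF ids overriding the
#'   rownames.
#' @return An object of class `count_table`: a list with elements
#'   `orf_ids`, `counts`, `library_sizes` and `cpm` (`NULL` until
#'   [counts_to_cpm()] is called).
#' @seealso [counts_to_cpm()], [read_count_table()], [call_candidates()]
#' @export
count_table <- function(counts, orf_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(orf_ids)) stop("ORF ids required (rownames of `counts` or `orf_ids`)")
  if (anyDuplicated(orf_ids)) stop("duplicate ORF ids in count table")
  if (length(orf_ids) != nrow(counts)) stop("`orf_ids` length must match rows of `counts`")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(colnames(counts))) colnames(counts) <- paste0("rep", seq_len(ncol(counts)))
  rownames(counts) <- orf_ids
  storage.mode(counts) <- "double"
  structure(
    list(
      orf_ids = as.character(orf_ids),
      counts = counts,
      library_sizes = colSums(counts),
      cpm = NULL
    ),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d ORFs x %d replicates\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:", paste(sprintf("%s=%d", colnames(x$counts),
                                      as.integer(x$library_sizes)),
                              collapse = ", "), "\n")
  cat("cpm:", if (is.null(x$cpm)) "not computed" else "computed", "\n")
  invisible(x)
}

#' Convert counts to counts-per-million (CPM)
#'
#' Interaction signal in pooled screens is taken proportional to read
#' counts per million: `cpm[i, j] = counts[i, j] * 1e6 / library_size[j]`.
#' Columns with zero library size become all-zero CPM with a warning.
#'
#' @param table A [count_table()].
#' @return The same `count_table` with its `cpm` matrix filled; each CPM
#'   column sums to 1e6 whenever its library size is positive.
#' @examples
#' ct <- count_table(matrix(c(1, 1, 2, 2, 0, 2), nrow = 3,
#'                          dimnames = list(c("A", "B", "C"), NULL)))
#' counts_to_cpm(ct)$cpm
#' @export
counts_to_cpm <- function(table) {
  stopifnot(inherits(table, "count_table"))
  lib <- table$library_sizes
  if (any(lib == 0)) {
    warning("zero library size in column(s) ",
            paste(colnames(table$counts)[lib == 0], collapse = ", "),
            "; CPM set to 0 there")
  }
  scale <- ifelse(lib > 0, 1e6 / lib, 0)
  table$cpm <- sweep(table$counts, 2, scale, `*`)
  table
}

#' Write / read a count table as TSV
#'
#' Plain-text interchange format: a header `orf_id<TAB>rep1<TAB>rep2...`
#' followed by one row per ORF.
#'
#' @param table A [count_table()].
#' @param path File path.
#' @return `write_count_table` returns `path` invisibly;
#'   `read_count_table` returns a [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(orf_id = table$orf_ids, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "orf_id") stop("expected first column `orf_id` in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$orf_id
  count_table(m)
}
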