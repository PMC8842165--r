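#' Call candidate interactors from a two-replicate count table
#'
#' Applies the pooled-screen count filter: an ORF is removed iff its
#' count is below `min_count` in *both* replicates, i.e. retained when at
#' least one replicate reaches the threshold. Per-replicate detection
#' flags (count >= `min_count`) are recorded for overlap reporting.
#'
#' @param table A [count_table()] with at least two replicate columns.
#' @param bait Bait label for the candidate list.
#' @param min_count Detection threshold (default 3 reads).
#' @param allow_single_replicate Set `TRUE` to permit a one-column table
#'   (the filter degenerates to a simple threshold); the default errors
#'   to make the choice explicit.
#' @return A `candidate_list`: list with `bait`, `orf_ids` (retained
#'   set), `detected_in` (named list: ORF -> replicate labels where
#'   detected) and `min_count`.
#' @examples
#' ct <- count_table(matrix(c(2, 3, 3, 2, 0, 3), nrow = 3, byrow = TRUE,
#'                          dimnames = list(c("A", "B", "C"), NULL)))
#' call_candidates(ct, "wtCFTR")$orf_ids  # "A" removed (2,2); B and C kept
#' @export
call_candidates <- function(table, bait, min_count = 3,
                            allow_single_replicate = FALSE) {
  stopifnot(inherits(table, "count_table"))
  stop_if_not_count(min_count, "min_count")
  n_rep <- ncol(table$counts)
  if (n_rep < 2 && !allow_single_replicate) {
    stop("count table has a single replicate; set `allow_single_replicate = TRUE` ",
         "to apply the threshold to one column")
  }
  detected <- table$counts >= min_count
  keep <- rowSums(detected) >= 1
  ids <- table$orf_ids[keep]
  rep_labels <- colnames(table$counts)
  detected_in <- lapply(which(keep), function(i) rep_labels[detected[i, ]])
  names(detected_in) <- ids
  structure(list(bait = bait, orf_ids = ids, detected_in = detected_in,
                 min_count = min_count),
            class = "candidate_list")
}

#' @export
print.candidate_list <- function(x, ...) {
  cat(sprintf("candidate_list: bait %s, %d candidates (min_count = %d)\n",
              x$bait, length(x$orf_ids), x$min_count))
  invisible(x)
}

#' Technical-replicate overlap of a candidate list
#'
#' Reports how many candidates were detected in both technical
#' replicates, and the integer percentage (round-half-to-even), the
#' robustness figure quoted for pooled screens.
#'
#' @param list A [call_candidates()] result built from exactly two
#'   replicates.
#' @return A list: `n_total`, `n_both`, `percent_both` (0 with attribute
#'   `undefined` when the candidate list is empty).
#' @examples
#' # 209 of 224 candidates seen in both replicates -> 93%
#' report_percent(209, 224)
#' @export
replicate_overlap <- function(list) {
  stopifnot(inherits(list, "candidate_list"))
  rep_labels <- unique(unlist(list$detected_in, use.names = FALSE))
  if (length(rep_labels) > 2) stop("replicate_overlap expects exactly 2 replicates")
  n_total <- length(list$orf_ids)
  n_both <- sum(vapply(list$detected_in, length, integer(1)) >= 2)
  list(n_total = n_total, n_both = n_both,
       percent_both = report_percent(n_both, n_total))
}
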