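#' Remove flagged frequent fliers from a candidate list
#'
#' @param list A [call_candidates()] result.
#' @param fliers Character vector of flier ORF ids (e.g. from
#'   [flag_frequent_fliers()]).
#' @return The filtered `candidate_list`; the number of candidates
#'   removed is recorded in its `n_removed` element.
#' @examples
#' # 494 pooled candidates minus 47 fliers leaves 447
#' @export
remove_fliers <- function(list, fliers) {
  stopifnot(inherits(list, "candidate_list"))
  fliers <- as.character(fliers)
  keep <- !(list$orf_ids %in% fliers)
  out <- list
  out$orf_ids <- list$orf_ids[keep]
  out$detected_in <- list$detected_in[keep]
  out$n_removed <- sum(!keep)
  out
}

#' Compare the interactomes of two baits
#'
#' Set algebra on two flier-filtered candidate lists: shared preys,
#' per-bait unique preys, union size, and rounded percentages (replicate
#' overlap per bait, shared-of-union at one decimal).
#'
#' @param a,b [call_candidates()] results for the two baits (after
#'   [remove_fliers()]).
#' @return An `interactome_comparison`: list with `bait_a`, `bait_b`,
#'   `set_a`, `set_b`, `shared`, `unique_a`, `unique_b`, `union_size` and
#'   `percents` (`shared_of_union` at one decimal; per-bait
#'   `overlap_a`/`overlap_b` replicate percentages when computable).
#' @examples
#' # |a| = 224, |b| = 269, 46 shared -> 178 and 223 unique, union 447
#' @export
compare_baits <- function(a, b) {
  stopifnot(inherits(a, "candidate_list"), inherits(b, "candidate_list"))
  set_a <- a$orf_ids
  set_b <- b$orf_ids
  shared <- intersect(set_a, set_b)
  unique_a <- setdiff(set_a, set_b)
  unique_b <- setdiff(set_b, set_a)
  union_size <- length(set_a) + length(set_b) - length(shared)
  structure(list(
    bait_a = a$bait, bait_b = b$bait,
    set_a = set_a, set_b = set_b,
    shared = shared, unique_a = unique_a, unique_b = unique_b,
    union_size = union_size,
    percents = list(
      shared_of_union = report_percent(length(shared), union_size, digits = 1),
      overlap_a = tryCatch(replicate_overlap(a)$percent_both, error = function(e) NA),
      overlap_b = tryCatch(replicate_overlap(b)$percent_both, error = function(e) NA)
    )
  ), class = "interactome_comparison")
}

#' @export
print.interactome_comparison <- function(x, ...) {
  cat(sprintf("interactome_comparison: %s (%d) vs %s (%d)\n",
              x$bait_a, length(x$set_a), x$bait_b, length(x$set_b)))
  cat(sprintf("  shared %d (%.1f%% of union %d); unique %d / %d\n",
              length(x$shared), as.numeric(x$percents$shared_of_union),
              x$union_size, length(x$unique_a), length(x$unique_b)))
  invisible(x)
}

#' Export an interactome comparison as an edge list
#'
#' One row per (bait, prey) pair with a category encoding the standard
#' network colouring: `shared` (both baits), `bait_a_only`,
#' `bait_b_only`. Both baits list their shared preys. Rows are ordered
#' deterministically (bait, then prey id, lexicographic) so re-export is
#' byte-identical.
#'
#' @param comparison An [compare_baits()] result.
#' @param path Optional TSV output path (header `bait   prey   category`).
#' @param annotations Optional data.frame keyed by `prey` to join onto
#'   the edge list (pre-built external annotations; never fetched).
#' @return The edge-list data.frame, invisibly when `path` is given.
#' @export
export_edges <- function(comparison, path = NULL, annotations = NULL) {
  stopifnot(inherits(comparison, "interactome_comparison"))
  edge_block <- function(bait, preys, category) {
    data.frame(bait = rep(bait, length(preys)), prey = preys,
               category = rep(category, length(preys)), stringsAsFactors = FALSE)
  }
  edges <- rbind(
    edge_block(comparison$bait_a, comparison$shared, "shared"),
    edge_block(comparison$bait_a, comparison$unique_a, "bait_a_only"),
    edge_block(comparison$bait_b, comparison$shared, "shared"),
    edge_block(comparison$bait_b, comparison$unique_b, "bait_b_only")
  )
  edges <- edges[order(edges$bait, edges$prey, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(annotations)) {
    stopifnot("prey" %in% names(annotations))
    edges <- merge(edges, annotations, by = "prey", all.x = TRUE, sort = FALSE)
    edges <- edges[order(edges$bait, edges$prey, method = "radix"),
                   union(c("bait", "prey", "category"), names(edges)), drop = FALSE]
    rownames(edges) <- NULL
  }
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(edges))
  }
  edges
}

#' Summarise an interactome comparison as a named count list
#'
#' @param comparison An [compare_baits()] result.
#' @return Named list of the counts and percentages (suitable for JSON
#'   export).
#' @export
comparison_summary <- function(comparison) {
  stopifnot(inherits(comparison, "interactome_comparison"))
  list(
    bait_a = comparison$bait_a,
    bait_b = comparison$bait_b,
    n_a = length(comparison$set_a),
    n_b = length(comparison$set_b),
    n_shared = length(comparison$shared),
    n_unique_a = length(comparison$unique_a),
    n_unique_b = length(comparison$unique_b),
    union_size = comparison$union_size,
    shared_of_union_percent = as.numeric(comparison$percents$shared_of_union)
  )
}
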