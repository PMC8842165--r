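#' CPM matrix of control-bait screens
#'
#' Stack of per-screen CPM columns used to detect promiscuous
#' ("frequent flier") preys: preys with consistently strong signal
#' across screens of unrelated control baits are assay artifacts, not
#' interactors.
#'
#' @param cpm Non-negative numeric matrix, preys in rows (rownames are
#'   the ORF ids), one column per control screen. At least 2 screens.
#' @param orf_ids,screen_labels Optional overrides for the dimnames.
#' @return A `control_screen_matrix`.
#' @export
control_screen_matrix <- function(cpm, orf_ids = rownames(cpm),
                                  screen_labels = colnames(cpm)) {
  cpm <- as.matrix(cpm)
  if (ncol(cpm) < 2) stop("at least 2 control screens required")
  if (any(cpm < 0)) stop("CPM values must be non-negative")
  if (is.null(orf_ids)) stop("ORF ids required (rownames of `cpm`)")
  if (anyDuplicated(orf_ids)) stop("duplicate ORF ids")
  if (is.null(screen_labels)) screen_labels <- paste0("screen", seq_len(ncol(cpm)))
  dimnames(cpm) <- list(orf_ids, screen_labels)
  structure(list(orf_ids = as.character(orf_ids), cpm = cpm,
                 screen_labels = screen_labels),
            class = "control_screen_matrix")
}

# per-screen descending ranks: highest CPM gets rank 1, ties averaged so
# rank sums are conserved
cpm_ranks <- function(cpm) {
  apply(cpm, 2, function(x) rank(-x, ties.method = "average"))
}

#' Rank products across control screens
#'
#' Within each screen, CPMs are ranked descending (highest CPM = rank 1,
#' ties receive the average of the tied positions; preys with zero CPM
#' are simply tied last, no imputation). The rank product of a prey is
#' the geometric mean of its per-screen ranks; small values mean
#' consistently strong signal.
#'
#' @param m A [control_screen_matrix()].
#' @return Named numeric vector of rank products, in `[1, n_orfs]`.
#' @examples
#' m <- control_screen_matrix(matrix(c(10, 5, 5, 10), 2,
#'                                   dimnames = list(c("a", "b"), NULL)))
#' compute_rank_products(m)  # both sqrt(2)
#' @export
compute_rank_products <- function(m) {
  stopifnot(inherits(m, "control_screen_matrix"))
  r <- cpm_ranks(m$cpm)
  stats::setNames(exp(rowMeans(log(r))), m$orf_ids)
}

#' Permutation p-values for rank products
#'
#' The null keeps each screen's rank column but randomly permutes it,
#' independently per screen and per iteration. For prey i,
#' `p = (# iterations where the randomized rank product at position i is
#' <= the observed rank product of prey i) / n_iter` (comparison and a
#' +1/+1 small-sample correction are configurable; the defaults follow
#' the literal divide-by-n_iter rule, and `<=` is the reading under which
#' completely tied data give p = 1 for every prey).
#'
#' @param m A [control_screen_matrix()].
#' @param n_iter Number of permutation iterations (default 100000).
#' @param seed Integer seed for the permutation stream.
#' @param comparison `"le"` (default) counts randomized rank products
#'   `<=` observed; `"lt"` counts strictly smaller.
#' @param correct If `TRUE`, use `(count + 1) / (n_iter + 1)` so p-values
#'   are never exactly 0. Default `FALSE`.
#' @return Named numeric p-value vector in `[0, 1]`.
#' @export
permutation_pvalues <- function(m, n_iter = 100000, seed = 1L,
                                comparison = c("le", "lt"),
                                correct = FALSE) {
  stopifnot(inherits(m, "control_screen_matrix"))
  stop_if_not_count(n_iter, "n_iter")
  if (n_iter < 1) stop("n_iter must be >= 1")
  comparison <- match.arg(comparison)
  n <- nrow(m$cpm)
  if (n_iter < 100) {
    warning("n_iter = ", n_iter, " gives p-value resolution of only 1/", n_iter)
  }
  log_ranks <- log(cpm_ranks(m$cpm))
  obs <- rowSums(log_ranks)  # log rank product * n_screens, monotone equivalent
  n_screens <- ncol(log_ranks)
  set.seed(seed)
  count <- numeric(n)
  tol <- 1e-9  # guard against log-arithmetic jitter in tie comparison
  for (it in seq_len(n_iter)) {
    rnd <- numeric(n)
    for (s in seq_len(n_screens)) {
      rnd <- rnd + log_ranks[sample.int(n), s]
    }
    count <- count + if (comparison == "le") (rnd <= obs + tol) else (rnd < obs - tol)
  }
  p <- if (correct) (count + 1) / (n_iter + 1) else count / n_iter
  stats::setNames(p, m$orf_ids)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegating to [stats::p.adjust()]):
#' sort ascending, `adj_i = min over j >= i of (p_j * m / j)`, capped at
#' 1, restored to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Rank-product frequent-flier test
#'
#' Runs the full procedure on a control-screen CPM matrix: rank products,
#' permutation p-values, BH adjustment and flier flags.
#'
#' @inheritParams permutation_pvalues
#' @param alpha Adjusted-p threshold for flagging (default 0.05).
#' @return A data.frame (class `rank_product_result`) with columns
#'   `orf_id, rank_product, p_value, p_adjusted, is_flier`, plus
#'   attributes `seed`, `n_iter`, `comparison` and `alpha` recording the
#'   run metadata.
#' @export
rank_product_test <- function(m, n_iter = 100000, seed = 1L, alpha = 0.05,
                              comparison = c("le", "lt"), correct = FALSE) {
  comparison <- match.arg(comparison)
  rp <- compute_rank_products(m)
  p <- permutation_pvalues(m, n_iter = n_iter, seed = seed,
                           comparison = comparison, correct = correct)
  padj <- bh_adjust(p)
  res <- data.frame(orf_id = m$orf_ids, rank_product = unname(rp),
                    p_value = unname(p), p_adjusted = unname(padj),
                    is_flier = unname(alpha > 0 & padj <= alpha),
                    stringsAsFactors = FALSE)
  attr(res, "seed") <- seed
  attr(res, "n_iter") <- n_iter
  attr(res, "comparison") <- comparison
  attr(res, "alpha") <- alpha
  class(res) <- c("rank_product_result", class(res))
  res
}

#' Flag frequent fliers from a rank-product result
#'
#' @param results A [rank_product_test()] data.frame (or any data.frame
#'   with `orf_id` and `p_adjusted`).
#' @param alpha Adjusted-p threshold (default 0.05). `alpha = 0` disables
#'   flagging entirely: an uncorrected Monte-Carlo p of 0 means
#'   "below 1/n_iter", not exactly zero, so it never beats a zero
#'   threshold.
#' @return Character vector of flagged ORF ids.
#' @export
flag_frequent_fliers <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("orf_id", "p_adjusted") %in% names(results)))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (alpha == 0) return(character(0))
  results$orf_id[results$p_adjusted <= alpha]
}
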