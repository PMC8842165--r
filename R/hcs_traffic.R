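#' QC-filter per-image well summaries
#'
#' Images are rejected when they have fewer than `min_cells` cells
#' (strictly below 100 by default), a focus metric below
#' `focus_threshold`, or negligible reporter expression. The expression
#' cutoff defaults to a per-plate quantile of the negative-control
#' (siNeg1) wells' expression channel; an absolute value can be supplied
#' instead.
#'
#' @param measures Data.frame of per-image rows with at least `plate_id,
#'   row, col, replicate, n_cells, median_traffic, median_expression,
#'   focus_metric` (see [simulate_plate()] for the full layout).
#' @param min_cells Minimum cell count per image (images with fewer are
#'   excluded; default 100).
#' @param focus_threshold Minimum focus metric (default 0.5).
#' @param expression_threshold Absolute expression floor; if `NULL`
#'   (default) it is taken per plate as `expression_quantile` of the
#'   negative-control images' expression (falling back to all images when
#'   a plate has no controls).
#' @param expression_quantile Quantile for the adaptive floor (default
#'   0.1).
#' @return List with `kept` (passing rows), `rejected` (failing rows plus
#'   a `reason` column; the first failing check in the order min-cells,
#'   focus, expression is reported) and `tally` (named rejection counts).
#' @export
qc_filter <- function(measures, min_cells = 100, focus_threshold = 0.5,
                      expression_threshold = NULL, expression_quantile = 0.1) {
  needed <- c("plate_id", "row", "col", "replicate", "n_cells",
              "median_traffic", "median_expression", "focus_metric")
  stopifnot(all(needed %in% names(measures)))
  expr_floor <- if (!is.null(expression_threshold)) {
    rep(expression_threshold, nrow(measures))
  } else {
    floors <- vapply(split(measures, measures$plate_id), function(d) {
      ref <- if ("is_negative_control" %in% names(d) && any(d$is_negative_control)) {
        d$median_expression[d$is_negative_control]
      } else d$median_expression
      stats::quantile(ref, expression_quantile, names = FALSE)
    }, numeric(1))
    floors[as.character(measures$plate_id)]
  }
  reason <- rep(NA_character_, nrow(measures))
  reason[is.na(reason) & measures$n_cells < min_cells] <- "low_cells"
  reason[is.na(reason) & measures$focus_metric < focus_threshold] <- "out_of_focus"
  reason[is.na(reason) & measures$median_expression < expr_floor] <- "low_expression"
  rejected <- measures[!is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!is.na(reason)]
  list(kept = measures[is.na(reason), , drop = FALSE],
       rejected = rejected,
       tally = table(factor(reason[!is.na(reason)],
                            levels = c("low_cells", "out_of_focus", "low_expression"))))
}

#' Per-well summaries from QC-passing images
#'
#' The well value is the median of its valid images' traffic-channel
#' medians, per plate and biological replicate. Wells whose images were
#' all rejected simply do not appear (invalid downstream).
#'
#' @param kept Data.frame of QC-passing per-image rows (from
#'   [qc_filter()]`$kept`).
#' @return Data.frame with one row per (plate_id, replicate, row, col):
#'   `value` (median of image medians), `n_images`, and carried-through
#'   `sirna_id`/`gene`/`is_negative_control` labels when present.
#' @export
well_summary <- function(kept) {
  stopifnot(nrow(kept) > 0)
  key <- interaction(kept$plate_id, kept$replicate, kept$row, kept$col, drop = TRUE)
  first <- !duplicated(key)
  out <- kept[first, intersect(c("plate_id", "replicate", "row", "col",
                                 "sirna_id", "gene", "is_negative_control"),
                               names(kept)), drop = FALSE]
  out$value <- as.numeric(tapply(kept$median_traffic, key, stats::median))[
    match(key[first], levels(key))]
  out$n_images <- as.integer(table(key))[match(key[first], levels(key))]
  rownames(out) <- NULL
  out
}

# 5x5 neighbourhood median for one plate matrix (NA = invalid well);
# window truncated at plate edges, centre well included
neighbourhood_median <- function(mat, half = 2L, include_center = TRUE) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- max(1, i - half):min(nr, i + half)
    for (j in seq_len(nc)) {
      cols <- max(1, j - half):min(nc, j + half)
      win <- mat[rows, cols]
      if (!include_center) win <- win[-(which(rows == i) + (which(cols == j) - 1) * length(rows))]
      if (all(is.na(win))) next
      out[i, j] <- stats::median(win, na.rm = TRUE)
    }
  }
  out
}

#' Neighbourhood Z-scores for a plate of well summaries
#'
#' For each well, the location reference is the median of the valid well
#' summaries in the 5x5 window centred on it (truncated at the plate
#' edges; the well itself included unless `include_center = FALSE`). The
#' scale is, by default, the plate-level robust SD of the local residuals
#' (1.4826 x MAD of well minus its neighbourhood median): a 25-well local
#' MAD is noisy and frequently zero under ties, so a plate-level residual
#' scale is the B-score-adjacent compromise. `Z = residual / scale`, and
#' 0 when the scale itself is 0 (e.g. a constant plate).
#'
#' @param wells Data.frame from [well_summary()] (any subset of plates
#'   and replicates; Z-scores are computed per plate x replicate).
#' @param n_rows,n_cols Plate dimensions (defaults: max observed
#'   coordinates).
#' @param scale One of `"plate_mad"` (default), `"neighborhood_mad"`
#'   (per-well 5x5 residual MAD) or `"neg_control_sd"` (SD of
#'   negative-control residuals).
#' @param include_center Include the well in its own window (default
#'   `TRUE`).
#' @return The input with a `z` column appended. Plates with fewer than
#'   2 valid wells are dropped with a warning.
#' @export
neighborhood_zscore <- function(wells, n_rows = NULL, n_cols = NULL,
                                scale = c("plate_mad", "neighborhood_mad",
                                          "neg_control_sd"),
                                include_center = TRUE) {
  scale <- match.arg(scale)
  nr <- if (is.null(n_rows)) max(wells$row) else n_rows
  nc <- if (is.null(n_cols)) max(wells$col) else n_cols
  pieces <- split(wells, interaction(wells$plate_id, wells$replicate, drop = TRUE))
  out <- lapply(pieces, function(d) {
    if (nrow(d) < 2) {
      warning("plate ", d$plate_id[1], " / ", d$replicate[1],
              " has < 2 valid wells; skipped")
      return(NULL)
    }
    mat <- matrix(NA_real_, nr, nc)
    mat[cbind(d$row, d$col)] <- d$value
    center <- neighbourhood_median(mat, include_center = include_center)
    resid_mat <- mat - center
    resid <- resid_mat[cbind(d$row, d$col)]
    s <- switch(scale,
      plate_mad = stats::mad(resid, na.rm = TRUE),
      neighborhood_mad = {
        local_mad <- neighbourhood_median(abs(resid_mat - stats::median(resid, na.rm = TRUE)),
                                          include_center = include_center)
        1.4826 * local_mad[cbind(d$row, d$col)]
      },
      neg_control_sd = {
        if (!("is_negative_control" %in% names(d)) || !any(d$is_negative_control)) {
          stop("scale = 'neg_control_sd' needs negative-control wells")
        }
        stats::sd(resid[d$is_negative_control])
      })
    s <- rep_len(s, nrow(d))  # scalar for plate-level scales, vector for local
    d$z <- ifelse(is.na(s) | s == 0, 0, resid / s)
    d$z[is.na(resid)] <- NA_real_
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-well Z-scores into siRNA and gene calls
#'
#' The reported Z-score of an siRNA is the median of its wells' Z-scores
#' across replicate wells and biological replicates. Hits are siRNAs with
#' Z above `+z_threshold` (increase) or below `-z_threshold` (decrease).
#' A gene is called `enhancer`/`inhibitor` when at least one of its
#' siRNAs passes in a single direction, `ambiguous` when siRNAs pass in
#' both directions, `none` otherwise.
#'
#' @param zscores Data.frame from [neighborhood_zscore()] with `sirna_id`
#'   and `gene` columns.
#' @param z_threshold Hit threshold (default 1).
#' @return List with `sirna` (data.frame: `sirna_id, gene, z_score,
#'   n_valid_replicates, direction`) and `gene` (data.frame: `gene,
#'   gene_call`). siRNAs with no valid wells in any replicate appear with
#'   `n_valid_replicates = 0` and direction `none`.
#' @export
aggregate_and_call <- function(zscores, z_threshold = 1) {
  stopifnot(all(c("sirna_id", "gene", "z", "replicate") %in% names(zscores)))
  by_sirna <- split(zscores, zscores$sirna_id)
  sirna <- do.call(rbind, lapply(by_sirna, function(d) {
    ok <- !is.na(d$z)
    data.frame(
      sirna_id = d$sirna_id[1], gene = d$gene[1],
      z_score = if (any(ok)) stats::median(d$z[ok]) else NA_real_,
      n_valid_replicates = length(unique(d$replicate[ok])),
      stringsAsFactors = FALSE
    )
  }))
  sirna$direction <- with(sirna, ifelse(
    is.na(z_score) | n_valid_replicates == 0, "none",
    ifelse(z_score > z_threshold, "increase",
           ifelse(z_score < -z_threshold, "decrease", "none"))))
  rownames(sirna) <- NULL
  gene <- do.call(rbind, lapply(split(sirna, sirna$gene), function(d) {
    up <- any(d$direction == "increase")
    down <- any(d$direction == "decrease")
    call <- if (up && down) "ambiguous" else if (up) "enhancer" else if (down) "inhibitor" else "none"
    data.frame(gene = d$gene[1], gene_call = call, stringsAsFactors = FALSE)
  }))
  rownames(gene) <- NULL
  list(sirna = sirna, gene = gene)
}

#' Run the full traffic-screen analysis
#'
#' QC filter, per-well medians, per-plate neighbourhood Z-scores and
#' siRNA/gene calls in one step.
#'
#' @inheritParams qc_filter
#' @inheritParams neighborhood_zscore
#' @inheritParams aggregate_and_call
#' @return List with `qc` (the [qc_filter()] result), `wells`,
#'   `zscores`, `sirna` and `gene`.
#' @export
traffic_screen <- function(measures, min_cells = 100, focus_threshold = 0.5,
                           expression_threshold = NULL,
                           expression_quantile = 0.1,
                           scale = "plate_mad", include_center = TRUE,
                           z_threshold = 1) {
  qc <- qc_filter(measures, min_cells = min_cells,
                  focus_threshold = focus_threshold,
                  expression_threshold = expression_threshold,
                  expression_quantile = expression_quantile)
  wells <- well_summary(qc$kept)
  zs <- neighborhood_zscore(wells, scale = scale, include_center = include_center)
  calls <- aggregate_and_call(zs, z_threshold = z_threshold)
  c(list(qc = qc, wells = wells, zscores = zs), calls)
}
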