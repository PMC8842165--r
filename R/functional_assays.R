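#' Time-ordered assay trace with event markers
#'
#' Container for FLIPR-style fluorescence traces (RFU) or organoid
#' relative-area series (% of initial area): ascending times, one value
#' per scan, and explicit drug-addition event markers (the operator knows
#' the addition times; they are never inferred from the signal).
#'
#' @param times Numeric, strictly ascending (seconds, or minutes for
#'   swelling series).
#' @param values Numeric, same length.
#' @param events Data.frame with columns `label` (e.g. `"fsk"`,
#'   `"vx770"`, `"inhibitor"`) and `time`; all event times must lie
#'   within the time range.
#' @param sample_id,condition Optional labels.
#' @return An `assay_trace`.
#' @export
assay_trace <- function(times, values, events = data.frame(label = character(0),
                                                           time = numeric(0)),
                        sample_id = NA_character_, condition = NA_character_) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("times must be strictly ascending")
  stopifnot(all(c("label", "time") %in% names(events)))
  if (nrow(events) > 0 &&
      (min(events$time) < min(times) || max(events$time) > max(times))) {
    stop("event times must lie within the trace time range")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 events = events, sample_id = sample_id, condition = condition),
            class = "assay_trace")
}

event_time <- function(trace, label) {
  t <- trace$events$time[trace$events$label == label]
  if (length(t) == 0) return(NA_real_)
  t[1]
}

#' Maximum forskolin response of a FLIPR trace
#'
#' `F0` is the baseline RFU right before stimulation — by default the
#' mean of all pre-forskolin scans (at least 4 by protocol), for noise
#' robustness; `baseline = "last"` uses the single last pre-event scan.
#' The statistic is the maximum of `value / F0` over post-forskolin scans
#' (up to any inhibitor event).
#'
#' @param trace An [assay_trace()] with a `fsk` event and at least one
#'   scan on each side of it.
#' @param baseline `"mean"` (default) or `"last"`.
#' @return Maximum F/F0 (1.0 for a flat trace).
#' @export
flipr_fsk_response <- function(trace, baseline = c("mean", "last")) {
  stopifnot(inherits(trace, "assay_trace"))
  baseline <- match.arg(baseline)
  t_fsk <- event_time(trace, "fsk")
  if (is.na(t_fsk)) stop("trace has no `fsk` event")
  pre <- trace$values[trace$times < t_fsk]
  if (length(pre) == 0) stop("no scans before the fsk event")
  f0 <- if (baseline == "mean") mean(pre) else pre[length(pre)]
  if (f0 <= 0) stop("non-physical baseline: F0 <= 0")
  t_inh <- event_time(trace, "inhibitor")
  upper <- if (is.na(t_inh)) Inf else t_inh
  post <- trace$values[trace$times > t_fsk & trace$times < upper]
  if (length(post) == 0) stop("no scans after the fsk event")
  max(post) / f0
}

#' Inhibitor response of a FLIPR trace
#'
#' `F1` is the value at the last scan before the inhibitor event;
#' `F_inh` is the minimum value from the inhibitor event to the end of
#' the trace. Returns `F1 / F_inh` (1.0 when there is no post-inhibitor
#' decline). This is the readout for F508del-CFTR, which needs full
#' stimulation (forskolin + potentiator) before the inhibitor step.
#'
#' @param trace An [assay_trace()] with an `inhibitor` event and at
#'   least one scan on each side of it.
#' @return The ratio F1 / F_inh.
#' @export
flipr_inhibitor_response <- function(trace) {
  stopifnot(inherits(trace, "assay_trace"))
  t_inh <- event_time(trace, "inhibitor")
  if (is.na(t_inh)) stop("trace has no `inhibitor` event")
  pre <- trace$values[trace$times < t_inh]
  post <- trace$values[trace$times > t_inh]
  if (length(pre) == 0 || length(post) == 0) {
    stop("need at least one scan before and after the inhibitor event")
  }
  f1 <- pre[length(pre)]
  f_inh <- min(post)
  if (f_inh <= 0) stop("non-physical post-inhibitor minimum: F_inh <= 0")
  f1 / f_inh
}

#' Normalize per-sample metrics to a control group and t-test each condition
#'
#' Each value is divided by the mean of the control group; each
#' non-control condition is compared to the control by a two-sided
#' unpaired t-test (pooled-variance Student by default; `welch = TRUE`
#' for unequal variances). Significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param values Numeric vector of per-sample metrics.
#' @param condition Character vector of condition labels, same length.
#' @param control_label The control condition (must be present with >= 2
#'   samples).
#' @param welch Use the Welch statistic instead of pooled variance.
#' @return List with `fold` (per-sample values / control mean), `summary`
#'   (data.frame: `condition, n, fold_mean, fold_sd, t, p, stars`;
#'   control row has `NA` test fields).
#' @export
normalize_and_test <- function(values, condition, control_label,
                               welch = FALSE) {
  stopifnot(length(values) == length(condition))
  if (!(control_label %in% condition)) stop("control group `", control_label, "` missing")
  ctrl <- values[condition == control_label]
  if (length(ctrl) < 2) stop("control group needs >= 2 samples")
  fold <- values / mean(ctrl)
  conds <- unique(condition)
  summary <- do.call(rbind, lapply(conds, function(cc) {
    v <- values[condition == cc]
    if (cc == control_label) {
      t_stat <- NA_real_; p <- NA_real_
    } else {
      if (length(v) < 2) stop("condition `", cc, "` needs >= 2 samples")
      ht <- stats::t.test(v, ctrl, var.equal = !welch)
      t_stat <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(condition = cc, n = length(v),
               fold_mean = mean(v) / mean(ctrl),
               fold_sd = stats::sd(v) / mean(ctrl),
               t = t_stat, p = p,
               stars = if (is.na(p)) NA_character_ else p_stars(p),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(fold = fold, summary = summary)
}

#' Forskolin-induced swelling AUC
#'
#' Trapezoidal integral of (relative area - 100) from stimulation (t = 0,
#' area 100%) to `t_end` minutes. Negative increments contribute
#' negatively (no clipping). A series ending before `t_end` is integrated
#' to its last point with a warning; a series extending past `t_end` is
#' linearly interpolated at `t_end`.
#'
#' @param series An [assay_trace()] in percent-of-initial-area units
#'   starting at t = 0 with value 100.
#' @param t_end Integration endpoint in minutes (default 60).
#' @return AUC in percent x minutes (0 for a constant 100% series; 1800
#'   for a linear rise to 160% over 60 min).
#' @export
fis_auc <- function(series, t_end = 60) {
  stopifnot(inherits(series, "assay_trace"))
  t <- series$times
  v <- series$values
  if (abs(t[1]) > 1e-9 || abs(v[1] - 100) > 1e-6) {
    stop("series must start at t = 0 with value 100 (% of initial area)")
  }
  if (max(t) < t_end) {
    warning("series ends at t = ", max(t), " < ", t_end, "; integrating to last point")
    t_end <- max(t)
  } else if (max(t) > t_end) {
    v_end <- stats::approx(t, v, xout = t_end)$y
    keep <- t < t_end
    t <- c(t[keep], t_end)
    v <- c(v[keep], v_end)
  }
  y <- v - 100
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Ussing-chamber recording
#'
#' Transepithelial potential (mV) and resistance (Ohm cm^2) series with
#' drug-addition events.
#'
#' @param times Ascending numeric times (s).
#' @param vte Transepithelial potential (mV).
#' @param rte Transepithelial resistance (Ohm cm^2), strictly positive.
#' @param events Data.frame `label`/`time` (`amiloride`, `fsk`,
#'   `inhibitor`, ...).
#' @return An `ussing_recording`.
#' @export
ussing_recording <- function(times, vte, rte, events) {
  stopifnot(length(times) == length(vte), length(vte) == length(rte))
  if (any(diff(times) <= 0)) stop("times must be strictly ascending")
  if (any(rte <= 0)) stop("rte must be > 0 throughout")
  stopifnot(all(c("label", "time") %in% names(events)))
  structure(list(times = as.numeric(times), vte = as.numeric(vte),
                 rte = as.numeric(rte), events = events),
            class = "ussing_recording")
}

#' Equivalent transepithelial current metrics
#'
#' By Ohm's law, `Ieq(t) = Vte(t) / Rte(t)`; with Vte in mV and Rte in
#' Ohm cm^2 the result is reported in uA cm^-2 (x1000). CFTR activity is
#' the Ieq difference after forskolin: the median over the post-forskolin
#' plateau window minus the median over the baseline window
#' (post-amiloride when an `amiloride` event exists, else from the start,
#' up to forskolin). The inhibitor delta is analogous (post-inhibitor
#' median minus the forskolin plateau median).
#'
#' @param rec An [ussing_recording()] whose events include `fsk`.
#' @return List with `ieq` (uA cm^-2 series), `delta_fsk` and
#'   `delta_inhibitor` (`NA` when no inhibitor event).
#' @export
ussing_metrics <- function(rec) {
  stopifnot(inherits(rec, "ussing_recording"))
  t_fsk <- event_time(rec, "fsk")
  if (is.na(t_fsk)) stop("recording has no `fsk` event")
  ieq <- 1000 * rec$vte / rec$rte  # mV / (Ohm cm^2) -> uA cm^-2
  t_ami <- event_time(rec, "amiloride")
  t_inh <- event_time(rec, "inhibitor")
  lower <- if (is.na(t_ami)) -Inf else t_ami
  base_win <- rec$times > lower & rec$times < t_fsk
  plateau_upper <- if (is.na(t_inh)) Inf else t_inh
  fsk_win <- rec$times > t_fsk & rec$times < plateau_upper
  if (!any(base_win) || !any(fsk_win)) stop("empty baseline or post-fsk window")
  delta_fsk <- stats::median(ieq[fsk_win]) - stats::median(ieq[base_win])
  delta_inh <- if (is.na(t_inh)) NA_real_ else {
    stats::median(ieq[rec$times > t_inh]) - stats::median(ieq[fsk_win])
  }
  list(ieq = ieq, delta_fsk = delta_fsk, delta_inhibitor = delta_inh)
}

#' Western-blot band quantification: fold changes and ANOVA
#'
#' Band intensities are first expressed relative to the calnexin loading
#' control; fold changes are then taken versus the mean normalized
#' intensity of the baseline condition. A one-way ANOVA across conditions
#' is computed per band. As the post hoc step, pairwise Welch t-tests of
#' each condition against baseline with BH adjustment are reported
#' (labelled in the output; a multivariate-t Dunnett procedure is
#' deliberately not used).
#'
#' @param quants Data.frame with columns `sample_id, condition, band_b,
#'   band_c, calnexin` (intensities >= 0; samples with calnexin 0 are
#'   excluded with a warning).
#' @param baseline_label Condition used as the fold-change denominator.
#' @return List with `folds` (per-sample data.frame: normalized and
#'   fold-change values per band), `anova` (per-band data.frame: `band,
#'   F, p`), `posthoc` (per band x condition: Welch t vs baseline, BH
#'   adjusted) and `posthoc_method`.
#' @export
wb_fold_change <- function(quants, baseline_label) {
  needed <- c("sample_id", "condition", "band_b", "band_c", "calnexin")
  stopifnot(all(needed %in% names(quants)))
  if (!(baseline_label %in% quants$condition)) {
    stop("baseline condition `", baseline_label, "` missing")
  }
  bad <- quants$calnexin <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with calnexin <= 0 excluded")
    quants <- quants[!bad, , drop = FALSE]
  }
  norm <- data.frame(sample_id = quants$sample_id, condition = quants$condition,
                     band_b = quants$band_b / quants$calnexin,
                     band_c = quants$band_c / quants$calnexin,
                     stringsAsFactors = FALSE)
  base <- norm$condition == baseline_label
  folds <- norm
  for (band in c("band_b", "band_c")) {
    folds[[paste0(band, "_fold")]] <- norm[[band]] / mean(norm[[band]][base])
  }
  anova <- do.call(rbind, lapply(c("band_b", "band_c"), function(band) {
    fit <- stats::aov(norm[[band]] ~ factor(norm$condition))
    s <- summary(fit)[[1]]
    data.frame(band = band, F = s[["F value"]][1], p = s[["Pr(>F)"]][1])
  }))
  rownames(anova) <- NULL
  others <- setdiff(unique(norm$condition), baseline_label)
  posthoc <- do.call(rbind, lapply(c("band_b", "band_c"), function(band) {
    p <- vapply(others, function(cc) {
      x <- norm[[band]][norm$condition == cc]
      if (length(x) < 2 || sum(base) < 2) return(NA_real_)  # untestable group
      stats::t.test(x, norm[[band]][base])$p.value
    }, numeric(1))
    padj <- rep(NA_real_, length(p))
    padj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
    data.frame(band = band, condition = others, p = unname(p),
               p_adjusted = unname(padj), stringsAsFactors = FALSE)
  }))
  rownames(posthoc) <- NULL
  posthoc$stars <- p_stars(posthoc$p_adjusted)
  list(folds = folds, anova = anova, posthoc = posthoc,
       posthoc_method = "pairwise Welch t-tests vs baseline, BH-adjusted (Dunnett substitute)")
}
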