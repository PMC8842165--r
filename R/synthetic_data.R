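#' Configuration for simulated pooled interaction screens
#'
#' Defines the enrichment/noise structure a sorted-cell pooled screen
#' assumes: background preys at a low negative-binomial mean, true bait
#' interactors enriched `enrichment_fold`-fold after selection, and
#' promiscuous "frequent flier" preys enriched `flier_fold`-fold in every
#' screen regardless of bait.
#'
#' @param n_orfs Number of prey ORFs in the library.
#' @param n_true_interactors Number of true interactors of the simulated
#'   bait.
#' @param n_fliers Number of frequent-flier preys.
#' @param enrichment_fold Mean count multiplier for true interactors
#'   after sorting (>= 1).
#' @param flier_fold Multiplier applied to fliers in every screen (>= 1).
#' @param base_mean Background negative-binomial mean count.
#' @param dispersion Negative-binomial size parameter (> 0); small values
#'   give the overdispersion a nontrivial rank-product null needs.
#' @param n_replicates Technical replicates per screen (default 2).
#' @param n_control_screens Control-bait screens for flier detection
#'   (default 9, one per control bait class; at least 2 — a rank product
#'   is a multi-screen consensus).
#' @param read_length Read length in bases for emitted reads.
#' @param orf_length Length of each simulated ORF sequence.
#' @param reads_per_orf_unit Reads emitted per counted unit (default 1).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_orfs = 1000,
                              n_true_interactors = 20,
                              n_fliers = 5,
                              enrichment_fold = 50,
                              flier_fold = 100,
                              base_mean = 0.5,
                              dispersion = 0.5,
                              n_replicates = 2,
                              n_control_screens = 9,
                              read_length = 150,
                              orf_length = 500,
                              reads_per_orf_unit = 1,
                              seed = 1L) {
  for (nm in c("n_orfs", "n_true_interactors", "n_fliers", "n_replicates",
               "n_control_screens", "read_length", "orf_length",
               "reads_per_orf_unit")) {
    stop_if_not_count(get(nm), nm)
  }
  if (n_true_interactors + n_fliers > n_orfs) {
    stop("n_true_interactors + n_fliers must not exceed n_orfs")
  }
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (flier_fold < 1) stop("flier_fold must be >= 1")
  if (base_mean <= 0) stop("base_mean must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (n_control_screens < 2) {
    stop("at least 2 control screens are required (rank product is a multi-screen consensus)")
  }
  if (read_length > orf_length) stop("read_length must not exceed orf_length")
  structure(as.list(environment())[c(
    "n_orfs", "n_true_interactors", "n_fliers", "enrichment_fold",
    "flier_fold", "base_mean", "dispersion", "n_replicates",
    "n_control_screens", "read_length", "orf_length",
    "reads_per_orf_unit", "seed")], class = "screen_sim_config")
}

# assign disjoint roles to the ORF library; fliers come first, then true
# interactors, rest background (ids are exchangeable so order is harmless)
orf_roles <- function(config) {
  ids <- sprintf("ORF%05d", seq_len(config$n_orfs))
  role <- rep("background", config$n_orfs)
  if (config$n_fliers > 0) role[seq_len(config$n_fliers)] <- "flier"
  if (config$n_true_interactors > 0) {
    role[config$n_fliers + seq_len(config$n_true_interactors)] <- "true_interactor"
  }
  data.frame(orf_id = ids, role = role, stringsAsFactors = FALSE)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# expected per-ORF negative-binomial mean for one screen of `bait`
role_means <- function(config, role) {
  mu <- rep(config$base_mean, length(role))
  mu[role == "true_interactor"] <- config$base_mean * config$enrichment_fold
  mu[role == "flier"] <- config$base_mean * config$flier_fold
  mu
}

#' Simulate one pooled screen of a bait (two technical replicates)
#'
#' Per-ORF read counts are drawn from a negative binomial with mean
#' `base_mean` (background), `base_mean * enrichment_fold` (this bait's
#' true interactors) or `base_mean * flier_fold` (fliers, for every
#' bait). Reads are error-free forward-strand substrings of the ORF
#' sequences. Identical seed and config give byte-identical output.
#'
#' @param config A [screen_sim_config()].
#' @param bait_label Bait name recorded in the output.
#' @param emit_reads If `FALSE`, skip read-sequence generation and return
#'   counts only (faster for large simulations).
#' @return A list with `bait`, `reference` (an [orf_reference()], only
#'   when `emit_reads`), `reads` (per-replicate character vectors of read
#'   sequences), `table` (the true per-ORF [count_table()] with CPM) and
#'   `truth` (data.frame of ORF roles, a disjoint partition).
#' @export
simulate_screen <- function(config, bait_label = "bait", emit_reads = TRUE) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  truth <- orf_roles(config)
  mu <- role_means(config, truth$role)
  counts <- vapply(seq_len(config$n_replicates), function(r) {
    stats::rnbinom(config$n_orfs, size = config$dispersion, mu = mu)
  }, numeric(config$n_orfs))
  rownames(counts) <- truth$orf_id
  colnames(counts) <- paste0("rep", seq_len(config$n_replicates))
  reference <- NULL
  reads <- NULL
  if (emit_reads) {
    seqs <- random_dna(config$n_orfs, config$orf_length)
    reference <- orf_reference(truth$orf_id, seqs)
    reads <- lapply(seq_len(config$n_replicates), function(r) {
      n_reads <- counts[, r] * config$reads_per_orf_unit
      orf_idx <- rep(seq_len(config$n_orfs), n_reads)
      starts <- sample.int(config$orf_length - config$read_length + 1,
                           length(orf_idx), replace = TRUE)
      substring(seqs[orf_idx], starts, starts + config$read_length - 1)
    })
    names(reads) <- colnames(counts)
  }
  list(bait = bait_label, reference = reference, reads = reads,
       table = counts_to_cpm(count_table(counts)), truth = truth)
}

#' Simulate the control-bait screen stack for flier detection
#'
#' One pooled count column per control screen: fliers keep their elevated
#' mean in every screen, background is resampled independently per
#' screen. True-interactor enrichment does not apply (control baits have
#' no designed interactors).
#'
#' @param config A [screen_sim_config()].
#' @return A list with `matrix` (a [control_screen_matrix()] of CPMs,
#'   `n_orfs x n_control_screens`), `counts` (the underlying count
#'   matrix) and `truth`.
#' @export
simulate_control_screens <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed + 1L)
  truth <- orf_roles(config)
  mu <- rep(config$base_mean, config$n_orfs)
  mu[truth$role == "flier"] <- config$base_mean * config$flier_fold
  counts <- vapply(seq_len(config$n_control_screens), function(s) {
    stats::rnbinom(config$n_orfs, size = config$dispersion, mu = mu)
  }, numeric(config$n_orfs))
  dimnames(counts) <- list(truth$orf_id,
                           paste0("ctrl", seq_len(config$n_control_screens)))
  lib <- colSums(counts)
  scale <- ifelse(lib > 0, 1e6 / lib, 0)
  cpm <- sweep(counts, 2, scale, `*`)
  list(matrix = control_screen_matrix(cpm), counts = counts, truth = truth)
}

#' Configuration for simulated 384-well traffic-screen plates
#'
#' Per-image well intensities follow a smooth planar spatial gradient
#' times the plate background, plus well-level siRNA effects expressed in
#' units of the image-level noise SD, plus Gaussian noise. A configured
#' fraction of images is injected with QC failures (low cell count,
#' out-of-focus, negligible reporter expression).
#'
#' @param n_rows,n_cols Plate dimensions (default 16 x 24, a 384-well
#'   plate).
#' @param gradient_amplitude Maximum fractional deviation of the planar
#'   gradient from the plate background (0 = flat).
#' @param effect_wells Named numeric vector of well effects in robust-SD
#'   units; names are wells as `"R05C07"`.
#' @param background Plate background intensity (arbitrary units).
#' @param noise_sd Image-level additive noise SD (same units).
#' @param mean_cells Poisson mean of cells per image.
#' @param images_per_well Sub-positions imaged per well (default 4).
#' @param n_replicates Independent biological replicates (default 4).
#' @param qc_fail_rate Probability an image is injected with a QC failure.
#' @param seed Integer seed.
#' @return A `plate_sim_config` list.
#' @export
plate_sim_config <- function(n_rows = 16, n_cols = 24,
                             gradient_amplitude = 0.1,
                             effect_wells = numeric(0),
                             background = 1000,
                             noise_sd = 50,
                             mean_cells = 500,
                             images_per_well = 4,
                             n_replicates = 4,
                             qc_fail_rate = 0,
                             seed = 1L) {
  for (nm in c("n_rows", "n_cols", "images_per_well", "n_replicates")) {
    stop_if_not_count(get(nm), nm)
  }
  if (qc_fail_rate < 0 || qc_fail_rate > 1) stop("qc_fail_rate must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(effect_wells) > 0) {
    if (is.null(names(effect_wells))) stop("effect_wells must be named R..C.. wells")
    rc <- parse_wells(names(effect_wells))
    if (any(rc$row < 1 | rc$row > n_rows | rc$col < 1 | rc$col > n_cols)) {
      stop("effect_wells keys must lie on the plate")
    }
  }
  structure(as.list(environment())[c(
    "n_rows", "n_cols", "gradient_amplitude", "effect_wells", "background",
    "noise_sd", "mean_cells", "images_per_well", "n_replicates",
    "qc_fail_rate", "seed")], class = "plate_sim_config")
}

well_name <- function(row, col) sprintf("R%02dC%02d", row, col)

parse_wells <- function(x) {
  m <- regmatches(x, regexec("^R([0-9]+)C([0-9]+)$", x))
  if (any(lengths(m) != 3)) stop("malformed well name(s); expected e.g. 'R05C07'")
  data.frame(row = as.integer(vapply(m, `[`, character(1), 2)),
             col = as.integer(vapply(m, `[`, character(1), 3)))
}

#' Simulate per-image well summaries for a traffic-screen plate
#'
#' Emulates the measured layer of a high-content siRNA screen: each well
#' imaged at `images_per_well` sub-positions across `n_replicates`
#' biological replicates, with per-image cell counts, focus metric,
#' reporter-expression and surface-reporter (traffic) channel medians.
#' Negative-control wells (non-targeting siRNA, label `siNeg1`) occupy
#' column 1; remaining wells carry one siRNA each, two siRNAs per gene.
#'
#' @param config A [plate_sim_config()].
#' @param plate_id Plate identifier recorded in the output.
#' @return A list with `measures` (data.frame of per-image rows:
#'   `plate_id, row, col, replicate, image_index, n_cells,
#'   median_traffic, median_expression, focus_metric, sirna_id, gene,
#'   is_negative_control, qc_truth`) and `truth` (per-well data.frame of
#'   injected effects, a disjoint role partition).
#' @export
simulate_plate <- function(config, plate_id = "plate1") {
  stopifnot(inherits(config, "plate_sim_config"))
  set.seed(config$seed + 2L)
  nr <- config$n_rows; nc <- config$n_cols
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  # planar tilt: a 5x5 running-median reference removes a plane exactly in
  # the plate interior, so the gradient itself must not generate hits
  tilt <- (grid$row - (nr + 1) / 2) / nr + (grid$col - (nc + 1) / 2) / nc
  tilt_max <- max(abs(tilt))
  gradient <- 1 + if (tilt_max > 0) config$gradient_amplitude * tilt / tilt_max else 0
  wells <- well_name(grid$row, grid$col)
  effect <- stats::setNames(rep(0, length(wells)), wells)
  if (length(config$effect_wells) > 0) {
    effect[names(config$effect_wells)] <- config$effect_wells
  }
  is_neg <- grid$col == 1L
  sirna <- ifelse(is_neg, "siNeg1", sprintf("si%s", wells))
  target_idx <- cumsum(!is_neg)
  gene <- ifelse(is_neg, "NEG1", sprintf("GENE%04d", (target_idx + 1) %/% 2))
  well_mu <- config$background * gradient + effect * config$noise_sd

  n_img <- config$images_per_well
  reps <- config$n_replicates
  img <- expand.grid(well_i = seq_along(wells), replicate = seq_len(reps),
                     image_index = seq_len(n_img))
  n <- nrow(img)
  measures <- data.frame(
    plate_id = plate_id,
    row = grid$row[img$well_i],
    col = grid$col[img$well_i],
    replicate = paste0("bio", img$replicate),
    image_index = img$image_index,
    n_cells = stats::rpois(n, config$mean_cells),
    median_traffic = well_mu[img$well_i] + stats::rnorm(n, 0, config$noise_sd),
    median_expression = config$background + stats::rnorm(n, 0, config$noise_sd),
    focus_metric = stats::runif(n, 0.7, 1),
    sirna_id = sirna[img$well_i],
    gene = gene[img$well_i],
    is_negative_control = is_neg[img$well_i],
    qc_truth = "pass",
    stringsAsFactors = FALSE
  )
  if (config$qc_fail_rate > 0) {
    fail <- which(stats::runif(n) < config$qc_fail_rate)
    mode <- sample(c("low_cells", "out_of_focus", "low_expression"),
                   length(fail), replace = TRUE)
    measures$qc_truth[fail] <- mode
    measures$n_cells[fail[mode == "low_cells"]] <-
      sample(0:99, sum(mode == "low_cells"), replace = TRUE)
    measures$focus_metric[fail[mode == "out_of_focus"]] <-
      stats::runif(sum(mode == "out_of_focus"), 0, 0.2)
    measures$median_expression[fail[mode == "low_expression"]] <-
      stats::runif(sum(mode == "low_expression"), 0, 1)
  }
  truth <- data.frame(plate_id = plate_id, well = wells, row = grid$row,
                      col = grid$col, sirna_id = sirna, gene = gene,
                      is_negative_control = is_neg, effect = unname(effect),
                      stringsAsFactors = FALSE)
  list(measures = measures, truth = truth)
}

#' Configuration for simulated FLIPR-style fluorescence traces
#'
#' A trace has three segments: baseline scans, post-agonist (forskolin)
#' response rising to `baseline * (1 + response_amplitude)`, and
#' post-inhibitor decay to `peak * (1 - inhibitor_drop)`. Drug-addition
#' times are explicit event markers, as the plate-reader operator knows
#' them.
#'
#' @param n_baseline_scans Scans before the agonist (>= 4, per protocol).
#' @param n_response_scans,n_inhibitor_scans Scans in the later segments.
#' @param baseline_value Baseline RFU.
#' @param response_amplitude Fractional fluorescence rise after agonist.
#' @param inhibitor_drop Fractional drop from peak after inhibitor, in
#'   [0, 1).
#' @param noise_sd Additive Gaussian noise SD (RFU).
#' @param scan_interval Seconds between scans.
#' @param seed Integer seed.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(n_baseline_scans = 5,
                             n_response_scans = 5,
                             n_inhibitor_scans = 5,
                             baseline_value = 100,
                             response_amplitude = 0.5,
                             inhibitor_drop = 0.3,
                             noise_sd = 0,
                             scan_interval = 60,
                             seed = 1L) {
  stop_if_not_count(n_baseline_scans, "n_baseline_scans")
  if (n_baseline_scans < 4) stop("n_baseline_scans must be >= 4 (protocol baseline)")
  if (inhibitor_drop < 0 || inhibitor_drop >= 1) stop("inhibitor_drop must be in [0, 1)")
  if (baseline_value <= 0) stop("baseline_value must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(as.list(environment())[c(
    "n_baseline_scans", "n_response_scans", "n_inhibitor_scans",
    "baseline_value", "response_amplitude", "inhibitor_drop", "noise_sd",
    "scan_interval", "seed")], class = "trace_sim_config")
}

#' Simulate a membrane-potential dye trace
#'
#' @param config A [trace_sim_config()].
#' @param responsive If `FALSE` the trace stays flat (up to noise) after
#'   the agonist: a cell line without functional channel activity.
#' @param sample_id Sample label for the trace.
#' @return An [assay_trace()] with `fsk` and `inhibitor` event markers.
#' @export
simulate_trace <- function(config, responsive = TRUE, sample_id = "sample1") {
  stopifnot(inherits(config, "trace_sim_config"))
  set.seed(config$seed + 3L)
  nb <- config$n_baseline_scans
  nr <- config$n_response_scans
  ni <- config$n_inhibitor_scans
  amp <- if (responsive) config$response_amplitude else 0
  drop <- if (responsive) config$inhibitor_drop else 0
  b <- config$baseline_value
  peak <- b * (1 + amp)
  floor_v <- peak * (1 - drop)
  # ramp reaches the peak exactly at the last pre-inhibitor scan, and the
  # floor exactly at the trace end, so noiseless metrics are exact
  response <- b + (peak - b) * seq_len(nr) / nr
  decay <- peak - (peak - floor_v) * seq_len(ni) / ni
  values <- c(rep(b, nb), response, decay)
  n <- length(values)
  times <- (seq_len(n) - 1) * config$scan_interval
  if (config$noise_sd > 0) values <- values + stats::rnorm(n, 0, config$noise_sd)
  events <- data.frame(
    label = c("fsk", "inhibitor"),
    time = c((times[nb] + times[nb + 1]) / 2,
             (times[nb + nr] + times[nb + nr + 1]) / 2)
  )
  assay_trace(times, values, events, sample_id = sample_id)
}

#' Simulate an organoid swelling (FIS) area series
#'
#' Relative organoid area, normalized to 100% at forskolin addition
#' (t = 0), rising linearly to `100 + swell_amplitude` percent at
#' `t_end` minutes.
#'
#' @param swell_amplitude Total percent-point area increase at `t_end`.
#' @param t_end Duration in minutes (default 60).
#' @param dt Sampling interval in minutes.
#' @param noise_sd Additive noise SD in percent points.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return An [assay_trace()] in percent-of-initial-area units with a
#'   `fsk` event at t = 0.
#' @export
simulate_swelling <- function(swell_amplitude = 60, t_end = 60, dt = 5,
                              noise_sd = 0, seed = 1L, sample_id = "org1") {
  set.seed(seed + 4L)
  times <- seq(0, t_end, by = dt)
  values <- 100 + swell_amplitude * times / t_end
  if (noise_sd > 0) values <- values + stats::rnorm(length(values), 0, noise_sd)
  values[1] <- 100  # normalization anchors the first frame
  assay_trace(times, values, data.frame(label = "fsk", time = 0),
              sample_id = sample_id)
}

#' Simulate an Ussing-chamber recording
#'
#' Transepithelial potential with a configured step after forskolin and a
#' reversion after inhibitor, at constant resistance.
#'
#' @param v_baseline Baseline potential (mV) after amiloride.
#' @param v_step Potential step (mV) added after forskolin.
#' @param rte Transepithelial resistance (Ohm cm^2), constant.
#' @param n_per_segment Samples per segment (amiloride / fsk / inhibitor).
#' @param noise_sd Additive noise SD on Vte (mV).
#' @param seed Integer seed.
#' @return An [ussing_recording()] with `amiloride`, `fsk` and
#'   `inhibitor` events.
#' @export
simulate_ussing <- function(v_baseline = 5, v_step = 10, rte = 1000,
                            n_per_segment = 20, noise_sd = 0, seed = 1L) {
  set.seed(seed + 5L)
  n <- n_per_segment
  times <- seq_len(3 * n)
  vte <- c(rep(v_baseline, n), rep(v_baseline + v_step, n), rep(v_baseline, n))
  if (noise_sd > 0) vte <- vte + stats::rnorm(length(vte), 0, noise_sd)
  events <- data.frame(label = c("amiloride", "fsk", "inhibitor"),
                       time = c(times[1] - 0.5, times[n] + 0.5, times[2 * n] + 0.5))
  ussing_recording(times, vte, rep(rte, 3 * n), events)
}
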