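# small helper: one flat plate's worth of per-image rows, built by hand
flat_measures <- function(nr = 8, nc = 8, value = 100, reps = "bio1",
                          images = 2) {
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc),
                   replicate = reps, image_index = seq_len(images),
                   stringsAsFactors = FALSE)
  data.frame(plate_id = "p1", g,
             n_cells = 500, median_traffic = value, median_expression = 1000,
             focus_metric = 0.9,
             sirna_id = sprintf("si_%02d_%02d", g$row, g$col),
             gene = sprintf("G%02d%02d", g$row, g$col),
             is_negative_control = g$col == 1,
             stringsAsFactors = FALSE)
}

test_that("QC boundaries: 99 cells rejected, 100 kept; reasons tallied", {
  m <- flat_measures()
  m$n_cells[1] <- 99
  m$n_cells[2] <- 100
  m$focus_metric[3] <- 0.1
  m$median_expression[4] <- 0  # below any plate quantile
  qc <- qc_filter(m)
  expect_equal(unname(qc$tally["low_cells"]), 1)
  expect_equal(unname(qc$tally["out_of_focus"]), 1)
  expect_equal(unname(qc$tally["low_expression"]), 1)
  expect_equal(qc$rejected$reason[qc$rejected$n_cells == 99], "low_cells")
  expect_false(2 %in% rownames(qc$rejected))
  expect_equal(nrow(qc$kept) + nrow(qc$rejected), nrow(m))
})

test_that("injected QC failures are recovered from the simulator truth", {
  cfg <- plate_sim_config(qc_fail_rate = 0.05, n_replicates = 2, seed = 81)
  sim <- simulate_plate(cfg)
  qc <- qc_filter(sim$measures, expression_threshold = 500)
  truth_fail <- sum(sim$measures$qc_truth != "pass")
  expect_equal(nrow(qc$rejected), truth_fail)
  expect_setequal(rownames(qc$rejected), rownames(sim$measures)[sim$measures$qc_truth != "pass"])
})

test_that("well summary is the median of image medians", {
  m <- flat_measures(nr = 1, nc = 1, images = 4)
  m$median_traffic <- c(1, 2, 3, 4)
  m$is_negative_control <- FALSE
  ws <- well_summary(m)
  expect_equal(ws$value, 2.5)
  expect_equal(ws$n_images, 4L)
  # single valid image -> that value
  ws1 <- well_summary(m[2, , drop = FALSE])
  expect_equal(ws1$value, 2)
})

test_that("constant plates give all-zero Z and a planar gradient is removed", {
  ws <- well_summary(flat_measures())
  z <- neighborhood_zscore(ws)
  expect_true(all(z$z == 0))
  # noiseless planar gradient, effects off: local reference removes it
  cfg <- plate_sim_config(n_rows = 16, n_cols = 24, gradient_amplitude = 0.3,
                          noise_sd = 0, n_replicates = 1, seed = 82)
  sim <- simulate_plate(cfg)
  z2 <- neighborhood_zscore(well_summary(qc_filter(sim$measures)$kept))
  interior <- z2$row >= 3 & z2$row <= 14 & z2$col >= 3 & z2$col <= 22
  expect_true(all(abs(z2$z[interior]) < 1))
})

test_that("a spiked well stands out and the scale is location/scale equivariant", {
  set.seed(83)
  ws <- well_summary(flat_measures(nr = 12, nc = 12))
  ws$value <- ws$value + rnorm(nrow(ws), 0, 5)
  spike_i <- which(ws$row == 6 & ws$col == 6)
  ws$value[spike_i] <- ws$value[spike_i] + 5 * 5  # +5 noise-SD
  z <- neighborhood_zscore(ws)
  expect_gt(z$z[spike_i], 1)
  expect_equal(mean(abs(z$z[-spike_i]) > abs(z$z[spike_i])), 0)
  # invariance: add a constant / multiply by a positive constant
  ws_shift <- ws; ws_shift$value <- ws$value + 1000
  expect_equal(neighborhood_zscore(ws_shift)$z, z$z)
  ws_scale <- ws; ws_scale$value <- ws$value * 7
  expect_equal(neighborhood_zscore(ws_scale)$z, z$z)
})

test_that("null Z-scores are calibrated (mean ~ 0, SD ~ 1)", {
  zs <- unlist(lapply(1:30, function(s) {
    cfg <- plate_sim_config(n_rows = 16, n_cols = 24, gradient_amplitude = 0.1,
                            noise_sd = 50, n_replicates = 1, seed = 900 + s)
    sim <- simulate_plate(cfg)
    neighborhood_zscore(well_summary(sim$measures))$z
  }))
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(abs(sd(zs) - 1), 0.1)
})

test_that("siRNA aggregation and gene calls follow the threshold rules", {
  d <- data.frame(
    plate_id = "p1", replicate = rep(paste0("bio", 1:4), times = 6),
    row = 1, col = rep(1:6, each = 4),
    sirna_id = rep(sprintf("si%d", 1:6), each = 4),
    gene = rep(c("AMBI", "AMBI", "FGL2", "FGL2", "UPUP", "UPUP"), each = 4),
    z = c(1.4, 1.5, 1.3, 1.6,      # si1: increase
          -1.2, -1.3, -1.1, -1.4,  # si2: decrease -> AMBI ambiguous
          0.46, 0.46, 0.46, 0.46,  # si3 }
          0.75, 0.75, 0.75, 0.75,  # si4 }  FGL2-like: consistent but sub-threshold
          1.2, 1.5, 0.9, 1.1,      # si5: median 1.15 -> increase
          0.2, 0.1, 0.0, 0.3),     # si6: none
    stringsAsFactors = FALSE)
  out <- aggregate_and_call(d)
  s <- out$sirna[match(sprintf("si%d", 1:6), out$sirna$sirna_id), ]
  expect_equal(s$z_score[5], 1.15)
  expect_equal(s$direction, c("increase", "decrease", "none", "none", "increase", "none"))
  g <- out$gene[match(c("AMBI", "FGL2", "UPUP"), out$gene$gene), ]
  expect_equal(g$gene_call, c("ambiguous", "none", "enhancer"))
  expect_true(all(s$n_valid_replicates == 4))
})

test_that("siRNAs with no valid wells are reported but not called", {
  d <- data.frame(plate_id = "p1", replicate = "bio1", row = 1, col = 1:2,
                  sirna_id = c("siA", "siB"), gene = c("GA", "GB"),
                  z = c(NA, 2), stringsAsFactors = FALSE)
  out <- aggregate_and_call(d)
  a <- out$sirna[out$sirna$sirna_id == "siA", ]
  expect_equal(a$n_valid_replicates, 0)
  expect_equal(a$direction, "none")
})
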