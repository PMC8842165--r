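hand_trace <- function(values, fsk_after = 5, inh_after = NULL) {
  times <- seq_along(values) * 10
  ev <- data.frame(label = "fsk", time = times[fsk_after] + 5)
  if (!is.null(inh_after)) {
    ev <- rbind(ev, data.frame(label = "inhibitor", time = times[inh_after] + 5))
  }
  assay_trace(times, values, ev)
}

test_that("FLIPR forskolin response: flat, constructed and scale-invariant", {
  flat <- hand_trace(rep(100, 12))
  expect_equal(flipr_fsk_response(flat), 1)
  tr <- hand_trace(c(rep(100, 5), 120, 150, 140, 130, 120, 110, 105))
  expect_equal(flipr_fsk_response(tr), 1.5)
  # scaling the whole trace leaves the ratio unchanged
  tr2 <- tr; tr2$values <- tr$values * 37.5
  expect_equal(flipr_fsk_response(tr2), 1.5)
  # baseline = "last" uses the final pre-fsk scan
  tr3 <- hand_trace(c(96, 99, 102, 103, 125, 150, 150, 150, 150, 150, 150, 150),
                    fsk_after = 4)
  expect_equal(flipr_fsk_response(tr3, baseline = "last"), 150 / 103)
  expect_equal(flipr_fsk_response(tr3), 150 / 100)
  # the max is taken before any inhibitor event
  tr4 <- hand_trace(c(rep(100, 5), 150, 140, 200, 200, 200, 200, 200),
                    inh_after = 7)
  expect_equal(flipr_fsk_response(tr4), 1.5)
  expect_error(flipr_fsk_response(hand_trace(c(-200, -200, -200, -200, -200, 1,
                                               1, 1, 1, 1, 1, 1))), "F0")
})

test_that("FLIPR inhibitor response matches the hand-built 12-point trace", {
  vals <- c(100, 100, 100, 100, 100, 120, 140, 150, 130, 115, 105, 100)
  tr <- hand_trace(vals, inh_after = 8)
  expect_equal(flipr_inhibitor_response(tr), 150 / 100)
  # no post-inhibitor decline -> 1.0
  tr_flat <- hand_trace(c(rep(100, 5), rep(150, 7)), inh_after = 8)
  expect_equal(flipr_inhibitor_response(tr_flat), 1)
  # scale invariance
  tr_big <- tr; tr_big$values <- vals * 3
  expect_equal(flipr_inhibitor_response(tr_big), 1.5)
})

test_that("normalization and pooled t-test match the textbook formulas", {
  vals <- c(1, 2, 3, 4, 5, 6)
  cond <- rep(c("ctrl", "trt"), each = 3)
  out <- normalize_and_test(vals, cond, "ctrl")
  expect_equal(out$fold, vals / 2)
  row <- out$summary[out$summary$condition == "trt", ]
  oracle <- brute_pooled_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(row$t, oracle$t)
  expect_equal(row$p, oracle$p)
  expect_equal(row$fold_mean, 2.5)
  # condition identical to control: fold 1, t = 0
  out2 <- normalize_and_test(c(1, 2, 3, 1, 2, 3), cond, "ctrl")
  row2 <- out2$summary[out2$summary$condition == "trt", ]
  expect_equal(row2$fold_mean, 1)
  expect_equal(row2$t, 0)
  expect_equal(row2$p, 1)
  expect_error(normalize_and_test(vals, cond, "missing"), "control")
})

test_that("t-test type-I error is near nominal under the null", {
  set.seed(101)
  hits <- vapply(1:10000, function(i) {
    v <- rnorm(6)
    out <- normalize_and_test(v + 10, rep(c("c", "t"), each = 3), "c")
    out$summary$p[out$summary$condition == "t"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("FIS AUC: degenerate, triangle and quadrature-oracle cases", {
  const <- assay_trace(seq(0, 60, 5), rep(100, 13),
                       data.frame(label = "fsk", time = 0))
  expect_equal(fis_auc(const), 0)
  lin <- assay_trace(seq(0, 60, 5), 100 + seq(0, 60, 5),
                     data.frame(label = "fsk", time = 0))
  expect_equal(fis_auc(lin), 1800)
  # piecewise series vs fine-step numeric integration of the interpolant
  set.seed(102)
  t <- seq(0, 80, 10)
  v <- 100 + cumsum(rnorm(9, 3, 4)); v[1] <- 100
  tr <- assay_trace(t, v, data.frame(label = "fsk", time = 0))
  fine_t <- seq(0, 60, 0.01)
  fine_v <- approx(t, v, xout = fine_t)$y - 100
  oracle <- sum((head(fine_v, -1) + tail(fine_v, -1)) / 2 * diff(fine_t))
  expect_equal(fis_auc(tr), oracle, tolerance = 1e-6)
  # additivity over subintervals
  expect_equal(fis_auc(tr, t_end = 30) +
                 sum(diff(t[t >= 30 & t <= 60]) *
                       (head(v[t >= 30 & t <= 60] - 100, -1) +
                          tail(v[t >= 30 & t <= 60] - 100, -1)) / 2),
               fis_auc(tr, t_end = 60))
  # short series integrates to its last point with a warning
  short <- assay_trace(seq(0, 40, 5), rep(100, 9),
                       data.frame(label = "fsk", time = 0))
  expect_warning(a <- fis_auc(short), "ends at")
  expect_equal(a, 0)
})

test_that("Ussing metrics follow Ohm's law and recover constructed steps", {
  rec <- simulate_ussing(v_baseline = 10, v_step = 0, rte = 1000, noise_sd = 0)
  m <- ussing_metrics(rec)
  expect_equal(m$ieq, rep(10, length(rec$times)))  # 10 mV / 1000 Ohm cm2 = 10 uA cm-2
  rec2 <- simulate_ussing(v_baseline = 5, v_step = 10, rte = 1000, noise_sd = 0)
  m2 <- ussing_metrics(rec2)
  expect_equal(m2$delta_fsk, 10)
  expect_equal(m2$delta_inhibitor, -10)
  # pointwise Ohm's law on random series
  set.seed(103)
  vte <- runif(30, -20, 20); rte <- runif(30, 500, 2000)
  rec3 <- ussing_recording(1:30, vte, rte,
                           data.frame(label = "fsk", time = 15.5))
  expect_equal(ussing_metrics(rec3)$ieq, 1000 * vte / rte)
  expect_error(ussing_recording(1:3, c(1, 2, 3), c(1, -1, 1),
                                data.frame(label = "fsk", time = 2)), "rte")
})

test_that("noisy Ussing recordings recover the configured step", {
  deltas <- vapply(1:100, function(s) {
    ussing_metrics(simulate_ussing(v_step = 10, noise_sd = 1, seed = s))$delta_fsk
  }, numeric(1))
  se <- sd(deltas) / 10
  expect_lt(abs(mean(deltas) - 10), 3 * se)
})

test_that("Western-blot folds and ANOVA match closed forms", {
  q <- data.frame(sample_id = sprintf("s%d", 1:9),
                  condition = rep(c("siNeg1", "siA", "siB"), each = 3),
                  band_b = c(1, 1.2, 0.8, 2, 2.1, 1.9, 3, 2.9, 3.1),
                  band_c = c(0.5, 0.6, 0.4, 1.5, 1.4, 1.6, 2.5, 2.4, 2.6),
                  calnexin = 1)
  out <- wb_fold_change(q, "siNeg1")
  expect_equal(out$folds$band_b_fold[1:3], c(1, 1.2, 0.8))
  expect_equal(mean(out$folds$band_c_fold[1:3]), 1)
  # band 2.0 / calnexin 0.5 over baseline mean 1.0 -> fold 4
  q2 <- data.frame(sample_id = c("a", "b", "c"),
                   condition = c("base", "base", "trt"),
                   band_b = c(1, 1, 2), band_c = c(1, 1, 2),
                   calnexin = c(1, 1, 0.5))
  expect_equal(wb_fold_change(q2, "base")$folds$band_b_fold[3], 4)
  # ANOVA F equals the sum-of-squares closed form
  set.seed(104)
  q3 <- data.frame(sample_id = sprintf("s%d", 1:9),
                   condition = rep(c("siNeg1", "siA", "siB"), each = 3),
                   band_b = rnorm(9, 2), band_c = rnorm(9, 1), calnexin = 1)
  out3 <- wb_fold_change(q3, "siNeg1")
  oracle <- brute_anova_f(q3$band_b, q3$condition)
  expect_equal(out3$anova$F[out3$anova$band == "band_b"], oracle$F)
  expect_equal(out3$anova$p[out3$anova$band == "band_b"], oracle$p)
  # zero calnexin excluded with a warning
  q4 <- q3; q4$calnexin[5] <- 0
  expect_warning(wb_fold_change(q4, "siNeg1"), "excluded")
})
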