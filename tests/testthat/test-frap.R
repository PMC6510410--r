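test_that("normalization implements the whole-nucleus ratio arithmetic", {
  mk <- function(I_o, A_o, I_t, A_t) {
    frap_trace(time_s = c(0, 0.1, 0.2), I_t = c(I_t, I_t, I_t),
               A_t = c(A_t, A_t, A_t), I_o = I_o, A_o = A_o)
  }
  # prebleach ratio: R = 1 when nothing changed
  expect_equal(normalize_recovery(mk(10, 100, 9.99, 100))$R[1],
               0.999, tolerance = 1e-12)
  # uniform 10% decay cancels exactly
  expect_identical(normalize_recovery(mk(10, 100, 9, 90))$R[1], 1.0)
  # direct arithmetic: (200 * 5) / (180 * 20)
  expect_equal(normalize_recovery(mk(20, 200, 5, 180))$R[1],
               1000 / 3600, tolerance = 1e-12)
  expect_equal(round(normalize_recovery(mk(20, 200, 5, 180))$R[1], 4), 0.2778)
  # non-positive nucleus intensity flags a segmentation failure
  bad <- mk(10, 100, 5, 90); bad$A_t[2] <- 0
  expect_error(normalize_recovery(bad), "non-positive")
})

test_that("a global gain change leaves the normalized recovery unchanged", {
  cfg <- frap_sim_config(noise_sd = 0, acquisition_decay_per_frame = 0.002)
  mv <- simulate_frap_movie(cfg)
  tr1 <- measure_trace(mv$stack, mv$nucleus_mask, mv$bleach_roi)
  tr2 <- measure_trace(mv$stack * 0.5, mv$nucleus_mask, mv$bleach_roi)
  expect_lt(max(abs(normalize_recovery(tr1)$R - normalize_recovery(tr2)$R)),
            1e-12)
})

test_that("measure_trace validates geometry and handles constant movies", {
  stack <- array(1, dim = c(40, 40, 5))
  nuc <- disk_image(40, 40, 20, 20, 15) > 0
  roi <- list(center = c(20, 24), radius = 4)
  # constant movie has no bleach: the trace constructor must refuse it
  expect_error(measure_trace(stack, nuc, roi), "bleach")
  # but the measured raw values are I_t = I_o, A_t = A_o throughout
  stack2 <- stack
  stack2[, , 2][disk_image(40, 40, 20, 24, 4) > 0] <- 0.2
  tr <- measure_trace(stack2, nuc, roi)
  expect_equal(tr$A_o, sum(nuc))
  expect_equal(tr$I_t[2:4], rep(tr$I_o, 3))
  expect_equal(tr$A_t[2:4], rep(tr$A_o, 3))
  expect_error(measure_trace(stack2, nuc, list(center = c(20, 37), radius = 4)),
               "outside")
  expect_error(measure_trace(stack2, nuc, roi, prebleach_index = 5), "precede")
})

test_that("fitting inverts the generator across the (k, plateau) grid", {
  for (k in c(0.5, 0.8, 1.0, 1.6, 1.9)) {
    for (p in c(0.85, 0.91, 1.0)) {
      cfg <- frap_sim_config(k_true = k, plateau_true = p, bleach_depth = 0.3,
                             noise_sd = 0, acquisition_decay_per_frame = 0)
      fit <- fit_recovery(normalize_recovery(simulate_frap_trace(cfg)))
      expect_true(fit$converged)
      expect_lt(abs(fit$k - k) / k, 1e-6)
      expect_lt(abs(fit$plateau - p) / p, 1e-6)
      expect_equal(fit$percent_recovery, 100 * fit$plateau)
    }
  }
})

test_that("flat or short inputs are flagged, not fitted", {
  flat <- data.frame(time_s = seq(0, 5.9, by = 0.1), R = rep(0.5, 60))
  fit <- fit_recovery(flat)
  expect_false(fit$converged)
  expect_true(is.na(fit$k))
  short <- data.frame(time_s = seq(0, 0.5, by = 0.1), R = runif(6))
  expect_error(fit_recovery(short), "at least 10")
})

test_that("noisy traces recover the true rate without systematic error", {
  cfg <- frap_sim_config(k_true = 1.0, plateau_true = 0.91, bleach_depth = 0.3,
                         noise_sd = 0.03, acquisition_decay_per_frame = 0.002)
  ks <- vapply(1:100, function(i) {
    tr <- simulate_frap_trace(cfg, seed = 1000 + i)
    fit_recovery(normalize_recovery(tr))$k
  }, numeric(1))
  ks <- ks[!is.na(ks)]
  expect_gt(length(ks), 95)
  sem <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 1.0), 3 * sem)
})

test_that("trial aggregation reports both per-trial and pooled fits", {
  cfg <- frap_sim_config(k_true = 1.6, noise_sd = 0.03, n_trials = 3,
                         n_cells_per_trial = 6, seed = 21)
  ex <- simulate_frap_experiment(cfg, "FL")
  curves <- curves_from_traces(ex$traces, ex$index)
  summ <- aggregate_trials(curves)
  expect_equal(nrow(summ), 1)
  expect_equal(summ$n_trials, 3)
  expect_true(all(c("k_mean", "k_sem", "pct_recovery_mean",
                    "k_avg_curve", "pct_recovery_avg_curve") %in% names(summ)))
  expect_lt(abs(summ$k_mean - 1.6), 0.2)
  # three identical trials: SEM exactly zero
  one <- curves[curves$trial == 1, ]
  trip <- do.call(rbind, lapply(1:3, function(t) transform(one, trial = t)))
  s3 <- aggregate_trials(trip)
  expect_equal(s3$k_sem, 0)
  expect_equal(s3$pct_recovery_sem, 0)
  expect_equal(s3$k_mean, s3$k_avg_curve, tolerance = 1e-8)
  # below three trials the SEM is suppressed with a warning
  expect_warning(s2 <- aggregate_trials(curves[curves$trial < 3, ]),
                 "fewer than 3")
  expect_true(is.na(s2$k_sem))
  # mismatched time grids are refused
  shift <- curves
  shift$time_s[shift$trial == 2] <- shift$time_s[shift$trial == 2] + 0.01
  expect_error(aggregate_trials(shift), "common time grid")
})

test_that("extending the acquisition window barely moves the plateau", {
  short_cfg <- frap_sim_config(k_true = 1.6, noise_sd = 0.01,
                               frame_interval_s = 0.1, n_frames = 60, seed = 3)
  long_cfg <- frap_sim_config(k_true = 1.6, noise_sd = 0.01,
                              frame_interval_s = 0.5, n_frames = 30, seed = 3)
  p_short <- fit_recovery(normalize_recovery(simulate_frap_trace(short_cfg)))$plateau
  p_long <- fit_recovery(normalize_recovery(simulate_frap_trace(long_cfg)))$plateau
  expect_lt(abs(p_long - p_short) / p_short, 0.02)
})

test_that("bleach-depth QC measures and compares first-frame fractions", {
  tr <- frap_trace(time_s = c(0, 0.1), I_t = c(3, 5), A_t = c(95, 95),
                   I_o = 10, A_o = 100)
  qc <- bleach_depth_qc(list(tr))
  expect_equal(qc$fractions$fraction, 0.3)
  # distinct depths at low noise are detected
  mk_group <- function(depth, seeds) {
    lapply(seeds, function(s) {
      simulate_frap_trace(frap_sim_config(bleach_depth = depth, noise_sd = 0.005),
                          seed = s)
    })
  }
  a <- mk_group(0.3, 1:6)
  b <- mk_group(0.6, 7:12)
  qc2 <- bleach_depth_qc(c(a, b), groups = rep(c("FL", "T490A"), each = 6))
  expect_lt(qc2$p_value, 0.001)
  expect_error(bleach_depth_qc(c(a, b), groups = rep("FL", 12)), "two groups")
})
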