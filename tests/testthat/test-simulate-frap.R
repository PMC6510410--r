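test_that("noise-free trace reproduces the closed-form model exactly", {
  cfg <- frap_sim_config(k_true = 1.6, plateau_true = 0.91, bleach_depth = 0.30,
                         noise_sd = 0, acquisition_decay_per_frame = 0)
  nr <- normalize_recovery(simulate_frap_trace(cfg))
  expect_lt(max(abs(nr$R - closed_form_R(nr$time_s, 1.6, 0.91, 0.30))), 1e-12)
  expect_equal(nr$time_s[1], 0)
  expect_equal(length(nr$R), 60)
})

test_that("vanishing recovery amplitude gives a flat trace at bleach depth", {
  eps <- 1e-9
  cfg <- frap_sim_config(k_true = 2.3, plateau_true = 0.30 + eps,
                         bleach_depth = 0.30, noise_sd = 0,
                         acquisition_decay_per_frame = 0)
  nr <- normalize_recovery(simulate_frap_trace(cfg))
  expect_lt(max(abs(nr$R - 0.30)), 1e-8)
})

test_that("uniform acquisition decay cancels in the normalization", {
  base <- frap_sim_config(noise_sd = 0, acquisition_decay_per_frame = 0)
  decayed <- frap_sim_config(noise_sd = 0, acquisition_decay_per_frame = 0.01)
  r0 <- normalize_recovery(simulate_frap_trace(base))$R
  r1 <- normalize_recovery(simulate_frap_trace(decayed))$R
  expect_lt(max(abs(r0 - r1)), 1e-9)
  # and the decayed raw series really does decay
  expect_lt(simulate_frap_trace(decayed)$A_t[60],
            simulate_frap_trace(base)$A_t[60])
})

test_that("config invariants are enforced", {
  expect_error(frap_sim_config(bleach_depth = 0.95, plateau_true = 0.91),
               "smaller than plateau")
  expect_error(frap_sim_config(k_true = -1), "positive")
  expect_error(frap_sim_config(plateau_true = 1.5), "\\(0, 1.2\\]")
  expect_error(frap_sim_config(noise_sd = -0.1), "non-negative")
})

test_that("traces are reproducible and experiments have full structure", {
  cfg <- frap_sim_config(noise_sd = 0.05, seed = 9)
  expect_identical(simulate_frap_trace(cfg)$I_t, simulate_frap_trace(cfg)$I_t)
  ex <- simulate_frap_experiment(frap_sim_config(n_trials = 3,
                                                 n_cells_per_trial = 4,
                                                 seed = 2), "FL")
  expect_length(ex$traces, 12)
  expect_equal(unique(ex$index$condition), "FL")
  expect_equal(table(ex$index$trial), table(rep(1:3, each = 4)),
               ignore_attr = TRUE)
  # distinct cells get distinct noise
  expect_false(identical(ex$traces[[1]]$I_t, ex$traces[[2]]$I_t))
})

test_that("noise-free movie agrees with the trace-level simulator", {
  cfg <- frap_sim_config(noise_sd = 0, acquisition_decay_per_frame = 0.002)
  mv <- simulate_frap_movie(cfg)
  tr <- measure_trace(mv$stack, mv$nucleus_mask, mv$bleach_roi)
  # same model evaluated through the pixel path
  cfg_match <- frap_sim_config(noise_sd = 0, acquisition_decay_per_frame = 0.002,
                               nucleus_area_px = mv$ground_truth$nucleus_area_px,
                               spot_area_px = mv$ground_truth$spot_area_px)
  ref <- simulate_frap_trace(cfg_match)
  expect_lt(max(abs(tr$I_t - ref$I_t)), 1e-9)
  expect_lt(max(abs(tr$A_t - ref$A_t)), 1e-9)
  expect_lt(max(abs(normalize_recovery(tr)$R - normalize_recovery(ref)$R)), 1e-9)
})

test_that("decay-free movies conserve total nuclear intensity post-bleach", {
  cfg <- frap_sim_config(noise_sd = 0, acquisition_decay_per_frame = 0)
  mv <- simulate_frap_movie(cfg)
  totals <- vapply(seq_len(dim(mv$stack)[3] - 1) + 1, function(j) {
    sum(mv$stack[, , j][mv$nucleus_mask])
  }, numeric(1))
  expect_lt(diff(range(totals)), 1e-9)
})

test_that("immobile-pool movies hold a constant post-bleach spot mean", {
  eps <- 1e-9
  cfg <- frap_sim_config(k_true = 1.0, plateau_true = 0.4 + eps,
                         bleach_depth = 0.4, noise_sd = 0,
                         acquisition_decay_per_frame = 0)
  mv <- simulate_frap_movie(cfg)
  tr <- measure_trace(mv$stack, mv$nucleus_mask, mv$bleach_roi)
  expect_lt(diff(range(tr$I_t)), 1e-8)
})

test_that("movie geometry is validated and scales by the area integral", {
  cfg <- frap_sim_config(noise_sd = 0, acquisition_decay_per_frame = 0)
  bad <- list(image_size_px = c(80L, 80L), nucleus_center = c(40, 40),
              nucleus_axes = c(20, 16), bleach_center = c(40, 70),
              bleach_radius = 5)
  expect_error(simulate_frap_movie(cfg, bad), "outside the nucleus")

  geo1 <- list(image_size_px = c(120L, 120L), nucleus_center = c(60, 60),
               nucleus_axes = c(28, 22), bleach_center = c(60, 66),
               bleach_radius = 5)
  geo2 <- geo1
  geo2$nucleus_axes <- c(28, 22) * sqrt(2)   # double the nucleus area
  mv1 <- simulate_frap_movie(cfg, geo1)
  mv2 <- simulate_frap_movie(cfg, geo2)
  tr1 <- measure_trace(mv1$stack, mv1$nucleus_mask, mv1$bleach_roi)
  tr2 <- measure_trace(mv2$stack, mv2$nucleus_mask, mv2$bleach_roi)
  # area-integral oracle: post-bleach the nuclear pool is N - (1 - B) * m,
  # and the spot recovers toward the remaining pool's concentration, so
  # I(t) scales with (N - (1 - B) * m) / N across nucleus sizes
  N1 <- mv1$ground_truth$nucleus_area_px
  N2 <- mv2$ground_truth$nucleus_area_px
  m <- mv1$ground_truth$spot_area_px
  expect_equal(mv2$ground_truth$spot_area_px, m)
  expect_gt(N2 / N1, 1.8)
  lost <- (1 - 0.30) * m
  expect_equal(tr2$A_t / tr1$A_t, rep((N2 - lost) / (N1 - lost), 60),
               tolerance = 1e-9)
  expect_equal(tr2$I_t / tr1$I_t,
               rep(((N2 - lost) / N2) / ((N1 - lost) / N1), 60),
               tolerance = 1e-9)
  # the spot's dependence on nucleus size is only through that pool factor
  expect_lt(max(abs(tr1$I_t - tr2$I_t)), 0.05)
})
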