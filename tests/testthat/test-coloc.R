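test_that("nuclear mask recovers disk geometry", {
  dapi <- disk_image(100, 100, 50, 50, 20)
  mask <- make_nuclear_mask(dapi, min_area_px = 50, smooth_sigma = 1)
  expect_equal(n_regions(mask), 1L)
  expect_lt(abs(mask$table$centroid_r - 50), 1)
  expect_lt(abs(mask$table$centroid_c - 50), 1)
  expect_lt(abs(mask$table$area_px - pi * 20^2) / (pi * 20^2), 0.05)
})

test_that("blank image yields an empty mask, not an error", {
  mask <- make_nuclear_mask(matrix(0, 64, 64))
  expect_equal(n_regions(mask), 0L)
})

test_that("simulated nuclei are segmented one-to-one", {
  cfg <- nucleus_sim_config(image_size_px = c(128, 230), n_nuclei = 2,
                            nucleus_radius_px = 22, poisson_scale = Inf,
                            read_noise_sd = 0, seed = 12)
  sim <- simulate_nucleus_image(cfg)
  mask <- make_nuclear_mask(get_channel(sim$image, "dapi"))
  truth <- sim$ground_truth$nuclei
  expect_equal(n_regions(mask), 2L)
  # one-to-one centroid matching against ground truth
  for (i in seq_len(2)) {
    d <- sqrt((mask$table$centroid_r - truth$center_r[i])^2 +
              (mask$table$centroid_c - truth$center_c[i])^2)
    expect_lt(min(d), 3)
    expect_equal(sum(d < 3), 1)
  }
})

test_that("background subtraction removes the extra-nuclear median", {
  mask <- make_nuclear_mask(disk_image(80, 80, 40, 40, 15), min_area_px = 20,
                            smooth_sigma = 1)
  # constant image: everything subtracted away
  const <- matrix(3.5, 80, 80)
  out <- subtract_background(const, mask)
  expect_true(all(out == 0))
  expect_equal(attr(out, "background"), 3.5)
  # signal s on background b: interior recovers s exactly
  img <- matrix(2, 80, 80)
  img[mask$labels == 1] <- 7
  out2 <- subtract_background(img, mask)
  expect_true(all(out2[mask$labels == 1] == 5))
  expect_true(all(out2[mask$labels == 0] == 0))
  # idempotence: second pass subtracts nothing
  out3 <- subtract_background(out2, mask)
  expect_identical(as.numeric(out3), as.numeric(out2))
  expect_equal(attr(out3, "background"), 0)
  # full-coverage mask has no background pixels
  full <- label_mask(matrix(1L, 80, 80))
  expect_error(subtract_background(img, full), "background")
})

test_that("pearson_rho hits the analytic anchor cases exactly", {
  sim <- simulate_nucleus_image(quiet_ncfg())
  mask <- make_nuclear_mask(get_channel(sim$image, "dapi"))
  a <- get_channel(sim$image, "h3k4me3")
  expect_identical(pearson_rho(a, a, mask, 1), 1.0)
  inv <- (max(a) + 1) - a
  expect_identical(pearson_rho(a, inv, mask, 1), -1.0)
  # invariance under positive affine gain/offset on either channel
  b <- get_channel(sim$image, "gfp")
  r0 <- pearson_rho(a, b, mask, 1)
  expect_equal(pearson_rho(2.7 * a + 5, b, mask, 1), r0, tolerance = 1e-12)
  expect_equal(pearson_rho(a, 0.3 * b + 1.1, mask, 1), r0, tolerance = 1e-12)
  # symmetry
  expect_equal(pearson_rho(b, a, mask, 1), r0, tolerance = 1e-15)
})

test_that("degenerate regions are flagged, tiny regions rejected", {
  m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
  mask <- label_mask(m)
  flat <- matrix(1, 10, 10)
  varying <- matrix(runif(100), 10, 10)
  expect_warning(r <- pearson_rho(flat, varying, mask, 1), "zero variance")
  expect_true(is.na(r))
  tiny <- label_mask(matrix(c(1L, 1L, rep(0L, 98)), 10, 10))
  expect_error(pearson_rho(varying, varying, tiny, 1), "3 pixels")
})

test_that("independent noise channels decorrelate at the null rate", {
  set.seed(11)
  m <- matrix(0L, 100, 100); m[1:100, 1:100] <- 1L
  mask <- label_mask(m)
  a <- matrix(rnorm(1e4), 100, 100)
  b <- matrix(rnorm(1e4), 100, 100)
  expect_lt(abs(pearson_rho(a, b, mask, 1)), 3 / sqrt(1e4))
})

test_that("per-cell records cover every simulated nucleus", {
  cfg <- nucleus_sim_config(image_size_px = c(250, 360), n_nuclei = 6,
                            nucleus_radius_px = 20, seed = 5)
  sim <- simulate_nucleus_image(cfg)
  mask <- make_nuclear_mask(get_channel(sim$image, "dapi"))
  rec <- per_cell_coloc(sim$image, mask,
                        pairs = list(c("gfp", "h3k4me3"), "gfp:h3k9me3"))
  expect_equal(nrow(rec), 6)
  expect_true(all(c("rho_gfp_h3k4me3", "rho_gfp_h3k9me3",
                    "mean_dapi", "mean_gfp") %in% names(rec)))
  expect_true(all(abs(rec$rho_gfp_h3k4me3) <= 1))
  # identical-channel pair: rho = 1 for every cell
  rec2 <- per_cell_coloc(sim$image, mask, pairs = list(c("dapi", "dapi")))
  expect_true(all(abs(rec2$rho_dapi_dapi - 1) < 1e-12))
  # empty mask: empty record table
  empty <- per_cell_coloc(sim$image, label_mask(matrix(0L, 250, 360)),
                          pairs = list(c("gfp", "h3k4me3")))
  expect_equal(nrow(empty), 0)
  expect_error(per_cell_coloc(sim$image, mask, pairs = list(c("gfp", "nope"))),
               "not in image")
})

test_that("per-region rho matches a brute-force two-pass oracle", {
  sim <- simulate_nucleus_image(
    nucleus_sim_config(image_size_px = c(250, 360), n_nuclei = 6,
                       nucleus_radius_px = 20, seed = 31)
  )
  a <- get_channel(sim$image, "gfp")
  b <- get_channel(sim$image, "h3k4me3")
  set.seed(202)
  lab <- matrix(0L, 250, 360)
  for (i in 1:50) {
    r0 <- sample(1:230, 1); c0 <- sample(1:340, 1)
    lab[r0:(r0 + sample(3:15, 1)), c0:(c0 + sample(3:15, 1))] <- i
  }
  mask <- label_mask(lab)
  for (id in mask$table$id) {
    sel <- mask$labels == id
    if (sum(sel) < 3 || sd(a[sel]) == 0 || sd(b[sel]) == 0) next
    expect_equal(pearson_rho(a, b, mask, id), brute_cor(a[sel], b[sel]),
                 tolerance = 1e-12)
  }
})

test_that("rho-vs-intensity regression recovers exact linear structure", {
  # constant rho: slope exactly 0
  rec <- data.frame(rho_x = rep(0.4, 8), mean_gfp = 1:8)
  qc <- rho_vs_intensity_qc(rec, "gfp", rho_col = "rho_x")
  expect_equal(qc$slope, 0, tolerance = 1e-14)
  # exact linear relation recovered to machine precision
  I <- seq(0.5, 4, length.out = 10)
  rec2 <- data.frame(rho_x = 0.1 + 0.003 * I, mean_gfp = I)
  qc2 <- rho_vs_intensity_qc(rec2, "gfp", rho_col = "rho_x")
  expect_equal(qc2$slope, 0.003, tolerance = 1e-9)
  expect_equal(qc2$intercept, 0.1, tolerance = 1e-9)
  expect_error(rho_vs_intensity_qc(rec2[1:2, ], "gfp", rho_col = "rho_x"),
               "at least 3")
})

test_that("rho-vs-intensity null: CI covers zero when rho is brightness-free", {
  set.seed(88)
  rec <- data.frame(rho_x = 0.4 + rnorm(40, sd = 0.05),
                    mean_gfp = runif(40, 0.5, 2))
  qc <- rho_vs_intensity_qc(rec, "gfp", rho_col = "rho_x")
  expect_lt(qc$ci[1], 0)
  expect_gt(qc$ci[2], 0)
})

test_that("line profiles interpolate bilinearly along the segment", {
  ramp <- outer(1:40, 1:50, function(r, c) 2 * r + 3 * c)
  img <- multichannel_image(list(x = ramp), 0.1)
  # horizontal line along a row reproduces that row exactly
  pr <- line_profile(img, c(7, 3), c(7, 12), channels = "x")
  expect_equal(pr$x, ramp[7, 3:12])
  expect_equal(nrow(pr), 10)
  # sample count is ceil(length) + 1
  d <- sqrt(10^2 + 17^2)
  pr2 <- line_profile(img, c(5, 6), c(15, 23), channels = "x")
  expect_equal(nrow(pr2), ceiling(d) + 1)
  # bilinear interpolation is exact on a linear ramp
  f <- seq(0, 1, length.out = nrow(pr2))
  rs <- 5 + f * 10; cs <- 6 + f * 17
  expect_equal(pr2$x, 2 * rs + 3 * cs, tolerance = 1e-9)
  expect_error(line_profile(img, c(0, 5), c(10, 10)), "inside")
  expect_error(line_profile(img, c(5, 5), c(41, 10)), "inside")
})
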