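#' Configuration for the synthetic nucleus-image simulator
#'
#' Builds a validated configuration for [simulate_nucleus_image()]. The
#' simulator draws elliptical nuclei whose DAPI channel is bright in a
#' peripheral heterochromatin rim plus random interior heterochromatin
#' blobs, and dim in the interchromatin (DAPI-poor) space between them.
#' H3K9me3 follows the heterochromatin pattern; H3K4me3 is rendered as
#' Gaussian puncta whose centers lie only in DAPI-poor pixels; the GFP
#' channel splits its nuclear mass between a uniform DAPI-poor pool and
#' the H3K4me3 puncta according to `gfp_puncta_association`.
#'
#' @param image_size_px integer pair, image height and width in pixels.
#' @param pixel_size_um physical pixel size (micrometers).
#' @param n_nuclei number of nuclei to place (0 allowed: blank field).
#' @param nucleus_radius_px mean nucleus radius in pixels.
#' @param radius_jitter fractional jitter applied to each ellipse semi-axis.
#' @param heterochromatin_fraction target fraction of nuclear area occupied
#'   by heterochromatin (rim + blobs), in \[0, 1\].
#' @param n_het_blobs_range integer pair: range of interior heterochromatin
#'   blob counts per nucleus.
#' @param n_puncta_per_nucleus number of H3K4me3 puncta per nucleus.
#' @param puncta_sigma_px Gaussian sigma of a rendered punctum, pixels.
#' @param puncta_min_sep_px minimum separation between punctum centers.
#' @param gfp_puncta_association in \[0, 1\]: 0 = GFP uniform over the
#'   DAPI-poor zone, 1 = all nuclear GFP concentrated at the puncta.
#' @param gfp_cytoplasm_fraction fraction of total GFP mass rendered in a
#'   dim cytoplasmic annulus around the nucleus, in \[0, 1\].
#' @param gfp_het_leak relative GFP intensity inside heterochromatin
#'   (1 = no exclusion; 0 = complete exclusion). High values emulate an
#'   unfused GFP control that diffuses freely through chromatin.
#' @param psf_sigma_px Gaussian PSF sigma in pixels (confocal ~1.1 px at
#'   0.1 um/px; SIM-like imaging ~0.45 px).
#' @param poisson_scale photons per intensity unit for shot noise; use
#'   `Inf` to disable Poisson noise.
#' @param read_noise_sd additive Gaussian read noise sd (intensity units);
#'   0 disables it.
#' @param pda_mode logical; emulates histone-demethylase inhibition by
#'   scaling H3K4me3 puncta count and amplitude up (H3K9me3 untouched).
#' @param pda_puncta_factor multiplier applied to puncta count and
#'   amplitude when `pda_mode` is on.
#' @param pda_association_factor multiplier applied to a nonzero
#'   `gfp_puncta_association` when `pda_mode` is on (capped at 1),
#'   representing PHD-dependent binding of the elevated H3K4me3 pool;
#'   constructs with zero association are unaffected.
#' @param seed integer seed; every random draw flows from it.
#' @return a `nucleus_sim_config` list.
#' @export
nucleus_sim_config <- function(image_size_px = c(256L, 256L),
                               pixel_size_um = 0.1,
                               n_nuclei = 4L,
                               nucleus_radius_px = 24,
                               radius_jitter = 0.1,
                               heterochromatin_fraction = 0.35,
                               n_het_blobs_range = c(3L, 8L),
                               n_puncta_per_nucleus = 10L,
                               puncta_sigma_px = 1.5,
                               puncta_min_sep_px = 10,
                               gfp_puncta_association = 0.3,
                               gfp_cytoplasm_fraction = 0.1,
                               gfp_het_leak = 0.15,
                               psf_sigma_px = 1.1,
                               poisson_scale = 200,
                               read_noise_sd = 0.01,
                               pda_mode = FALSE,
                               pda_puncta_factor = 1.5,
                               pda_association_factor = 1.25,
                               seed = 1L) {
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    n_nuclei = as.integer(n_nuclei),
    nucleus_radius_px = nucleus_radius_px,
    radius_jitter = radius_jitter,
    heterochromatin_fraction = heterochromatin_fraction,
    n_het_blobs_range = as.integer(n_het_blobs_range),
    n_puncta_per_nucleus = as.integer(n_puncta_per_nucleus),
    puncta_sigma_px = puncta_sigma_px,
    puncta_min_sep_px = puncta_min_sep_px,
    gfp_puncta_association = gfp_puncta_association,
    gfp_cytoplasm_fraction = gfp_cytoplasm_fraction,
    gfp_het_leak = gfp_het_leak,
    psf_sigma_px = psf_sigma_px,
    poisson_scale = poisson_scale,
    read_noise_sd = read_noise_sd,
    pda_mode = isTRUE(pda_mode),
    pda_puncta_factor = pda_puncta_factor,
    pda_association_factor = pda_association_factor,
    seed = as.integer(seed)
  )
  validate_nucleus_sim_config(cfg)
  class(cfg) <- "nucleus_sim_config"
  cfg
}

validate_nucleus_sim_config <- function(cfg) {
  if (length(cfg$image_size_px) != 2 || any(cfg$image_size_px <= 0)) {
    stop("image_size_px must be a pair of positive integers")
  }
  if (cfg$pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (cfg$n_nuclei < 0) stop("n_nuclei must be non-negative")
  if (cfg$nucleus_radius_px <= 0) stop("nucleus_radius_px must be positive")
  frac <- c(heterochromatin_fraction = cfg$heterochromatin_fraction,
            gfp_puncta_association = cfg$gfp_puncta_association,
            gfp_cytoplasm_fraction = cfg$gfp_cytoplasm_fraction,
            gfp_het_leak = cfg$gfp_het_leak,
            radius_jitter = cfg$radius_jitter)
  bad <- frac < 0 | frac > 1
  if (any(bad)) {
    stop(sprintf("fractions must lie in [0, 1]: %s",
                 paste(names(frac)[bad], collapse = ", ")))
  }
  if (cfg$n_puncta_per_nucleus < 0) stop("n_puncta_per_nucleus must be non-negative")
  if (cfg$puncta_sigma_px <= 0) stop("puncta_sigma_px must be positive")
  if (cfg$psf_sigma_px <= 0) stop("psf_sigma_px must be positive")
  if (cfg$poisson_scale <= 0) stop("poisson_scale must be positive (use Inf to disable)")
  if (cfg$read_noise_sd < 0) stop("read_noise_sd must be non-negative")
  invisible(cfg)
}

#' GFP-construct presets for the nucleus simulator
#'
#' Convenience parameter bundles representing GFP-RAG2 constructs studied
#' in pre-B nuclei: full-length protein (`"FL"`), the T490A noncore mutant
#' (stronger H3K4me3 association, `"T490A"`), the core truncation lacking
#' the PHD (`"Core"`), the PHD-dead double mutant (`"W453A.T490A"`), and
#' unfused GFP (`"GFP"`, near-homogeneous labeling). Association strengths
#' are free simulator parameters chosen to reproduce the qualitative
#' ordering of the constructs, not measured values.
#'
#' @param condition one of `"FL"`, `"T490A"`, `"Core"`, `"W453A.T490A"`, `"GFP"`.
#' @param ... overrides passed on to [nucleus_sim_config()].
#' @return a `nucleus_sim_config`.
#' @export
nucleus_preset <- function(condition = c("FL", "T490A", "Core", "W453A.T490A", "GFP"),
                           ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    FL = list(gfp_puncta_association = 0.30, gfp_cytoplasm_fraction = 0.15,
              gfp_het_leak = 0.15),
    T490A = list(gfp_puncta_association = 0.60, gfp_cytoplasm_fraction = 0.05,
                 gfp_het_leak = 0.15),
    Core = list(gfp_puncta_association = 0.25, gfp_cytoplasm_fraction = 0.10,
                gfp_het_leak = 0.15),
    W453A.T490A = list(gfp_puncta_association = 0.30, gfp_cytoplasm_fraction = 0.05,
                       gfp_het_leak = 0.15),
    GFP = list(gfp_puncta_association = 0, gfp_cytoplasm_fraction = 0.5,
               gfp_het_leak = 0.85)
  )
  args <- utils::modifyList(base, list(...))
  do.call(nucleus_sim_config, args)
}

# Run expr with a temporarily-seeded RNG, restoring global state after.
with_sim_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derived per-nucleus seed: stable when n_nuclei changes.
sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483647)
}

#' Simulate a multi-channel nucleus field
#'
#' Renders `dapi`, `gfp`, `h3k4me3` and `h3k9me3` channels for a field of
#' synthetic nuclei, applies Gaussian PSF blur and Poisson + Gaussian
#' detection noise, and returns the image together with a ground-truth
#' record (noise-free channel maps, nucleus label image, heterochromatin
#' and DAPI-poor zone masks, punctum centers).
#'
#' By construction H3K9me3 co-varies with DAPI, H3K4me3 anti-varies with
#' DAPI (its puncta are confined to DAPI-poor pixels), and the GFP channel
#' concentrates in DAPI-poor pixels with extra mass at the puncta in
#' proportion to `gfp_puncta_association`.
#'
#' @param config a [nucleus_sim_config()].
#' @return list with elements `image` ([multichannel_image]) and
#'   `ground_truth` (class `nucleus_ground_truth`).
#' @examples
#' sim <- simulate_nucleus_image(nucleus_sim_config(n_nuclei = 1, seed = 7))
#' sim$image
#' @export
simulate_nucleus_image <- function(config) {
  validate_nucleus_sim_config(config)
  h <- config$image_size_px[1]
  w <- config$image_size_px[2]
  blank <- matrix(0, h, w)
  gt <- list(
    nucleus_labels = matrix(0L, h, w),
    het_mask = matrix(FALSE, h, w),
    eu_mask = matrix(FALSE, h, w),
    puncta = data.frame(nucleus = integer(0), r = numeric(0), c = numeric(0)),
    nuclei = data.frame(id = integer(0), center_r = numeric(0),
                        center_c = numeric(0), axis_a = numeric(0),
                        axis_b = numeric(0), theta = numeric(0)),
    config = config
  )
  maps <- list(dapi = blank, gfp = blank, h3k4me3 = blank, h3k9me3 = blank)

  if (config$n_nuclei > 0) {
    centers <- nucleus_grid_centers(h, w, config)
    for (i in seq_len(config$n_nuclei)) {
      one <- with_sim_seed(sub_seed(config$seed, i), {
        render_one_nucleus(config, centers[i, ], h, w, i)
      })
      for (ch in names(maps)) maps[[ch]] <- maps[[ch]] + one$maps[[ch]]
      gt$nucleus_labels[one$mask] <- i
      gt$het_mask <- gt$het_mask | one$het
      gt$eu_mask <- gt$eu_mask | one$eu
      gt$puncta <- rbind(gt$puncta, one$puncta)
      gt$nuclei <- rbind(gt$nuclei, one$geom)
    }
  }

  # optical blur, then detection noise (per channel, independent)
  maps <- lapply(maps, blur_psf, sigma = config$psf_sigma_px)
  gt$noise_free <- maps
  noisy <- with_sim_seed(sub_seed(config$seed, 0L), {
    lapply(maps, add_detection_noise,
           poisson_scale = config$poisson_scale,
           read_noise_sd = config$read_noise_sd)
  })
  img <- multichannel_image(noisy, pixel_size_um = config$pixel_size_um)
  class(gt) <- "nucleus_ground_truth"
  list(image = img, ground_truth = gt)
}

# Non-overlapping placement: nuclei on a jittered grid.
nucleus_grid_centers <- function(h, w, config) {
  n <- config$n_nuclei
  rmax <- config$nucleus_radius_px * (1 + config$radius_jitter)
  nc <- ceiling(sqrt(n * w / h))
  nr <- ceiling(n / nc)
  cell_h <- h / nr
  cell_w <- w / nc
  if (min(cell_h, cell_w) < 2 * rmax + 2) {
    stop("nuclei do not fit in the field: reduce n_nuclei or nucleus_radius_px")
  }
  jit <- max(0, (min(cell_h, cell_w) / 2 - rmax - 1) * 0.8)
  centers <- matrix(0, n, 2)
  with_sim_seed(sub_seed(config$seed, 999983L), {
    for (i in seq_len(n)) {
      ri <- (i - 1) %/% nc
      ci <- (i - 1) %% nc
      centers[i, ] <- c((ri + 0.5) * cell_h + runif(1, -jit, jit),
                        (ci + 0.5) * cell_w + runif(1, -jit, jit))
    }
    centers
  })
}

render_one_nucleus <- function(config, center, h, w, id) {
  j <- config$radius_jitter
  a <- config$nucleus_radius_px * (1 + runif(1, -j, j))
  b <- config$nucleus_radius_px * (1 + runif(1, -j, j))
  theta <- runif(1, 0, pi)

  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- rr - center[1]
  dc <- cc - center[2]
  u <- (dr * cos(theta) + dc * sin(theta)) / a
  v <- (-dr * sin(theta) + dc * cos(theta)) / b
  rho2 <- u^2 + v^2        # normalized squared ellipse radius
  mask <- rho2 <= 1

  # heterochromatin: peripheral rim sized for ~60% of the target fraction,
  # the rest in 3-8 interior blobs
  f <- config$heterochromatin_fraction
  q2 <- 1 - 0.6 * f        # rim: rho2 in (q2, 1]
  het <- mask & rho2 > q2
  nb <- sample(seq(config$n_het_blobs_range[1], config$n_het_blobs_range[2]), 1)
  blob_r <- sqrt(a * b) * sqrt(0.4 * f / max(nb, 1))
  for (k in seq_len(nb)) {
    br <- sqrt(runif(1)) * 0.75
    ang <- runif(1, 0, 2 * pi)
    bu <- br * cos(ang)
    bv <- br * sin(ang)
    bcr <- center[1] + bu * a * cos(theta) - bv * b * sin(theta)
    bcc <- center[2] + bu * a * sin(theta) + bv * b * cos(theta)
    het <- het | (mask & ((rr - bcr)^2 + (cc - bcc)^2 <= blob_r^2))
  }
  eu <- mask & !het

  pda_f <- if (config$pda_mode) config$pda_puncta_factor else 1
  n_pun <- round(config$n_puncta_per_nucleus * pda_f)
  amp_pun <- 1.0 * pda_f

  # punctum centers: only DAPI-poor pixels, with minimum separation
  pun <- sample_puncta_centers(eu, n_pun, config$puncta_min_sep_px)
  puncta_map <- matrix(0, h, w)
  if (nrow(pun) > 0) {
    for (k in seq_len(nrow(pun))) {
      puncta_map <- puncta_map +
        gaussian_spot(h, w, pun$r[k], pun$c[k], config$puncta_sigma_px)
    }
  }

  dapi <- 0.3 * mask + 0.7 * het
  h3k9 <- 0.15 * mask + 0.85 * het
  # H3K4me3 is purely punctate (superresolution shows discrete foci); a
  # diffuse euchromatin term would alias the GFP pool's zone shape and
  # break the monotone link between association and measured rho
  h3k4 <- amp_pun * puncta_map * eu

  # GFP: nuclear mass split between a uniform DAPI-poor pool (with partial
  # leak into heterochromatin) and the puncta; plus a cytoplasmic annulus
  assoc <- config$gfp_puncta_association
  if (config$pda_mode && assoc > 0) {
    # PHD-competent constructs bind the elevated H3K4me3 pool
    assoc <- min(1, assoc * config$pda_association_factor)
  }
  leak <- config$gfp_het_leak
  zone <- eu + leak * het          # relative occupancy pattern
  zone_mass <- sum(zone)
  pmass <- sum(puncta_map * eu)
  nuc_total <- sum(mask) * 0.5     # arbitrary intensity scale
  gfp <- matrix(0, h, w)
  if (zone_mass > 0) {
    gfp <- gfp + (1 - assoc) * nuc_total * zone / zone_mass
  }
  if (assoc > 0 && pmass > 0) {
    gfp <- gfp + assoc * nuc_total * puncta_map * eu / pmass
  }
  cyto_frac <- config$gfp_cytoplasm_fraction
  if (cyto_frac > 0) {
    ring <- !mask & rho2 <= 1.3^2
    if (sum(ring) > 0) {
      # mass such that cytoplasm holds cyto_frac of the cell's total GFP
      cyto_mass <- sum(gfp) * cyto_frac / (1 - cyto_frac)
      gfp <- gfp + ring * (cyto_mass / sum(ring))
    }
  }

  list(
    maps = list(dapi = dapi, gfp = gfp, h3k4me3 = h3k4, h3k9me3 = h3k9),
    mask = mask, het = het, eu = eu,
    puncta = if (nrow(pun) > 0) {
      data.frame(nucleus = id, r = pun$r, c = pun$c)
    } else {
      data.frame(nucleus = integer(0), r = numeric(0), c = numeric(0))
    },
    geom = data.frame(id = id, center_r = center[1], center_c = center[2],
                      axis_a = a, axis_b = b, theta = theta)
  )
}

sample_puncta_centers <- function(eu, n, min_sep) {
  out <- data.frame(r = numeric(0), c = numeric(0))
  if (n == 0) return(out)
  cand <- which(eu, arr.ind = TRUE)
  if (nrow(cand) == 0) return(out)
  ord <- sample.int(nrow(cand))
  for (i in ord) {
    p <- cand[i, ]
    if (nrow(out) == 0 ||
        min((out$r - p[1])^2 + (out$c - p[2])^2) >= min_sep^2) {
      out <- rbind(out, data.frame(r = p[1], c = p[2]))
      if (nrow(out) == n) break
    }
  }
  out
}

gaussian_spot <- function(h, w, r0, c0, sigma) {
  ext <- ceiling(4 * sigma)
  rs <- max(1, floor(r0 - ext)):min(h, ceiling(r0 + ext))
  cs <- max(1, floor(c0 - ext)):min(w, ceiling(c0 + ext))
  m <- matrix(0, h, w)
  gr <- exp(-((rs - r0)^2) / (2 * sigma^2))
  gc <- exp(-((cs - c0)^2) / (2 * sigma^2))
  m[rs, cs] <- outer(gr, gc)
  m
}

blur_psf <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

add_detection_noise <- function(m, poisson_scale, read_noise_sd) {
  out <- m
  if (is.finite(poisson_scale)) {
    out <- matrix(rpois(length(m), lambda = pmax(m, 0) * poisson_scale),
                  nrow(m), ncol(m)) / poisson_scale
  }
  if (read_noise_sd > 0) {
    out <- out + matrix(rnorm(length(m), sd = read_noise_sd), nrow(m), ncol(m))
  }
  pmax(out, 0)
}

#' Simulate a double-labeled field for the correlation ceiling
#'
#' One underlying label structure (the simulated H3K4me3 distribution) is
#' imaged through two detection channels that differ only in gain and in
#' independent Gaussian detection noise — the in-silico analogue of
#' staining one primary antibody with two distinct secondary antibodies.
#' The resulting `label_a` / `label_b` channel pair bounds the Pearson
#' correlation attainable by the imaging system at that noise level
#' (see [calibration_ceiling()]).
#'
#' @param config a [nucleus_sim_config()]; supplies the structure, PSF and
#'   the DAPI channel used for masking.
#' @param noise_a,noise_b Gaussian detection-noise sd for the two channels
#'   (must be non-negative).
#' @param gain_a,gain_b channel gains (positive; Pearson rho is gain-free).
#' @param structure_amplitude multiplier on the shared structure; 0 gives
#'   two channels of pure independent noise.
#' @return a [multichannel_image] with channels `dapi`, `label_a`, `label_b`.
#' @export
simulate_double_label <- function(config, noise_a, noise_b,
                                  gain_a = 1, gain_b = 1,
                                  structure_amplitude = 1) {
  if (noise_a < 0 || noise_b < 0) stop("noise sds must be non-negative")
  if (gain_a <= 0 || gain_b <= 0) stop("gains must be positive")
  sim <- simulate_nucleus_image(config)
  s <- sim$ground_truth$noise_free$h3k4me3 * structure_amplitude
  dapi <- get_channel(sim$image, "dapi")
  h <- nrow(s); w <- ncol(s)
  noisy <- with_sim_seed(sub_seed(config$seed, 424243L), {
    list(
      a = gain_a * s + matrix(rnorm(h * w, sd = noise_a), h, w),
      b = gain_b * s + matrix(rnorm(h * w, sd = noise_b), h, w)
    )
  })
  multichannel_image(
    list(dapi = dapi,
         label_a = pmax(noisy$a, 0),
         label_b = pmax(noisy$b, 0)),
    pixel_size_um = config$pixel_size_um
  )
}

#' Detection-noise level for a target correlation ceiling
#'
#' For two detections of one structure with independent additive Gaussian
#' noise of sd `sigma`, the expected Pearson correlation is
#' `s^2 / (s^2 + sigma^2)` where `s` is the structure's pixelwise sd
#' within the nucleus. Inverting this gives the noise level at which the
#' imaging system's correlation ceiling equals `ceiling`. The default
#' target of 0.70 reproduces the ceiling typical of confocal double-label
#' calibrations of immunostained chromatin marks.
#'
#' @param config a [nucleus_sim_config()]; the noise-free structure is
#'   simulated once to measure `s`.
#' @param ceiling target mean Pearson rho, in (0, 1).
#' @return noise sd (intensity units) to pass as `noise_a` / `noise_b` to
#'   [simulate_double_label()].
#' @export
double_label_noise_for_ceiling <- function(config, ceiling = 0.70) {
  if (ceiling <= 0 || ceiling >= 1) stop("ceiling must lie in (0, 1)")
  sim <- simulate_nucleus_image(config)
  s <- sim$ground_truth$noise_free$h3k4me3
  lab <- sim$ground_truth$nucleus_labels
  sds <- vapply(seq_len(max(lab, 1)), function(i) {
    v <- s[lab == i]
    if (length(v) > 1) sd(v) else NA_real_
  }, numeric(1))
  s_bar <- mean(sds, na.rm = TRUE)
  if (!is.finite(s_bar) || s_bar == 0) stop("structure has no variance within nuclei")
  s_bar * sqrt((1 - ceiling) / ceiling)
}
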