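#' Configuration for the FRAP simulator
#'
#' Parameterizes simulated fluorescence-recovery experiments. The model is
#' a one-component exponential in the normalized-recovery domain:
#' \deqn{R(t) = P - (P - B) e^{-k t}}
#' with rate constant `k_true` (1/s), plateau `plateau_true` (P) and
#' bleach depth `bleach_depth` (B, the normalized spot signal immediately
#' after the bleach). The simulated raw series additionally carry the two
#' instrumental effects that the whole-nucleus normalization is designed
#' to remove: a multiplicative per-frame acquisition photobleaching decay
#' applied to both spot and nucleus, and the loss of whole-nucleus signal
#' caused by the fluorophore mass destroyed in the bleach itself.
#'
#' @param k_true recovery rate constant, 1/s (> 0).
#' @param plateau_true plateau of the normalized recovery, in (0, 1.2\].
#' @param bleach_depth normalized spot signal remaining immediately after
#'   the bleach, in \[0, 1); must be smaller than `plateau_true`.
#' @param acquisition_decay_per_frame fractional fluorescence loss per
#'   acquired frame, in \[0, 1).
#' @param frame_interval_s time between frames, seconds.
#' @param n_frames number of post-bleach frames.
#' @param noise_sd additive Gaussian noise sd on the spot series, in units
#'   of the prebleach spot intensity. Whole-nucleus noise is scaled down by
#'   `sqrt(spot_area_px / nucleus_area_px)` (averaging over a larger area).
#' @param n_cells_per_trial FRAP measurements per trial.
#' @param n_trials number of independent trials.
#' @param nucleus_area_px,spot_area_px areas (pixels) used to convert
#'   between spot-mean and nucleus-total intensities.
#' @param seed integer seed.
#' @return a `frap_sim_config` list.
#' @export
frap_sim_config <- function(k_true = 1.6,
                            plateau_true = 0.91,
                            bleach_depth = 0.30,
                            acquisition_decay_per_frame = 0.002,
                            frame_interval_s = 0.1,
                            n_frames = 60L,
                            noise_sd = 0.03,
                            n_cells_per_trial = 10L,
                            n_trials = 3L,
                            nucleus_area_px = 1600,
                            spot_area_px = 79,
                            seed = 1L) {
  cfg <- list(k_true = k_true, plateau_true = plateau_true,
              bleach_depth = bleach_depth,
              acquisition_decay_per_frame = acquisition_decay_per_frame,
              frame_interval_s = frame_interval_s,
              n_frames = as.integer(n_frames),
              noise_sd = noise_sd,
              n_cells_per_trial = as.integer(n_cells_per_trial),
              n_trials = as.integer(n_trials),
              nucleus_area_px = nucleus_area_px,
              spot_area_px = spot_area_px,
              seed = as.integer(seed))
  validate_frap_sim_config(cfg)
  class(cfg) <- "frap_sim_config"
  cfg
}

validate_frap_sim_config <- function(cfg) {
  if (cfg$k_true <= 0) stop("k_true must be positive")
  if (cfg$plateau_true <= 0 || cfg$plateau_true > 1.2) {
    stop("plateau_true must lie in (0, 1.2]")
  }
  if (cfg$bleach_depth < 0 || cfg$bleach_depth >= 1) {
    stop("bleach_depth must lie in [0, 1)")
  }
  if (cfg$bleach_depth >= cfg$plateau_true) {
    stop("bleach_depth must be smaller than plateau_true")
  }
  if (cfg$acquisition_decay_per_frame < 0 || cfg$acquisition_decay_per_frame >= 1) {
    stop("acquisition_decay_per_frame must lie in [0, 1)")
  }
  if (cfg$frame_interval_s <= 0) stop("frame_interval_s must be positive")
  if (cfg$n_frames < 1) stop("n_frames must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$n_cells_per_trial < 1 || cfg$n_trials < 1) {
    stop("n_cells_per_trial and n_trials must be positive")
  }
  if (cfg$nucleus_area_px <= cfg$spot_area_px || cfg$spot_area_px <= 0) {
    stop("need 0 < spot_area_px < nucleus_area_px")
  }
  invisible(cfg)
}

#' FRAP condition presets for GFP-RAG2 constructs
#'
#' Ground-truth kinetic parameters for the four GFP-RAG2 constructs
#' measured by FRAP in pre-B cell nuclei: full-length RAG2 (`FL`), the
#' noncore mutant `T490A` (half the recovery rate of FL), the PHD-less
#' `Core` truncation, and the PHD-dead double mutant `W453A.T490A`.
#' Rate constants and plateaus reflect published pre-B-cell measurements
#' of these constructs; bleach depths are simulator choices (T490A is
#' given a slightly lower post-bleach intercept, as its slower exchange
#' captures less recovery within the bleach frame).
#'
#' @return data.frame with columns `condition`, `k_true`, `plateau_true`,
#'   `bleach_depth`.
#' @export
frap_condition_presets <- function() {
  data.frame(
    condition = c("FL", "T490A", "Core", "W453A.T490A"),
    k_true = c(1.6, 0.8, 1.9, 1.8),
    plateau_true = c(0.91, 0.91, 0.90, 0.91),
    bleach_depth = c(0.30, 0.25, 0.30, 0.30),
    stringsAsFactors = FALSE
  )
}

# Closed-form normalized recovery model.
frap_model_R <- function(t, k, plateau, bleach_depth) {
  plateau - (plateau - bleach_depth) * exp(-k * t)
}

# Shared deterministic backbone for trace- and movie-level simulators.
# Returns per-frame noise-free quantities (prebleach frame excluded).
frap_series_noise_free <- function(cfg, nucleus_area = cfg$nucleus_area_px,
                                   spot_area = cfg$spot_area_px) {
  t <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval_s
  I_o <- 1                                   # spot mean, prebleach
  A_o <- nucleus_area                        # nucleus total, prebleach
  lost <- (1 - cfg$bleach_depth) * spot_area # fluorophore mass destroyed
  A_base <- A_o - lost
  decay <- (1 - cfg$acquisition_decay_per_frame)^seq_len(cfg$n_frames)
  R <- frap_model_R(t, cfg$k_true, cfg$plateau_true, cfg$bleach_depth)
  A_t <- decay * A_base
  I_t <- R * I_o * A_t / A_o
  list(time_s = t, I_t = I_t, A_t = A_t, I_o = I_o, A_o = A_o, R = R)
}

#' Simulate one FRAP intensity trace
#'
#' Generates a spot/nucleus intensity trace from the one-component
#' exponential recovery model, with multiplicative acquisition decay
#' applied identically to spot and whole-nucleus series, whole-nucleus
#' signal reduced by the bleached fluorophore mass, and additive Gaussian
#' noise. With noise and decay both zero, [normalize_recovery()] applied
#' to the result reproduces the closed-form model exactly.
#'
#' @param config a [frap_sim_config()].
#' @param seed optional seed override (defaults to `config$seed`).
#' @return a [frap_trace].
#' @export
simulate_frap_trace <- function(config, seed = config$seed) {
  validate_frap_sim_config(config)
  nf <- frap_series_noise_free(config)
  sd_I <- config$noise_sd * nf$I_o
  sd_A <- config$noise_sd * nf$A_o *
    sqrt(config$spot_area_px / config$nucleus_area_px)
  noisy <- with_sim_seed(seed, {
    list(I = nf$I_t + rnorm(length(nf$I_t), sd = sd_I),
         A = nf$A_t + rnorm(length(nf$A_t), sd = sd_A))
  })
  frap_trace(time_s = nf$time_s, I_t = noisy$I, A_t = pmax(noisy$A, 1e-9),
             I_o = nf$I_o, A_o = nf$A_o)
}

#' Simulate a multi-trial FRAP experiment
#'
#' Draws `n_trials` x `n_cells_per_trial` independent traces from one
#' configuration, each with its own derived seed.
#'
#' @param config a [frap_sim_config()].
#' @param condition optional condition label attached to the output.
#' @return list with `traces` (list of [frap_trace]) and `index`
#'   (data.frame: condition, trial, cell, trace list-index).
#' @export
simulate_frap_experiment <- function(config, condition = "cond") {
  validate_frap_sim_config(config)
  traces <- list()
  idx <- expand.grid(cell = seq_len(config$n_cells_per_trial),
                     trial = seq_len(config$n_trials))
  idx$condition <- condition
  for (i in seq_len(nrow(idx))) {
    traces[[i]] <- simulate_frap_trace(config, seed = sub_seed(config$seed, i))
  }
  idx$trace <- seq_len(nrow(idx))
  list(traces = traces, index = idx[, c("condition", "trial", "cell", "trace")])
}

#' Simulate a FRAP movie
#'
#' Renders the trace-level model as an image stack: a uniformly labeled
#' elliptical nucleus, one prebleach frame, then post-bleach frames in
#' which the bleach-spot pixels follow the recovery model while the
#' remaining nuclear pixels carry the balance of the (conserved, then
#' acquisition-decayed) nuclear signal. Measuring the stack with
#' [measure_trace()] reproduces the trace-level simulator.
#'
#' @param config a [frap_sim_config()]; `nucleus_area_px` / `spot_area_px`
#'   are ignored in favor of the pixel-counted areas of `geometry`.
#' @param geometry list with `image_size_px` (pair), `nucleus_center`
#'   (row, col), `nucleus_axes` (semi-axes, px), `bleach_center` (row, col),
#'   `bleach_radius` (px). Defaults mimic an 80 x 80 acquisition ROI with a
#'   10-pixel-diameter bleach circle.
#' @return list: `stack` (h x w x (n_frames + 1) array, frame 1 prebleach),
#'   `nucleus_mask` (logical matrix), `bleach_roi` (list: center, radius),
#'   `prebleach_index` (1), `ground_truth` (noise-free series + areas).
#' @export
simulate_frap_movie <- function(config,
                                geometry = list(
                                  image_size_px = c(80L, 80L),
                                  nucleus_center = c(40, 40),
                                  nucleus_axes = c(30, 24),
                                  bleach_center = c(40, 48),
                                  bleach_radius = 5
                                )) {
  validate_frap_sim_config(config)
  h <- geometry$image_size_px[1]
  w <- geometry$image_size_px[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  nuc <- ((rr - geometry$nucleus_center[1]) / geometry$nucleus_axes[1])^2 +
         ((cc - geometry$nucleus_center[2]) / geometry$nucleus_axes[2])^2 <= 1
  spot <- (rr - geometry$bleach_center[1])^2 +
          (cc - geometry$bleach_center[2])^2 <= geometry$bleach_radius^2
  if (any(spot & !nuc)) stop("bleach ROI extends outside the nucleus")
  if (!any(spot)) stop("bleach ROI contains no pixels")
  N <- sum(nuc)
  m <- sum(spot)
  nf <- frap_series_noise_free(config, nucleus_area = N, spot_area = m)

  stack <- array(0, dim = c(h, w, config$n_frames + 1))
  stack[, , 1][nuc] <- 1                    # uniform prebleach labeling
  for (j in seq_len(config$n_frames)) {
    A_j <- nf$A_t[j]
    s_j <- nf$I_t[j]                        # spot pixel value (mean = value)
    u_j <- (A_j - s_j * m) / (N - m)        # balance over the rest
    fr <- matrix(0, h, w)
    fr[nuc] <- u_j
    fr[spot] <- s_j
    stack[, , j + 1] <- fr
  }
  if (config$noise_sd > 0) {
    stack <- with_sim_seed(sub_seed(config$seed, 777773L), {
      stack + array(rnorm(length(stack), sd = config$noise_sd), dim = dim(stack))
    })
    stack <- pmax(stack, 0)
  }
  list(stack = stack, nucleus_mask = nuc,
       bleach_roi = list(center = geometry$bleach_center,
                         radius = geometry$bleach_radius),
       prebleach_index = 1L,
       ground_truth = c(nf, list(nucleus_area_px = N, spot_area_px = m)))
}
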