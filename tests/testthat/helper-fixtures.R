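# Shared fixtures and independent oracles used across test files.

# Small, fast simulator configuration; noise off unless a test turns it on.
quiet_ncfg <- function(...) {
  defaults <- list(
    image_size_px = c(128L, 128L), n_nuclei = 1L, nucleus_radius_px = 24,
    poisson_scale = Inf, read_noise_sd = 0, seed = 42L
  )
  do.call(nucleus_sim_config, utils::modifyList(defaults, list(...)))
}

# Independent two-pass Pearson correlation (oracle for pearson_rho).
brute_cor <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Synthetic disk image: binary disk of radius r centered at (r0, c0).
disk_image <- function(h, w, r0, c0, radius, value = 1) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  value * (((rr - r0)^2 + (cc - c0)^2) <= radius^2)
}

# Closed-form one-component recovery model (oracle for the simulator/fit).
closed_form_R <- function(t, k, plateau, bleach) {
  plateau - (plateau - bleach) * exp(-k * t)
}
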