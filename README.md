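# nucleodyn

Quantitative imaging of nuclear protein localization and dynamics.

Chromatin-reader proteins such as the V(D)J recombinase subunit RAG2
concentrate in the DAPI-poor interchromatin space of the nucleus, where the
active-chromatin mark H3K4me3 sits in discrete puncta, and are excluded from
DAPI-rich heterochromatin marked by H3K9me3. Two measurements characterize
how a GFP-tagged construct engages this landscape:

* **Where it sits** — per-cell Pearson colocalization of the GFP channel
  with immunolabeled histone marks, restricted to a DAPI-derived nuclear
  mask, plus the fraction of each H3K4me3 punctum covered by GFP signal in
  high-resolution images.
* **How fast it moves** — FRAP: a small spot is bleached and the recovery
  of its fluorescence reports the protein's exchange rate and mobile
  fraction.

`nucleodyn` implements both, for users analyzing multi-channel nucleus
images and FRAP movies/traces (cell biologists, imaging-core analysts), and
pairs them with a seeded synthetic-microscopy simulator so the entire
pipeline can be exercised and validated without microscope data.

## The statistics at the core

**Pearson colocalization.** For each nucleus, over its masked,
background-subtracted pixels,

ρ = Σ(aᵢ − ā)(bᵢ − b̄) / √(Σ(aᵢ − ā)² Σ(bᵢ − b̄)²) ∈ [−1, 1],

measured per cell and summarized over trials. A double-label calibration
(one structure, two detection channels) gives the instrument's ceiling on
ρ; for Gaussian detection noise σ on structure of sd s the ceiling is
s²/(s² + σ²).

**FRAP normalization and fit.** Spot intensity I and whole-nucleus
intensity A (prebleach values I₀, A₀) are combined into the
double-normalized recovery

R(t) = (A₀ · Iₜ) / (Aₜ · I₀),

which cancels acquisition photobleaching and corrects for the fluorophore
mass destroyed by the bleach. R(t) is fit with a one-component exponential

R(t) = P − (P − R₀)·exp(−k·t),

giving the rate constant k (s⁻¹) and percent recovery 100·P.

## Worked example

Simulate a field of six nuclei with a strongly puncta-associated construct,
mask, background-subtract, and measure per-cell colocalization:

```r
library(nucleodyn)

cfg <- nucleus_preset("T490A", n_nuclei = 6, image_size_px = c(256, 384),
                      nucleus_radius_px = 22, seed = 11)
sim  <- simulate_nucleus_image(cfg)
mask <- make_nuclear_mask(get_channel(sim$image, "dapi"))
chans <- lapply(channel_names(sim$image),
                function(ch) subtract_background(get_channel(sim$image, ch), mask))
img <- multichannel_image(setNames(chans, channel_names(sim$image)),
                          sim$image$pixel_size_um)
rec <- per_cell_coloc(img, mask,
                      pairs = list(c("gfp", "h3k4me3"), c("gfp", "h3k9me3")))
round(rec[, 1:4], 3)
#>   cell_id area_px rho_gfp_h3k4me3 rho_gfp_h3k9me3
#> 1       1    1572           0.970          -0.351
#> 2       2    2013           0.972          -0.355
#> 3       3    1789           0.969          -0.366
#> 4       4    1788           0.970          -0.371
#> 5       5    1640           0.968          -0.329
#> 6       6    1758           0.969          -0.355
```

Each row is one nucleus: the construct correlates strongly with the
H3K4me3 puncta it binds (ρ ≈ 0.97 at this association strength and noise
level) and anti-correlates with heterochromatin-resident H3K9me3
(ρ ≈ −0.35).

Simulate a three-trial FRAP experiment for a slow-exchanging construct and
run the normalize → average → fit pipeline:

```r
fcfg <- frap_sim_config(k_true = 0.8, plateau_true = 0.91,
                        bleach_depth = 0.25, seed = 11)
ex   <- simulate_frap_experiment(fcfg, "T490A")
summ <- aggregate_trials(curves_from_traces(ex$traces, ex$index))
print(summ, digits = 3)
#>   condition n_trials k_mean  k_sem pct_recovery_mean pct_recovery_sem
#> 1     T490A        3  0.802 0.0129              90.9             0.27
#>   k_avg_curve pct_recovery_avg_curve
#> 1       0.802                   90.9
```

The fitted rate constant (0.80 ± 0.01 s⁻¹) and percent recovery (90.9%)
recover the generating parameters (0.8 s⁻¹, 91%); `k_mean`/`k_sem`
summarize per-trial fits while `k_avg_curve` fits the trial-averaged
curve. `frap_condition_presets()` carries published pre-B-cell kinetics
for the FL, T490A, Core and W453A,T490A GFP-RAG2 constructs.

A thin command-line wrapper is installed at
`system.file("scripts", "nucleodyn", package = "nucleodyn")` with
subcommands `simulate-nucleus`, `simulate-frap`, `coloc`, `puncta` and
`frap-fit`.

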