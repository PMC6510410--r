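#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing followed by Otsu thresholding, hole filling,
#' removal of small objects and of objects touching the image border,
#' then connected-component labeling. A blank (all-zero) image yields an
#' empty mask rather than an error.
#'
#' @param dapi 2D numeric matrix of non-negative finite intensities.
#' @param min_area_px minimum object area kept, pixels.
#' @param smooth_sigma Gaussian smoothing sigma before thresholding, px.
#' @return a [label_mask] with one label per nucleus.
#' @export
make_nuclear_mask <- function(dapi, min_area_px = 200, smooth_sigma = 2) {
  if (is.null(dim(dapi))) stop("`dapi` must be a matrix")
  if (any(!is.finite(dapi)) || any(dapi < 0)) {
    stop("`dapi` must be finite and non-negative")
  }
  rng <- range(dapi)
  if (rng[2] <= rng[1]) {
    return(label_mask(matrix(0L, nrow(dapi), ncol(dapi))))
  }
  sm <- if (smooth_sigma > 0) blur_psf(dapi, smooth_sigma) else dapi
  norm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  lab <- as.matrix(lab)
  # drop small and border-touching objects
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(which(areas < min_area_px), setdiff(border_ids, 0L))
    lab[lab %in% drop] <- 0L
  }
  label_mask(lab)
}

#' Subtract the extra-nuclear background
#'
#' The scalar background is the median intensity over all pixels outside
#' the labeled nuclei; it is subtracted from every pixel and the result is
#' clipped at zero. The estimated background is attached as attribute
#' `"background"`.
#'
#' @param image 2D numeric matrix.
#' @param mask a [label_mask] on the same grid (typically nuclei).
#' @return background-subtracted matrix, clipped at 0.
#' @export
subtract_background <- function(image, mask) {
  stopifnot(inherits(mask, "label_mask"))
  if (!identical(dim(image), dim(mask$labels))) {
    stop("image and mask must share dimensions")
  }
  outside <- mask$labels == 0L
  if (!any(outside)) stop("mask covers the entire image: no background pixels")
  bg <- median(image[outside])
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}

#' Pearson correlation of two channels within one labeled region
#'
#' Standard product-moment correlation over the pixels of a single region.
#' If either channel is constant over the region the correlation is
#' undefined; `NA` is returned with a warning so that the record can be
#' excluded from population statistics.
#'
#' @param chan_a,chan_b 2D numeric matrices on the mask's grid.
#' @param mask a [label_mask].
#' @param region region id to evaluate.
#' @return Pearson rho in \[-1, 1\], or `NA` for a degenerate region.
#' @export
pearson_rho <- function(chan_a, chan_b, mask, region) {
  stopifnot(inherits(mask, "label_mask"))
  sel <- mask$labels == region
  n <- sum(sel)
  if (n < 3) stop("region must contain at least 3 pixels")
  a <- chan_a[sel]
  b <- chan_b[sel]
  if (sd(a) == 0 || sd(b) == 0) {
    warning(sprintf("region %d: zero variance in a channel; rho undefined", region))
    return(NA_real_)
  }
  cor(a, b)
}

parse_pairs <- function(pairs) {
  if (is.character(pairs)) pairs <- as.list(pairs)
  lapply(pairs, function(p) {
    if (is.character(p) && length(p) == 1) p <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(p) != 2) stop("each pair must name exactly two channels")
    as.character(p)
  })
}

#' Per-cell colocalization measurements
#'
#' Computes Pearson rho for each requested channel pair within each
#' labeled nucleus, along with per-channel mean intensities and region
#' area. One row per nucleus; degenerate (zero-variance) regions carry
#' `NA` in the affected rho column.
#'
#' @param image a [multichannel_image] (channels should already be
#'   background-subtracted; see [subtract_background()]).
#' @param mask a [label_mask] of nuclei.
#' @param pairs list of 2-element channel-name vectors, or strings of the
#'   form `"gfp:h3k4me3"`.
#' @return data.frame with columns `cell_id`, `area_px`, one
#'   `rho_<a>_<b>` column per pair, and one `mean_<channel>` column per
#'   channel present in the image.
#' @export
per_cell_coloc <- function(image, mask, pairs = list(c("gfp", "h3k4me3"))) {
  stopifnot(inherits(image, "multichannel_image"), inherits(mask, "label_mask"))
  pairs <- parse_pairs(pairs)
  for (p in pairs) {
    for (ch in p) {
      if (!ch %in% channel_names(image)) stop(sprintf("channel '%s' not in image", ch))
    }
  }
  ids <- mask$table$id
  chans <- channel_names(image)
  out <- data.frame(cell_id = ids, area_px = mask$table$area_px)
  for (p in pairs) {
    col <- sprintf("rho_%s_%s", p[1], p[2])
    out[[col]] <- vapply(ids, function(id) {
      pearson_rho(get_channel(image, p[1]), get_channel(image, p[2]), mask, id)
    }, numeric(1))
  }
  for (ch in chans) {
    m <- get_channel(image, ch)
    out[[sprintf("mean_%s", ch)]] <- vapply(ids, function(id) {
      mean(m[mask$labels == id])
    }, numeric(1))
  }
  out
}

#' Correlation ceiling from a double-labeled field
#'
#' Mean per-nucleus Pearson rho between the two detection channels of a
#' double-label acquisition (one structure, two secondaries). This bounds
#' the rho attainable for truly colocalized signals at the system's noise
#' level: 1 at zero noise, decreasing as detection noise grows.
#'
#' @param image a [multichannel_image] from [simulate_double_label()] (or a
#'   real double-label field) with the two detection channels.
#' @param mask a [label_mask] of nuclei.
#' @param pair the two detection channel names.
#' @return list: `ceiling` (mean rho), `sem` (over nuclei), `n`, and the
#'   per-cell `records`.
#' @export
calibration_ceiling <- function(image, mask, pair = c("label_a", "label_b")) {
  rec <- per_cell_coloc(image, mask, pairs = list(pair))
  col <- sprintf("rho_%s_%s", pair[1], pair[2])
  rho <- rec[[col]][!is.na(rec[[col]])]
  if (length(rho) == 0) stop("no usable nuclei for the calibration ceiling")
  list(ceiling = mean(rho),
       sem = if (length(rho) > 1) sd(rho) / sqrt(length(rho)) else NA_real_,
       n = length(rho),
       records = rec)
}

#' Regression QC: does rho depend on labeling intensity?
#'
#' Ordinary least-squares regression of per-cell rho on per-cell mean
#' channel intensity. A slope indistinguishable from zero indicates that
#' the measured colocalization is not an artifact of label brightness.
#'
#' @param records output of [per_cell_coloc()].
#' @param channel channel whose mean intensity is the predictor.
#' @param rho_col name of the rho column to regress (defaults to the first
#'   `rho_` column present).
#' @return list: `slope`, `intercept`, `ci` (95% CI on the slope),
#'   `n`, and the fitted `lm` object.
#' @export
rho_vs_intensity_qc <- function(records, channel, rho_col = NULL) {
  if (is.null(rho_col)) {
    rho_col <- grep("^rho_", names(records), value = TRUE)[1]
  }
  icol <- sprintf("mean_%s", channel)
  if (!icol %in% names(records)) stop(sprintf("no column '%s' in records", icol))
  d <- records[!is.na(records[[rho_col]]), c(rho_col, icol)]
  if (nrow(d) < 3) stop("need at least 3 records for the regression")
  names(d) <- c("rho", "intensity")
  fit <- lm(rho ~ intensity, data = d)
  ci <- suppressWarnings(confint(fit, "intensity", level = 0.95))
  list(slope = unname(coef(fit)["intensity"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       ci = c(ci[1], ci[2]),
       n = nrow(d),
       fit = fit)
}

#' Intensity profile along a line segment
#'
#' Samples one or more channels at unit-pixel spacing along the segment
#' from `p0` to `p1` using bilinear interpolation. Coordinates are
#' (row, col) with pixel centers at integer positions.
#'
#' @param image a [multichannel_image].
#' @param p0,p1 numeric (row, col) endpoints, inside the image.
#' @param channels channel names to sample (default: all).
#' @return data.frame with `distance_px` and one column per channel;
#'   `ceiling(||p1 - p0||) + 1` rows.
#' @export
line_profile <- function(image, p0, p1, channels = channel_names(image)) {
  stopifnot(inherits(image, "multichannel_image"))
  d <- dim(image$channels[[1]])
  for (p in list(p0, p1)) {
    if (length(p) != 2 || p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2]) {
      stop("endpoints must lie inside the image")
    }
  }
  len <- sqrt(sum((p1 - p0)^2))
  n <- ceiling(len) + 1
  f <- if (n == 1) 0 else seq(0, 1, length.out = n)
  rs <- p0[1] + f * (p1[1] - p0[1])
  cs <- p0[2] + f * (p1[2] - p0[2])
  out <- data.frame(distance_px = f * len)
  for (ch in channels) {
    out[[ch]] <- bilinear_sample(get_channel(image, ch), rs, cs)
  }
  out
}

bilinear_sample <- function(m, rs, cs) {
  h <- nrow(m); w <- ncol(m)
  r0 <- pmin(pmax(floor(rs), 1), h - 1)
  c0 <- pmin(pmax(floor(cs), 1), w - 1)
  # degenerate 1-row/col images: clamp offsets
  if (h == 1) r0 <- rep(1, length(rs))
  if (w == 1) c0 <- rep(1, length(cs))
  fr <- rs - r0
  fc <- cs - c0
  r1 <- pmin(r0 + 1, h)
  c1 <- pmin(c0 + 1, w)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc +
    m[cbind(r1, c1)] * fr * fc
}
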