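#' Write / read a multi-channel image as multi-page TIFF
#'
#' Channels are stored as 32-bit float TIFF pages in a fixed order. TIFF
#' page values must lie in \[0, 1\], so each channel is divided by its
#' maximum on write; the per-channel scale factors, channel names and
#' pixel size go into a JSON sidecar (`<file>.json`) and are re-applied on
#' read, so a round trip restores the container to 32-bit float precision.
#'
#' @param image a [multichannel_image].
#' @param path output `.tif` path.
#' @return (invisibly) the path written.
#' @export
write_multichannel_tiff <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  scales <- vapply(image$channels, function(ch) max(ch, 1e-300), numeric(1))
  pages <- mapply(function(ch, s) ch / s, image$channels, scales,
                  SIMPLIFY = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(channels = channel_names(image),
         scales = unname(scales),
         pixel_size_um = image$pixel_size_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_multichannel_tiff
#' @param pixel_size_um pixel size override when no sidecar is present.
#' @param channels channel-name override when no sidecar is present.
#' @export
read_multichannel_tiff <- function(path, pixel_size_um = NULL, channels = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(channels)) channels <- meta$channels
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
    if (!is.null(meta$scales)) {
      pages <- mapply(function(p, s) p * s, pages, meta$scales,
                      SIMPLIFY = FALSE)
    }
  }
  if (is.null(channels)) channels <- sprintf("channel%d", seq_along(pages))
  if (is.null(pixel_size_um)) stop("pixel_size_um unknown: no sidecar found")
  if (length(channels) != length(pages)) {
    stop("channel name count does not match TIFF page count")
  }
  multichannel_image(setNames(pages, channels), pixel_size_um = pixel_size_um)
}

#' Write / read FRAP traces as CSV
#'
#' One CSV per trace, columns `frame`, `time_s`, `spot_intensity`,
#' `nucleus_intensity`, `is_prebleach`. The prebleach frame is stored as
#' frame 0 with `is_prebleach = TRUE` and a time of `NA`.
#'
#' @param trace a [frap_trace].
#' @param path output `.csv` path.
#' @return (invisibly) the path written.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  d <- data.frame(
    frame = c(0L, seq_along(trace$time_s)),
    time_s = c(NA_real_, trace$time_s),
    spot_intensity = c(trace$I_o, trace$I_t),
    nucleus_intensity = c(trace$A_o, trace$A_t),
    is_prebleach = c(TRUE, rep(FALSE, length(trace$time_s)))
  )
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  pre <- d[d$is_prebleach, ]
  post <- d[!d$is_prebleach, ]
  if (nrow(pre) != 1) stop("trace CSV must contain exactly one prebleach row")
  frap_trace(time_s = post$time_s, I_t = post$spot_intensity,
             A_t = post$nucleus_intensity,
             I_o = pre$spot_intensity, A_o = pre$nucleus_intensity)
}

#' Write / read simulator configurations as YAML
#'
#' @param config a `nucleus_sim_config` or `frap_sim_config`.
#' @param path output `.yaml` path.
#' @return (invisibly) the path written.
#' @export
write_config_yaml <- function(config, path) {
  kind <- class(config)[1]
  payload <- unclass(config)
  payload$.kind <- kind
  # YAML has no Inf literal guaranteed round-trippable across parsers
  if (!is.null(payload$poisson_scale) && is.infinite(payload$poisson_scale)) {
    payload$poisson_scale <- ".inf"
  }
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  payload <- yaml::read_yaml(path)
  kind <- payload$.kind
  payload$.kind <- NULL
  if (identical(payload$poisson_scale, ".inf")) payload$poisson_scale <- Inf
  builder <- switch(kind,
    nucleus_sim_config = nucleus_sim_config,
    frap_sim_config = frap_sim_config,
    stop("unknown config kind: ", kind)
  )
  do.call(builder, payload)
}

#' Write ground truth as a JSON sidecar
#'
#' Serializes the tabular parts of a `nucleus_ground_truth` (nucleus
#' geometry, punctum centers, configuration); the pixel-level maps are
#' image-sized and belong in TIFF, not JSON.
#'
#' @param gt a `nucleus_ground_truth` from [simulate_nucleus_image()].
#' @param path output `.json` path.
#' @return (invisibly) the path written.
#' @export
write_ground_truth_json <- function(gt, path) {
  stopifnot(inherits(gt, "nucleus_ground_truth"))
  cfg <- unclass(gt$config)
  if (is.infinite(cfg$poisson_scale)) cfg$poisson_scale <- ".inf"
  jsonlite::write_json(
    list(nuclei = gt$nuclei, puncta = gt$puncta, config = cfg),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' Write a label mask as 16-bit TIFF
#'
#' @param mask a [label_mask].
#' @param path output `.tif` path.
#' @return (invisibly) the path written.
#' @export
write_label_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) stop("too many labels for 16-bit storage")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  label_mask(round(m * 65535))
}
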