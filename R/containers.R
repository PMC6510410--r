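#' Multi-channel image container
#'
#' Bundles named 2D intensity channels that share one pixel grid, together
#' with the physical pixel size. All imaging operations in the package take
#' and return this container (or individual channel matrices drawn from it).
#'
#' @param channels named list of numeric matrices, all the same dimension,
#'   finite and non-negative.
#' @param pixel_size_um physical pixel size in micrometers (scalar > 0).
#' @return An object of class `multichannel_image`: a list with elements
#'   `channels` and `pixel_size_um`.
#' @examples
#' img <- multichannel_image(list(dapi = matrix(1, 8, 8)), pixel_size_um = 0.1)
#' channel_names(img)
#' @export
multichannel_image <- function(channels, pixel_size_um) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("every channel must be a matrix")
  }
  d0 <- dims[[1]]
  for (d in dims) {
    if (!identical(d, d0)) stop("all channels must share the same dimensions")
  }
  for (ch in channels) {
    if (any(!is.finite(ch))) stop("channel intensities must be finite")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a positive scalar")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um),
    class = "multichannel_image"
  )
}

#' @rdname multichannel_image
#' @param x a `multichannel_image`.
#' @export
channel_names <- function(x) names(x$channels)

#' Extract one channel as a matrix
#'
#' @param x a `multichannel_image`.
#' @param name channel name.
#' @return the channel's intensity matrix.
#' @export
get_channel <- function(x, name) {
  stopifnot(inherits(x, "multichannel_image"))
  if (!name %in% names(x$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(x$channels), collapse = ", ")))
  }
  x$channels[[name]]
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> %d x %d px (%.3f um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Labeled-region mask
#'
#' Integer label image (0 = background, 1..n = regions) plus a region table
#' with area and centroid per label. Used both for nuclei and for puncta.
#' Pixel coordinates are 1-based (row, col) matrix indices; centroids are
#' intensity-free (geometric).
#'
#' @param labels integer matrix of region ids (0 background).
#' @return `label_mask` object: list with `labels` (integer matrix) and
#'   `table` (data.frame: id, area_px, centroid_r, centroid_c).
#' @export
label_mask <- function(labels) {
  if (is.null(dim(labels))) stop("`labels` must be a matrix")
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    # relabel to contiguous 1..n
    lut <- integer(max(ids))
    lut[ids] <- seq_along(ids)
    pos <- labels > 0L
    labels[pos] <- lut[labels[pos]]
    ids <- seq_along(ids)
  }
  tab <- region_table(labels, ids)
  structure(list(labels = labels, table = tab), class = "label_mask")
}

region_table <- function(labels, ids) {
  if (length(ids) == 0) {
    return(data.frame(id = integer(0), area_px = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0)))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  area <- tabulate(lab, nbins = max(ids))
  cr <- vapply(split(idx[, 1], lab), mean, numeric(1))
  cc <- vapply(split(idx[, 2], lab), mean, numeric(1))
  data.frame(id = ids, area_px = area[ids],
             centroid_r = unname(cr), centroid_c = unname(cc))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d region(s)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$table)))
  invisible(x)
}

#' Number of regions in a label mask
#' @param x a `label_mask`.
#' @export
n_regions <- function(x) nrow(x$table)

#' FRAP trace container
#'
#' Post-bleach spot and whole-nucleus intensity series together with their
#' prebleach references. Time is measured from the first post-bleach frame
#' (`time_s[1] == 0`); the prebleach frame itself is stored only through
#' `I_o` and `A_o` and is excluded from fitting.
#'
#' @param time_s non-negative times of the post-bleach frames, seconds.
#' @param I_t spot (bleach-ROI) intensity per post-bleach frame.
#' @param A_t whole-nucleus total intensity per post-bleach frame.
#' @param I_o prebleach spot intensity (> 0).
#' @param A_o prebleach whole-nucleus intensity (> 0).
#' @return `frap_trace` object.
#' @export
frap_trace <- function(time_s, I_t, A_t, I_o, A_o) {
  n <- length(time_s)
  if (length(I_t) != n || length(A_t) != n) {
    stop("time_s, I_t and A_t must have equal length")
  }
  if (n < 1) stop("trace must contain at least one post-bleach frame")
  if (any(time_s < 0) || is.unsorted(time_s)) {
    stop("time_s must be non-negative and increasing")
  }
  if (!is.finite(I_o) || I_o <= 0) stop("prebleach spot intensity I_o must be > 0")
  if (!is.finite(A_o) || A_o <= 0) stop("prebleach nucleus intensity A_o must be > 0")
  if (I_t[1] >= I_o) {
    stop("first post-bleach spot intensity must be below the prebleach value (no bleach detected)")
  }
  structure(list(time_s = as.numeric(time_s), I_t = as.numeric(I_t),
                 A_t = as.numeric(A_t), I_o = as.numeric(I_o),
                 A_o = as.numeric(A_o)),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames over %.2f s; bleach depth I1/Io = %.3f\n",
              length(x$time_s), max(x$time_s), x$I_t[1] / x$I_o))
  invisible(x)
}
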