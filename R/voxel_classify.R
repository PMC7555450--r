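#' Threshold and noise-filter configuration
#'
#' One low-intensity threshold per channel (same units as the stored
#' intensities; a voxel is positive when its intensity strictly exceeds the
#' threshold) plus the minimum-area filter used to discard small noise
#' regions. Thresholds are always user-supplied per experiment; see
#' [auto_thresholds()] for an explicit, never-implicit initializer.
#'
#' @param thresholds named numeric, one value per channel in
#'   \code{TK_CHANNELS}; a single unnamed value is recycled.
#' @param min_area minimum connected-region area in um^2, applied per z-slice
#'   (\code{mode = "slice"}); regions strictly smaller are removed. In
#'   \code{mode = "volume"} the criterion is a minimum volume of
#'   \code{min_area * dz} applied to 3D components.
#' @param connectivity 2D neighborhood: 4 or 8 (slice mode); 3D: 6 or 26
#'   (volume mode).
#' @param mode \code{"slice"} (default; region finding per 2D z-slice,
#'   mirroring area-based counting) or \code{"volume"} (3D components).
#' @return object of class \code{threshold_config}.
#' @export
threshold_config <- function(thresholds, min_area = 0, connectivity = NULL,
                             mode = c("slice", "volume")) {
  mode <- match.arg(mode)
  thresholds <- expand_channel_vec(thresholds)
  if (any(thresholds < 0)) stop_config("thresholds must be >= 0")
  if (!is_scalar_number(min_area) || min_area < 0)
    stop_config("min_area must be a single number >= 0")
  connectivity <- connectivity %||% if (mode == "slice") 8L else 26L
  ok <- if (mode == "slice") c(4L, 8L) else c(6L, 26L)
  if (!as.integer(connectivity) %in% ok)
    stop_config("connectivity must be one of ", paste(ok, collapse = "/"),
                " in ", mode, " mode")
  structure(list(thresholds = thresholds, min_area = min_area,
                 connectivity = as.integer(connectivity), mode = mode),
            class = "threshold_config")
}

#' Threshold one channel of a stack
#'
#' @param stack a [channel_stack()].
#' @param channel channel name (one of \code{TK_CHANNELS}).
#' @param config a [threshold_config()].
#' @return logical array, TRUE where intensity strictly exceeds the
#'   channel's threshold.
#' @export
threshold_channel <- function(stack, channel, config) {
  stopifnot(inherits(stack, "channel_stack"),
            inherits(config, "threshold_config"))
  if (!channel %in% names(stack$channels))
    stop_config("unknown channel: ", channel, "; available: ",
                paste(names(stack$channels), collapse = ", "))
  stack$channels[[channel]] > config$thresholds[channel]
}

# Scan-order-negative half of the neighborhood, rows (d1, d2, d3) in array
# index space; passing it once per adjacent pair is enough for union-find.
half_offsets <- function(connectivity, ndim) {
  offs <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1,
                                d3 = if (ndim == 3) -1:1 else 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity %in% c(4L, 6L))
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  neg <- offs[, 3] < 0 |
    (offs[, 3] == 0 & (offs[, 2] < 0 | (offs[, 2] == 0 & offs[, 1] < 0)))
  storage.mode(offs) <- "integer"
  offs[neg, , drop = FALSE]
}

#' Label connected components of a binary mask
#'
#' Union-find labeling; background is 0, components are numbered from 1 in
#' scan order. For matrices use connectivity 4 or 8; for 3D arrays 6 or 26.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity neighborhood definition.
#' @return integer matrix/array of component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  connectivity <- as.integer(connectivity)
  d <- dim(mask)
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop_config("mask must be a matrix or a 3D array")
  if (length(d) == 2L) {
    if (!connectivity %in% c(4L, 8L))
      stop_config("2D connectivity must be 4 or 8")
    lab <- cc_label_core(as.logical(mask), c(d, 1L),
                         half_offsets(connectivity, 2L))
    dim(lab) <- d
  } else {
    if (!connectivity %in% c(6L, 26L))
      stop_config("3D connectivity must be 6 or 26")
    lab <- cc_label_core(as.logical(mask), d, half_offsets(connectivity, 3L))
    dim(lab) <- d
  }
  lab
}

#' Remove connected regions smaller than the minimum area
#'
#' In slice mode, components are found independently in every z-slice and a
#' component of \code{n} pixels is kept iff \code{n * dx * dy >= min_area}.
#' In volume mode, 3D components are kept iff
#' \code{n * dx * dy * dz >= min_area * dz}. \code{min_area = 0} is the
#' identity; an empty mask passes through.
#'
#' @param mask logical 3D array (or matrix, treated as one slice).
#' @param config a [threshold_config()] (uses min_area, connectivity, mode).
#' @param voxel_size named numeric \code{c(dx=, dy=, dz=)}, um.
#' @return filtered logical mask of the same shape.
#' @export
filter_min_area <- function(mask, config, voxel_size) {
  stopifnot(inherits(config, "threshold_config"))
  voxel_size <- expand_voxel_size(voxel_size)
  if (config$min_area <= 0) return(mask)
  px_area <- voxel_size["dx"] * voxel_size["dy"]
  d <- dim(mask)
  if (is.null(d)) stop_config("mask must be a matrix or a 3D array")

  drop_small <- function(lab, unit) {
    if (!any(lab > 0L)) return(lab > 0L)
    sizes <- tabulate(lab)
    keep <- which(sizes * unit >= config$min_area)
    array(lab %in% keep & lab > 0L, dim = dim(lab))
  }

  if (length(d) == 2L)
    return(drop_small(label_components(mask, config$connectivity), px_area))

  if (config$mode == "volume") {
    lab <- label_components(mask, config$connectivity)
    # volume criterion min_area * dz <=> n * dx * dy >= min_area
    return(drop_small(lab, px_area))
  }
  out <- mask
  for (z in seq_len(d[1]))
    out[z, , ] <- drop_small(label_components(mask[z, , ],
                                              config$connectivity), px_area)
  out
}

# code = green + 2*red + 4*apc  ->  class
CLASS_LOOKUP <- c("background",   # 0: - - -
                  "live",         # 1: g - -
                  "til",          # 2: - r -
                  "til_on_live",  # 3: g r -
                  "dead",         # 4: - - a
                  "dying",        # 5: g - a
                  "dying_til",    # 6: - r a
                  "dying_til")    # 7: g r a  (TIL death dominates)

#' Classify voxels by channel co-localization
#'
#' Implements the five-class color scheme of the assay readout: green only =
#' live tumor, APC only = dead, green+APC = dying tumor, red only = TIL,
#' red+APC = dying TIL (magenta), red+green = TIL overlying live tumor.
#' Triple-positive voxels are assigned to dying_til (TIL death dominates);
#' this precedence is recorded in the object. Classes are mutually exclusive
#' and exhaustive over the grid.
#'
#' @param masks named list of logical arrays (names \code{TK_CHANNELS}) on a
#'   common grid, typically thresholded and min-area-filtered.
#' @param voxel_size named numeric \code{c(dx=, dy=, dz=)}, um.
#' @param config the [threshold_config()] used (stored as provenance).
#' @param fragment_id,time_h optional provenance carried into records.
#' @return object of class \code{classified_volume}: integer label array
#'   (values index \code{TK_CLASSES}), per-class voxel \code{counts} and
#'   \code{volumes_um3}, the voxel size and provenance.
#' @export
classify_voxels <- function(masks, voxel_size, config = NULL,
                            fragment_id = NA_character_, time_h = NA_real_) {
  if (!setequal(names(masks), TK_CHANNELS))
    stop_config("masks must be named exactly: ",
                paste(TK_CHANNELS, collapse = ", "))
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1))))
    stop_config("channel masks do not share one grid")
  voxel_size <- expand_voxel_size(voxel_size)

  code <- masks$live_green + 2L * masks$til_red + 4L * masks$dead_apc
  cls <- CLASS_LOOKUP[code + 1L]
  labels <- array(match(cls, TK_CLASSES), dim = d)
  counts <- stats::setNames(tabulate(labels, nbins = length(TK_CLASSES)),
                            TK_CLASSES)
  structure(list(labels = labels, classes = TK_CLASSES, counts = counts,
                 volumes_um3 = counts * prod(voxel_size),
                 voxel_size = voxel_size, config = config,
                 precedence = "triple-positive -> dying_til",
                 fragment_id = fragment_id, time_h = time_h),
            class = "classified_volume")
}

#' @export
print.classified_volume <- function(x, ...) {
  cat("<classified_volume>", x$fragment_id, "at", x$time_h, "h\n")
  print(x$counts)
  invisible(x)
}

#' Threshold, filter and classify a whole stack
#'
#' Convenience wrapper: thresholds every channel, applies the minimum-area
#' filter to each channel mask, then classifies by co-localization.
#'
#' @inheritParams threshold_channel
#' @return a \code{classified_volume}.
#' @export
classify_stack <- function(stack, config) {
  masks <- lapply(stats::setNames(TK_CHANNELS, TK_CHANNELS), function(ch)
    filter_min_area(threshold_channel(stack, ch, config), config,
                    stack$voxel_size))
  classify_voxels(masks, stack$voxel_size, config = config,
                  fragment_id = stack$fragment_id, time_h = stack$time_h)
}

#' Otsu threshold initializer, pooled over an experiment
#'
#' Suggests one threshold per channel by maximizing between-class variance on
#' the pooled intensity histogram of all supplied stacks. This is an explicit
#' initializer only: nothing in the pipeline applies it silently, and the
#' values should be reviewed (and recorded in the experiment config) before
#' use.
#'
#' @param stacks list of \code{channel_stack} objects.
#' @param n_bins histogram resolution.
#' @return named numeric vector of suggested thresholds.
#' @export
auto_thresholds <- function(stacks, n_bins = 256) {
  if (inherits(stacks, "channel_stack")) stacks <- list(stacks)
  vapply(stats::setNames(TK_CHANNELS, TK_CHANNELS), function(ch) {
    v <- unlist(lapply(stacks, function(s) as.vector(s$channels[[ch]])))
    otsu_threshold(v, n_bins)
  }, numeric(1))
}

# Maximize between-class variance over histogram bin boundaries.
otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  breaks[which.max(between) + 1L]
}
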