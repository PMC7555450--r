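#' One fragment's three-channel intensity volume at one timepoint
#'
#' @param channels named list of 3D numeric arrays (dim \code{(nz, ny, nx)}),
#'   names exactly \code{TK_CHANNELS}; intensities must be non-negative.
#' @param voxel_size named numeric \code{c(dx=, dy=, dz=)}, um.
#' @param time_h hours since the start of perfusion.
#' @param fragment_id opaque fragment identifier.
#' @return object of class \code{channel_stack}.
#' @export
channel_stack <- function(channels, voxel_size, time_h, fragment_id) {
  if (!setequal(names(channels), TK_CHANNELS))
    stop_config("channels must be named exactly: ",
                paste(TK_CHANNELS, collapse = ", "))
  channels <- channels[TK_CHANNELS]
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_config("all three channels must be 3D arrays of identical dimension")
  if (any(vapply(channels, function(a) any(a < 0), logical(1))))
    stop_config("intensities must be non-negative")
  voxel_size <- expand_voxel_size(voxel_size)
  if (voxel_size["dz"] <= 0) stop_config("dz must be positive")
  structure(list(channels = channels, voxel_size = voxel_size,
                 time_h = as.numeric(time_h),
                 fragment_id = as.character(fragment_id)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<channel_stack>", x$fragment_id, "at", x$time_h, "h\n")
  cat("  dim:", paste(d, collapse = " x "), "(nz x ny x nx); voxel",
      paste(x$voxel_size, collapse = " x "), "um\n")
  invisible(x)
}

#' Write a channel stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-major (all z-slices of the first channel, then the
#' second, ...) in the channel order recorded in the sidecar; readers must use
#' the sidecar, never assume page order. Intensities are stored as 16-bit
#' samples scaled by \code{intensity_scale} (65535), so integer intensities in
#' 0..65535 round-trip losslessly.
#'
#' @param stack a \code{channel_stack}.
#' @param path output TIFF path.
#' @param sidecar output JSON sidecar path (default \code{<path>.json}).
#' @return invisibly, the sidecar list.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "channel_stack"))
  scale <- 65535
  if (max(vapply(stack$channels, max, numeric(1))) > scale)
    stop_config("intensities above ", scale, " cannot be stored losslessly")
  nz <- dim(stack$channels[[1]])[1]
  pages <- list()
  for (ch in TK_CHANNELS)
    for (z in seq_len(nz))
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][z, , ] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "LZW")
  meta <- list(fragment_id = stack$fragment_id,
               time_h = stack$time_h,
               channels = as.list(TK_CHANNELS),
               n_z = nz,
               voxel_size_um = as.list(stack$voxel_size),
               intensity_scale = scale)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(meta)
}

#' Read a channel stack from TIFF + sidecar
#'
#' Channels are mapped by the names declared in the sidecar; the file must
#' provide \code{n_z} pages for each of the three expected channels.
#'
#' @param path TIFF path.
#' @param sidecar JSON sidecar path (default \code{<path>.json}).
#' @return a \code{channel_stack}.
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop_config("stack file not found: ", path)
  if (!file.exists(sidecar)) stop_config("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("channels", "n_z", "voxel_size_um", "time_h", "fragment_id")
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop_config("sidecar ", sidecar, " is missing field(s): ",
                paste(miss, collapse = ", "))
  declared <- unlist(meta$channels)
  missing_ch <- setdiff(TK_CHANNELS, declared)
  if (length(missing_ch))
    stop_config("sidecar does not declare channel(s): ",
                paste(missing_ch, collapse = ", "))
  nz <- as.integer(meta$n_z)
  scale <- meta$intensity_scale %||% 65535

  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  need <- nz * length(declared)
  if (length(pages) < need) {
    n_complete <- length(pages) %/% nz
    short <- declared[seq.int(n_complete + 1L, length(declared))]
    stop_config("TIFF ", path, " has ", length(pages), " pages but ", need,
                " are required; missing slices for channel(s): ",
                paste(short, collapse = ", "))
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(pg) identical(dim(pg), d1), logical(1))))
    stop_config("TIFF pages have mismatched dimensions in ", path)

  channels <- list()
  for (i in seq_along(declared)) {
    arr <- array(0, dim = c(nz, d1[1], d1[2]))
    for (z in seq_len(nz))
      arr[z, , ] <- round(pages[[(i - 1L) * nz + z]] * scale)
    channels[[declared[i]]] <- arr
  }
  channel_stack(channels[TK_CHANNELS],
                voxel_size = unlist(meta$voxel_size_um),
                time_h = meta$time_h,
                fragment_id = meta$fragment_id)
}

# ---- experiment layout ------------------------------------------------------

#' Load and validate an experiment layout
#'
#' The layout is a YAML file describing a multi-fragment, multi-condition,
#' multi-timepoint experiment:
#' \preformatted{
#' time_points: [0, 24, 48]
#' conditions: [isotype, anti_PD1, anti_CTLA4]   # optional; derived if absent
#' fragments:
#'   - fragment_id: frag01
#'     condition: isotype
#'     tumor_model: MC38
#'     stacks:
#'       "0":  stacks/frag01_t1.tif
#'       "24": stacks/frag01_t2.tif
#' }
#' Relative stack paths are resolved against the layout file's directory.
#' Validation is exhaustive and fails before any stack is opened: unknown
#' condition labels (closed vocabulary), duplicate fragment ids, an empty
#' fragment list, or a declared condition with zero fragments are all errors.
#'
#' @param path layout YAML path.
#' @return object of class \code{experiment_layout}: list with
#'   \code{fragments} (data.frame: fragment_id, condition, tumor_model),
#'   \code{time_points}, and \code{stacks} (data.frame: fragment_id, time_h,
#'   path, sidecar).
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop_config("layout file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_layout(raw, base_dir = dirname(path))
}

validate_layout <- function(raw, base_dir = ".") {
  frs <- raw$fragments
  if (is.null(frs) || length(frs) == 0)
    stop_config("layout declares no fragments")
  if (is.null(raw$time_points) || length(raw$time_points) == 0)
    stop_config("layout declares no time_points")

  ids <- vapply(frs, function(f) as.character(f$fragment_id %||% ""),
                character(1))
  conds <- vapply(frs, function(f) as.character(f$condition %||% ""),
                  character(1))
  if (any(ids == "")) stop_config("every fragment needs a fragment_id")
  if (anyDuplicated(ids))
    stop_config("duplicate fragment_id: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- setdiff(unique(conds), TK_CONDITIONS)
  if (length(bad))
    stop_config("unknown condition(s): ", paste(bad, collapse = ", "),
                "; allowed conditions are: ",
                paste(TK_CONDITIONS, collapse = ", "))
  declared <- unlist(raw$conditions) %||% unique(conds)
  bad <- setdiff(declared, TK_CONDITIONS)
  if (length(bad))
    stop_config("unknown declared condition(s): ", paste(bad, collapse = ", "),
                "; allowed conditions are: ",
                paste(TK_CONDITIONS, collapse = ", "))
  empty <- setdiff(declared, conds)
  if (length(empty))
    stop_config("condition(s) with zero fragments: ",
                paste(empty, collapse = ", "))

  tp <- as.numeric(unlist(raw$time_points))
  fragments <- data.frame(
    fragment_id = ids, condition = conds,
    tumor_model = vapply(frs, function(f)
      as.character(f$tumor_model %||% NA_character_), character(1)),
    stringsAsFactors = FALSE)

  stacks <- do.call(rbind, lapply(seq_along(frs), function(i) {
    st <- frs[[i]]$stacks
    if (is.null(st) || length(st) == 0) return(NULL)
    p <- vapply(st, as.character, character(1))
    full <- ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
    data.frame(fragment_id = ids[i], time_h = as.numeric(names(st)),
               path = full, sidecar = paste0(full, ".json"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(stacks)) rownames(stacks) <- NULL

  structure(list(fragments = fragments, time_points = tp,
                 stacks = stacks %||%
                   data.frame(fragment_id = character(0), time_h = numeric(0),
                              path = character(0), sidecar = character(0))),
            class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat("<experiment_layout>", nrow(x$fragments), "fragments,",
      length(x$time_points), "timepoints\n")
  print(table(condition = x$fragments$condition))
  invisible(x)
}

#' Report layout stack paths that do not exist on disk
#'
#' Fail-fast helper: the pipeline calls this before opening any stack.
#' @param layout an \code{experiment_layout}.
#' @return character vector of missing paths (possibly empty).
#' @export
layout_missing_paths <- function(layout) {
  stopifnot(inherits(layout, "experiment_layout"))
  p <- c(layout$stacks$path, layout$stacks$sidecar)
  p[!file.exists(p)]
}

#' Write an experiment layout as YAML
#'
#' @param layout an \code{experiment_layout}; stack paths are written as
#'   given (the simulator writes paths relative to the layout file).
#' @param path output YAML path.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "experiment_layout"))
  frs <- lapply(seq_len(nrow(layout$fragments)), function(i) {
    id <- layout$fragments$fragment_id[i]
    st <- layout$stacks[layout$stacks$fragment_id == id, , drop = FALSE]
    out <- list(fragment_id = id,
                condition = layout$fragments$condition[i])
    if (!is.na(layout$fragments$tumor_model[i]))
      out$tumor_model <- layout$fragments$tumor_model[i]
    if (nrow(st))
      out$stacks <- stats::setNames(as.list(st$path),
                                    format(st$time_h, trim = TRUE))
    out
  })
  yaml::write_yaml(list(time_points = layout$time_points,
                        conditions = unique(layout$fragments$condition),
                        fragments = frs), path)
  invisible(path)
}
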