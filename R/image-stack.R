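#' Image stack container
#'
#' A lightweight carrier for 2D/3D(+time, +channel) fluorescence image data
#' with physical calibration. `data` is a numeric array whose dimensions are
#' named by the `axes` string (one letter per dimension, in order, drawn from
#' `t` time, `c` channel, `z` slice, `y` row, `x` column). Physical
#' coordinates are `index * pixel_size` with 0-based pixel indices and the
#' origin at the top-left.
#'
#' @param data numeric array (or matrix for a single 2D plane).
#' @param axes character string such as `"yx"`, `"tyx"`, `"czyx"`.
#' @param pixel_size lateral pixel size, um/px.
#' @param frame_interval time between frames, s.
#' @param z_step axial spacing, um (defaults to `pixel_size`).
#' @param channels optional character vector naming the `c` axis.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, axes, pixel_size = 0.106, frame_interval = 1,
                        z_step = pixel_size, channels = NULL) {
  data <- as.array(data)
  ax <- strsplit(axes, "")[[1]]
  stopifnot(
    length(dim(data)) == length(ax),
    all(ax %in% c("t", "c", "z", "y", "x")), !anyDuplicated(ax),
    pixel_size > 0, frame_interval > 0, z_step > 0,
    all(is.finite(data))
  )
  if (!is.null(channels)) stopifnot(length(channels) == dim(data)[match("c", ax)])
  structure(
    list(data = data, axes = axes, pixel_size = pixel_size,
         frame_interval = frame_interval, z_step = z_step, channels = channels),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", paste(dim(x$data), collapse = " x "),
      " [", x$axes, "], pixel ", x$pixel_size, " um, dt ", x$frame_interval,
      " s\n", sep = "")
  if (!is.null(x$channels)) cat("  channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

axis_index <- function(stack, axis) {
  ax <- strsplit(stack$axes, "")[[1]]
  i <- match(axis, ax)
  if (is.na(i)) stop("stack has no '", axis, "' axis", call. = FALSE)
  i
}

n_frames <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1]]
  if ("t" %in% ax) dim(stack$data)[match("t", ax)] else 1L
}

#' Extract a plane or sub-stack
#'
#' Slices the requested frame and/or channel out of an `image_stack`,
#' returning the remaining (z)yx array. Channels may be addressed by label.
#'
#' @param stack an `image_stack`.
#' @param frame 1-based frame index (for stacks with a `t` axis).
#' @param channel channel index or label (for stacks with a `c` axis).
#' @return numeric matrix (y, x) or 3D array (z, y, x).
#' @export
get_plane <- function(stack, frame = NULL, channel = NULL) {
  a <- stack$data
  ax <- strsplit(stack$axes, "")[[1]]
  idx <- rep(list(quote(expr = )), length(ax))
  if (!is.null(frame)) idx[[match("t", ax)]] <- frame
  if (!is.null(channel)) {
    ci <- match("c", ax)
    if (is.character(channel)) {
      channel <- match(channel, stack$channels)
      if (is.na(channel)) stop("unknown channel", call. = FALSE)
    }
    idx[[ci]] <- channel
  }
  out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  keep <- ax %in% c("z", "y", "x")
  array(out, dim(out)[keep])
}

#' Read a TIFF image stack with JSON sidecar metadata
#'
#' Reads a single- or multi-page TIFF. Calibration (pixel size, frame
#' interval, axes, channel labels) is taken from a JSON sidecar named
#' `<path>.json` when present; otherwise the axes are inferred from the page
#' count (`yx` for one page, `tyx` for several) and the documented default
#' pixel size of 0.106 um (typical EMCCD effective pixel at 100x) is used
#' with a warning.
#'
#' @param path TIFF file path.
#' @param axes optional axes hint overriding inference, e.g. `"czyx"`.
#' @return an `image_stack`.
#' @export
read_image <- function(path, axes = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- if (length(pages) == 1) pages[[1]] else
    aperm(array(unlist(pages), c(dim(pages[[1]]), length(pages))), c(3, 1, 2))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (is.null(meta)) {
    warning("no metadata sidecar for '", path,
            "': assuming pixel_size = 0.106 um, frame_interval = 1 s", call. = FALSE)
    meta <- list()
  }
  ax <- axes %||% meta$axes %||% if (length(pages) == 1) "yx" else "tyx"
  if (nchar(ax) != length(dim(arr))) {
    if (nchar(ax) > length(dim(arr)) && length(pages) > 1) {
      # fold the page dimension back into the leading axes (e.g. "czyx")
      dims_meta <- meta$dim
      if (is.null(dims_meta))
        stop("axes hint '", ax, "' needs a 'dim' entry in the sidecar", call. = FALSE)
      nlead <- length(dims_meta) - 2L
      ny <- dims_meta[nlead + 1L]; nx <- dims_meta[nlead + 2L]
      tmp <- array(aperm(arr, c(2, 3, 1)), c(ny, nx, dims_meta[seq_len(nlead)]))
      arr <- aperm(tmp, c(2L + seq_len(nlead), 1L, 2L))
    } else stop("axes '", ax, "' do not match image dimensions", call. = FALSE)
  }
  image_stack(arr, ax,
              pixel_size = meta$pixel_size %||% 0.106,
              frame_interval = meta$frame_interval %||% 1,
              z_step = meta$z_step %||% meta$pixel_size %||% 0.106,
              channels = meta$channels)
}

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored as 32-bit float; calibration, axes and channel
#' labels go to `<path>.json` so that [read_image()] round-trips losslessly.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(stack, path) {
  a <- stack$data
  ax <- strsplit(stack$axes, "")[[1]]
  d <- dim(a)
  ny <- d[match("y", ax)]; nx <- d[match("x", ax)]
  npage <- prod(d) / (ny * nx)
  perm <- c(setdiff(seq_along(ax), match(c("y", "x"), ax)), match(c("y", "x"), ax))
  flat <- array(aperm(a, perm), c(npage, ny, nx))
  pages <- lapply(seq_len(npage), function(i) flat[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(axes = stack$axes, dim = dim(a), pixel_size = stack$pixel_size,
         frame_interval = stack$frame_interval, z_step = stack$z_step,
         channels = stack$channels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read / write trajectory tables
#'
#' Trajectories are stored as plain CSV with columns
#' `track_id, frame, t_s, x_um, y_um, quality` (units embedded in names).
#'
#' @param traj tibble of linked trajectories.
#' @param path CSV path.
#' @return the tibble (read) or `path` invisibly (write).
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(traj, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
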