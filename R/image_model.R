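#' Calibrated image stack
#'
#' The universal input container of the pipeline: a scalar intensity array
#' with any subset of the axes t (time), z (slice), c (channel), y, x, plus
#' physical calibration. Axes are declared explicitly (never guessed) and are
#' stored internally in canonical `tzcyx` order (restricted to the axes
#' present); `y` and `x` are always last.
#'
#' Coordinate convention: 0-based pixel indices, voxel centers at integers,
#' physical position = index × pixel size.
#'
#' @param data numeric array; dimensions in the order given by `axes`.
#' @param axes character string naming the axes of `data`, a permutation of a
#'   subset of `"tzcyx"` that contains `"y"` and `"x"` (e.g. `"yx"`,
#'   `"zcyx"`, `"tyx"`).
#' @param pixel_size_xy pixel size in µm/pixel (> 0).
#' @param pixel_size_z slice spacing in µm (> 0); required iff a z axis is
#'   present.
#' @param frame_interval time between frames in seconds (> 0); required iff a
#'   t axis is present.
#' @param channel_names character vector naming the channels; must match the
#'   channel axis length. Defaults to `"ch1"`, `"ch2"`, ...
#' @return An `ImageStack` object (list with elements `data`, `axes`,
#'   `pixel_size_xy`, `pixel_size_z`, `frame_interval`, `channel_names`).
#' @export
image_stack <- function(data, axes, pixel_size_xy,
                        pixel_size_z = NULL, frame_interval = NULL,
                        channel_names = NULL) {
  if (!is.numeric(data) && !is.logical(data))
    validation_error("image data must be numeric")
  if (is.null(dim(data))) dim(data) <- length(data)
  ax <- parse_axes(axes, length(dim(data)))
  # canonical order: tzcyx restricted to present axes
  canon <- intersect(c("t", "z", "c", "y", "x"), ax)
  if (!identical(ax, canon)) data <- aperm(data, match(canon, ax))
  if (any(!is.finite(data))) validation_error("image intensities must be finite")
  check_number(pixel_size_xy, "pixel_size_xy", min = 0, strict_min = TRUE)
  has_z <- "z" %in% canon
  has_t <- "t" %in% canon
  has_c <- "c" %in% canon
  if (has_z) {
    if (is.null(pixel_size_z)) calibration_error("z axis present but pixel_size_z missing")
    check_number(pixel_size_z, "pixel_size_z", min = 0, strict_min = TRUE)
  } else pixel_size_z <- NA_real_
  if (has_t) {
    if (is.null(frame_interval)) calibration_error("t axis present but frame_interval missing")
    check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  } else frame_interval <- NA_real_
  nc <- if (has_c) dim(data)[match("c", canon)] else 1L
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    validation_error("channel_names length (%d) != channel axis length (%d)",
                     length(channel_names), nc)
  structure(list(data = data, axes = paste(canon, collapse = ""),
                 pixel_size_xy = as.numeric(pixel_size_xy),
                 pixel_size_z = as.numeric(pixel_size_z),
                 frame_interval = as.numeric(frame_interval),
                 channel_names = as.character(channel_names)),
            class = "ImageStack")
}

parse_axes <- function(axes, ndim) {
  if (!is.character(axes) || length(axes) != 1L)
    axis_ambiguity_error("axes must be a single string such as \"yx\" or \"zcyx\"")
  ax <- strsplit(axes, "")[[1]]
  if (anyDuplicated(ax) || !all(ax %in% c("t", "z", "c", "y", "x")) ||
      !all(c("y", "x") %in% ax))
    axis_ambiguity_error("axes \"%s\" is not a subset of \"tzcyx\" containing y and x", axes)
  if (length(ax) != ndim)
    axis_ambiguity_error("axes \"%s\" declares %d axes but data has %d dimensions",
                         axes, length(ax), ndim)
  ax
}

#' @export
print.ImageStack <- function(x, ...) {
  cat(sprintf("ImageStack [%s] %s; %g um/px", x$axes,
              paste(dim(x$data), collapse = "x"), x$pixel_size_xy))
  if (!is.na(x$pixel_size_z)) cat(sprintf("; z %g um", x$pixel_size_z))
  if (!is.na(x$frame_interval)) cat(sprintf("; dt %g s", x$frame_interval))
  cat("; channels:", paste(x$channel_names, collapse = ","), "\n")
  invisible(x)
}

axis_index <- function(stack, axis) match(axis, strsplit(stack$axes, "")[[1]])

#' Extract one channel (and optionally one frame) as a spatial array
#'
#' @param stack an [image_stack()].
#' @param channel channel name or index; ignored when no channel axis exists.
#' @param frame time frame index (1-based); required to reduce a t axis.
#' @return numeric array with axes `zyx` or `yx`.
#' @export
channel_data <- function(stack, channel = 1L, frame = NULL) {
  a <- stack$data
  ax <- strsplit(stack$axes, "")[[1]]
  if ("t" %in% ax) {
    if (is.null(frame))
      validation_error("stack has a time axis; a frame index is required")
    a <- slice_axis(a, match("t", ax), frame)
    ax <- setdiff(ax, "t")
  }
  if ("c" %in% ax) {
    ci <- if (is.character(channel)) match(channel, stack$channel_names) else as.integer(channel)
    if (is.na(ci) || ci < 1L || ci > length(stack$channel_names))
      validation_error("unknown channel '%s'", as.character(channel))
    a <- slice_axis(a, match("c", ax), ci)
  }
  a
}

# drop one axis at position `which`, keeping index `i`
slice_axis <- function(a, which, i) {
  d <- dim(a)
  idx <- rep(list(quote(expr = )), length(d))
  idx[[which]] <- i
  out <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  newd <- d[-which]
  dim(out) <- newd
  out
}

spatial_dims <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1]]
  dim(stack$data)[ax %in% c("z", "y", "x")]
}

#' Binary mask tied to an image's spatial frame
#'
#' Holds manually outlined or computed regions (tumor margins, somite ROIs,
#' stain-positive areas). The data are logical; the spatial shape must match
#' the source image's `zyx`/`yx` shape when a frame of reference is given.
#'
#' @param data logical (or 0/1 numeric) array.
#' @param frame_of_reference optional [image_stack()] the mask refers to.
#' @return a `Mask` object.
#' @export
mask <- function(data, frame_of_reference = NULL) {
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      validation_error("mask values must be 0/1")
    data <- array(data != 0, dim = dim(data) %||% length(data))
  }
  if (!is.logical(data)) validation_error("mask data must be logical or 0/1")
  if (is.null(dim(data))) dim(data) <- length(data)
  if (!is.null(frame_of_reference)) {
    sd <- spatial_dims(frame_of_reference)
    if (!identical(as.integer(dim(data)), as.integer(sd)))
      frame_mismatch_error("mask shape (%s) != source spatial shape (%s)",
                           paste(dim(data), collapse = "x"),
                           paste(sd, collapse = "x"))
  }
  structure(list(data = data), class = "Mask")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_mask_array <- function(m) {
  if (inherits(m, "Mask")) m$data
  else if (is.logical(m)) m
  else if (is.numeric(m)) array(m != 0, dim = dim(m) %||% length(m))
  else validation_error("not a mask")
}

#' Integer-labeled object image
#'
#' Produced by detection; labels are 1..n_labels with no gaps, 0 is
#' background. `provenance` records the detection parameters that produced it.
#'
#' @param data non-negative integer array.
#' @param provenance named list of parameter values.
#' @return a `LabelMap` object with elements `data`, `n_labels`, `provenance`.
#' @export
label_map <- function(data, provenance = list()) {
  if (is.null(dim(data))) dim(data) <- length(data)
  storage.mode(data) <- "integer"
  if (any(data < 0L)) validation_error("labels must be non-negative")
  n <- if (any(data > 0L)) max(data) else 0L
  present <- sort(unique(data[data > 0L]))
  if (length(present) != n || (n > 0L && !identical(present, seq_len(n))))
    validation_error("labels must be 1..n with no gaps")
  structure(list(data = data, n_labels = as.integer(n), provenance = provenance),
            class = "LabelMap")
}

#' Canonical relabeling
#'
#' Maps the positive labels of an arbitrary non-negative integer array to
#' 1..n ordered by each label's first occurrence in the array's linear
#' (raster) order. The partition of foreground voxels is preserved.
#'
#' @param data integer array of labels (gaps allowed).
#' @param provenance carried into the resulting [label_map()].
#' @return a `LabelMap`.
#' @export
relabel_canonical <- function(data, provenance = list()) {
  if (inherits(data, "LabelMap")) { provenance <- data$provenance; data <- data$data }
  d <- dim(data) %||% length(data)
  v <- as.integer(data)
  pos <- which(v > 0L)
  if (length(pos) == 0L) {
    return(label_map(array(0L, dim = d), provenance))
  }
  first <- !duplicated(v[pos])
  old <- v[pos][first]                       # labels in first-occurrence order
  lut <- integer(max(old))
  lut[old] <- seq_along(old)
  v[pos] <- lut[v[pos]]
  label_map(array(v, dim = d), provenance)
}

#' Object table from a label map
#'
#' One row per labeled object: centroid in 0-based continuous pixel
#' coordinates, voxel count, axis-aligned bounding box and source channel.
#'
#' @param labels a [label_map()] (2D `yx` or 3D `zyx`).
#' @param channel identifier stored with each record.
#' @return data.frame with columns `label`, `x`, `y` (`z` for 3D),
#'   `voxel_count`, `xmin`,`xmax`,`ymin`,`ymax` (`zmin`,`zmax`) and `channel`.
#' @export
object_records <- function(labels, channel = "ch1") {
  lm <- if (inherits(labels, "LabelMap")) labels else label_map(labels)
  d <- dim(lm$data)
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) validation_error("object_records expects a 2D or 3D label map")
  n <- lm$n_labels
  if (n == 0L) {
    cols <- c("label", "x", "y", if (nd == 3L) "z", "voxel_count",
              "xmin", "xmax", "ymin", "ymax", if (nd == 3L) c("zmin", "zmax"),
              "channel")
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$channel <- character(0)
    return(out)
  }
  idx <- which(lm$data > 0L)
  lab <- lm$data[idx]
  coords <- arrayInd(idx, d) - 1L   # 0-based; columns follow array axes
  # axes are (y, x) for 2D, (z, y, x) for 3D
  if (nd == 2L) { yc <- coords[, 1]; xc <- coords[, 2]; zc <- NULL }
  else { zc <- coords[, 1]; yc <- coords[, 2]; xc <- coords[, 3] }
  cnt <- tabulate(lab, nbins = n)
  out <- data.frame(
    label = seq_len(n),
    x = as.numeric(tapply(xc, lab, mean)),
    y = as.numeric(tapply(yc, lab, mean))
  )
  if (nd == 3L) out$z <- as.numeric(tapply(zc, lab, mean))
  out$voxel_count <- cnt
  out$xmin <- as.numeric(tapply(xc, lab, min)); out$xmax <- as.numeric(tapply(xc, lab, max))
  out$ymin <- as.numeric(tapply(yc, lab, min)); out$ymax <- as.numeric(tapply(yc, lab, max))
  if (nd == 3L) { out$zmin <- as.numeric(tapply(zc, lab, min)); out$zmax <- as.numeric(tapply(zc, lab, max)) }
  out$channel <- as.character(channel)
  rownames(out) <- NULL
  out
}
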