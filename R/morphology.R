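# Binary morphology and object labeling.

#' Fill holes in a binary mask
#'
#' Background components not connected to the image border become foreground.
#' Performed in the mask's native dimensionality (2D or 3D). The background
#' is traced with the connectivity complementary to the foreground
#' convention (foreground 8 ↔ background 4; foreground 26 ↔ background 6).
#'
#' @param m a [mask()] or logical array.
#' @param connectivity foreground connectivity (4/8 in 2D, 6/26 in 3D);
#'   default 8/26.
#' @return a [mask()] with holes filled.
#' @export
fill_holes <- function(m, connectivity = NULL) {
  a <- as_mask_array(m)
  d <- dim(a)
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) validation_error("fill_holes expects a 2D or 3D mask")
  connectivity <- default_connectivity(connectivity, nd)
  bg_full <- !connectivity_is_full(connectivity, nd)  # complementary convention
  bg <- ccl_label(as.logical(!a), as.integer(d), bg_full)
  n <- attr(bg, "n_labels")
  if (n == 0L) return(mask(a))
  dim(bg) <- d
  border_labels <- unique(c(border_values(bg)))
  border_labels <- border_labels[border_labels > 0L]
  hole <- !(bg == 0L) & !(array(bg %in% border_labels, dim = d))
  mask(a | hole)
}

border_values <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) {
    c(a[1, ], a[d[1], ], a[, 1], a[, d[2]])
  } else {
    c(a[1, , ], a[d[1], , ], a[, 1, ], a[, d[2], ], a[, , 1], a[, , d[3]])
  }
}

default_connectivity <- function(connectivity, nd) {
  if (is.null(connectivity)) return(if (nd == 2L) 8L else 26L)
  connectivity <- as.integer(connectivity)
  if (nd == 2L && !connectivity %in% c(4L, 8L))
    validation_error("2D connectivity must be 4 or 8")
  if (nd == 3L && !connectivity %in% c(6L, 26L))
    validation_error("3D connectivity must be 6 or 26")
  connectivity
}

connectivity_is_full <- function(connectivity, nd) {
  connectivity == (if (nd == 2L) 8L else 26L)
}

#' Label connected foreground components
#'
#' Maximal connected foreground regions ("contiguous foreground-labeled
#' regions") are labeled 1..n, numbered by each component's
#' first-encountered voxel in the array's linear (raster) order.
#'
#' @param m a [mask()] or logical array (2D or 3D).
#' @param connectivity 4 or 8 (2D), 6 or 26 (3D); default 8/26.
#' @param provenance optional parameter record carried into the result.
#' @return a [label_map()].
#' @export
label_components <- function(m, connectivity = NULL, provenance = list()) {
  a <- as_mask_array(m)
  d <- dim(a)
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) validation_error("label_components expects a 2D or 3D mask")
  connectivity <- default_connectivity(connectivity, nd)
  lab <- ccl_label(as.logical(a), as.integer(d),
                  connectivity_is_full(connectivity, nd))
  n <- attr(lab, "n_labels")
  attr(lab, "n_labels") <- NULL
  dim(lab) <- d
  label_map(lab, provenance = c(provenance, list(connectivity = connectivity)))
}

#' Split touching objects with the watershed method
#'
#' Shape-based splitting of touching convex objects: the watershed of the
#' negated Euclidean distance transform, seeded from the distance maxima and
#' constrained to the mask, so every foreground voxel is assigned to exactly
#' one label. 3D masks are split per z-slice (morphology is 2D per plane).
#'
#' @param m a [mask()] or logical array.
#' @param connectivity used only for relabeling order bookkeeping; splitting
#'   itself follows the standard 2D watershed.
#' @param tolerance minimum distance-map depth separating two objects
#'   (passed to the watershed; merges shallow seed pairs).
#' @return a [label_map()] partitioning exactly the input foreground.
#' @export
watershed_split <- function(m, connectivity = NULL, tolerance = 1) {
  a <- as_mask_array(m)
  d <- dim(a)
  nd <- length(d)
  if (!nd %in% c(2L, 3L)) validation_error("watershed_split expects a 2D or 3D mask")
  split_plane <- function(plane) {
    if (!any(plane)) return(matrix(0L, nrow(plane), ncol(plane)))
    dt <- EBImage::distmap(EBImage::Image(plane * 1))
    w <- EBImage::watershed(dt, tolerance = tolerance, ext = 1)
    matrix(as.integer(EBImage::imageData(w)), nrow(plane), ncol(plane))
  }
  if (nd == 2L) {
    lab <- split_plane(a)
  } else {
    lab <- array(0L, dim = d)
    offset <- 0L
    for (z in seq_len(d[1])) {
      pl <- split_plane(array(a[z, , ], dim = d[2:3]))
      pos <- pl > 0L
      lab[z, , ][pos] <- pl[pos] + offset
      offset <- offset + max(0L, max(pl))
    }
  }
  relabel_canonical(lab, provenance = list(method = "watershed", tolerance = tolerance))
}

#' Filter detected objects by size and region of interest
#'
#' Objects smaller than a user-defined voxel-count threshold are removed;
#' when an ROI mask is given, objects whose centroid lies outside it are
#' removed. Survivors are relabeled canonically (1..n, raster order).
#'
#' @param labels a [label_map()].
#' @param min_voxels minimum voxel count to keep (>= 1).
#' @param roi optional [mask()] of the same spatial shape.
#' @return a filtered [label_map()].
#' @export
filter_objects <- function(labels, min_voxels = 1L, roi = NULL) {
  lm <- if (inherits(labels, "LabelMap")) labels else label_map(labels)
  check_number(min_voxels, "min_voxels", min = 1, integer = TRUE)
  if (lm$n_labels == 0L) return(lm)
  d <- dim(lm$data)
  counts <- tabulate(lm$data[lm$data > 0L], nbins = lm$n_labels)
  keep <- counts >= min_voxels
  if (!is.null(roi)) {
    ra <- as_mask_array(roi)
    if (!identical(dim(ra), d))
      frame_mismatch_error("roi shape (%s) != label shape (%s)",
                           paste(dim(ra), collapse = "x"), paste(d, collapse = "x"))
    rec <- object_records(lm)
    inside <- centroid_in_mask(rec, ra)
    keep <- keep & inside
  }
  v <- lm$data
  v[v > 0L & !keep[pmax(v, 1L)]] <- 0L
  relabel_canonical(v, provenance = c(lm$provenance,
                                      list(min_voxels = min_voxels,
                                           roi_applied = !is.null(roi))))
}

# TRUE for records whose rounded centroid voxel lies inside the mask
centroid_in_mask <- function(rec, roi_array) {
  d <- dim(roi_array)
  yi <- pmin(pmax(round(rec$y) + 1L, 1L), d[length(d) - 1L])
  xi <- pmin(pmax(round(rec$x) + 1L, 1L), d[length(d)])
  if (length(d) == 3L) {
    zi <- pmin(pmax(round(rec$z) + 1L, 1L), d[1])
    roi_array[cbind(zi, yi, xi)]
  } else {
    roi_array[cbind(yi, xi)]
  }
}
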