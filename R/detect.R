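# The detection core shared by the pigmentation, burden, uptake, immune-cell,
# colocalization and section workflows: prefilter -> background subtraction ->
# threshold (with multiplier k and minimum permitted threshold) -> strict
# binarization -> optional hole filling -> connected-components labeling ->
# optional watershed split -> size/ROI filtering.

#' Detection parameters
#'
#' Bundles every user-controlled setting of the detection pipeline. The
#' threshold multiplier `k` and minimum permitted threshold `t_min` implement
#' the systematic threshold adjustment used to keep background out of the
#' segmentation.
#'
#' @param prefilter `"none"`, `"median"`, `"gaussian"` or `"variance"`.
#' @param prefilter_radius window radius (median/variance), pixels.
#' @param prefilter_sigma Gaussian sigma, pixels.
#' @param background `"none"` or `"rolling_ball"`.
#' @param background_radius rolling-ball radius, pixels.
#' @param threshold_method `"otsu"`, `"mean"` or `"fixed"`.
#' @param k positive threshold multiplier (default 1).
#' @param t_min minimum permitted threshold (default 0).
#' @param t fixed threshold (for `threshold_method = "fixed"`).
#' @param t_min_fractional interpret `t_min` as a fraction of the intensity
#'   range rather than an absolute intensity.
#' @param fill_holes fill enclosed background before labeling.
#' @param split_touching split touching objects with the watershed method.
#' @param min_object_voxels drop objects smaller than this (>= 1).
#' @param roi optional [mask()]; objects with centroids outside it are
#'   dropped.
#' @param connectivity 4/8 (2D) or 6/26 (3D); default 8/26.
#' @return a `DetectionParams` list.
#' @export
detection_params <- function(prefilter = c("none", "median", "gaussian", "variance"),
                             prefilter_radius = 1L, prefilter_sigma = 1,
                             background = c("none", "rolling_ball"),
                             background_radius = 15L,
                             threshold_method = c("otsu", "mean", "fixed"),
                             k = 1, t_min = 0, t = NULL,
                             t_min_fractional = FALSE,
                             fill_holes = FALSE, split_touching = FALSE,
                             min_object_voxels = 1L, roi = NULL,
                             connectivity = NULL) {
  prefilter <- match.arg(prefilter)
  background <- match.arg(background)
  threshold_method <- match.arg(threshold_method)
  check_number(k, "k", min = 0, strict_min = TRUE)
  check_number(t_min, "t_min")
  check_number(min_object_voxels, "min_object_voxels", min = 1, integer = TRUE)
  check_flag(fill_holes, "fill_holes")
  check_flag(split_touching, "split_touching")
  check_flag(t_min_fractional, "t_min_fractional")
  if (prefilter %in% c("median", "variance"))
    check_number(prefilter_radius, "prefilter_radius", min = 1, integer = TRUE)
  if (prefilter == "gaussian") check_number(prefilter_sigma, "prefilter_sigma", min = 0)
  if (background == "rolling_ball")
    check_number(background_radius, "background_radius", min = 1, integer = TRUE)
  if (threshold_method == "fixed") check_number(t, "t")
  structure(list(prefilter = prefilter, prefilter_radius = prefilter_radius,
                 prefilter_sigma = prefilter_sigma, background = background,
                 background_radius = background_radius,
                 threshold_method = threshold_method, k = k, t_min = t_min,
                 t = t, t_min_fractional = t_min_fractional,
                 fill_holes = fill_holes, split_touching = split_touching,
                 min_object_voxels = min_object_voxels, roi = roi,
                 connectivity = connectivity),
            class = "DetectionParams")
}

#' Detect objects in one channel of an image stack
#'
#' Runs the full detection pipeline on one channel (and optionally one time
#' frame) and returns the label map plus one record per detected object. All
#' parameter values are recorded in the label map's provenance.
#'
#' @param stack an [image_stack()] or numeric array.
#' @param channel channel name or index.
#' @param params a [detection_params()].
#' @param frame time frame (for movies).
#' @return list with elements `labels` (a [label_map()]), `objects` (a
#'   data.frame of [object_records()]) and `threshold` (the applied
#'   intensity threshold).
#' @export
detect <- function(stack, channel = 1L, params = detection_params(), frame = NULL) {
  if (!inherits(params, "DetectionParams"))
    validation_error("params must come from detection_params()")
  img <- if (inherits(stack, "ImageStack")) channel_data(stack, channel, frame)
         else stack
  img <- switch(params$prefilter,
    none = img,
    median = median_filter_2d(img, params$prefilter_radius),
    gaussian = gaussian_filter(img, params$prefilter_sigma),
    variance = variance_filter(img, params$prefilter_radius))
  if (params$background == "rolling_ball")
    img <- rolling_ball_subtract(img, params$background_radius)
  thr <- compute_threshold(img, params$threshold_method, k = params$k,
                           t_min = params$t_min, t = params$t,
                           t_min_fractional = params$t_min_fractional)
  m <- binarize(img, thr)
  if (params$fill_holes) m <- fill_holes(m, params$connectivity)
  prov <- c(unclass(params)[setdiff(names(params), "roi")],
            list(threshold_applied = thr))
  labels <- if (params$split_touching) {
    ws <- watershed_split(m, params$connectivity)
    ws$provenance <- c(prov, list(split = "watershed"))
    ws
  } else {
    label_components(m, params$connectivity, provenance = prov)
  }
  labels <- filter_objects(labels, params$min_object_voxels, params$roi)
  chname <- if (inherits(stack, "ImageStack")) {
    if (is.character(channel)) channel else stack$channel_names[as.integer(channel)]
  } else "img"
  list(labels = labels, objects = object_records(labels, channel = chname),
       threshold = thr)
}
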