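# Readouts: containment of protocells in leukocytes, marker colocalization,
# pigmentation and stained-area fractions, fluorescent pixel counts, tumor
# area/growth and serial-section (Cavalieri) volume.

#' Protocell containment in labeled cells
#'
#' Classifies each detected protocell (PC) as inside or outside a cell: a PC
#' is inside iff the cell label at its rounded centroid voxel is nonzero,
#' and that label is its owner. Reports per-cell PC counts and the two
#' headline percentages: % of PCs inside any cell and % of cells containing
#' at least one PC.
#'
#' @param cells a [label_map()] of detected cells.
#' @param pcs [object_records()] of detected PCs (same frame of reference),
#'   or a detection result list from [detect()].
#' @param rule `"centroid"` (default) or `"full_overlap"`; the latter calls
#'   a PC inside only when every voxel of the PC lies within a single cell
#'   label (sensitivity-check variant; requires `pc_labels`).
#' @param pc_labels optional [label_map()] of the PCs, needed for
#'   `rule = "full_overlap"`.
#' @return list of class `ContainmentResult`: `per_cell` (data.frame
#'   `cell_label`, `n_pcs`), `per_pc` (data.frame `pc_label`, `inside`,
#'   `owner_cell`), `pct_pcs_inside`, `pct_cells_with_pc`, `n_inside`,
#'   `n_outside`, `n_pcs`, `n_cells`.
#' @export
containment <- function(cells, pcs, rule = c("centroid", "full_overlap"),
                        pc_labels = NULL) {
  rule <- match.arg(rule)
  lm <- if (inherits(cells, "LabelMap")) cells else label_map(cells)
  if (is.list(pcs) && !is.data.frame(pcs) && !is.null(pcs$objects)) {
    if (is.null(pc_labels)) pc_labels <- pcs$labels
    pcs <- pcs$objects
  }
  d <- dim(lm$data)
  n_cells <- lm$n_labels
  n_pcs <- nrow(pcs)
  if (n_pcs > 0L) {
    if (!is.null(pc_labels) && !identical(dim(pc_labels$data), d))
      frame_mismatch_error("pc label shape != cell label shape")
    out_of_frame <- pcs$x < -0.5 | pcs$x > d[length(d)] - 0.5 |
                    pcs$y < -0.5 | pcs$y > d[length(d) - 1L] - 0.5
    if (any(out_of_frame))
      frame_mismatch_error("%d PC centroid(s) outside the cell frame", sum(out_of_frame))
    owner <- owner_at_centroid(pcs, lm$data)
    if (rule == "full_overlap") {
      if (is.null(pc_labels))
        validation_error("rule 'full_overlap' needs pc_labels")
      owner <- full_overlap_owner(pcs, pc_labels, lm$data, owner)
    }
  } else owner <- integer(0)
  inside <- owner > 0L
  per_pc <- data.frame(pc_label = if (n_pcs) pcs$label else integer(0),
                       inside = inside,
                       owner_cell = ifelse(inside, owner, NA_integer_))
  counts <- tabulate(owner[inside], nbins = n_cells)
  per_cell <- data.frame(cell_label = seq_len(n_cells), n_pcs = counts)
  structure(list(
    per_cell = per_cell, per_pc = per_pc,
    n_inside = sum(inside), n_outside = sum(!inside), n_pcs = n_pcs,
    n_cells = n_cells,
    pct_pcs_inside = if (n_pcs) 100 * sum(inside) / n_pcs else NA_real_,
    pct_cells_with_pc = if (n_cells) 100 * sum(counts > 0L) / n_cells else NA_real_
  ), class = "ContainmentResult")
}

owner_at_centroid <- function(rec, cell_array) {
  d <- dim(cell_array)
  yi <- pmin(pmax(round(rec$y) + 1L, 1L), d[length(d) - 1L])
  xi <- pmin(pmax(round(rec$x) + 1L, 1L), d[length(d)])
  if (length(d) == 3L) {
    zi <- pmin(pmax(round(rec$z %||% 0) + 1L, 1L), d[1])
    as.integer(cell_array[cbind(zi, yi, xi)])
  } else {
    as.integer(cell_array[cbind(yi, xi)])
  }
}

full_overlap_owner <- function(rec, pc_labels, cell_array, centroid_owner) {
  vapply(seq_len(nrow(rec)), function(i) {
    vox <- which(pc_labels$data == rec$label[i])
    owners <- unique(cell_array[vox])
    if (length(owners) == 1L && owners > 0L) as.integer(owners) else 0L
  }, integer(1))
}

#' Fraction of an object's voxels inside a marker mask
#'
#' @param obj one row of [object_records()] (with `label`), or a label id.
#' @param labels the [label_map()] the object belongs to.
#' @param marker a [mask()] of the same shape.
#' @return overlap fraction in \[0,1\].
#' @export
overlap_fraction <- function(obj, labels, marker) {
  lab <- if (is.data.frame(obj)) obj$label[1] else as.integer(obj)
  lm <- if (inherits(labels, "LabelMap")) labels else label_map(labels)
  ma <- as_mask_array(marker)
  if (!identical(dim(ma), dim(lm$data)))
    frame_mismatch_error("marker shape != label shape")
  vox <- lm$data == lab
  nv <- sum(vox)
  if (nv == 0L) validation_error("label %d has no voxels", lab)
  sum(ma[vox]) / nv
}

#' Classify objects as marker-positive by overlap fraction
#'
#' An object is positive iff the fraction of its voxels inside the marker
#' mask is at least `tau`. `tau = 1` encodes the "fully colocalized" rule
#' used for lysosome containment; `tau = 0.5` is the default for intact-PC
#' (membrane/cargo colocalization) calls.
#'
#' @param labels a [label_map()] of the objects.
#' @param marker a [mask()] of the same shape.
#' @param tau minimum overlap fraction in \[0,1\].
#' @return list: `per_object` (data.frame `label`, `overlap`, `positive`),
#'   `pct_positive`, `n_positive`, `n_objects`.
#' @export
classify_marker_positive <- function(labels, marker, tau = 1.0) {
  check_number(tau, "tau", min = 0, max = 1)
  lm <- if (inherits(labels, "LabelMap")) labels else label_map(labels)
  ma <- as_mask_array(marker)
  if (!identical(dim(ma), dim(lm$data)))
    frame_mismatch_error("marker shape != label shape")
  n <- lm$n_labels
  idx <- lm$data > 0L
  lab <- lm$data[idx]
  tot <- tabulate(lab, nbins = n)
  hit <- tabulate(lab[ma[idx]], nbins = n)
  ov <- ifelse(tot > 0L, hit / tot, 0)
  pos <- ov >= tau
  list(per_object = data.frame(label = seq_len(n), overlap = ov, positive = pos),
       pct_positive = if (n) 100 * sum(pos) / n else NA_real_,
       n_positive = sum(pos), n_objects = n)
}

#' Pigmentation fraction of a region
#'
#' Percentage of region pixels on the pigment side of an automatically
#' computed threshold. For brightfield images pigment is dark, so the
#' default polarity counts pixels at or below the threshold.
#'
#' @param brightfield an [image_stack()] or numeric matrix/array.
#' @param region optional [mask()] restricting the analysis (default: whole
#'   image). The threshold is computed from region pixels only.
#' @param method threshold method (see [compute_threshold()]); default Otsu.
#' @param polarity `"dark"` (pigment below threshold) or `"bright"`.
#' @param ... further arguments (`k`, `t_min`, `t`) for [compute_threshold()].
#' @return percentage in \[0,100\].
#' @export
pigmentation_fraction <- function(brightfield, region = NULL,
                                  method = "otsu", polarity = c("dark", "bright"),
                                  ...) {
  polarity <- match.arg(polarity)
  img <- if (inherits(brightfield, "ImageStack")) brightfield$data else brightfield
  sel <- if (is.null(region)) rep(TRUE, length(img)) else {
    ra <- as_mask_array(region)
    if (!identical(dim(ra), dim(img) %||% length(img)))
      frame_mismatch_error("region shape != image shape")
    as.logical(ra)
  }
  vals <- img[sel]
  if (length(vals) == 0L) validation_error("empty region")
  thr <- compute_threshold(vals, method = method, ...)
  n_pig <- if (polarity == "dark") sum(vals <= thr) else sum(vals > thr)
  100 * n_pig / length(vals)
}

#' Fluorescent pixel count
#'
#' Number of region pixels strictly above the threshold; a proxy for cell
#' burden in whole-region fluorescence images.
#'
#' @param img an [image_stack()] or numeric matrix/array.
#' @param t intensity threshold.
#' @param region optional [mask()].
#' @return integer count.
#' @export
fluorescent_pixel_count <- function(img, t, region = NULL) {
  a <- if (inherits(img, "ImageStack")) img$data else img
  check_number(t, "t")
  fg <- a > t
  if (!is.null(region)) {
    ra <- as_mask_array(region)
    if (!identical(dim(ra), dim(a) %||% length(a)))
      frame_mismatch_error("region shape != image shape")
    fg <- fg & ra
  }
  sum(fg)
}

#' Double-positive area fraction
#'
#' Percentage of the region covered by the intersection of two stain masks
#' (e.g. leukocyte marker × cytokine reporter over the tumor area).
#'
#' @param maskA,maskB stain [mask()]s.
#' @param region region [mask()] (e.g. the tumor outline).
#' @return percentage in \[0,100\].
#' @export
double_positive_area_fraction <- function(maskA, maskB, region) {
  a <- as_mask_array(maskA); b <- as_mask_array(maskB); r <- as_mask_array(region)
  if (!identical(dim(a), dim(r)) || !identical(dim(b), dim(r)))
    frame_mismatch_error("mask shapes differ")
  nr <- sum(r)
  if (nr == 0L) validation_error("empty region")
  100 * sum(a & b & r) / nr
}

#' Positive area fraction
#'
#' Percentage of the region covered by a stain mask (e.g. pH3- or
#' TUNEL-positive area over total tumor area).
#'
#' @param m stain [mask()].
#' @param region region [mask()].
#' @return percentage in \[0,100\].
#' @export
positive_area_fraction <- function(m, region) {
  a <- as_mask_array(m); r <- as_mask_array(region)
  if (!identical(dim(a), dim(r))) frame_mismatch_error("mask shapes differ")
  nr <- sum(r)
  if (nr == 0L) validation_error("empty region")
  100 * sum(a & r) / nr
}

#' Tumor area from an outline mask
#'
#' Pure pixel counting in physical units: foreground pixels × pixel size².
#'
#' @param outline_mask a [mask()] of the outlined tumoral mass.
#' @param pixel_size µm/pixel.
#' @return area in µm².
#' @export
tumor_area <- function(outline_mask, pixel_size) {
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  sum(as_mask_array(outline_mask)) * pixel_size^2
}

#' Relative tumor growth
#'
#' Area at each timepoint as a percentage of the first timepoint.
#'
#' @param areas time-ordered numeric vector of areas (µm²).
#' @return numeric vector of percentages; first element is 100.
#' @export
relative_growth <- function(areas) {
  if (!is.numeric(areas) || length(areas) == 0L)
    validation_error("areas must be a non-empty numeric vector")
  if (areas[1] == 0) degenerate_baseline_error("first-timepoint area is zero")
  100 * areas / areas[1]
}

#' Serial-section (Cavalieri) volume
#'
#' Each section's area × section thickness, summed over sections.
#'
#' @param per_section_areas numeric vector of per-section areas (µm²).
#' @param thickness section thickness in µm (default 10).
#' @return volume in µm³.
#' @export
section_volume <- function(per_section_areas, thickness = 10) {
  check_number(thickness, "thickness", min = 0, strict_min = TRUE)
  if (length(per_section_areas) == 0L) return(0)
  if (!is.numeric(per_section_areas) || any(per_section_areas < 0))
    validation_error("per-section areas must be non-negative numbers")
  sum(per_section_areas * thickness)
}

#' Per-section quantification of a section series
#'
#' Applies area quantification to paired (tumor, stain-positive) masks for a
#' series of sections and reconstructs total volume.
#'
#' @param sections list of lists with elements `tumor` and `positive`
#'   ([mask()]s of equal shape), as produced by [gen_section_series()].
#' @param pixel_size µm/pixel.
#' @param thickness section thickness in µm.
#' @return list of class `SectionQuant`: `per_section` data.frame
#'   (`section`, `tumor_area`, `positive_area`, `positive_fraction`),
#'   `total_volume`, `thickness`.
#' @export
quantify_sections <- function(sections, pixel_size, thickness = 10) {
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  rows <- lapply(seq_along(sections), function(i) {
    s <- sections[[i]]
    ta <- tumor_area(s$tumor, pixel_size)
    pa <- tumor_area(s$positive, pixel_size)
    if (pa > ta) validation_error("positive area exceeds tumor area in section %d", i)
    data.frame(section = i, tumor_area = ta, positive_area = pa,
               positive_fraction = if (ta > 0) pa / ta else 0)
  })
  per <- do.call(rbind, rows)
  structure(list(per_section = per,
                 total_volume = section_volume(per$tumor_area, thickness),
                 thickness = thickness),
            class = "SectionQuant")
}
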