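# Named end-to-end workflows over the stage functions, with validated
# configuration, provenance headers on every output CSV and a run log.
# Workflow names map onto the study's quantifications: pigment, fpc, growth,
# speed, uptake, cells, lyso, intact, sections, volume, synth.

#' Workflow configuration
#'
#' Bundles and validates every user-controlled parameter before any image is
#' read. Unknown keys are rejected.
#'
#' @param seed integer seed used by every stochastic stage.
#' @param detection named list of [detection_params()] (keys `cells`, `pcs`
#'   as needed by the workflow).
#' @param tracking a [tracking_params()] or NULL.
#' @param scene a [scene_params()] or NULL.
#' @param quantify list of quantification thresholds: `tau_lysosome`
#'   (default 1: the "fully colocalized" rule), `tau_intact` (default 0.5),
#'   `pigment_method` (default `"otsu"`), `pigment_polarity` (default
#'   `"dark"`), `fpc_threshold` (default 0), `section_thickness` µm
#'   (default 10).
#' @param axes default axis declaration for TIFF inputs.
#' @return a validated `WorkflowConfig` list.
#' @export
workflow_config <- function(seed = 1L, detection = list(),
                            tracking = NULL, scene = NULL,
                            quantify = list(), axes = NULL) {
  check_number(seed, "seed", integer = TRUE)
  if (!is.list(detection)) validation_error("detection must be a list")
  for (nm in names(detection))
    if (!inherits(detection[[nm]], "DetectionParams"))
      validation_error("detection$%s must come from detection_params()", nm)
  if (!is.null(tracking) && !inherits(tracking, "TrackingParams"))
    validation_error("tracking must come from tracking_params()")
  if (!is.null(scene) && !inherits(scene, "SceneParams"))
    validation_error("scene must come from scene_params()")
  qdef <- list(tau_lysosome = 1.0, tau_intact = 0.5, pigment_method = "otsu",
               pigment_polarity = "dark", fpc_threshold = 0,
               section_thickness = 10)
  unknown <- setdiff(names(quantify), names(qdef))
  if (length(unknown))
    validation_error("unknown quantify key(s): %s", paste(unknown, collapse = ", "))
  q <- utils::modifyList(qdef, quantify)
  check_number(q$tau_lysosome, "tau_lysosome", min = 0, max = 1)
  check_number(q$tau_intact, "tau_intact", min = 0, max = 1)
  check_number(q$fpc_threshold, "fpc_threshold")
  check_number(q$section_thickness, "section_thickness", min = 0, strict_min = TRUE)
  if (!q$pigment_method %in% c("otsu", "mean", "fixed"))
    validation_error("pigment_method must be otsu/mean/fixed")
  if (!q$pigment_polarity %in% c("dark", "bright"))
    validation_error("pigment_polarity must be dark/bright")
  if (!is.null(axes)) parse_axes(axes, nchar(axes))
  structure(list(seed = as.integer(seed), detection = detection,
                 tracking = tracking, scene = scene, quantify = q,
                 axes = axes),
            class = "WorkflowConfig")
}

# 32-bit FNV-1a over the deparsed config; auditable run identity
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- h - h %% 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    # 32-bit modular multiply split into 16-bit halves (exact in doubles)
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

provenance_header <- function(name, config) {
  c(sprintf("# pcquant %s", as.character(utils::packageVersion("pcquant"))),
    sprintf("# workflow %s", name),
    sprintf("# seed %d", config$seed),
    sprintf("# config_hash %s", config_hash(config)))
}

write_csv_prov <- function(df, path, header_lines) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header_lines, con)
  out <- as.data.frame(lapply(df, format_full_precision), optional = TRUE)
  names(out) <- names(df)
  utils::write.csv(out, con, row.names = FALSE)
  path
}

log_params <- function(con, x, prefix = "") {
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v) && !is.data.frame(v) && !inherits(v, "Mask"))
      log_params(con, v, paste0(prefix, nm, "."))
    else if (inherits(v, "Mask"))
      writeLines(sprintf("%s%s = <mask %s>", prefix, nm,
                         paste(dim(v$data), collapse = "x")), con)
    else writeLines(sprintf("%s%s = %s", prefix, nm,
                            paste(format(v), collapse = ",")), con)
  }
}

#' Run a named quantification workflow
#'
#' Dispatches to the stage functions with the validated configuration,
#' writes tidy CSVs (one row per object/cell/section/track step plus a
#' summary) with a provenance header, and logs every parameter value.
#' Reruns with an identical config and seed produce byte-identical outputs.
#'
#' @param name one of `"pigment"`, `"fpc"`, `"growth"`, `"speed"`,
#'   `"uptake"`, `"cells"`, `"lyso"`, `"intact"`, `"sections"`, `"volume"`,
#'   `"synth"`.
#' @param config a [workflow_config()].
#' @param inputs named list of workflow inputs (stacks, masks, areas, paths
#'   — see each workflow's stage functions).
#' @param outdir output directory (created if missing).
#' @return named list of output file paths (invisibly also written to
#'   `outdir`), plus a `summary` element with the workflow's headline
#'   numbers.
#' @export
run_workflow <- function(name = c("pigment", "fpc", "growth", "speed", "uptake",
                                  "cells", "lyso", "intact", "sections",
                                  "volume", "synth"),
                         config = workflow_config(), inputs = list(),
                         outdir = ".") {
  name <- match.arg(name)
  if (!inherits(config, "WorkflowConfig"))
    validation_error("config must come from workflow_config()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(name, config)
  logf <- file.path(outdir, paste0(name, ".log"))
  con <- file(logf, open = "wt")
  writeLines(sub("^# ", "", hdr), con)
  log_params(con, unclass(config))
  close(con)
  out <- withCallingHandlers(
    switch(name,
      synth = wf_synth(config, outdir, hdr),
      uptake = wf_uptake(config, inputs, outdir, hdr),
      cells = wf_cells(config, inputs, outdir, hdr),
      pigment = wf_pigment(config, inputs, outdir, hdr),
      fpc = wf_fpc(config, inputs, outdir, hdr),
      growth = wf_growth(config, inputs, outdir, hdr),
      speed = wf_speed(config, inputs, outdir, hdr),
      lyso = wf_marker(config, inputs, outdir, hdr, config$quantify$tau_lysosome, "lyso"),
      intact = wf_marker(config, inputs, outdir, hdr, config$quantify$tau_intact, "intact"),
      sections = wf_sections(config, inputs, outdir, hdr),
      volume = wf_volume(config, inputs, outdir, hdr)),
    error = function(e) {
      if (!inherits(e, "pcquant_error"))
        pcq_stop("workflow_error", "workflow '%s' failed: %s", name,
                 conditionMessage(e))
    })
  c(out, list(log = logf))
}

as_stack_input <- function(x, config) {
  if (inherits(x, "ImageStack")) x
  else if (is.character(x)) read_stack(x, axes = config$axes)
  else validation_error("input must be an ImageStack or a TIFF path")
}

wf_synth <- function(config, outdir, hdr) {
  sp <- config$scene %||% scene_params(seed = config$seed)
  scene <- gen_uptake_scene(sp)
  img <- scene$stack
  img$data <- pmin(pmax(img$data, 0), 1)
  tif <- file.path(outdir, "scene.tif")
  write_stack(img, tif)
  cells_csv <- write_csv_prov(scene$truth$cells, file.path(outdir, "truth_cells.csv"), hdr)
  pcs_csv <- write_csv_prov(scene$truth$pcs, file.path(outdir, "truth_pcs.csv"), hdr)
  list(stack = tif, truth_cells = cells_csv, truth_pcs = pcs_csv,
       summary = list(containment_fraction_cells = scene$truth$containment_fraction_cells,
                      pct_pcs_inside = scene$truth$pct_pcs_inside))
}

wf_uptake <- function(config, inputs, outdir, hdr) {
  stack <- as_stack_input(inputs$stack, config)
  dp <- config$detection
  cells <- detect(stack, "cells", dp$cells %||% uptake_detection_params()$cells)
  pcs <- detect(stack, "pcs", dp$pcs %||% uptake_detection_params()$pcs)
  res <- containment(cells$labels, pcs)
  f1 <- write_csv_prov(res$per_cell, file.path(outdir, "uptake_per_cell.csv"), hdr)
  f2 <- write_csv_prov(res$per_pc, file.path(outdir, "uptake_per_pc.csv"), hdr)
  smry <- data.frame(n_cells = res$n_cells, n_pcs = res$n_pcs,
                     n_inside = res$n_inside, n_outside = res$n_outside,
                     pct_pcs_inside = res$pct_pcs_inside,
                     pct_cells_with_pc = res$pct_cells_with_pc)
  f3 <- write_csv_prov(smry, file.path(outdir, "uptake_summary.csv"), hdr)
  list(per_cell = f1, per_pc = f2, summary_csv = f3, summary = as.list(smry),
       result = res)
}

wf_cells <- function(config, inputs, outdir, hdr) {
  stack <- as_stack_input(inputs$stack, config)
  dp <- config$detection$cells %||%
    detection_params(prefilter = "gaussian", prefilter_sigma = 1,
                     min_object_voxels = 20L, roi = inputs$roi)
  det <- detect(stack, inputs$channel %||% 1L, dp)
  f <- write_csv_prov(det$objects, file.path(outdir, "cells_objects.csv"), hdr)
  list(objects = f, summary = list(n_cells = det$labels$n_labels))
}

wf_pigment <- function(config, inputs, outdir, hdr) {
  stack <- as_stack_input(inputs$image, config)
  pct <- pigmentation_fraction(stack, region = inputs$region,
                               method = config$quantify$pigment_method,
                               polarity = config$quantify$pigment_polarity)
  f <- write_csv_prov(data.frame(pigmented_pct = pct),
                      file.path(outdir, "pigment_summary.csv"), hdr)
  list(summary_csv = f, summary = list(pigmented_pct = pct))
}

wf_fpc <- function(config, inputs, outdir, hdr) {
  stack <- as_stack_input(inputs$image, config)
  n <- fluorescent_pixel_count(stack, config$quantify$fpc_threshold,
                               region = inputs$region)
  f <- write_csv_prov(data.frame(fluorescent_pixels = n),
                      file.path(outdir, "fpc_summary.csv"), hdr)
  list(summary_csv = f, summary = list(fluorescent_pixels = n))
}

wf_growth <- function(config, inputs, outdir, hdr) {
  areas <- inputs$areas
  if (is.character(areas)) areas <- read_table(areas)$area
  rg <- relative_growth(areas)
  df <- data.frame(timepoint = seq_along(areas), area = areas, relative_pct = rg)
  f <- write_csv_prov(df, file.path(outdir, "growth.csv"), hdr)
  list(growth = f, summary = list(final_relative_pct = rg[length(rg)]))
}

wf_speed <- function(config, inputs, outdir, hdr) {
  stack <- as_stack_input(inputs$stack, config)
  if (!"t" %in% strsplit(stack$axes, "")[[1]])
    validation_error("speed workflow needs a time axis")
  nt <- dim(stack$data)[axis_index(stack, "t")]
  dp <- config$detection$pcs %||%
    detection_params(threshold_method = "otsu", min_object_voxels = 3L)
  dets <- lapply(seq_len(nt), function(f) detect(stack, 1L, dp, frame = f)$objects)
  tp <- config$tracking %||% tracking_params(max_link_distance = 5)
  ts <- link(dets, tp, pixel_size = stack$pixel_size_xy,
             frame_interval = stack$frame_interval)
  steps <- merge(ts$tracks, ts$velocities,
                 by.x = c("track_id", "frame"), by.y = c("track_id", "frame_from"),
                 all.x = TRUE)
  steps <- steps[order(steps$track_id, steps$frame),
                 c("track_id", "frame", "x", "y", "v")]
  f1 <- write_csv_prov(steps, file.path(outdir, "tracks.csv"), hdr)
  f2 <- write_csv_prov(ts$summary, file.path(outdir, "track_summary.csv"), hdr)
  list(tracks = f1, summary_csv = f2,
       summary = list(n_tracks = nrow(ts$summary),
                      mean_speed = mean(ts$velocities$v)),
       result = ts)
}

wf_marker <- function(config, inputs, outdir, hdr, tau, prefix) {
  labels <- inputs$labels
  marker <- inputs$marker
  res <- classify_marker_positive(labels, marker, tau = tau)
  f1 <- write_csv_prov(res$per_object,
                       file.path(outdir, paste0(prefix, "_per_object.csv")), hdr)
  smry <- data.frame(n_objects = res$n_objects, n_positive = res$n_positive,
                     pct_positive = res$pct_positive, tau = tau)
  f2 <- write_csv_prov(smry, file.path(outdir, paste0(prefix, "_summary.csv")), hdr)
  list(per_object = f1, summary_csv = f2, summary = as.list(smry))
}

wf_sections <- function(config, inputs, outdir, hdr) {
  sq <- quantify_sections(inputs$sections, pixel_size = inputs$pixel_size,
                          thickness = config$quantify$section_thickness)
  f1 <- write_csv_prov(sq$per_section, file.path(outdir, "sections.csv"), hdr)
  f2 <- write_csv_prov(data.frame(total_volume = sq$total_volume,
                                  thickness = sq$thickness),
                       file.path(outdir, "volume_summary.csv"), hdr)
  list(per_section = f1, summary_csv = f2,
       summary = list(total_volume = sq$total_volume))
}

wf_volume <- function(config, inputs, outdir, hdr) {
  areas <- inputs$areas
  if (is.character(areas)) areas <- read_table(areas)$tumor_area
  vol <- section_volume(areas, config$quantify$section_thickness)
  f <- write_csv_prov(data.frame(total_volume = vol,
                                 thickness = config$quantify$section_thickness),
                      file.path(outdir, "volume_summary.csv"), hdr)
  list(summary_csv = f, summary = list(total_volume = vol))
}

#' Default detection parameters for the two-channel uptake scene
#'
#' The settings used by the uptake workflow when none are configured:
#' Gaussian-smoothed Otsu detection for the cell channel, median-filtered
#' Otsu detection with a small size filter for the PC channel.
#'
#' @return list with elements `cells` and `pcs` ([detection_params()]).
#' @export
uptake_detection_params <- function() {
  list(cells = detection_params(prefilter = "gaussian", prefilter_sigma = 1,
                                threshold_method = "otsu",
                                min_object_voxels = 50L),
       pcs = detection_params(prefilter = "median", prefilter_radius = 1L,
                              threshold_method = "otsu",
                              min_object_voxels = 4L))
}
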