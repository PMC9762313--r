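# TIFF and table I/O.
#
# Pages of a multi-page TIFF enumerate the non-spatial axes of the declared
# axis string with the rightmost axis varying fastest (so "zcyx" stores pages
# c1z1, c2z1, c1z2, ...). Calibration and axis layout are written to a
# plain-text sidecar (<path>.meta) alongside the TIFF, giving exact
# round-trips; X/YResolution tags of third-party files are honoured on read.

DESC_PREFIX <- "pcquant1;"

encode_description <- function(stack) {
  ax <- strsplit(stack$axes, "")[[1]]
  d <- dim(stack$data)
  paste0(DESC_PREFIX,
         "axes=", stack$axes, ";",
         "dims=", paste(d, collapse = ","), ";",
         "pixel_size_xy=", sprintf("%.17g", stack$pixel_size_xy), ";",
         "pixel_size_z=", sprintf("%.17g", stack$pixel_size_z), ";",
         "frame_interval=", sprintf("%.17g", stack$frame_interval), ";",
         "channel_names=", paste(stack$channel_names, collapse = ","), ";")
}

decode_description <- function(desc) {
  if (is.null(desc) || !is.character(desc) || length(desc) != 1L ||
      !startsWith(desc, DESC_PREFIX)) return(NULL)
  body <- substr(desc, nchar(DESC_PREFIX) + 1L, nchar(desc))
  kv <- strsplit(strsplit(body, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  out <- list()
  for (p in kv) if (length(p) == 2L) out[[p[1]]] <- p[2]
  out
}

#' Read a TIFF file into a calibrated image stack
#'
#' Single- or multi-page grayscale TIFF. Axis layout is taken from the
#' embedded description written by [write_stack()] when present; otherwise it
#' must be declared via `axes` (and `axis_sizes` when more than one
#' non-spatial axis is present) — axis order is never guessed. Calibration is
#' taken from explicit overrides first, then file metadata; a stack with no
#' usable calibration is an error.
#'
#' Integer TIFFs (8/16-bit) are returned on their native integer scale
#' (0–255 / 0–65535); float TIFFs are returned as stored.
#'
#' @param path TIFF file path.
#' @param axes axis declaration (see [image_stack()]); optional when the file
#'   is single-page (`"yx"` assumed) or self-describing.
#' @param axis_sizes named integer vector giving the lengths of the
#'   non-spatial axes (e.g. `c(z = 5, c = 2)`); optional when at most one
#'   non-spatial axis is present.
#' @param pixel_size_xy,pixel_size_z,frame_interval,channel_names calibration
#'   overrides; override file metadata when given.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, axes = NULL, axis_sizes = NULL,
                       pixel_size_xy = NULL, pixel_size_z = NULL,
                       frame_interval = NULL, channel_names = NULL) {
  if (!file.exists(path)) format_error("cannot read '%s': no such file", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) format_error("unreadable TIFF '%s': %s",
                                                     path, conditionMessage(e)))
  if (length(pages) == 0L) format_error("'%s' contains no pages", path)
  info <- attributes(pages[[1]])
  sidecar <- paste0(path, ".meta")
  meta <- decode_description(info$description)
  if (is.null(meta) && file.exists(sidecar))
    meta <- decode_description(readLines(sidecar, warn = FALSE)[1])

  if (is.null(axes)) {
    if (!is.null(meta$axes)) axes <- meta$axes
    else if (length(pages) == 1L) axes <- "yx"
    else axis_ambiguity_error(
      "'%s' has %d pages and no axis declaration", path, length(pages))
  }
  ax <- strsplit(axes, "")[[1]]
  extra <- setdiff(ax, c("y", "x"))

  for (p in pages) if (length(dim(p)) == 3L)
    format_error("'%s' has multi-sample pages; only grayscale TIFF is supported", path)
  hw <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), hw), logical(1))))
    format_error("'%s': pages differ in size", path)

  if (length(extra) == 0L) {
    if (length(pages) != 1L)
      axis_ambiguity_error("axes \"%s\" but file has %d pages", axes, length(pages))
    sizes <- integer(0)
  } else if (!is.null(meta$dims) && identical(meta$axes, axes)) {
    d <- as.integer(strsplit(meta$dims, ",")[[1]])
    sizes <- d[seq_along(extra)]
  } else if (length(extra) == 1L) {
    sizes <- length(pages)
  } else {
    if (is.null(axis_sizes) || !all(extra %in% names(axis_sizes)))
      axis_ambiguity_error(
        "axes \"%s\" needs axis_sizes for %s", axes, paste(extra, collapse = ","))
    sizes <- as.integer(axis_sizes[extra])
  }
  if (prod(sizes) != length(pages) && length(extra) > 0L)
    axis_ambiguity_error("declared axis sizes (%s) do not match %d pages",
                         paste(sizes, collapse = "x"), length(pages))

  # integer TIFFs come back scaled to [0,1]; return native integer counts
  bits <- info$bits.per.sample %||% 8L
  if (bits %in% c(8L, 16L))
    pages <- lapply(pages, function(p) round(p * (2^bits - 1)))

  # assemble: pages enumerate `extra` with the last axis fastest
  arr <- array(0, dim = c(hw[1], hw[2], max(1L, length(pages))))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  if (length(extra) == 0L) {
    data <- array(arr[, , 1], dim = hw)
  } else {
    # page index varies last-of-extra fastest, so reshaping gives
    # (y, x, e_k, ..., e_1); permute to (e_1, ..., e_k, y, x)
    data <- aperm(array(arr, dim = c(hw, rev(sizes))),
                  c(rev(seq_along(extra)) + 2L, 1L, 2L))
  }

  # calibration: override > embedded description > resolution tags
  num_or_null <- function(x) {
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) NULL else v
  }
  px <- pixel_size_xy %||% num_or_null(meta$pixel_size_xy) %||% resolution_pixel_size(info)
  if (is.null(px) || !is.finite(px)) calibration_error("'%s': no pixel size metadata and no override", path)
  if (px <= 0) calibration_error("'%s': non-positive pixel size %g", path, px)
  pz <- pixel_size_z %||% num_or_null(meta$pixel_size_z)
  if (!is.null(pz) && is.na(pz)) pz <- NULL
  fi <- frame_interval %||% num_or_null(meta$frame_interval)
  if (!is.null(fi) && is.na(fi)) fi <- NULL
  cn <- channel_names %||%
    (if (!is.null(meta$channel_names)) strsplit(meta$channel_names, ",")[[1]] else NULL)

  image_stack(data, paste(c(extra, "y", "x"), collapse = ""),
              pixel_size_xy = px, pixel_size_z = pz,
              frame_interval = fi, channel_names = cn)
}

resolution_pixel_size <- function(info) {
  xr <- info$x.resolution
  if (is.null(xr) || !is.numeric(xr) || xr == 0) return(NULL)
  unit <- info$resolution.unit %||% "inch"
  per_um <- switch(unit,
                   cm = xr / 1e4,
                   inch = xr / 25400,
                   xr)          # "none": treat as pixels per µm
  1 / per_um
}

#' Write an image stack to a multi-page TIFF
#'
#' Dtypes: `"uint8"` (integers 0–255), `"uint16"` (0–65535) and `"float"`
#' (values in \[0,1\], stored as 32-bit samples on the `s / 2^32` grid; see
#' [storage_quantize()]). Calibration and axis layout go to a plain-text
#' sidecar so [read_stack()] round-trips exactly.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @param dtype `"uint8"`, `"uint16"` or `"float"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, dtype = c("float", "uint8", "uint16")) {
  dtype <- match.arg(dtype)
  a <- stack$data
  ax <- strsplit(stack$axes, "")[[1]]
  extra <- setdiff(ax, c("y", "x"))
  d <- dim(a)
  if (length(extra) > 0L) {
    # -> (y, x, rev(extra)); pages then enumerate extra with last axis fastest
    a <- aperm(a, c(length(ax) - 1L, length(ax), rev(seq_along(extra))))
    npages <- prod(d[seq_along(extra)])
    dim(a) <- c(d[length(ax) - 1L], d[length(ax)], npages)
    pages <- lapply(seq_len(npages), function(i) a[, , i])
  } else {
    pages <- list(a)
  }
  rng <- range(stack$data)
  pages <- switch(dtype,
    uint8 = {
      if (any(stack$data != round(stack$data)) || rng[1] < 0 || rng[2] > 255)
        format_error("uint8 output requires integer data in [0,255]")
      lapply(pages, function(p) p / 255)
    },
    uint16 = {
      if (any(stack$data != round(stack$data)) || rng[1] < 0 || rng[2] > 65535)
        format_error("uint16 output requires integer data in [0,65535]")
      lapply(pages, function(p) p / 65535)
    },
    float = {
      if (rng[1] < 0 || rng[2] > 1)
        format_error("float output requires data in [0,1] (got range %g..%g)", rng[1], rng[2])
      # 32-bit samples hold s/2^32 grid values; pre-compensate the writer's
      # floor(v*(2^32-1)) scaling so read-back returns exactly s/2^32
      lapply(pages, function(p) {
        s <- pmin(round(p * 4294967296), 4294967295)
        q <- pmin((s + 0.5) / 4294967295, 1)
        dim(q) <- dim(p)
        q
      })
    })
  bits <- c(uint8 = 8L, uint16 = 16L, float = 32L)[[dtype]]
  tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
    TRUE
  }, error = function(e) format_error("cannot write '%s': %s", path, conditionMessage(e)),
     warning = function(w) format_error("TIFF write warning for '%s': %s", path, conditionMessage(w)))
  writeLines(encode_description(stack), paste0(path, ".meta"))
  invisible(path)
}

#' Quantize intensities to the stored 32-bit grid
#'
#' [write_stack()]'s `"float"` dtype stores values on the `s / 2^32` grid
#' (32-bit samples). Applying this quantization first makes
#' read-after-write an exact identity.
#'
#' @param x numeric values in \[0,1\].
#' @return values rounded to the storage grid (error at most 2^-33).
#' @export
storage_quantize <- function(x) {
  q <- pmin(round(x * 4294967296), 4294967295) / 4294967296
  dim(q) <- dim(x)
  q
}

#' Write a table of records as CSV
#'
#' Header row, input row order, numeric fields serialized with full
#' (shortest round-trippable) precision.
#'
#' @param records a data.frame, or a list of same-schema named lists/rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- coerce_records(records)
  out <- as.data.frame(lapply(df, format_full_precision),
                       optional = TRUE, stringsAsFactors = FALSE)
  names(out) <- names(df)
  ok <- tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
                 error = function(e) pcq_stop("io_error", "cannot write '%s': %s",
                                              path, conditionMessage(e)))
  invisible(path)
}

# %.17g round-trips every double exactly through read.csv
format_full_precision <- function(col) {
  if (!is.double(col)) return(col)
  out <- sprintf("%.17g", col)
  out[is.na(col)] <- NA_character_
  out
}

coerce_records <- function(records) {
  if (is.data.frame(records)) return(records)
  if (!is.list(records)) validation_error("records must be a data.frame or list of rows")
  if (length(records) == 0L) validation_error("empty record list has no schema; pass a 0-row data.frame")
  schemas <- lapply(records, names)
  if (!all(vapply(schemas, identical, logical(1), y = schemas[[1]])))
    schema_error("records do not share a schema")
  do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Read back a quantification CSV
#'
#' Companion to [write_table()] / workflow outputs: skips `#` provenance
#' comment lines.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' QC overlay: detected object outlines over the raw image
#'
#' Writes an 8-bit RGB PNG with the (contrast-stretched) image in gray and
#' label boundaries in red. 3D inputs are maximum-projected.
#'
#' @param img 2D numeric matrix, or 3D `zyx` array, or [image_stack()]
#'   (single channel).
#' @param labels a [label_map()] (same spatial shape).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, labels, path) {
  if (inherits(img, "ImageStack")) img <- channel_data(img)
  lab <- if (inherits(labels, "LabelMap")) labels$data else labels
  if (length(dim(img)) == 3L) {
    img <- apply(img, c(2, 3), max)
    lab <- apply(lab, c(2, 3), max)
  }
  if (!identical(dim(img), dim(lab))) frame_mismatch_error("image/label shape mismatch")
  rng <- range(img)
  g <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  b <- label_boundaries(lab)
  rgb <- array(0, dim = c(dim(img), 3L))
  rgb[, , 1] <- ifelse(b, 1, g)
  rgb[, , 2] <- ifelse(b, 0, g)
  rgb[, , 3] <- ifelse(b, 0, g)
  png::writePNG(rgb, path)
  invisible(path)
}

# boundary = labeled pixel with a 4-neighbor of a different label
label_boundaries <- function(lab) {
  d <- dim(lab)
  pad <- function(m, dy, dx) {
    i <- pmin(pmax(seq_len(d[1]) + dy, 1L), d[1])
    j <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
    m[i, j, drop = FALSE]
  }
  diff <- (lab != pad(lab, 1, 0)) | (lab != pad(lab, -1, 0)) |
          (lab != pad(lab, 0, 1)) | (lab != pad(lab, 0, -1))
  diff & lab > 0L
}
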