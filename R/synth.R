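# Synthetic-microscopy generator: scenes, movies and section series with
# planted ground truth, so every quantification stage can be verified
# without original imaging data.
#
# One global integer seed drives hierarchical substreams (independent derived
# seeds per stage/particle/section), so e.g. adding PCs does not perturb the
# cell placements. All generators are bitwise deterministic for a fixed seed
# and exactly noiseless at snr = Inf.

# deterministic substream seed < 2^31 derived from a seed and a tag
derive_seed <- function(seed, tag) {
  x <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(as.character(tag))) x <- (x * 69069 + c) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic uptake scene parameters
#'
#' Conditions emulating the in-vivo uptake assay: blob-like leukocytes with
#' ~2 µm protocell (PC) spheres planted inside or outside them at a
#' controlled containment fraction, over a smooth background with
#' Poisson + Gaussian noise.
#'
#' @param n_cells number of cells (>= 0).
#' @param cell_radius_range cell radius range, µm.
#' @param n_pcs number of PCs (>= 0).
#' @param pc_diameter PC diameter, µm (default 2, the design diameter for
#'   intravenous delivery; must be smaller than the smallest cell).
#' @param frac_cells_with_pc planted fraction of cells owning >= 1 PC.
#' @param pcs_per_loaded_cell_range integer range of PCs per loaded cell.
#' @param field_size field of view (y, x), µm.
#' @param pixel_size µm/pixel.
#' @param snr peak signal / Poisson noise sd at peak; `Inf` = noiseless.
#' @param background `c(offset, gradient_amplitude)` as fractions of peak
#'   signal; the gradient direction is drawn per scene.
#' @param read_noise Gaussian read-noise sd as a fraction of the Poisson sd
#'   at peak.
#' @param blob_softness cell edge softness (logistic fall-off width), µm;
#'   makes the threshold choice non-trivial, as in real fluorescence.
#' @param clearance minimum gap between an outside PC and any cell boundary,
#'   µm (>= one PC radius).
#' @param seed integer scene seed.
#' @return a `SceneParams` list.
#' @export
scene_params <- function(n_cells = 50, cell_radius_range = c(4, 7),
                         n_pcs = 60, pc_diameter = 2,
                         frac_cells_with_pc = 0.4,
                         pcs_per_loaded_cell_range = c(1L, 2L),
                         field_size = c(140, 140), pixel_size = 0.5,
                         snr = 20, background = c(0.05, 0.02),
                         read_noise = 0.5, blob_softness = 0.75,
                         clearance = 2, seed = 1L) {
  check_number(n_cells, "n_cells", min = 0, integer = TRUE)
  check_number(n_pcs, "n_pcs", min = 0, integer = TRUE)
  check_number(frac_cells_with_pc, "frac_cells_with_pc", min = 0, max = 1)
  check_number(pc_diameter, "pc_diameter", min = 0, strict_min = TRUE)
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0)
    validation_error("snr must be > 0 (Inf allowed)")
  check_number(read_noise, "read_noise", min = 0)
  check_number(blob_softness, "blob_softness", min = 0, strict_min = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (length(cell_radius_range) != 2L || any(cell_radius_range <= 0) ||
      cell_radius_range[1] > cell_radius_range[2])
    validation_error("bad cell_radius_range")
  if (n_cells > 0 && pc_diameter >= 2 * cell_radius_range[1])
    validation_error("pc_diameter must be smaller than the smallest cell diameter")
  if (clearance < pc_diameter / 2)
    validation_error("clearance must be >= one PC radius")
  structure(list(n_cells = as.integer(n_cells),
                 cell_radius_range = as.numeric(cell_radius_range),
                 n_pcs = as.integer(n_pcs), pc_diameter = pc_diameter,
                 frac_cells_with_pc = frac_cells_with_pc,
                 pcs_per_loaded_cell_range = as.integer(pcs_per_loaded_cell_range),
                 field_size = as.numeric(field_size), pixel_size = pixel_size,
                 snr = snr, background = as.numeric(background),
                 read_noise = read_noise, blob_softness = blob_softness,
                 clearance = clearance, seed = as.integer(seed)),
            class = "SceneParams")
}

#' Density presets matching the injected titers
#'
#' The study used high/medium/low titers of 1.25e7, 5e6 and 2.5e6 PCs/µL;
#' scene PC counts scale in the same 5 : 2 : 1 proportion.
#'
#' @param level `"high"`, `"medium"` or `"low"`.
#' @param base_n_pcs PC count at the high titer.
#' @param base_frac_cells_with_pc loaded-cell fraction at the high titer;
#'   scaled with the titer ratio (fewer circulating PCs load fewer cells).
#' @param ... passed to [scene_params()].
#' @return a `SceneParams` list.
#' @export
titer_preset <- function(level = c("high", "medium", "low"), base_n_pcs = 60L,
                         base_frac_cells_with_pc = 0.4, ...) {
  level <- match.arg(level)
  ratio <- c(high = 1, medium = 0.4, low = 0.2)[[level]]  # 1.25e7 : 5e6 : 2.5e6
  scene_params(n_pcs = max(1L, as.integer(round(base_n_pcs * ratio))),
               frac_cells_with_pc = base_frac_cells_with_pc * ratio, ...)
}

# logistic radial blob added into img (matrix, y rows x cols); 0-based pixel
# centers at index * px µm
render_blob <- function(img, cx, cy, R, w, px, peak = 1) {
  d <- dim(img)
  reach <- R + 6 * w
  xs <- max(0L, floor((cx - reach) / px)):min(d[2] - 1L, ceiling((cx + reach) / px))
  ys <- max(0L, floor((cy - reach) / px)):min(d[1] - 1L, ceiling((cy + reach) / px))
  if (length(xs) == 0L || length(ys) == 0L) return(img)
  dist <- sqrt(outer((ys * px - cy)^2, (xs * px - cx)^2, `+`))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
    peak / (1 + exp((dist - R) / w))
  img
}

smooth_background <- function(d, offset, amplitude, seed) {
  if (amplitude == 0) return(matrix(offset, d[1], d[2]))
  with_seed(seed, {
    theta <- stats::runif(1, 0, 2 * pi)
    u <- outer(seq_len(d[1]) / d[1] * sin(theta),
               rep(1, d[2])) +
         outer(rep(1, d[1]), seq_len(d[2]) / d[2] * cos(theta))
    offset + amplitude * (u - min(u)) / max(1e-12, diff(range(u)))
  })
}

# Poisson shot + Gaussian read noise at a given snr; Inf = exact render
apply_noise <- function(render, snr, read_noise, seed) {
  if (!is.finite(snr)) return(render)
  with_seed(seed, {
    photons <- stats::rpois(length(render), as.numeric(render) * snr^2)
    noisy <- photons + stats::rnorm(length(render), 0, read_noise * snr)
    out <- pmax(noisy, 0) / snr^2
    dim(out) <- dim(render)
    out
  })
}

#' Generate a synthetic uptake scene
#'
#' Channel 1 holds soft-edged cell bodies, channel 2 the PC spheres. Exactly
#' `round(frac_cells_with_pc * n_cells)` cells own at least one PC; inside
#' PCs have their centers within the owner's boundary minus one PC radius;
#' the remaining PCs lie outside all cells with the configured clearance.
#'
#' @param params a [scene_params()].
#' @return list with `stack` (2-channel [image_stack()], axes `cyx`,
#'   channels `cells`, `pcs`) and `truth` (a `SceneTruth`: data.frames
#'   `cells` (`id`, `x`, `y`, `r`, `loaded`) and `pcs` (`id`, `x`, `y`,
#'   `inside`, `owner`) in µm, plus `containment_fraction_cells`,
#'   `pct_pcs_inside`, scene geometry and the seed).
#' @export
gen_uptake_scene <- function(params = scene_params()) {
  if (!inherits(params, "SceneParams"))
    validation_error("params must come from scene_params()")
  p <- params
  fs <- p$field_size
  pc_r <- p$pc_diameter / 2

  # --- cells (substream "cells") -------------------------------------------
  cells <- with_seed(derive_seed(p$seed, "cells"), {
    xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
    for (i in seq_len(p$n_cells)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        r <- stats::runif(1, p$cell_radius_range[1], p$cell_radius_range[2])
        margin <- r + 1
        x <- stats::runif(1, margin, fs[2] - margin)
        y <- stats::runif(1, margin, fs[1] - margin)
        if (all(sqrt((xs - x)^2 + (ys - y)^2) >= rs + r + 3)) {
          xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        packing_error("could not place cell %d of %d in a %gx%g um field",
                      i, p$n_cells, fs[1], fs[2])
    }
    data.frame(id = seq_len(p$n_cells), x = xs, y = ys, r = rs)
  })

  # --- PC ownership (substream "pcs") --------------------------------------
  n_loaded <- round(p$frac_cells_with_pc * p$n_cells)
  if (p$n_pcs < n_loaded)
    validation_error("n_pcs (%d) < cells that must own a PC (%d)", p$n_pcs, n_loaded)
  own <- with_seed(derive_seed(p$seed, "pcs"), {
    loaded <- if (n_loaded > 0) sample(seq_len(p$n_cells), n_loaded) else integer(0)
    lo <- p$pcs_per_loaded_cell_range[1]; hi <- p$pcs_per_loaded_cell_range[2]
    counts <- if (n_loaded > 0) lo + sample.int(hi - lo + 1L, n_loaded, replace = TRUE) - 1L
              else integer(0)
    while (sum(counts) > p$n_pcs) {
      i <- which(counts > 1L)
      if (length(i) == 0L) break
      i <- i[sample.int(length(i), 1L)]
      counts[i] <- counts[i] - 1L
    }
    list(loaded = loaded, counts = counts)
  })
  if (sum(own$counts) > p$n_pcs)
    validation_error("cannot satisfy frac_cells_with_pc with n_pcs = %d", p$n_pcs)
  n_outside <- p$n_pcs - sum(own$counts)

  # --- PC placement (substream "pcpos") ------------------------------------
  pcs <- with_seed(derive_seed(p$seed, "pcpos"), {
    px <- numeric(0); py <- numeric(0); inside <- logical(0); owner <- integer(0)
    place_sep <- function(x, y) all(sqrt((px - x)^2 + (py - y)^2) >= p$pc_diameter * 2)
    sep <- p$pc_diameter * 2
    for (ci in seq_along(own$loaded)) {
      cell <- cells[own$loaded[ci], ]
      rmax <- cell$r - pc_r
      cnt <- own$counts[ci]
      ok <- FALSE
      for (try in seq_len(2000L)) {
        if (cnt == 1L) {
          a <- stats::runif(1, 0, 2 * pi)
          rr <- sqrt(stats::runif(1)) * rmax
          cx <- cell$x + rr * cos(a); cy <- cell$y + rr * sin(a)
        } else {
          # jittered ring: equal angular spacing guarantees the pairwise
          # separation that independent uniform draws cannot
          phi <- stats::runif(1, 0, 2 * pi) +
                 2 * pi * (seq_len(cnt) - 1L) / cnt +
                 stats::runif(cnt, -0.15, 0.15)
          rad <- stats::runif(cnt, 0.75, 0.95) * rmax
          cx <- cell$x + rad * cos(phi); cy <- cell$y + rad * sin(phi)
          if (cnt > 1L && min(stats::dist(cbind(cx, cy))) < sep) next
        }
        if (all(vapply(seq_along(cx), function(i) place_sep(cx[i], cy[i]),
                       logical(1)))) { ok <- TRUE; break }
      }
      if (!ok) packing_error("could not place %d PC(s) inside cell %d", cnt, cell$id)
      px <- c(px, cx); py <- c(py, cy); inside <- c(inside, rep(TRUE, cnt))
      owner <- c(owner, rep(cell$id, cnt))
    }
    for (k in seq_len(n_outside)) {
      ok <- FALSE
      for (try in seq_len(4000L)) {
        x <- stats::runif(1, pc_r + 1, fs[2] - pc_r - 1)
        y <- stats::runif(1, pc_r + 1, fs[1] - pc_r - 1)
        clear <- if (nrow(cells)) all(sqrt((cells$x - x)^2 + (cells$y - y)^2) >=
                                      cells$r + pc_r + p$clearance) else TRUE
        if (clear && place_sep(x, y)) { ok <- TRUE; break }
      }
      if (!ok) packing_error("could not place free PC %d outside all cells", k)
      px <- c(px, x); py <- c(py, y); inside <- c(inside, FALSE)
      owner <- c(owner, NA_integer_)
    }
    if (length(px) == 0L)
      data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                 inside = logical(0), owner = integer(0))
    else data.frame(id = seq_along(px), x = px, y = py, inside = inside,
                    owner = owner)
  })

  # --- render + noise ------------------------------------------------------
  d <- c(round(fs[1] / p$pixel_size), round(fs[2] / p$pixel_size))
  ch_cells <- smooth_background(d, p$background[1], p$background[2],
                                derive_seed(p$seed, "bg1"))
  for (i in seq_len(nrow(cells)))
    ch_cells <- render_blob(ch_cells, cells$x[i], cells$y[i], cells$r[i],
                            p$blob_softness, p$pixel_size)
  ch_pcs <- smooth_background(d, p$background[1], p$background[2],
                              derive_seed(p$seed, "bg2"))
  for (i in seq_len(nrow(pcs)))
    ch_pcs <- render_blob(ch_pcs, pcs$x[i], pcs$y[i], pc_r, 0.25, p$pixel_size)
  ch_cells <- apply_noise(ch_cells, p$snr, p$read_noise, derive_seed(p$seed, "noise1"))
  ch_pcs <- apply_noise(ch_pcs, p$snr, p$read_noise, derive_seed(p$seed, "noise2"))

  data <- array(0, dim = c(2L, d))
  data[1, , ] <- ch_cells
  data[2, , ] <- ch_pcs
  stack <- image_stack(data, "cyx", pixel_size_xy = p$pixel_size,
                       channel_names = c("cells", "pcs"))
  truth <- structure(list(
    cells = transform(cells, loaded = id %in% own$loaded),
    pcs = pcs,
    containment_fraction_cells = if (p$n_cells) n_loaded / p$n_cells else NA_real_,
    pct_pcs_inside = if (p$n_pcs) 100 * sum(pcs$inside) / p$n_pcs else NA_real_,
    pc_diameter = p$pc_diameter, pixel_size = p$pixel_size,
    field_size = fs, seed = p$seed), class = "SceneTruth")
  list(stack = stack, truth = truth)
}

#' Re-derive containment flags from scene geometry
#'
#' Recomputes, for every PC, whether its center lies within some cell's
#' boundary minus one PC radius; used to check `SceneTruth`
#' self-consistency.
#'
#' @param truth a `SceneTruth` from [gen_uptake_scene()].
#' @return logical vector, one flag per PC.
#' @export
rederive_containment <- function(truth) {
  if (nrow(truth$pcs) == 0L) return(logical(0))
  pc_r <- truth$pc_diameter / 2
  vapply(seq_len(nrow(truth$pcs)), function(i) {
    d <- sqrt((truth$cells$x - truth$pcs$x[i])^2 +
              (truth$cells$y - truth$pcs$y[i])^2)
    any(d <= truth$cells$r - pc_r)
  }, logical(1))
}

#' Generate a pulsatile flow movie
#'
#' Particles advance each frame by `speed(t) * frame_interval` along
#' `direction_deg`, with `speed(t) = speed_mean * (1 + pulsatility *
#' sin(2*pi*t/pulse_period))`. Particles leaving the field are removed (and
#' logged in the truth). The truth stores per-step displacement vectors and
#' speeds.
#'
#' @param n_particles number of particles.
#' @param speed_mean mean speed, µm/s.
#' @param speed_pulsatility relative sinusoidal amplitude in \[0,1).
#' @param direction_deg flow direction (0 = +x).
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds/frame.
#' @param field field of view (y, x), µm.
#' @param pixel_size µm/pixel.
#' @param snr,read_noise noise model as in [scene_params()].
#' @param pulse_period pulsatility period, s (default 0.5, a larval
#'   zebrafish heartbeat).
#' @param spot_sigma rendered spot size, µm.
#' @param seed integer seed.
#' @return list with `stack` (a `tyx` [image_stack()]) and `truth`
#'   (`SceneTruth` with `positions` (`particle`, `frame`, `x`, `y`, in µm),
#'   `steps` (`particle`, `frame_from`, `frame_to`, `dx`, `dy`, `speed`),
#'   `left_field` log, and the generating parameters).
#' @export
gen_flow_movie <- function(n_particles = 8, speed_mean = 10,
                           speed_pulsatility = 0, direction_deg = 0,
                           n_frames = 100, frame_interval = 0.1,
                           field = c(50, 150), pixel_size = 0.5,
                           snr = 20, read_noise = 0.5, pulse_period = 0.5,
                           spot_sigma = 0.6, seed = 1L) {
  check_number(n_particles, "n_particles", min = 0, integer = TRUE)
  check_number(speed_mean, "speed_mean", min = 0)
  check_number(speed_pulsatility, "speed_pulsatility", min = 0, max = 1)
  check_number(n_frames, "n_frames", min = 2, integer = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(seed, "seed", integer = TRUE)

  dir <- direction_deg * pi / 180
  init <- with_seed(derive_seed(seed, "init"), {
    data.frame(particle = seq_len(n_particles),
               x = stats::runif(n_particles, 2, field[2] * 0.4),
               y = stats::runif(n_particles, 3, field[1] - 3))
  })

  pos <- list(); steps <- list(); left <- list()
  x <- init$x; y <- init$y
  alive <- rep(TRUE, n_particles)
  for (f in seq_len(n_frames)) {
    pos[[f]] <- data.frame(particle = init$particle[alive], frame = f,
                           x = x[alive], y = y[alive])
    if (f == n_frames) break
    t_now <- (f - 1) * frame_interval
    sp <- speed_mean * (1 + speed_pulsatility * sin(2 * pi * t_now / pulse_period))
    dx <- sp * frame_interval * cos(dir)
    dy <- sp * frame_interval * sin(dir)
    nx <- x + dx; ny <- y + dy
    in_field <- nx >= 0 & nx <= field[2] & ny >= 0 & ny <= field[1]
    stepped <- alive & in_field
    if (any(stepped))
      steps[[f]] <- data.frame(particle = init$particle[stepped],
                               frame_from = f, frame_to = f + 1,
                               dx = dx, dy = dy, speed = sp)
    gone <- alive & !in_field
    if (any(gone))
      left[[f]] <- data.frame(particle = init$particle[gone], frame = f + 1)
    alive <- stepped
    x <- nx; y <- ny
  }

  d <- c(round(field[1] / pixel_size), round(field[2] / pixel_size))
  frames <- array(0, dim = c(n_frames, d))
  for (f in seq_len(n_frames)) {
    img <- smooth_background(d, 0.05, 0.02, derive_seed(seed, paste0("bg", f)))
    pf <- pos[[f]]
    for (i in seq_len(nrow(pf)))
      img <- render_blob(img, pf$x[i], pf$y[i], spot_sigma, spot_sigma / 2,
                         pixel_size)
    frames[f, , ] <- apply_noise(img, snr, read_noise,
                                 derive_seed(seed, paste0("noise", f)))
  }
  stack <- image_stack(frames, "tyx", pixel_size_xy = pixel_size,
                       frame_interval = frame_interval)
  bindr <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  truth <- structure(list(
    positions = bindr(pos, data.frame(particle = integer(0), frame = integer(0),
                                      x = numeric(0), y = numeric(0))),
    steps = bindr(steps, data.frame(particle = integer(0), frame_from = integer(0),
                                    frame_to = integer(0), dx = numeric(0),
                                    dy = numeric(0), speed = numeric(0))),
    left_field = bindr(left, data.frame(particle = integer(0), frame = integer(0))),
    speed_mean = speed_mean, speed_pulsatility = speed_pulsatility,
    direction_deg = direction_deg, frame_interval = frame_interval,
    pixel_size = pixel_size, field = field, seed = seed), class = "SceneTruth")
  list(stack = stack, truth = truth)
}

#' Generate a serial-section series of a solid of known volume
#'
#' Sections a sphere or axis-aligned ellipsoid into slabs of the given
#' thickness; section k's tumor mask is the rasterized cross-section at
#' depth (k+1/2)·thickness, and the positive mask is a random sub-mask
#' occupying `positive_fraction` of the tumor pixels (to within one pixel).
#'
#' @param shape `list(type = "sphere", r = ...)` or
#'   `list(type = "ellipsoid", a = ..., b = ..., c = ...)`, semi-axes in µm
#'   (a along x, b along y, c along the sectioning axis).
#' @param section_thickness slab thickness, µm (default 10).
#' @param positive_fraction planted stain-positive fraction per section.
#' @param pixel_size µm/pixel (default 0.25, fine enough that rasterization
#'   error stays well below the sectioning error).
#' @param seed integer seed.
#' @return list with `sections` (list of `list(tumor, positive)` [mask()]
#'   pairs) and `truth` (`SceneTruth` with `analytic_volume`,
#'   `section_depths`, `analytic_section_areas`, `positive_fraction`,
#'   `pixel_size`, `thickness`).
#' @export
gen_section_series <- function(shape = list(type = "sphere", r = 50),
                               section_thickness = 10,
                               positive_fraction = 0.1,
                               pixel_size = 0.25, seed = 1L) {
  check_number(section_thickness, "section_thickness", min = 0, strict_min = TRUE)
  check_number(positive_fraction, "positive_fraction", min = 0, max = 1)
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (identical(shape$type, "sphere")) {
    a <- shape$r; b <- shape$r; cc <- shape$r
  } else if (identical(shape$type, "ellipsoid")) {
    a <- shape$a; b <- shape$b; cc <- shape$c
  } else validation_error("shape$type must be 'sphere' or 'ellipsoid'")
  extent <- 2 * cc
  if (section_thickness >= extent)
    degenerate_section_error("thickness %g um >= shape extent %g um",
                             section_thickness, extent)
  n_sections <- ceiling(extent / section_thickness)
  depths <- (seq_len(n_sections) - 0.5) * section_thickness

  d <- c(ceiling(2 * b / pixel_size) + 8L, ceiling(2 * a / pixel_size) + 8L)
  cx <- (d[2] - 1) / 2 * pixel_size
  cy <- (d[1] - 1) / 2 * pixel_size
  xs <- (0:(d[2] - 1)) * pixel_size - cx
  ys <- (0:(d[1] - 1)) * pixel_size - cy

  sections <- vector("list", n_sections)
  areas <- numeric(n_sections)
  for (k in seq_len(n_sections)) {
    z <- depths[k]
    s2 <- 1 - ((z - cc) / cc)^2
    if (s2 <= 0) {
      tum <- matrix(FALSE, d[1], d[2])
      areas[k] <- 0
    } else {
      ra <- a * sqrt(s2); rb <- b * sqrt(s2)
      tum <- outer(ys^2 / rb^2, xs^2 / ra^2, `+`) <= 1
      areas[k] <- pi * ra * rb
    }
    npos <- round(positive_fraction * sum(tum))
    posm <- matrix(FALSE, d[1], d[2])
    if (npos > 0) {
      idx <- with_seed(derive_seed(seed, paste0("pos", k)),
                       sample(which(tum), npos))
      posm[idx] <- TRUE
    }
    sections[[k]] <- list(tumor = mask(tum), positive = mask(posm))
  }
  truth <- structure(list(
    analytic_volume = 4 / 3 * pi * a * b * cc,
    section_depths = depths, analytic_section_areas = areas,
    positive_fraction = positive_fraction, pixel_size = pixel_size,
    thickness = section_thickness, seed = seed), class = "SceneTruth")
  list(sections = sections, truth = truth)
}

#' Generate a pigmented brightfield field
#'
#' Bimodal image whose dark-pixel fraction equals `dark_fraction` to within
#' one pixel: exactly `round(dark_fraction * n_pixels)` pixels are drawn
#' from the dark mode, the rest from the bright mode.
#'
#' @param dark_fraction planted dark-pixel fraction in \[0,1\].
#' @param field image size in pixels, `c(height, width)`.
#' @param pixel_size µm/pixel.
#' @param dark_level,bright_level mode centers (default 0.2 / 0.8).
#' @param noise_sd within-mode Gaussian sd (default 0.03; modes stay
#'   separable).
#' @param seed integer seed.
#' @return list with `stack` (a `yx` [image_stack()]) and `truth`
#'   (`SceneTruth` with `dark_fraction` (realized), `n_dark`, `dark_mask`).
#' @export
gen_pigment_image <- function(dark_fraction, field = c(100, 100),
                              pixel_size = 1, dark_level = 0.2,
                              bright_level = 0.8, noise_sd = 0.03,
                              seed = 1L) {
  check_number(dark_fraction, "dark_fraction", min = 0, max = 1)
  check_number(seed, "seed", integer = TRUE)
  d <- as.integer(field)
  n <- prod(d)
  n_dark <- round(dark_fraction * n)
  img <- with_seed(derive_seed(seed, "pigment"), {
    dark_idx <- if (n_dark > 0) sample(n, n_dark) else integer(0)
    v <- stats::rnorm(n, bright_level, noise_sd)
    v[dark_idx] <- stats::rnorm(n_dark, dark_level, noise_sd)
    m <- matrix(pmin(pmax(v, 0), 1), d[1], d[2])
    attr(m, "dark_idx") <- dark_idx
    m
  })
  dark_mask <- matrix(FALSE, d[1], d[2])
  dark_mask[attr(img, "dark_idx")] <- TRUE
  attr(img, "dark_idx") <- NULL
  stack <- image_stack(img, "yx", pixel_size_xy = pixel_size)
  truth <- structure(list(dark_fraction = n_dark / n, n_dark = n_dark,
                          dark_mask = mask(dark_mask), seed = seed),
                     class = "SceneTruth")
  list(stack = stack, truth = truth)
}
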