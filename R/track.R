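# Directionally gated particle tracking: per-frame detections are linked
# into trajectories with a hard admissibility gate (physical distance and
# deviation from a preferred flow direction), a globally minimum-cost
# one-to-one assignment per frame pair, and per-step instantaneous
# velocities.

#' Tracking parameters
#'
#' @param max_link_distance maximum physical step between linked detections,
#'   µm (> 0).
#' @param preferred_direction preferred flow direction in degrees; 0 = +x
#'   ("left to right").
#' @param max_deviation maximum permitted angular deviation from the
#'   preferred direction, degrees (0 < dev <= 180; default 70). The gate is
#'   inclusive at the boundary.
#' @param allow_gap_frames number of frames a track may skip and still be
#'   linked (default 0 = no gap closing).
#' @param min_track_length minimum number of points for a track to be kept
#'   (default 2).
#' @param angular_penalty optional soft penalty weight (µm per degree of
#'   deviation) added to the link cost; 0 (default) keeps the pure hard
#'   gate.
#' @param method `"global"` (minimum-total-distance assignment) or
#'   `"greedy"` (nearest-first; for cross-checks).
#' @return a `TrackingParams` list.
#' @export
tracking_params <- function(max_link_distance, preferred_direction = 0,
                            max_deviation = 70, allow_gap_frames = 0L,
                            min_track_length = 2L, angular_penalty = 0,
                            method = c("global", "greedy")) {
  check_number(max_link_distance, "max_link_distance", min = 0, strict_min = TRUE)
  check_number(preferred_direction, "preferred_direction")
  check_number(max_deviation, "max_deviation", min = 0, max = 180, strict_min = TRUE)
  check_number(allow_gap_frames, "allow_gap_frames", min = 0, integer = TRUE)
  check_number(min_track_length, "min_track_length", min = 1, integer = TRUE)
  check_number(angular_penalty, "angular_penalty", min = 0)
  structure(list(max_link_distance = max_link_distance,
                 preferred_direction = preferred_direction,
                 max_deviation = max_deviation,
                 allow_gap_frames = as.integer(allow_gap_frames),
                 min_track_length = as.integer(min_track_length),
                 angular_penalty = angular_penalty,
                 method = match.arg(method)),
            class = "TrackingParams")
}

# absolute circular difference between two angles in degrees, in [0, 180]
angle_deviation <- function(theta, preferred) {
  d <- (theta - preferred) %% 360
  pmin(d, 360 - d)
}

#' Link per-frame detections into tracks
#'
#' For each frame pair, admissible candidate links are detection pairs whose
#' physical distance is at most `max_link_distance` and whose displacement
#' angle deviates from the preferred direction by at most `max_deviation`
#' (inclusive; zero-length displacements carry no direction and pass).
#' Among admissible links a minimum-total-distance one-to-one assignment is
#' chosen; unmatched detections start new tracks; tracks shorter than
#' `min_track_length` are discarded.
#'
#' @param detections list (one element per frame) of data.frames or matrices
#'   with columns `x`, `y` — centroids in 0-based pixel coordinates.
#' @param params a [tracking_params()].
#' @param pixel_size µm/pixel.
#' @param frame_interval seconds/frame.
#' @return a `TrackSet`: list with `tracks` (data.frame `track_id`, `frame`,
#'   `x`, `y`), `velocities` (data.frame `track_id`, `frame_from`,
#'   `frame_to`, `v`), and `summary` (data.frame `track_id`, `n_points`,
#'   `mean_speed`).
#' @export
link <- function(detections, params, pixel_size = NULL, frame_interval = NULL) {
  if (!inherits(params, "TrackingParams"))
    validation_error("params must come from tracking_params()")
  if (is.null(pixel_size) || is.null(frame_interval))
    calibration_error("link() needs pixel_size and frame_interval")
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  if (!is.list(detections) || length(detections) < 2L)
    validation_error("need detections for at least 2 frames")
  dets <- lapply(detections, function(d) {
    d <- as.data.frame(d)
    if (!all(c("x", "y") %in% names(d))) validation_error("detections need x and y")
    d[c("x", "y")]
  })

  BIG <- 1e9
  next_id <- 0L
  active <- list()    # each: list(id, frame, x, y) of last point
  points <- list()    # accumulated rows

  add_point <- function(id, frame, x, y) {
    points[[length(points) + 1L]] <<- data.frame(track_id = id, frame = frame,
                                                 x = x, y = y)
  }

  for (f in seq_along(dets)) {
    det <- dets[[f]]
    nd <- nrow(det)
    matched_det <- rep(FALSE, max(nd, 0L))
    if (length(active) > 0L && nd > 0L) {
      last_f <- vapply(active, `[[`, numeric(1), "frame")
      eligible <- which(f - last_f <= params$allow_gap_frames + 1L)
      if (length(eligible) > 0L) {
        na <- length(eligible)
        cost <- matrix(BIG, na, nd)
        for (ai in seq_len(na)) {
          tr <- active[[eligible[ai]]]
          dx <- det$x - tr$x
          dy <- det$y - tr$y
          dist_um <- sqrt(dx^2 + dy^2) * pixel_size
          theta <- atan2(dy, dx) * 180 / pi
          dev <- angle_deviation(theta, params$preferred_direction)
          ok <- dist_um <= params$max_link_distance &
                (dist_um == 0 | dev <= params$max_deviation + 1e-9)
          cst <- dist_um + params$angular_penalty * ifelse(dist_um == 0, 0, dev)
          cost[ai, ok] <- cst[ok]
        }
        assign <- if (params$method == "global") solve_assignment(cost, BIG)
                  else greedy_assignment(cost, BIG)
        for (ai in seq_len(na)) {
          j <- assign[ai]
          if (j > 0L) {
            tr <- active[[eligible[ai]]]
            tr$frame <- f; tr$x <- det$x[j]; tr$y <- det$y[j]
            active[[eligible[ai]]] <- tr
            add_point(tr$id, f, det$x[j], det$y[j])
            matched_det[j] <- TRUE
          }
        }
      }
    }
    # retire tracks whose gap budget is exhausted
    if (length(active) > 0L) {
      last_f <- vapply(active, `[[`, numeric(1), "frame")
      active <- active[f - last_f <= params$allow_gap_frames]
    }
    # unmatched detections start new tracks
    if (nd > 0L) for (j in which(!matched_det)) {
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- list(id = next_id, frame = f,
                                            x = det$x[j], y = det$y[j])
      add_point(next_id, f, det$x[j], det$y[j])
    }
  }

  tracks <- if (length(points)) do.call(rbind, points) else
    data.frame(track_id = integer(0), frame = integer(0), x = numeric(0), y = numeric(0))
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  len <- table(factor(tracks$track_id, levels = unique(tracks$track_id)))
  keep_ids <- as.integer(names(len))[len >= params$min_track_length]
  tracks <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]

  vel <- compute_velocities(tracks, pixel_size, frame_interval)
  smry <- if (nrow(vel)) {
    agg <- stats::aggregate(v ~ track_id, vel, mean)
    np <- stats::aggregate(frame ~ track_id, tracks, length)
    data.frame(track_id = agg$track_id,
               n_points = np$frame[match(agg$track_id, np$track_id)],
               mean_speed = agg$v)
  } else data.frame(track_id = integer(0), n_points = integer(0), mean_speed = numeric(0))
  structure(list(tracks = tracks, velocities = vel, summary = smry,
                 params = params, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "TrackSet")
}

compute_velocities <- function(tracks, pixel_size, frame_interval) {
  if (nrow(tracks) == 0L)
    return(data.frame(track_id = integer(0), frame_from = integer(0),
                      frame_to = integer(0), v = numeric(0)))
  out <- lapply(split(tracks, tracks$track_id), function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    i <- seq_len(nrow(tr) - 1L)
    data.frame(track_id = tr$track_id[i], frame_from = tr$frame[i],
               frame_to = tr$frame[i + 1L],
               v = sqrt(diff(tr$x)^2 + diff(tr$y)^2) * pixel_size /
                   (diff(tr$frame) * frame_interval))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(track_id = integer(0), frame_from = integer(0),
                                      frame_to = integer(0), v = numeric(0))
  rownames(out) <- NULL
  out
}

#' Instantaneous velocities of one track
#'
#' v_i = ||p_(i+1) − p_i|| × pixel_size / (Δframes × frame_interval).
#'
#' @param track data.frame with columns `frame`, `x`, `y` (pixel coords).
#' @param pixel_size µm/pixel.
#' @param frame_interval seconds/frame.
#' @return numeric vector of µm/s, one per consecutive point pair.
#' @export
instantaneous_velocity <- function(track, pixel_size, frame_interval) {
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2L) return(numeric(0))
  sqrt(diff(track$x)^2 + diff(track$y)^2) * pixel_size /
    (diff(track$frame) * frame_interval)
}

# Minimum-total-cost one-to-one assignment (Hungarian algorithm with
# potentials, O(n^2 m)). cost: na x nd matrix; entries >= BIG mark
# inadmissible pairs. Returns, per row, the assigned column or 0. With a
# uniform BIG much larger than any admissible total, minimizing total cost
# yields the maximum-cardinality, minimum-distance assignment.
solve_assignment <- function(cost, BIG = 1e9) {
  na <- nrow(cost); nd <- ncol(cost)
  if (na == 0L || nd == 0L) return(integer(na))
  transposed <- FALSE
  if (na > nd) { cost <- t(cost); transposed <- TRUE; tmp <- na; na <- nd; nd <- tmp }
  INF <- Inf
  u <- numeric(na + 1L); v <- numeric(nd + 1L)
  p <- integer(nd + 1L); way <- integer(nd + 1L)
  for (i in seq_len(na)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, nd + 1L)
    used <- rep(FALSE, nd + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF; j1 <- 0L
      for (j in seq_len(nd)) if (!used[j + 1L]) {
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0L:nd) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- integer(na)
  for (j in seq_len(nd)) if (p[j + 1L] > 0L) assign_row[p[j + 1L]] <- j
  # drop inadmissible pairings
  for (i in seq_len(na)) if (assign_row[i] > 0L && cost[i, assign_row[i]] >= BIG / 2)
    assign_row[i] <- 0L
  if (!transposed) return(assign_row)
  out <- integer(nd)   # nd = original number of rows
  for (i in seq_len(na)) if (assign_row[i] > 0L) out[assign_row[i]] <- i
  out
}

# nearest-admissible-first greedy assignment; cross-check variant
greedy_assignment <- function(cost, BIG = 1e9) {
  na <- nrow(cost); nd <- ncol(cost)
  assign_row <- integer(na)
  used_col <- rep(FALSE, nd)
  ord <- order(cost)
  for (k in ord) {
    if (cost[k] >= BIG / 2) break
    i <- (k - 1L) %% na + 1L
    j <- (k - 1L) %/% na + 1L
    if (assign_row[i] == 0L && !used_col[j]) {
      assign_row[i] <- j
      used_col[j] <- TRUE
    }
  }
  assign_row
}
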