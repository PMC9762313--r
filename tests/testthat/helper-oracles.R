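# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive re-derivation (breadth-first flood fill, exhaustive
# search, permutation enumeration) kept free of the package's code paths.

# --- flood-fill connected components ---------------------------------------
# BFS from each unvisited foreground voxel, visiting starts in the array's
# linear order so label numbering matches the raster convention.
oracle_flood_fill <- function(mask, connectivity) {
  d <- dim(mask)
  nd <- length(d)
  full <- connectivity == (if (nd == 2L) 8L else 26L)
  deltas <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  deltas <- deltas[rowSums(abs(deltas)) > 0, , drop = FALSE]
  if (!full) deltas <- deltas[rowSums(abs(deltas)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(as.logical(mask))) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    frontier <- start
    while (length(frontier) > 0L) {
      cd <- arrayInd(frontier, d)
      nbr <- integer(0)
      for (k in seq_len(nrow(deltas))) {
        cc <- cd + matrix(deltas[k, ], nrow(cd), nd, byrow = TRUE)
        ok <- rep(TRUE, nrow(cc))
        for (ax in seq_len(nd)) ok <- ok & cc[, ax] >= 1L & cc[, ax] <= d[ax]
        if (!any(ok)) next
        cc <- cc[ok, , drop = FALSE]
        lin <- cc[, 1]
        mult <- 1
        for (ax in seq_len(nd - 1L)) {
          mult <- mult * d[ax]
          lin <- lin + (cc[, ax + 1L] - 1L) * mult
        }
        nbr <- c(nbr, lin)
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & lab[nbr] == 0L]
      lab[nbr] <- nxt
      frontier <- nbr
    }
  }
  lab
}

# same-partition check that ignores label numbering
same_partition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  fg <- which(a > 0L)
  if (length(fg) == 0L) return(TRUE)
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# --- exhaustive Otsu -------------------------------------------------------
# 255-candidate search over the same 256-bin histogram, using bin-midpoint
# intensities and a plain loop.
oracle_otsu <- function(img) {
  rng <- range(img)
  nb <- 256L
  b <- pmin(floor((as.numeric(img) - rng[1]) / (rng[2] - rng[1]) * nb), nb - 1L)
  h <- tabulate(b + 1L, nbins = nb)
  mids <- rng[1] + (seq_len(nb) - 0.5) * (rng[2] - rng[1]) / nb
  n <- sum(h)
  best <- -1
  best_b <- NA_integer_
  for (split in 0:(nb - 2L)) {
    i0 <- 1:(split + 1L)
    w0 <- sum(h[i0]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[i0] * mids[i0]) / sum(h[i0])
    mu1 <- sum(h[-i0] * mids[-i0]) / sum(h[-i0])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best * (1 + 1e-12)) {
      best <- sb
      best_b <- split
    }
  }
  rng[1] + (best_b + 1) * (rng[2] - rng[1]) / nb
}

# assorted random histogram shapes for threshold tests
random_test_image <- function(seed) {
  set.seed(seed)
  kind <- seed %% 4
  n <- 400
  v <- switch(as.character(kind),
    "0" = c(rnorm(n, 20, 4), rnorm(n, 180, 12)),
    "1" = runif(2 * n, 0, 255),
    "2" = c(rexp(n, 1 / 30), 255 - rexp(n, 1 / 20)),
    "3" = c(rnorm(round(0.95 * n), 30, 6), rnorm(round(0.05 * n), 220, 6)))
  matrix(v[seq_len(400)], 20, 20)
}

# --- exhaustive assignment -------------------------------------------------
# Enumerates all one-to-one pairings (including leaving detections
# unmatched) and returns the best objective: maximum number of admissible
# links, minimum total cost among those.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      block <- sub
      block <- cbind(block[, seq_len(pos - 1L), drop = FALSE], n,
                     block[, pos:(n - 1L), drop = FALSE])
    }
    out <- rbind(out, block)
  }
  out
}

oracle_best_matching <- function(cost, admissible) {
  na <- nrow(cost); nd <- ncol(cost)
  n <- max(na, nd)
  perms <- all_permutations(n)
  best_links <- -1L
  best_cost <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    links <- 0L
    tot <- 0
    for (i in seq_len(na)) {
      j <- p[i]
      if (j <= nd && admissible[i, j]) {
        links <- links + 1L
        tot <- tot + cost[i, j]
      }
    }
    if (links > best_links || (links == best_links && tot < best_cost - 1e-12)) {
      best_links <- links
      best_cost <- tot
    }
  }
  list(n_links = best_links, total_cost = best_cost)
}

# admissibility + cost for one frame pair, mirroring the gate definition
gate_costs <- function(from, to, max_dist_um, preferred, max_dev, pixel_size) {
  na <- nrow(from); nd <- nrow(to)
  cost <- matrix(0, na, nd)
  adm <- matrix(FALSE, na, nd)
  for (i in seq_len(na)) {
    dx <- to$x - from$x[i]
    dy <- to$y - from$y[i]
    dist_um <- sqrt(dx^2 + dy^2) * pixel_size
    theta <- atan2(dy, dx) * 180 / pi
    dev <- abs(((theta - preferred + 180) %% 360) - 180)
    cost[i, ] <- dist_um
    adm[i, ] <- dist_um <= max_dist_um & (dist_um == 0 | dev <= max_dev + 1e-9)
  }
  list(cost = cost, admissible = adm)
}

# total cost and link count actually accepted by link() for a 2-frame scene
linkset_cost <- function(ts, from, to, pixel_size) {
  v <- ts$velocities
  tr <- ts$tracks
  links <- 0L
  tot <- 0
  for (id in unique(tr$track_id)) {
    pts <- tr[tr$track_id == id, ]
    if (nrow(pts) == 2L) {
      links <- links + 1L
      tot <- tot + sqrt(diff(pts$x)^2 + diff(pts$y)^2) * pixel_size
    }
  }
  list(n_links = links, total_cost = tot)
}
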