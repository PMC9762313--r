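test_that("connectivity semantics distinguish diagonal adjacency", {
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(label_components(m, 4)$n_labels, 2)
  expect_equal(label_components(m, 8)$n_labels, 1)
  expect_equal(label_components(matrix(FALSE, 4, 4))$n_labels, 0)
})

test_that("labels are numbered by first-encountered voxel in raster order", {
  m <- matrix(FALSE, 5, 5)
  m[4, 1] <- TRUE     # linear index 4: first in column-major order
  m[1, 3] <- TRUE     # linear index 11
  lab <- label_components(m, 8)$data
  expect_equal(lab[4, 1], 1L)
  expect_equal(lab[1, 3], 2L)
})

test_that("labeling matches the flood-fill oracle on random 2D and 3D masks", {
  withr::local_seed(41)
  for (i in 1:12) {
    m2 <- matrix(runif(20 * 20) < 0.45, 20, 20)
    for (conn in c(4L, 8L)) {
      lm <- label_components(m2, conn)
      expect_identical(lm$data, oracle_flood_fill(m2, conn),
                       info = sprintf("2D case %d conn %d", i, conn))
    }
    m3 <- array(runif(10 * 9 * 8) < 0.35, c(10, 9, 8))
    for (conn in c(6L, 26L)) {
      lm <- label_components(m3, conn)
      expect_identical(lm$data, oracle_flood_fill(m3, conn),
                       info = sprintf("3D case %d conn %d", i, conn))
    }
  }
})

test_that("hole filling closes enclosed cavities and leaves open shapes alone", {
  ring <- matrix(FALSE, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    d <- sqrt((i - 5)^2 + (j - 5)^2)
    if (d >= 2.5 && d <= 3.7) ring[i, j] <- TRUE
  }
  filled <- fill_holes(ring)$data
  expect_true(all(filled[(row(ring) - 5)^2 + (col(ring) - 5)^2 <= 6]))

  cshape <- matrix(FALSE, 7, 7)
  cshape[2:6, 2] <- TRUE; cshape[2, 2:6] <- TRUE; cshape[6, 2:6] <- TRUE
  expect_identical(fill_holes(cshape)$data, cshape)

  shell <- array(FALSE, c(9, 9, 9))
  shell[2:8, 2:8, 2:8] <- TRUE
  shell[3:7, 3:7, 3:7] <- FALSE
  expect_equal(sum(fill_holes(shell)$data), 7^3)

  # border flood-fill oracle: filled = NOT(background reachable from border)
  withr::local_seed(42)
  for (i in 1:5) {
    m <- matrix(runif(15 * 15) < 0.4, 15, 15)
    bg <- oracle_flood_fill(!m, 4)
    border_labels <- unique(c(bg[1, ], bg[15, ], bg[, 1], bg[, 15]))
    reach <- array(bg %in% setdiff(border_labels, 0L), dim(m))
    expect_identical(fill_holes(m, 8)$data, m | (!m & !reach))
  }
})

test_that("watershed splits touching disks and conserves the foreground", {
  mk_disks <- function(centers, r, d = c(40, 60)) {
    m <- matrix(FALSE, d[1], d[2])
    for (cc in centers) {
      g <- expand.grid(y = 1:d[1], x = 1:d[2])
      m[(g$y - cc[1])^2 + (g$x - cc[2])^2 <= r^2] <- TRUE
    }
    m
  }
  single <- mk_disks(list(c(20, 30)), 8)
  expect_equal(watershed_split(single)$n_labels, 1)

  two <- mk_disks(list(c(20, 20), c(20, 35)), 10)   # overlap < one radius
  ws <- watershed_split(two)
  expect_equal(ws$n_labels, 2)
  expect_identical(ws$data > 0L, two)               # conservation
  # split approximately along the equidistant line x = 27.5 (+- 1 px)
  lab_left <- ws$data[20, 22]; lab_right <- ws$data[20, 33]
  expect_false(lab_left == lab_right)
  expect_true(all(abs(which(
    vapply(1:60, function(x) any(ws$data[, x] == lab_left) &&
             any(ws$data[, x] == lab_right), logical(1))) - 27.5) <= 1.6))

  withr::local_seed(43)
  for (i in 1:5) {
    m <- mk_disks(list(c(sample(12:28, 1), sample(12:48, 1)),
                       c(sample(12:28, 1), sample(12:48, 1))), 7)
    ws <- watershed_split(m)
    expect_identical(ws$data > 0L, m)     # partition covers exactly the mask
  }
})

test_that("object filtering honors size and centroid-in-ROI rules", {
  m <- matrix(FALSE, 10, 12)
  m[2:3, 2:3] <- TRUE                      # 4 voxels
  m[6:9, 6:9] <- TRUE                      # 16 voxels
  lm <- label_components(m, 8)
  expect_equal(filter_objects(lm, 1)$n_labels, 2)
  expect_equal(filter_objects(lm, 5)$n_labels, 1)
  expect_equal(filter_objects(lm, 17)$n_labels, 0)

  roi <- matrix(FALSE, 10, 12); roi[1:4, 1:4] <- TRUE
  kept <- filter_objects(lm, 1, roi = mask(roi))
  expect_equal(kept$n_labels, 1)
  rec <- object_records(kept)
  expect_lt(rec$x, 4)                      # the small top-left object survived
})
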