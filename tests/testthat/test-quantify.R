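test_that("containment classifies by the cell label at the PC centroid", {
  cells <- matrix(0L, 20, 20)
  cells[5:12, 5:12] <- 1L
  lm <- label_map(cells)

  on_bg <- data.frame(label = 1L, x = 16, y = 16, voxel_count = 1,
                      xmin = 16, xmax = 16, ymin = 16, ymax = 16, channel = "pcs")
  res <- containment(lm, on_bg)
  expect_equal(res$pct_cells_with_pc, 0)
  expect_false(res$per_pc$inside)

  ten_in <- data.frame(label = 1:10, x = rep(7, 10), y = 4 + (1:10 %% 8),
                       voxel_count = 1, xmin = 7, xmax = 7,
                       ymin = 5, ymax = 12, channel = "pcs")
  res2 <- containment(lm, ten_in)
  expect_equal(res2$pct_pcs_inside, 100)
  expect_equal(res2$per_cell$n_pcs[1], 10)
  expect_equal(res2$pct_cells_with_pc, 100)

  expect_error(containment(lm, data.frame(label = 1, x = 50, y = 2)),
               class = "pcquant_frame_mismatch_error")
})

test_that("containment conserves counts on random scenes", {
  withr::local_seed(51)
  for (i in 1:6) {
    sc <- gen_uptake_scene(scene_params(n_cells = 10, n_pcs = 12,
                                        field_size = c(70, 70), seed = i))
    dp <- uptake_detection_params()
    cd <- detect(sc$stack, "cells", dp$cells)
    pd <- detect(sc$stack, "pcs", dp$pcs)
    res <- containment(cd$labels, pd)
    expect_equal(res$n_inside + res$n_outside, res$n_pcs)
    expect_equal(sum(res$per_cell$n_pcs), res$n_inside)
    expect_equal(res$pct_pcs_inside, 100 * res$n_inside / res$n_pcs)
    expect_true(res$pct_cells_with_pc >= 0 && res$pct_cells_with_pc <= 100)
  }
})

test_that("overlap fraction counts object voxels inside the marker", {
  lab <- matrix(0L, 12, 12)
  lab[3:8, 3:8] <- 1L
  lm <- label_map(lab)
  full <- mask(matrix(TRUE, 12, 12))
  expect_equal(overlap_fraction(1, lm, full), 1)
  expect_equal(overlap_fraction(1, lm, mask(matrix(FALSE, 12, 12))), 0)
  half <- matrix(FALSE, 12, 12); half[, 1:5] <- TRUE   # covers 3 of 6 columns
  expect_equal(overlap_fraction(1, lm, mask(half)), 0.5)

  # monotone non-decreasing as the marker grows
  withr::local_seed(52)
  grown <- matrix(runif(144) < 0.3, 12, 12)
  f1 <- overlap_fraction(1, lm, mask(grown))
  f2 <- overlap_fraction(1, lm, mask(grown | half))
  expect_gte(f2, f1)
})

test_that("marker-positive classification recovers planted intact/degraded PCs", {
  lab <- matrix(0L, 20, 30)
  lab[3:6, 3:6] <- 1L       # intact: fully covered
  lab[3:6, 13:16] <- 2L     # degraded: uncovered
  lab[13:16, 3:6] <- 3L     # partial: half covered
  lm <- label_map(lab)
  marker <- matrix(FALSE, 20, 30)
  marker[3:6, 3:6] <- TRUE
  marker[13:16, 3:4] <- TRUE
  res_full <- classify_marker_positive(lm, mask(marker), tau = 1)
  expect_identical(res_full$per_object$positive, c(TRUE, FALSE, FALSE))
  res_half <- classify_marker_positive(lm, mask(marker), tau = 0.5)
  expect_identical(res_half$per_object$positive, c(TRUE, FALSE, TRUE))
  res_zero <- classify_marker_positive(lm, mask(marker), tau = 0)
  expect_true(all(res_zero$per_object$positive))
  expect_equal(res_full$pct_positive, 100 / 3)
})

test_that("pigmentation fraction recovers planted dark fractions", {
  g <- gen_pigment_image(0.3, field = c(100, 100), seed = 13)
  expect_lte(abs(pigmentation_fraction(g$stack) - 30), 0.1)

  # manual region covering half of a constructed two-level image
  img <- cbind(matrix(0.1, 10, 5), matrix(0.9, 10, 5))
  region <- matrix(FALSE, 10, 10); region[, 3:8] <- TRUE
  got <- pigmentation_fraction(img, mask(region), method = "fixed", t = 0.5)
  expect_equal(got, 100 * (3 * 10) / (6 * 10))   # 3 dark columns of 6 in region
})

test_that("fluorescent pixel count obeys threshold and region", {
  img <- matrix(seq(0, 1, length.out = 100), 10)
  expect_equal(fluorescent_pixel_count(img, 1), 0)
  expect_equal(fluorescent_pixel_count(img, -0.1), 100)
  region <- matrix(FALSE, 10, 10); region[1:5, ] <- TRUE
  expect_equal(fluorescent_pixel_count(img, -1, mask(region)), 50)
})

test_that("area fractions follow set arithmetic and recover planted sections", {
  r <- matrix(TRUE, 20, 20)
  a <- matrix(FALSE, 20, 20); a[1:10, ] <- TRUE
  b <- matrix(FALSE, 20, 20); b[, 1:10] <- TRUE
  expect_equal(double_positive_area_fraction(r, r, r), 100)
  expect_equal(double_positive_area_fraction(a, !a, r), 0)
  expect_equal(double_positive_area_fraction(a, b, r), 25)
  expect_equal(positive_area_fraction(matrix(FALSE, 20, 20), r), 0)
  expect_equal(positive_area_fraction(r, r), 100)

  g <- gen_section_series(list(type = "sphere", r = 40), 10, 0.12, seed = 5)
  mid <- g$sections[[4]]
  expect_lte(abs(positive_area_fraction(mid$positive, mid$tumor) - 12), 0.2)

  # independent placement: double-positive fraction ~ fA * fB
  withr::local_seed(53)
  fa <- 0.4; fb <- 0.3; n <- 200 * 200
  A <- matrix(runif(n) < fa, 200); B <- matrix(runif(n) < fb, 200)
  got <- double_positive_area_fraction(A, B, matrix(TRUE, 200, 200))
  expect_lte(abs(got - 100 * fa * fb), 100 * 3 * sqrt(fa * fb / n))
})

test_that("tumor area scales with the pixel size and matches the disk form", {
  sq <- matrix(FALSE, 20, 20); sq[1:10, 1:10] <- TRUE
  expect_equal(tumor_area(mask(sq), 1), 100)
  expect_equal(tumor_area(mask(sq), 2), 400)

  r_um <- 50; px <- 0.5
  n <- ceiling(2 * r_um / px) + 4
  g <- expand.grid(y = 1:n, x = 1:n)
  disk <- matrix((g$y - n / 2)^2 + (g$x - n / 2)^2 <= (r_um / px)^2, n, n)
  expect_lt(abs(tumor_area(mask(disk), px) - pi * r_um^2) / (pi * r_um^2), 0.02)
})

test_that("relative growth is anchored at 100 and rejects a zero baseline", {
  expect_equal(relative_growth(c(100, 150)), c(100, 150))
  expect_equal(relative_growth(rep(7, 5)), rep(100, 5))
  expect_error(relative_growth(c(0, 10)),
               class = "pcquant_degenerate_baseline_error")
})

test_that("section volume is the area-thickness sum and converges", {
  expect_equal(section_volume(c(100, 100, 100), 10), 3000)
  expect_equal(section_volume(numeric(0)), 0)

  V <- 4 / 3 * pi * 50^3
  errs <- vapply(c(10, 5, 2.5), function(th) {
    g <- gen_section_series(list(type = "sphere", r = 50), th, 0, seed = 3)
    sq <- quantify_sections(g$sections, g$truth$pixel_size, th)
    abs(sq$total_volume - V) / V
  }, numeric(1))
  expect_lt(errs[1], 0.05)
  expect_true(all(diff(errs) < 0))        # error shrinks as thickness halves
  expect_gt(errs[1] / errs[3], 5)         # consistent with ~thickness^2 scaling
})
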