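small_scene <- function(seed, ...) {
  args <- utils::modifyList(list(n_cells = 10, n_pcs = 12,
                                 field_size = c(70, 70), seed = seed),
                            list(...))
  do.call(scene_params, args)
}

test_that("generators are bitwise deterministic under a fixed seed", {
  a <- gen_uptake_scene(small_scene(4))
  b <- gen_uptake_scene(small_scene(4))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$pcs, b$truth$pcs)

  m1 <- gen_flow_movie(n_frames = 10, seed = 9)
  m2 <- gen_flow_movie(n_frames = 10, seed = 9)
  expect_identical(m1$stack$data, m2$stack$data)

  p1 <- gen_pigment_image(0.25, seed = 2)
  p2 <- gen_pigment_image(0.25, seed = 2)
  expect_identical(p1$stack$data, p2$stack$data)

  s1 <- gen_section_series(seed = 3)
  s2 <- gen_section_series(seed = 3)
  expect_identical(lapply(s1$sections, function(s) s$positive$data),
                   lapply(s2$sections, function(s) s$positive$data))
})

test_that("substreams are hierarchical: more PCs never move the cells", {
  a <- gen_uptake_scene(small_scene(5, n_pcs = 6))
  b <- gen_uptake_scene(small_scene(5, n_pcs = 12))
  expect_identical(a$truth$cells[c("x", "y", "r")], b$truth$cells[c("x", "y", "r")])
})

test_that("planted containment counts are exact and self-consistent", {
  sc <- gen_uptake_scene(scene_params(n_cells = 50, frac_cells_with_pc = 0.4,
                                      seed = 12))
  expect_equal(sum(sc$truth$cells$loaded), 20)        # round(0.4 * 50)
  expect_equal(sc$truth$containment_fraction_cells, 0.4)
  expect_equal(nrow(sc$truth$pcs), 60)

  none <- gen_uptake_scene(scene_params(n_cells = 0, n_pcs = 5,
                                        frac_cells_with_pc = 0,
                                        field_size = c(50, 50), seed = 1))
  expect_false(any(none$truth$pcs$inside))

  for (seed in c(3, 8, 15)) {
    tr <- gen_uptake_scene(small_scene(seed))$truth
    expect_identical(rederive_containment(tr), tr$pcs$inside)
    # inside PCs respect the geometric margin; outside PCs the clearance
    pc_r <- tr$pc_diameter / 2
    for (i in which(tr$pcs$inside)) {
      own <- tr$cells[tr$pcs$owner[i], ]
      expect_lte(sqrt((own$x - tr$pcs$x[i])^2 + (own$y - tr$pcs$y[i])^2),
                 own$r - pc_r + 1e-9)
    }
    for (i in which(!tr$pcs$inside)) {
      d <- sqrt((tr$cells$x - tr$pcs$x[i])^2 + (tr$cells$y - tr$pcs$y[i])^2)
      expect_true(all(d >= tr$cells$r + pc_r))
    }
  }
})

test_that("infeasible packing raises a packing error", {
  expect_error(
    gen_uptake_scene(scene_params(n_cells = 60, field_size = c(40, 40), seed = 1)),
    class = "pcquant_packing_error")
})

test_that("noise vanishes at infinite snr", {
  a <- gen_uptake_scene(small_scene(6, snr = Inf, read_noise = 0.5))
  b <- gen_uptake_scene(small_scene(6, snr = Inf, read_noise = 0))
  expect_identical(a$stack$data, b$stack$data)     # noise params inert at Inf
  # and the noiseless render is smooth: no negative values, max near peak
  expect_true(all(a$stack$data >= 0))
  expect_lt(max(a$stack$data), 1.2)
})

test_that("flow movie truth has the planted displacements and speeds", {
  m <- gen_flow_movie(n_particles = 5, speed_mean = 10, speed_pulsatility = 0,
                      direction_deg = 0, n_frames = 20, frame_interval = 0.1,
                      pixel_size = 0.5, snr = Inf, seed = 3)
  st <- m$truth$steps
  expect_equal(unique(st$dx), 1.0)                  # 10 um/s * 0.1 s
  expect_equal(unique(st$dy), 0.0)
  expect_lt(abs(mean(st$speed) - 10), 1e-9)

  back <- gen_flow_movie(n_particles = 5, speed_mean = 8, direction_deg = 180,
                         n_frames = 10, seed = 4)
  expect_true(all(back$truth$steps$dx < 0))

  puls <- gen_flow_movie(speed_mean = 10, speed_pulsatility = 0.3,
                         n_frames = 50, seed = 5)
  expect_true(max(puls$truth$steps$speed) > 10)
  expect_true(min(puls$truth$steps$speed) < 10)
})

test_that("section series carries the analytic volume and planted fractions", {
  g <- gen_section_series(list(type = "sphere", r = 50), 10, 0.2, seed = 7)
  expect_length(g$sections, 10)
  expect_equal(g$truth$analytic_volume, 4 / 3 * pi * 50^3)
  for (s in g$sections) {
    n_t <- sum(s$tumor$data)
    expect_lte(abs(sum(s$positive$data) - 0.2 * n_t), 1)
    expect_true(all(s$tumor$data[s$positive$data]))   # positive is a sub-mask
  }

  none <- gen_section_series(positive_fraction = 0, seed = 1)
  expect_true(all(vapply(none$sections, function(s) sum(s$positive$data) == 0,
                         logical(1))))

  ell <- gen_section_series(list(type = "ellipsoid", a = 30, b = 20, c = 40),
                            10, 0.1, seed = 2)
  expect_length(ell$sections, 8)
  expect_equal(ell$truth$analytic_volume, 4 / 3 * pi * 30 * 20 * 40)

  expect_error(gen_section_series(list(type = "sphere", r = 4), 10),
               class = "pcquant_degenerate_section_error")
})

test_that("pigment images plant the dark fraction to within one pixel", {
  g <- gen_pigment_image(0.3, field = c(100, 100), seed = 9)
  expect_equal(g$truth$n_dark, 3000)
  expect_equal(sum(g$truth$dark_mask$data), 3000)

  bright <- gen_pigment_image(0, seed = 1)
  expect_true(all(bright$stack$data > 0.5))
  dark <- gen_pigment_image(1, seed = 1)
  expect_true(all(dark$stack$data < 0.5))
})
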