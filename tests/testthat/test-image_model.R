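test_that("image_stack canonicalizes axes and validates calibration", {
  a <- array(runif(2 * 4 * 5), c(4, 5, 2))        # y, x, c order
  s <- image_stack(a, "yxc", pixel_size_xy = 0.5, channel_names = c("g", "r"))
  expect_equal(s$axes, "cyx")
  expect_equal(dim(s$data), c(2, 4, 5))
  expect_equal(s$data[2, 3, 4], a[3, 4, 2])

  expect_error(image_stack(matrix(1, 2, 2), "yx", pixel_size_xy = 0),
               class = "pcquant_validation_error")
  expect_error(image_stack(array(1, c(2, 3, 3)), "zyx", pixel_size_xy = 1),
               class = "pcquant_calibration_error")
  expect_error(image_stack(a, "yxc", 1, channel_names = "only_one"),
               class = "pcquant_validation_error")
  expect_error(image_stack(matrix(1, 2, 2), "ab", 1),
               class = "pcquant_axis_ambiguity_error")
})

test_that("TIFF round-trips are exact for uint8, uint16 and the float grid", {
  withr::local_seed(11)
  dir <- withr::local_tempdir()

  s8 <- image_stack(matrix(sample(0:255, 48, TRUE), 6, 8), "yx", 1.0)
  f8 <- file.path(dir, "u8.tif")
  write_stack(s8, f8, "uint8")
  r8 <- read_stack(f8)
  expect_identical(r8$data, s8$data * 1.0)
  expect_identical(r8$pixel_size_xy, 1.0)

  s16 <- image_stack(array(sample(0:65535, 3 * 2 * 10 * 12, TRUE), c(3, 2, 10, 12)),
                     "zcyx", 0.5, pixel_size_z = 2, channel_names = c("a", "b"))
  f16 <- file.path(dir, "u16.tif")
  write_stack(s16, f16, "uint16")
  r16 <- read_stack(f16)
  expect_identical(r16$data, s16$data * 1.0)
  expect_identical(r16$axes, "zcyx")
  expect_identical(r16$pixel_size_z, 2.0)
  expect_identical(r16$channel_names, c("a", "b"))

  v <- storage_quantize(matrix(c(0, 1, 0.5, runif(61)), 8))
  sfl <- image_stack(v, "yx", 1.25)
  ffl <- file.path(dir, "f32.tif")
  write_stack(sfl, ffl, "float")
  expect_identical(read_stack(ffl)$data, v)
})

test_that("reading without calibration or axis declaration errors", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bare.tif")
  tiff::writeTIFF(matrix(runif(25), 5), f)        # no metadata, no sidecar
  expect_error(read_stack(f), class = "pcquant_calibration_error")
  expect_s3_class(read_stack(f, pixel_size_xy = 0.4), "ImageStack")
  expect_error(read_stack(f, pixel_size_xy = -1),
               class = "pcquant_calibration_error")

  fm <- file.path(dir, "multi.tif")
  tiff::writeTIFF(list(matrix(runif(25), 5), matrix(runif(25), 5)), fm)
  expect_error(read_stack(fm, pixel_size_xy = 1),
               class = "pcquant_axis_ambiguity_error")
})

test_that("write_table round-trips records and rejects mixed schemas", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.csv")

  empty <- data.frame(label = integer(0), x = numeric(0))
  write_table(empty, f)
  expect_identical(readLines(f), "\"label\",\"x\"")

  df <- data.frame(label = 1:3, x = c(0.1, 1 / 3, 2.5e-17), who = c("a", "b", "c"))
  write_table(df, f)
  back <- read_table(f)
  expect_identical(back$x, df$x)          # full-precision doubles
  expect_identical(back$who, df$who)

  expect_error(write_table(list(list(a = 1), list(b = 2)), f),
               class = "pcquant_schema_error")
})

test_that("canonical relabeling preserves the foreground partition", {
  withr::local_seed(5)
  for (i in 1:20) {
    d <- sample(5:12, 2)
    lab <- matrix(sample(c(0L, 3L, 7L, 12L), prod(d), TRUE,
                         prob = c(0.5, 0.2, 0.2, 0.1)), d[1], d[2])
    lm <- relabel_canonical(lab)
    expect_true(same_partition(lab, lm$data))
    present <- sort(unique(lm$data[lm$data > 0]))
    expect_identical(present, seq_len(lm$n_labels))
    # first occurrences appear in increasing label order
    firsts <- vapply(seq_len(lm$n_labels), function(l) which(lm$data == l)[1], numeric(1))
    expect_true(all(diff(firsts) > 0))
  }
})

test_that("object records satisfy their geometric invariants", {
  withr::local_seed(6)
  for (i in 1:10) {
    m <- matrix(runif(30 * 30) < 0.3, 30, 30)
    rec <- object_records(label_components(m, 8))
    expect_true(all(rec$voxel_count >= 1))
    expect_true(all(rec$x >= rec$xmin - 1e-9 & rec$x <= rec$xmax + 1e-9))
    expect_true(all(rec$y >= rec$ymin - 1e-9 & rec$y <= rec$ymax + 1e-9))
    expect_equal(sum(rec$voxel_count), sum(m))
  }
})
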