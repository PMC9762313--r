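test_that("configuration is validated before any work happens", {
  expect_error(detection_params(k = -1), class = "pcquant_validation_error")
  expect_error(workflow_config(quantify = list(bogus_key = 1)),
               class = "pcquant_validation_error")
  expect_error(workflow_config(tracking = list(max_link_distance = 1)),
               class = "pcquant_validation_error")
  expect_error(workflow_config(quantify = list(tau_lysosome = 1.5)),
               class = "pcquant_validation_error")
  expect_error(run_workflow("uptake", config = list()),
               class = "pcquant_validation_error")
})

test_that("synth then uptake reproduces the planted summary end to end", {
  outdir <- withr::local_tempdir()
  cfg <- workflow_config(seed = 5, scene = scene_params(n_cells = 10, n_pcs = 12,
                                                        field_size = c(70, 70),
                                                        seed = 5))
  syn <- run_workflow("synth", cfg, outdir = file.path(outdir, "s"))
  up <- run_workflow("uptake", workflow_config(seed = 5),
                     inputs = list(stack = syn$stack),
                     outdir = file.path(outdir, "u"))
  expect_equal(up$summary$pct_cells_with_pc,
               100 * syn$summary$containment_fraction_cells)
  expect_equal(up$summary$pct_pcs_inside, syn$summary$pct_pcs_inside)
  expect_equal(up$summary$n_inside + up$summary$n_outside, up$summary$n_pcs)
})

test_that("reruns with identical config and seed are byte-identical", {
  base <- withr::local_tempdir()
  cfg <- workflow_config(seed = 7, scene = scene_params(n_cells = 8, n_pcs = 10,
                                                        field_size = c(60, 60),
                                                        seed = 7))
  a <- run_workflow("synth", cfg, outdir = file.path(base, "a"))
  b <- run_workflow("synth", cfg, outdir = file.path(base, "b"))
  for (f in c("scene.tif", "scene.tif.meta", "truth_cells.csv", "truth_pcs.csv")) {
    expect_identical(readBin(file.path(base, "a", f), "raw", 5e6),
                     readBin(file.path(base, "b", f), "raw", 5e6),
                     info = f)
  }
  ua <- run_workflow("uptake", workflow_config(seed = 7),
                     inputs = list(stack = a$stack), outdir = file.path(base, "ua"))
  ub <- run_workflow("uptake", workflow_config(seed = 7),
                     inputs = list(stack = a$stack), outdir = file.path(base, "ub"))
  for (f in c("uptake_per_cell.csv", "uptake_per_pc.csv", "uptake_summary.csv")) {
    expect_identical(readLines(file.path(base, "ua", f)),
                     readLines(file.path(base, "ub", f)), info = f)
  }
})

test_that("outputs carry a provenance header and a parameter log", {
  outdir <- withr::local_tempdir()
  cfg <- workflow_config(seed = 3)
  res <- run_workflow("growth", cfg, inputs = list(areas = c(100, 130, 180)),
                      outdir = outdir)
  lines <- readLines(res$growth)
  expect_match(lines[1], "^# pcquant ")
  expect_match(lines[2], "^# workflow growth")
  expect_match(lines[3], "^# seed 3")
  expect_match(lines[4], "^# config_hash [0-9a-f]+")
  expect_equal(read_table(res$growth)$relative_pct, c(100, 130, 180))
  log <- readLines(res$log)
  expect_true(any(grepl("quantify.section_thickness = 10", log)))

  # marker workflows route tau defaults from the config
  lab <- matrix(0L, 10, 10); lab[2:4, 2:4] <- 1L
  marker <- matrix(FALSE, 10, 10); marker[2:4, 2:4] <- TRUE
  ly <- run_workflow("lyso", cfg,
                     inputs = list(labels = label_map(lab), marker = mask(marker)),
                     outdir = outdir)
  expect_equal(ly$summary$pct_positive, 100)
  expect_equal(ly$summary$tau, 1)
})

test_that("pigment, sections and volume workflows report their summaries", {
  outdir <- withr::local_tempdir()
  g <- gen_pigment_image(0.3, seed = 4)
  pg <- run_workflow("pigment", workflow_config(seed = 4),
                     inputs = list(image = g$stack), outdir = outdir)
  expect_lte(abs(pg$summary$pigmented_pct - 30), 0.5)

  ss <- gen_section_series(list(type = "sphere", r = 30), 10, 0.1, seed = 2)
  sec <- run_workflow("sections", workflow_config(seed = 2),
                      inputs = list(sections = ss$sections,
                                    pixel_size = ss$truth$pixel_size),
                      outdir = outdir)
  expect_lt(abs(sec$summary$total_volume - ss$truth$analytic_volume) /
              ss$truth$analytic_volume, 0.05)

  per <- read_table(sec$per_section)
  vol <- run_workflow("volume", workflow_config(seed = 2),
                      inputs = list(areas = per$tumor_area), outdir = outdir)
  expect_equal(vol$summary$total_volume, sec$summary$total_volume)
})
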