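test_that("degradation is the identity without blur or noise", {
  img <- matrix(runif(400), 20, 20)
  expect_equal(degrade(img, 0, 0), img)
  expect_error(degrade(img, -1, 0), "psf_sigma")
})

test_that("the unit-sum kernel preserves a constant image and noise has the set variance", {
  flat <- matrix(0.5, 1000, 1000)
  expect_equal(degrade(flat, 2.5, 0), flat, tolerance = 1e-12)
  set.seed(20)
  noisy <- degrade(flat, 0, 0.00025)
  expect_equal(stats::var(as.numeric(noisy) - 0.5), 0.00025, tolerance = 0.1)
  expect_true(all(noisy >= 0 & noisy <= 1))
})

test_that("blur spreads mass but keeps the total (away from edges)", {
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  out <- degrade(img, 2, 0)
  expect_equal(sum(out), 1, tolerance = 1e-9)
  expect_lt(max(out), 1)
  expect_gt(out[21, 21], out[21, 30])
})

test_that("Beer-Lambert staining renders white background and the stain colours", {
  M <- default_stain_matrix("separation")
  zero <- matrix(0, 4, 4)
  rgb <- to_hne(zero, zero, M)
  expect_true(all(rgb == 1))
  one_n <- to_hne(matrix(1, 1, 1), matrix(0, 1, 1), M)
  expect_equal(as.numeric(one_n), exp(-c(0.6402, 0.6479, 0.4128)),
               tolerance = 1e-12)
  # monotone decreasing in each channel
  lo <- to_hne(matrix(0.3, 1, 1), matrix(0.2, 1, 1), M)
  hi <- to_hne(matrix(0.6, 1, 1), matrix(0.2, 1, 1), M)
  expect_true(all(hi < lo))
  expect_error(to_hne(zero, zero, matrix(c(1, NA), 2, 3)), "stain_matrix")
})

test_that("stain deconvolution inverts a noise-free render to 1e-6", {
  set.seed(21)
  I_n <- matrix(runif(900, 0, 1), 30, 30)
  I_c <- matrix(runif(900, 0, 1), 30, 30)
  for (nm in c("separation", "ruifrok")) {
    M <- default_stain_matrix(nm)
    rec <- stain_deconvolve(to_hne(I_n, I_c, M), M)
    expect_lt(max(abs(rec$nuclei - I_n)), 1e-6)
    expect_lt(max(abs(rec$cytoplasm - I_c)), 1e-6)
  }
})

test_that("the scalebar is drawn black at the converted pixel length", {
  cfg <- simulation_config(image_height = 300, image_width = 300,
                           magnification = 20, ccd_pixel_size = 11,
                           scalebar_length = 100)
  rgb <- array(1, dim = c(300, 300, 3))
  out <- add_scalebar(rgb, cfg)
  bar <- which(out[, , 1] == 0, arr.ind = TRUE)
  expect_equal(length(unique(bar[, "col"])), 182L)   # round(100 / 0.55)
  expect_equal(length(unique(bar[, "row"])), 4L)
  expect_true(all(out[out[, , 1] == 0] == 0))        # exactly (0,0,0)
  expect_equal(max(bar[, "col"]), 300L - 10L)
  cfg_nobar <- simulation_config(image_height = 300, image_width = 300)
  expect_identical(add_scalebar(rgb, cfg_nobar), rgb)
})

test_that("an empty scene renders blank white and a populated one does not", {
  cfg <- small_config(image_height = 64L, image_width = 64L,
                      cellularity_epithelial = 0, cellularity_stromal = 0,
                      render = "full", canvas_size = 16L, window_radius = 2L,
                      noise_variance = 0, psf_sigma = 0)
  sim <- simulate_image(cfg)
  # no crypts fit a 64 px field at 20x and cellularity is 0: empty channels
  expect_equal(length(sim$crypts), 0L)
  expect_true(all(sim$channels$nuclei == 0))
  expect_true(all(sim$rgb == 1))
})

test_that("full renders write and reproduce bit-identically", {
  cfg <- small_config(image_height = 200L, image_width = 200L, seed = 55,
                      render = "full", canvas_size = 32L, window_radius = 2L,
                      scalebar_length = 20)
  sim <- simulate_image(cfg)
  expect_true(all(sim$channels_ideal$nuclei >= 0 & sim$channels_ideal$nuclei <= 1))
  expect_true(all(sim$channels_ideal$cytoplasm >= 0 & sim$channels_ideal$cytoplasm <= 1))
  # nuclei channel support matches the union of nucleus masks
  sup <- which(sim$channels_ideal$nuclei > 0)
  expect_setequal(sup, unique(unlist(sim$nucleus_masks)))
  # later-drawn-wins labels: every labelled pixel belongs to that cell's mask
  ids <- setdiff(unique(as.vector(sim$labels$nuclei)), 0L)
  for (id in sample(ids, min(5, length(ids)))) {
    expect_true(all(which(sim$labels$nuclei == id) %in%
                      sim$nucleus_masks[[which(sim$cells$cell_id == id)]]))
  }

  out <- withr::local_tempdir()
  paths <- write_outputs(sim, out)
  expect_true(file.exists(file.path(out, "rgb.png")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  cells_back <- utils::read.csv(file.path(out, "cells.csv"))
  expect_equal(nrow(cells_back), nrow(sim$cells))
  lab_back <- read_label_tiff(file.path(out, "labels_nuclei.tif"))
  expect_true(all(lab_back == sim$labels$nuclei))
  expect_true(max(sim$labels$nuclei) < 65536)

  # bit-identical reproduction from the same config + seed
  sim2 <- simulate_image(cfg)
  expect_identical(sim2$rgb, sim$rgb)
  expect_identical(sim2$cells, sim$cells)
  out2 <- withr::local_tempdir()
  write_outputs(sim2, out2)
  expect_identical(readBin(file.path(out, "rgb.png"), "raw", 1e6),
                   readBin(file.path(out2, "rgb.png"), "raw", 1e6))
})
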