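test_that("stromal cell area interpolates between sparse and packed", {
  r <- 20
  expect_equal(stromal_cell_area(1, r), pi * r^2)
  expect_equal(stromal_cell_area(0, r), pi * (1.7 * r)^2)
  Ls <- seq(0, 1, by = 0.1)
  As <- vapply(Ls, stromal_cell_area, 1, r_px = r)
  expect_true(all(diff(As) < 0))
  expect_error(stromal_cell_area(1.5, r), "max_overlap")
})

test_that("cell counts follow the perimeter and stroma formulas", {
  # spp = 0.3 um/px so r = 6 um = 20 px
  cfg <- simulation_config(magnification = 20, ccd_pixel_size = 6,
                           cellularity_epithelial = 1, max_overlap = 0.25)
  expect_equal(microns_to_pixels(cfg$cell_radius, cfg), 20)
  cc <- cell_counts(cfg, stromal_area_px = 0, perimeter_px = 2000)
  expect_equal(cc$N_e, 50L)   # 2000 / (2 * (1.25 - 0.25) * 20)
  expect_equal(cc$N_s, 0L)
  cfg0 <- simulation_config(cellularity_epithelial = 0, cellularity_stromal = 0)
  cc0 <- cell_counts(cfg0, stromal_area_px = 5e5, perimeter_px = 3000)
  expect_equal(cc0$N, 0L)
})

test_that("overlap ratio is the asymmetric intersection fraction", {
  expect_equal(overlap_ratio(1:4, 1:4), 1)
  expect_equal(overlap_ratio(1:4, 9:12), 0)
  expect_equal(overlap_ratio(1:4, 3:10), 0.5)   # brute force: {3,4} of 4
  expect_equal(overlap_ratio(3:10, 1:4), 0.25)  # asymmetry
  expect_error(overlap_ratio(integer(0), 1:3), "region_i")
})

test_that("rejection placement enforces the overlap budget in both directions", {
  set.seed(2)
  # candidates are random 3x3 squares on a 12x12 grid
  mask_at <- function(pos) {
    xs <- pos[1] + 0:2; ys <- pos[2] + 0:2
    as.integer(outer((xs - 1) * 12, ys, "+"))
  }
  existing <- list(mask_at(c(1, 1)), mask_at(c(6, 6)))
  cand_fn <- function(t) c(sample.int(9, 1), sample.int(9, 1))
  nb_fn <- function(cand) existing
  res0 <- place_with_overlap_control(cand_fn, mask_at, nb_fn,
                                     local_L_max = 0, max_attempts = 500)
  expect_false(is.null(res0))
  for (ex in existing) expect_equal(length(intersect(res0$mask, ex)), 0L)
  # L_max = 1 imposes nothing: first candidate accepted
  res1 <- place_with_overlap_control(cand_fn, mask_at, nb_fn,
                                     local_L_max = 1, max_attempts = 10)
  expect_equal(res1$attempts, 1L)
  # pigeonhole: an over-packed field forces a skip at L_max = 0
  full <- lapply(as.list(seq(1, 9, by = 2)), function(x)
    unlist(lapply(seq(1, 9, by = 2), function(y) mask_at(c(x, y)))))
  res_skip <- place_with_overlap_control(cand_fn, mask_at,
                                         function(cand) full,
                                         local_L_max = 0, max_attempts = 30)
  expect_null(res_skip)
})

test_that("subtype assignment follows the grade-dependent tumour probability", {
  pr <- default_phenotype_profiles()
  set.seed(3)
  s0 <- replicate(5000, assign_subtype_and_phenotype("stromal", 0, pr)$subtype)
  expect_false(any(s0 == "tumour"))
  expect_equal(mean(s0 == "fibroblast"), 0.5, tolerance = 0.05)
  draws3 <- replicate(6000, {
    a <- assign_subtype_and_phenotype("stromal", 3, pr)
    c(tumour = a$subtype == "tumour", clustered = a$in_cluster)
  })
  expect_equal(mean(draws3["tumour", ]), 0.6, tolerance = 0.04)
  clustered_given_tumour <- mean(draws3["clustered", draws3["tumour", ] == 1])
  expect_equal(clustered_given_tumour, 0.5, tolerance = 0.04)
  # a point-mass phenotype table always yields that phenotype
  pr2 <- pr
  pr2$freq[, 1, 1] <- 0; pr2$freq[5, 1, 1] <- 1
  set.seed(4)
  ph <- replicate(50, assign_subtype_and_phenotype("epithelial", 0, pr2)$phenotype_id)
  expect_true(all(ph == 5L))
})

test_that("healthy epithelial cells sit exactly on the crypt outline, oriented inward", {
  crypt <- make_test_crypt(a = 60, b = 60)
  set.seed(6)
  r_px <- 11
  d0 <- place_epithelial(crypt, 40, grade = 0, r_px = r_px)
  expect_equal(d0$x, d0$x0, tolerance = 1e-12)
  expect_equal(d0$y, d0$y0, tolerance = 1e-12)
  # circular crypt: orientation is the angle towards the centre
  ang <- atan2(crypt$centre[2] - d0$y, crypt$centre[1] - d0$x)
  expect_equal(d0$orientation, ang)
  # grade 3: per-axis displacement bounded by 0.75 r
  d3 <- place_epithelial(crypt, 200, grade = 3, r_px = r_px)
  expect_true(all(abs(d3$x - d3$x0) <= 0.75 * r_px + 1e-9))
  expect_true(all(abs(d3$y - d3$y0) <= 0.75 * r_px + 1e-9))
  expect_true(any(abs(d3$x - d3$x0) > 0))
})

test_that("stromal cells stay in the stroma with a bounded orientation spread", {
  i_h <- 100L
  crypt_mask <- as.integer(outer((30:60 - 1) * i_h, 30:60, "+"))
  stroma <- setdiff(seq_len(i_h * 100L), crypt_mask)
  set.seed(9)
  phi <- 1.2
  d <- place_stromal(10000, stroma, phi, i_h)
  idx <- (d$x - 1) * i_h + d$y
  expect_true(all(idx %in% stroma))
  expect_true(all(d$orientation >= phi - pi / 6 & d$orientation <= phi + pi / 6))
  expect_equal(mean(d$orientation), phi, tolerance = 0.02)
  expect_warning(out <- place_stromal(3, integer(0), phi, i_h), "empty stromal")
  expect_equal(nrow(out), 0L)
})

test_that("the placed population respects counts, containment and the overlap cap", {
  cfg <- small_config(image_height = 320L, image_width = 320L, seed = 77,
                      max_overlap = 0.4)
  sim <- simulate_image(cfg)
  cells <- sim$cells
  expect_equal(nrow(cells), sim$counts$N - nrow(sim$skips))
  expect_true(all(cells$x >= 1 & cells$x <= 320 & cells$y >= 1 & cells$y <= 320))
  # nucleus inside cytoplasm for the stated subtypes
  for (i in seq_len(nrow(cells))) {
    if (cells$subtype[i] %in% c("epithelial", "lymphocyte", "tumour")) {
      expect_true(all(sim$nucleus_masks[[i]] %in% sim$cytoplasm_masks[[i]]))
    }
  }
  ov <- check_overlap_invariant(sim)
  expect_true(ov$pass)
  expect_lte(ov$max_ratio, 0.4 + 1e-12)
})
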