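test_that("coverage fraction follows the grade bands", {
  expect_equal(crypt_coverage_fraction(0), 1)
  expect_equal(crypt_coverage_fraction(1), 1)
  set.seed(1)
  f2 <- replicate(50, crypt_coverage_fraction(2))
  expect_true(all(f2 >= 0.5 & f2 <= 0.95))
  f3 <- replicate(1e4, crypt_coverage_fraction(3))
  expect_true(all(f3 >= 0 & f3 <= 0.5))
  expect_equal(mean(f3), 0.25, tolerance = 0.02)
  expect_error(crypt_coverage_fraction(4), "grade")
})

test_that("crypt count tiles the image by nominal crypt blocks", {
  cfg <- simulation_config(image_height = 1000, image_width = 1000)
  expect_equal(crypt_count(cfg, mu_b_px = 100, f_c = 1), 25L)
  expect_equal(crypt_count(cfg, mu_b_px = 600, f_c = 1), 0L)   # image < 2 mu_b
  expect_equal(crypt_count(cfg, mu_b_px = 100, f_c = 0), 0L)
  expect_equal(crypt_count(cfg, mu_b_px = 100, f_c = 0.5), 12L) # rounded
  expect_error(crypt_count(cfg, mu_b_px = 0, f_c = 1), "mu_b")
})

test_that("crypt axes sampling respects the ratio constraint and recovers its Gamma", {
  cfg <- simulation_config()
  gp <- grade_params_for(default_grade_params(), 0)
  set.seed(11)
  draws <- replicate(5000, {
    ax <- sample_crypt_axes(gp, cfg)
    c(a = ax$a, b = ax$b, e = ax$e)
  })
  expect_true(all(draws["e", ] > 0.2 & draws["e", ] <= 1))
  expect_true(all(draws["b", ] <= draws["a", ]))
  # moment refit of the minor axis (back in micrometres) recovers the shape
  b_um <- pixels_to_microns(draws["b", ], cfg)
  shape_hat <- mean(b_um)^2 / stats::var(b_um)
  expect_lt(abs(shape_hat - gp$alpha_b) / gp$alpha_b, 0.15)
  # degenerate ratio parameters are refused
  bad <- gp; bad$alpha_e <- 0.0001; bad$beta_e <- 1e6
  expect_error(sample_crypt_axes(bad, cfg), "degenerate")
})

test_that("the crypt outline reduces to the rotated-ellipse radius", {
  set.seed(5)
  a <- 80; b <- 50; phi <- 0.7
  out <- crypt_outline(a, b, phi, grade = 0)
  base <- out$radius - out$u   # undeformed polar radius at the vertices
  expected <- a * b * sqrt(2) /
    sqrt((b^2 - a^2) * cos(2 * out$theta - 2 * phi) + a^2 + b^2)
  expect_equal(base, expected, tolerance = 1e-12)
  # at theta = phi the radius is a; at phi + pi/2 it is b
  expect_equal(a * b * sqrt(2) / sqrt((b^2 - a^2) * cos(0) + a^2 + b^2), a)
  expect_equal(a * b * sqrt(2) / sqrt((b^2 - a^2) * cos(pi) + a^2 + b^2), b)
  # circular crypt: all undeformed radii equal R
  out2 <- crypt_outline(60, 60, 0, grade = 0)
  expect_equal(out2$radius - out2$u, rep(60, length(out2$u)), tolerance = 1e-9)
})

test_that("deformation offsets scale as (S^2+1) under a shared seed", {
  mk <- function(S) { set.seed(123); crypt_outline(80, 50, 0, grade = S)$u }
  expect_equal(mk(3) / mk(0), rep(10, 72), tolerance = 1e-12)
  expect_equal(mk(2) / mk(0), rep(5, 72), tolerance = 1e-12)
})

test_that("outline deformation is bounded and the curve stays star-shaped", {
  set.seed(21)
  for (S in 0:3) {
    out <- crypt_outline(90, 45, 1.1, grade = S)
    expect_true(all(out$u >= -(S^2 + 1) * 0.06 * 45 - 1e-12))
    expect_true(all(out$u <= (S^2 + 1) * 0.1 * 45 + 1e-12))
    # star-shaped closure: dense radius stays positive
    d <- sqrt(rowSums(out$outline^2))
    expect_true(all(d > 0))
    expect_true(all(d < 1.5 * 90))
  }
})

test_that("healthy placement admits no crypt-mask overlap; grade 2 at most pairs", {
  cfg0 <- small_config(image_height = 360L, image_width = 360L, seed = 31)
  set.seed(cfg0$seed)
  arch0 <- place_crypts(cfg0)
  expect_gt(arch0$n_placed, 0L)
  counts <- table(unlist(lapply(arch0$crypts, `[[`, "mask")))
  expect_true(all(counts == 1))   # no pixel in two healthy crypts
  for (cr in arch0$crypts) {
    expect_true(all(cr$centre >= 1 & cr$centre <= 360))
  }

  cfg2 <- small_config(image_height = 420L, image_width = 420L, grade = 2L, seed = 17)
  set.seed(cfg2$seed)
  arch2 <- place_crypts(cfg2, f_c = 0.9)
  if (arch2$n_placed > 1L) {
    counts2 <- table(unlist(lapply(arch2$crypts, `[[`, "mask")))
    expect_true(all(counts2 <= 2))  # never three crypts on one pixel
    for (i in seq_along(arch2$crypts)) {
      for (j in seq_along(arch2$crypts)) {
        if (i >= j) next
        ov <- length(intersect(arch2$crypts[[i]]$mask, arch2$crypts[[j]]$mask))
        if (ov > 0) {
          expect_lte(ov, 0.5 * min(arch2$crypts[[i]]$area, arch2$crypts[[j]]$area))
          expect_equal(arch2$crypts[[i]]$gland_group, arch2$crypts[[j]]$gland_group)
        }
      }
    }
  }
  expect_s3_class(crypt_table(arch0$crypts), "data.frame")
  expect_equal(nrow(crypt_table(arch0$crypts)), arch0$n_placed)
})

test_that("healthy crypt coverage saturates near the hard-core packing limit", {
  # condition chosen so the nominal tiling has negligible floor loss
  # (2 mu_b divides the image side). Sequential placement of
  # non-overlapping ellipses cannot exceed the random sequential adsorption
  # jamming density (~0.55 for discs), so the sanity band is anchored there
  # rather than at the bounding-box fill ratio pi/4.
  gp <- data.frame(class = "healthy", mu_b = 27.5, alpha_b = 100,
                   beta_b = 0.275, alpha_e = 400, beta_e = 0.9 / 400)
  cfg <- simulation_config(image_height = 600L, image_width = 600L,
                           magnification = 20, grade = 0, seed = 8,
                           render = "layout")
  set.seed(cfg$seed)
  arch <- place_crypts(cfg, validate_grade_params(gp))
  cover <- sum(arch$label > 0L) / (600 * 600)
  expect_gt(arch$n_placed, 0.55 * arch$n_requested)
  expect_gt(cover, 0.42)
  expect_lt(cover, pi / 4 + 0.15)
})
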