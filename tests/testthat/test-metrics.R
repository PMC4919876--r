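test_that("pixel Dice handles the canonical cases", {
  m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
  expect_equal(dice_pixel(m, m), 1)
  n <- matrix(FALSE, 8, 8); n[6:8, 6:8] <- TRUE
  expect_equal(dice_pixel(m, n), 0)
  expect_equal(dice_pixel(c(1L, 2L), c(2L, 9L)), 0.5)   # |g|=|o|=2, overlap 1
  expect_equal(dice_pixel(integer(0), integer(0)), 1)   # both-empty convention
  expect_error(dice_pixel(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("object Dice collapses to pixel Dice for single objects", {
  g <- matrix(0L, 10, 10); g[2:6, 2:6] <- 1L
  o <- matrix(0L, 10, 10); o[4:8, 4:8] <- 1L
  expect_equal(dice_object(g, o), dice_pixel(g > 0, o > 0))
  expect_equal(dice_object(g, g), 1)
  disjoint <- matrix(0L, 10, 10); disjoint[9:10, 9:10] <- 1L
  expect_equal(dice_object(g, disjoint), 0)
  # empty prediction: truth half only
  empty <- matrix(0L, 10, 10)
  expect_equal(dice_object(g, empty), 0)
})

test_that("both Dice indices match brute-force oracles on 100 random instances", {
  set.seed(30)
  for (rep in 1:100) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    g <- random_label_image(h, w, sample.int(4, 1))
    o <- random_label_image(h, w, sample.int(4, 1))
    expect_equal(dice_pixel(g > 0, o > 0),
                 oracle_dice_pixel(which(g > 0), which(o > 0)),
                 tolerance = 1e-12)
    expect_equal(dice_object(g, o), oracle_dice_object(g, o), tolerance = 1e-12)
  }
})

test_that("moment-ellipse morphometrics recover axis ratios and are rotation invariant", {
  # digital circle of radius 20
  xy <- expand.grid(x = 1:64, y = 1:64)
  circ <- matrix((xy$x - 32)^2 + (xy$y - 32)^2 <= 20^2, 64, 64, byrow = FALSE)
  circ <- matrix(FALSE, 64, 64); circ[as.matrix(xy[ (xy$x-32)^2 + (xy$y-32)^2 <= 400, c("y","x")])] <- TRUE
  m <- ellipse_morphometrics(circ)
  expect_equal(m[["e"]], 1, tolerance = 0.02)
  expect_equal(m[["major"]], 40, tolerance = 1)
  # 2:1 ellipse
  ell <- matrix(FALSE, 80, 80)
  ell[as.matrix(xy[ ((xy$x-32)/30)^2 + ((xy$y-32)/15)^2 <= 1, c("y","x")])] <- TRUE
  m2 <- ellipse_morphometrics(ell)
  expect_equal(m2[["e"]], 0.5, tolerance = 0.05)
  # 90 degree rotation leaves the ratio unchanged
  m3 <- ellipse_morphometrics(t(ell))
  expect_equal(m3[["e"]], m2[["e"]], tolerance = 1e-9)
  expect_error(ellipse_morphometrics(matrix(FALSE, 4, 4)), "empty")
})

test_that("Gamma fitting recovers parameters and is scale equivariant", {
  set.seed(31)
  x <- rgamma(2000, shape = 4, scale = 10)
  fit <- fit_gamma(x)
  expect_gt(fit$shape, 3.4); expect_lt(fit$shape, 4.6)
  expect_true(is.finite(fit$loglik))
  fit_scaled <- fit_gamma(3 * x)
  expect_equal(fit_scaled$shape, fit$shape, tolerance = 1e-3)
  expect_equal(fit_scaled$scale, 3 * fit$scale, tolerance = 1e-3)
  expect_error(fit_gamma(rep(2, 100)), "degenerate")
  expect_error(fit_gamma(c(-1, rexp(50))), "positive")
  expect_error(fit_gamma(rexp(10)), "30")
})

test_that("GLCM features match hand-computed values on simple patches", {
  expect_warning(hc <- haralick13(matrix(0.5, 6, 6)), "constant")
  expect_equal(hc[["asm"]], 1)
  expect_equal(hc[["entropy"]], 0)
  expect_equal(hc[["correlation"]], 0)
  # checkerboard, 2 levels, offset (0,1): every horizontal transition differs
  cb <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  h <- haralick13(cb, levels = 2L, offsets = list(c(0L, 1L)))
  expect_equal(h[["contrast"]], 1)          # all pairs have |i-j| = 1
  expect_equal(h[["asm"]], 0.5)             # two off-diagonal cells at 1/2 each
  expect_equal(h[["idm"]], 0.5)
  # symmetric offsets: transpose invariance
  set.seed(32)
  patch <- matrix(runif(144), 12, 12)
  expect_equal(haralick13(patch), haralick13(t(patch)), tolerance = 1e-12)
  expect_length(haralick13(patch), 13L)
})

test_that("affinity propagation finds the obvious structure", {
  set.seed(33)
  blobs <- rbind(matrix(rnorm(40, 0, 0.15), 20, 2),
                 matrix(rnorm(40, 5, 0.15), 20, 2))
  res <- phenotype_cluster(blobs)
  expect_equal(length(res$exemplars), 2L)
  expect_true(same_partition(res$labels, rep(1:2, each = 20)))
  # single row and identical rows collapse to one cluster
  expect_equal(phenotype_cluster(matrix(1, 1, 3))$labels, 1L)
  expect_equal(unique(phenotype_cluster(matrix(1, 5, 3))$labels), 1L)
})

test_that("affinity propagation agrees with a naive message-passing oracle", {
  set.seed(34)
  x <- rbind(matrix(rnorm(20, 0, 0.2), 10, 2),
             matrix(rnorm(20, 4, 0.2), 10, 2))
  res <- phenotype_cluster(x, damping = 0.9)
  s <- -as.matrix(dist(x))^2
  pref <- median(s[row(s) != col(s)])
  diag(s) <- pref
  oracle <- oracle_affinity_propagation(s, damping = 0.9, iters = 300)
  expect_true(same_partition(res$labels, oracle$labels))
})

test_that("affinity propagation labels are invariant to row order", {
  set.seed(35)
  x <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
             matrix(rnorm(30, 6, 0.3), 15, 2))
  perm <- sample.int(30)
  a <- phenotype_cluster(x)$labels
  b <- phenotype_cluster(x[perm, ])$labels
  expect_true(same_partition(a[perm], b))
})

test_that("phenotype distribution comparison computes total variation", {
  same <- compare_phenotype_distributions(c(1, 1, 2, 3), c(1, 1, 2, 3))
  expect_equal(same$distance, 0)
  disjoint <- compare_phenotype_distributions(rep(1, 5), rep(2, 7))
  expect_equal(disjoint$distance, 1)
  part <- compare_phenotype_distributions(c(1, 1, 2, 2), c(1, 2, 2, 2))
  expect_equal(part$distance, 0.25)
  expect_error(compare_phenotype_distributions(integer(0), 1), "empty")
})
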